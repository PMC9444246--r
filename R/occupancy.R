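#' Truncate a template by labelled components
#'
#' Zeroes the voxels of the named components (`mode = "remove"`) or zeroes
#' everything else (`mode = "keep"`). Box, voxel size and origin are
#' unchanged, so poses determined with the full template remain valid.
#'
#' @param v A [volume()] with `component_labels`.
#' @param components Character vector of component labels.
#' @param mode `"remove"` or `"keep"`.
#' @return A new `tm2d_volume`.
#' @export
truncate_template <- function(v, components, mode = c("remove", "keep")) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "tm2d_volume"))
  unknown <- setdiff(components, names(v$component_labels))
  if (length(unknown)) {
    stop("unknown component label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- unlist(v$component_labels[components], use.names = FALSE)
  out <- v
  if (mode == "remove") {
    out$data[idx] <- 0
  } else {
    keep <- out$data
    out$data[] <- 0
    out$data[idx] <- keep[idx]
  }
  out
}

#' Change in fixed-pose SNR under template truncation
#'
#' For each matched target, evaluates [snr_at_pose()] with the full and the
#' truncated template at the identical pose (both standardised the same
#' way) and records `delta = snr_truncated - snr_full`. A target whose
#' particles contain the removed component loses SNR (negative delta); a
#' target lacking it gains (positive delta), because the truncated template
#' then matches it better per unit template norm.
#'
#' @param targets Tibble with columns `image_id, x_px, y_px, phi_deg,
#'   theta_deg, psi_deg, dz_A` and optionally `target_id` and `group`.
#' @param full,truncated The full and truncated [volume()] templates (same
#'   geometry).
#' @param micrographs A named list of [micrograph()] objects keyed by
#'   `image_id`, or a single micrograph.
#' @param component_removed Label recorded in the output.
#' @return A tibble of delta records: `target_id, template_id,
#'   component_removed, snr_full, snr_truncated, delta, group`.
#' @export
delta_snr <- function(targets, full, truncated, micrographs,
                      component_removed = "component") {
  stopifnot(inherits(full, "tm2d_volume"), inherits(truncated, "tm2d_volume"))
  if (full$box_size != truncated$box_size ||
      full$voxel_size != truncated$voxel_size) {
    stop("truncated template must share the full template's geometry",
         call. = FALSE)
  }
  if (inherits(micrographs, "tm2d_micrograph")) {
    micrographs <- setNames(list(micrographs), micrographs$image_id)
  }
  whitened <- lapply(micrographs, whiten_image)
  rows <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    m <- micrographs[[tg$image_id]]
    if (is.null(m)) stop("no micrograph for image_id '", tg$image_id, "'",
                         call. = FALSE)
    nx <- nrow(m$data); ny <- ncol(m$data)
    if (tg$x_px < 0 || tg$x_px >= nx || tg$y_px < 0 || tg$y_px >= ny) {
      warning("target ", i, " out of bounds; skipped")
      return(NULL)
    }
    p <- pose(tg$x_px, tg$y_px, tg$phi_deg, tg$theta_deg, tg$psi_deg,
              tg$dz_A %||% 0)
    wh <- whitened[[tg$image_id]]
    s_full <- snr_at_pose(m, full, p, whitened = wh)
    s_trunc <- snr_at_pose(m, truncated, p, whitened = wh)
    tibble::tibble(
      target_id = tg$target_id %||% i,
      template_id = full$template_id %||% "template",
      component_removed = component_removed,
      snr_full = s_full, snr_truncated = s_trunc,
      delta = s_trunc - s_full,
      group = tg$group %||% NA_character_
    )
  })
  rows
}

#' Compare two groups of values with a two-sample K-S test
#'
#' Two-sided two-sample Kolmogorov-Smirnov test (exact for small samples
#' without ties, asymptotic otherwise), as used to compare compartment-wise
#' SNR-ratio distributions.
#'
#' @param a,b Numeric vectors, each with at least 5 values.
#' @return A tibble: `statistic` (D), `p_value`, `n_a`, `n_b`, `method`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 5 || length(b) < 5) {
    stop("each group needs at least 5 values", call. = FALSE)
  }
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 n_a = length(a), n_b = length(b),
                 method = "two-sample Kolmogorov-Smirnov")
}
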