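#' Match detections from two searches to shared physical targets
#'
#' One-to-one greedy matching by ascending inter-detection distance: the
#' closest unmatched pair is accepted repeatedly until no pair within `tol`
#' remains. Symmetric in its two arguments.
#'
#' @param a,b Detection tibbles (from [extract_peaks()]) from the same image.
#' @param tol Maximum matching distance in pixels (> 0). Default 5 px, well
#'   under a typical template radius.
#' @return A list with `pairs` (tibble: `idx_a`, `idx_b`, `distance`),
#'   `unmatched_a` and `unmatched_b` (integer row indices).
#' @export
match_coordinates <- function(a, b, tol = 5) {
  stopifnot(tol > 0)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) {
    return(list(
      pairs = tibble::tibble(idx_a = integer(), idx_b = integer(),
                             distance = double()),
      unmatched_a = seq_len(na), unmatched_b = seq_len(nb)
    ))
  }
  dmat <- outer(a$x_px, b$x_px, "-")^2 + outer(a$y_px, b$y_px, "-")^2
  cand <- which(dmat <= tol^2)
  ord <- cand[order(dmat[cand])]
  used_a <- logical(na); used_b <- logical(nb)
  ia <- ib <- integer(0); dd <- numeric(0)
  for (k in ord) {
    i <- (k - 1L) %% na + 1L
    j <- (k - 1L) %/% na + 1L
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      ia <- c(ia, i); ib <- c(ib, j); dd <- c(dd, sqrt(dmat[k]))
    }
  }
  list(
    pairs = tibble::tibble(idx_a = ia, idx_b = ib, distance = dd),
    unmatched_a = which(!used_a), unmatched_b = which(!used_b)
  )
}

#' Log2 SNR-ratio vector of one target
#'
#' For a target scored against K templates, the classification feature is the
#' vector of `log2(snr_ref / snr_k)` over the K-1 non-reference templates, in
#' template order. Log2 is used instead of the direct ratio so that swapping
#' numerator and denominator only mirrors the distribution about 0.
#'
#' @param snrs Numeric vector of K positive SNRs.
#' @param reference_index Index of the reference template (default 1).
#' @return Numeric vector of length K-1.
#' @export
ratio_vector <- function(snrs, reference_index = 1L) {
  if (any(!is.finite(snrs)) || any(snrs <= 0)) {
    stop("all SNRs must be positive and finite to form log2 ratios",
         call. = FALSE)
  }
  stopifnot(reference_index >= 1L, reference_index <= length(snrs))
  log2(snrs[reference_index] / snrs[-reference_index])
}

#' Number of ways a template can align to a detected target
#'
#' With an error of up to +/- one step in each positional and angular degree
#' of freedom, each degree of freedom contributes `options_per_dof`
#' possibilities (e.g. 3 for -1/0/+1), so the count is
#' `options_per_dof ^ (n_positional_dof + n_angular_dof)`. The defaults (2
#' positional + 3 angular, 3 options each) give 243.
#'
#' @param n_positional_dof Positional degrees of freedom (default 2: x, y).
#' @param n_angular_dof Angular degrees of freedom (default 3).
#' @param options_per_dof Discrete options per degree of freedom (default 3).
#' @return The configuration count.
#' @export
alignment_configurations <- function(n_positional_dof = 2L,
                                     n_angular_dof = 3L,
                                     options_per_dof = 3L) {
  stopifnot(n_positional_dof >= 0, n_angular_dof >= 0, options_per_dof >= 0)
  options_per_dof^(n_positional_dof + n_angular_dof)
}

#' Apparent noise SNR from alignment overfitting
#'
#' The expected maximum of `m` standard normal noise correlations grows as
#' `sqrt(2 * ln(m))`; this is the apparent SNR a template gains by partially
#' aligning itself to noise across `m_configs` alignment configurations.
#' At the 243 configurations of [alignment_configurations()] defaults it is
#' 3.31.
#'
#' @param m_configs Number of alignment configurations (>= 1).
#' @return The noise SNR (0 when `m_configs` is 1).
#' @export
noise_snr <- function(m_configs) {
  if (any(m_configs < 1)) stop("m_configs must be >= 1", call. = FALSE)
  sqrt(2 * log(m_configs))
}

#' Signal part of an observed SNR
#'
#' The observed SNR decomposes as `SNR_o = SNR_s + SNR_n`, where the noise
#' bias `SNR_n` comes from alignment overfitting ([noise_snr()]). Returns
#' `SNR_s = SNR_o - SNR_n`, floored at 0 with a warning when the observation
#' sits below the noise floor.
#'
#' @param observed Observed SNR.
#' @param m_configs Number of alignment configurations.
#' @return The signal SNR.
#' @export
signal_snr <- function(observed, m_configs) {
  sn <- noise_snr(m_configs)
  s <- observed - sn
  if (any(s < 0)) {
    warning("observed SNR below the overfitting noise floor; returning 0")
    s[s < 0] <- 0
  }
  s
}

#' Histograms of sub-threshold SNR values per compartment
#'
#' For each compartment label in the mask, locates a `box` x `box` window
#' fully inside the compartment (first such window in x-then-y scan order),
#' and histograms the MIP values below `threshold` within it with fixed-width
#' bins anchored at 0. Regions that cannot fit the box are skipped with a
#' warning.
#'
#' @param maps A `tm2d_snr_maps` object.
#' @param mask Character matrix of compartment labels, same shape as the MIP.
#' @param box Window edge in pixels.
#' @param bin_width Histogram bin width in SNR units.
#' @param threshold Values at or above this SNR are excluded.
#' @return A tibble: `region, bin_left, bin_right, bin_mid, count`.
#' @export
region_histogram <- function(maps, mask, box, bin_width, threshold) {
  stopifnot(inherits(maps, "tm2d_snr_maps"),
            identical(dim(mask), dim(maps$mip)), box >= 1, bin_width > 0)
  regions <- sort(unique(as.character(mask)))
  out <- purrr::map_dfr(regions, function(reg) {
    ind <- matrix(as.numeric(mask == reg), nrow(mask), ncol(mask))
    # summed-area table to find a fully-interior window
    sat <- apply(apply(ind, 2, cumsum), 1, cumsum)  # sat[y, x] after transpose
    sat <- t(sat)
    nx <- nrow(ind); ny <- ncol(ind)
    if (nx < box || ny < box) {
      warning("region '", reg, "' smaller than the box; skipped")
      return(NULL)
    }
    win_sum <- function(x0, y0) {  # 1-based top-left corner
      x1 <- x0 + box - 1L; y1 <- y0 + box - 1L
      s <- sat[x1, y1]
      if (x0 > 1) s <- s - sat[x0 - 1L, y1]
      if (y0 > 1) s <- s - sat[x1, y0 - 1L]
      if (x0 > 1 && y0 > 1) s <- s + sat[x0 - 1L, y0 - 1L]
      s
    }
    found <- NULL
    for (y0 in seq_len(ny - box + 1L)) {
      for (x0 in seq_len(nx - box + 1L)) {
        if (win_sum(x0, y0) == box^2) { found <- c(x0, y0); break }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      warning("region '", reg, "' has no ", box, "x", box,
              " interior window; skipped")
      return(NULL)
    }
    vals <- maps$mip[found[1] + 0:(box - 1L), found[2] + 0:(box - 1L)]
    vals <- vals[vals < threshold]
    if (!length(vals)) {
      return(tibble::tibble(region = reg, bin_left = double(),
                            bin_right = double(), bin_mid = double(),
                            count = integer()))
    }
    breaks <- seq(floor(min(vals) / bin_width) * bin_width,
                  ceiling(max(vals) / bin_width) * bin_width +
                    bin_width / 2, by = bin_width)
    h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
    tibble::tibble(region = reg, bin_left = h$breaks[-length(h$breaks)],
                   bin_right = h$breaks[-1], bin_mid = h$mids,
                   count = h$counts)
  })
  out
}

#' Particle density in a compartment
#'
#' @param detections Detection tibble (or anything with rows).
#' @param mask_area Compartment area in square micrometres (> 0).
#' @param thickness Sample thickness in micrometres (> 0).
#' @return Particles per cubic micrometre.
#' @export
particle_density <- function(detections, mask_area, thickness) {
  stopifnot(mask_area > 0, thickness > 0)
  nrow(detections) / (mask_area * thickness)
}

#' Extrapolate a compartment density to a per-cell count
#'
#' @param density Particles per cubic micrometre.
#' @param cell_volume Cell volume in cubic micrometres.
#' @param fraction Fraction of the cell volume occupied by the compartment,
#'   in `[0, 1]`.
#' @return Estimated particles per cell.
#' @export
per_cell_count <- function(density, cell_volume, fraction) {
  stopifnot(density >= 0, cell_volume > 0, fraction >= 0, fraction <= 1)
  density * cell_volume * fraction
}

#' Build a matched-target table from per-template SNRs
#'
#' Combines per-template SNR columns into the tidy per-target table used by
#' the classifier: one row per physical target, `snr_<template>` columns, and
#' `x_<template>` log2-ratio columns relative to the reference (first)
#' template. Targets with any non-positive SNR get `NA` ratios (and are
#' excluded from classification downstream).
#'
#' @param df Tibble with one row per target, containing `snr_<name>` columns.
#' @param templates Character vector of template names, reference first.
#' @return `df` with appended ratio columns `x_<name>` for the non-reference
#'   templates.
#' @export
add_ratio_columns <- function(df, templates) {
  stopifnot(length(templates) >= 2)
  snr_cols <- paste0("snr_", templates)
  if (!all(snr_cols %in% names(df))) {
    stop("missing SNR columns: ",
         paste(setdiff(snr_cols, names(df)), collapse = ", "), call. = FALSE)
  }
  ref <- df[[snr_cols[1]]]
  for (k in seq_along(templates)[-1]) {
    v <- df[[snr_cols[k]]]
    x <- rep(NA_real_, length(ref))
    ok <- !is.na(ref) & !is.na(v) & ref > 0 & v > 0
    x[ok] <- log2(ref[ok] / v[ok])
    df[[paste0("x_", templates[k])]] <- x
  }
  df
}
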