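#' Configuration of an end-to-end classification run
#'
#' @param grid Coarse [search_grid()] for the reference-template search.
#' @param expected_false_positives Expected false positives per image used
#'   to set the detection threshold (default 1).
#' @param match_tol Coordinate-matching tolerance in pixels (default 5).
#' @param K Number of mixture classes (default 2).
#' @param init_priors Optional initial class priors.
#' @param prior_mode `"updated"` or `"fixed"` (see [fit_mixture()]).
#' @param confidence Posterior confidence threshold in `[0.5, 1)`.
#' @param min_separation Peak exclusion radius in pixels (default: template
#'   radius).
#' @param refine Logical: refine detected poses before scoring alternates.
#' @param fine_grid Fine [search_grid()] used when `refine = TRUE`.
#' @param alt_search `"full"` (default): every template gets its own
#'   exhaustive search and targets are reconciled by coordinate matching,
#'   so each template's SNR carries the same search-maximisation bias and
#'   the log2 ratios stay unbiased. `"fixed"`: alternates are evaluated at
#'   the reference poses only (faster; ratios biased toward the reference
#'   template by the overfitting noise SNR).
#' @param seed RNG seed recorded with the run.
#' @return A `tm2d_run_config` list, serialisable with [yaml::as.yaml()].
#' @export
run_config <- function(grid = search_grid(), expected_false_positives = 1,
                       match_tol = 5, K = 2L, init_priors = NULL,
                       prior_mode = "updated", confidence = 0.5,
                       min_separation = NULL, refine = FALSE,
                       fine_grid = NULL, alt_search = c("full", "fixed"),
                       seed = 1L) {
  alt_search <- match.arg(alt_search)
  structure(
    list(grid = grid, expected_false_positives = expected_false_positives,
         match_tol = match_tol, K = K, init_priors = init_priors,
         prior_mode = prior_mode, confidence = confidence,
         min_separation = min_separation, refine = refine,
         fine_grid = fine_grid, alt_search = alt_search, seed = seed),
    class = "tm2d_run_config"
  )
}

#' Run the full search - match - ratio - classify pipeline
#'
#' For every image, runs the exhaustive 2DTM search with the reference
#' (first) template, thresholds at the expected-false-positive level,
#' extracts peaks, and scores the alternate templates. By default every
#' template gets its own exhaustive search and detections are reconciled
#' with [match_coordinates()], so all SNRs carry the same maximisation bias
#' and the log2 ratios are unbiased; with `alt_search = "fixed"` alternates
#' are instead evaluated at the reference poses only. Targets with positive SNR under every template form the
#' matched-target table with log2 SNR-ratio columns; a Gaussian mixture is
#' fitted to the ratios and every target receives Bayes posteriors, a
#' confidence-thresholded class label, and (for comparison) the simple
#' argmax-SNR label.
#'
#' @param images A [micrograph()] or list of micrographs.
#' @param templates Named list of [volume()] templates; the first is the
#'   reference whose search defines target positions and poses.
#' @param config A [run_config()].
#' @return A `tm2d_report`: `targets` (all detections with per-template
#'   SNRs and ratios), `assignments` (posterior + argmax labels for
#'   classified targets), `model` (`tm2d_mixture`), `thresholds` (per-image
#'   search summary), `config`, `log`.
#' @export
run_pipeline <- function(images, templates, config = run_config()) {
  stopifnot(inherits(config, "tm2d_run_config"))
  if (inherits(images, "tm2d_micrograph")) images <- list(images)
  if (length(templates) < 2 || is.null(names(templates))) {
    stop("need >= 2 named templates for classification", call. = FALSE)
  }
  set.seed(config$seed)
  tpl_names <- names(templates)
  ref_name <- tpl_names[1]
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  say("run seed=", config$seed, " reference=", ref_name,
      " templates=", paste(tpl_names, collapse = ","))

  thresholds <- NULL
  targets <- NULL
  for (m in images) {
    maps <- run_search(m, templates[[ref_name]], config$grid,
                       template_id = ref_name)
    thr <- detection_threshold(maps$n_correlations,
                               config$expected_false_positives)
    det <- extract_peaks(maps, thr, min_separation = config$min_separation)
    say("image=", maps$image_id, " n_correlations=", maps$n_correlations,
        " threshold=", round(thr, 4), " detections=", nrow(det))
    thresholds <- dplyr::bind_rows(thresholds, tibble::tibble(
      image_id = maps$image_id, n_correlations = maps$n_correlations,
      threshold = thr, n_detections = nrow(det)
    ))
    if (!nrow(det)) next
    if (config$refine && !is.null(config$fine_grid)) {
      det <- purrr::map_dfr(seq_len(nrow(det)), function(i) {
        refine_pose(m, templates[[ref_name]], det[i, ], config$fine_grid,
                    coarse = config$grid, whitened = maps$whitened)
      })
    }
    snr_cols <- list()
    snr_cols[[paste0("snr_", ref_name)]] <- det$snr
    keep <- rep(TRUE, nrow(det))
    for (alt in tpl_names[-1]) {
      if (config$alt_search == "full") {
        # search the alternate exhaustively and reconcile coordinates, so
        # both SNRs carry the same search-maximisation bias
        alt_maps <- run_search(m, templates[[alt]], config$grid,
                               template_id = alt)
        alt_thr <- detection_threshold(alt_maps$n_correlations,
                                       config$expected_false_positives)
        alt_det <- extract_peaks(alt_maps, alt_thr,
                                 min_separation = config$min_separation)
        mm <- match_coordinates(det, alt_det, tol = config$match_tol)
        if (config$refine && !is.null(config$fine_grid) &&
            nrow(mm$pairs)) {
          refined <- purrr::map_dfr(mm$pairs$idx_b, function(i) {
            refine_pose(m, templates[[alt]], alt_det[i, ],
                        config$fine_grid, coarse = config$grid,
                        whitened = alt_maps$whitened)
          })
          alt_det[mm$pairs$idx_b, ] <- refined
        }
        snr <- rep(NA_real_, nrow(det))
        snr[mm$pairs$idx_a] <- alt_det$snr[mm$pairs$idx_b]
        keep <- keep & !is.na(snr)
        snr_cols[[paste0("snr_", alt)]] <- snr
        say("image=", maps$image_id, " alt=", alt, " detections=",
            nrow(alt_det), " matched=", nrow(mm$pairs))
      } else {
        snr_cols[[paste0("snr_", alt)]] <-
          vapply(seq_len(nrow(det)), function(i) {
            snr_at_pose(m, templates[[alt]],
                        pose(det$x_px[i], det$y_px[i], det$phi_deg[i],
                             det$theta_deg[i], det$psi_deg[i],
                             det$dz_A[i]),
                        whitened = maps$whitened)
          }, 0)
      }
    }
    comp <- if (!is.null(m$mask)) {
      m$mask[cbind(det$x_px + 1L, det$y_px + 1L)]
    } else {
      NA_character_
    }
    targets <- dplyr::bind_rows(targets, dplyr::bind_cols(
      det[, c("image_id", "x_px", "y_px", "phi_deg", "theta_deg",
              "psi_deg", "dz_A")],
      tibble::tibble(compartment = comp),
      tibble::as_tibble(snr_cols)
    ))
  }
  if (is.null(targets) || !nrow(targets)) {
    stop("[search] no significant targets in any image", call. = FALSE)
  }
  targets <- dplyr::mutate(targets,
                           target_id = dplyr::row_number(), .before = 1)
  targets <- add_ratio_columns(targets, tpl_names)
  ratio_cols <- paste0("x_", tpl_names[-1])
  ok <- stats::complete.cases(targets[, ratio_cols])
  say("targets=", nrow(targets), " classified=", sum(ok),
      " (positive SNR under every template)")
  X <- as.matrix(targets[ok, ratio_cols])
  model <- fit_mixture(X, K = config$K, init_priors = config$init_priors,
                       prior_mode = config$prior_mode)
  say("mixture: loglik=", round(max(model$loglik_trace), 3),
      " iterations=", length(model$loglik_trace),
      " converged=", model$converged)
  assignments <- classify(model, X, confidence = config$confidence,
                          target_id = targets$target_id[ok])
  snr_mat <- as.matrix(targets[ok, paste0("snr_", tpl_names)])
  assignments$argmax_template <- tpl_names[max.col(snr_mat,
                                                   ties.method = "first")]
  assignments <- dplyr::left_join(
    assignments,
    targets[, c("target_id", "image_id", "compartment", ratio_cols)],
    by = "target_id"
  )
  structure(
    list(targets = targets, assignments = assignments, model = model,
         thresholds = thresholds, config = config, log = log_lines),
    class = "tm2d_report"
  )
}

#' @export
print.tm2d_report <- function(x, ...) {
  cat("<tm2d_report> ", nrow(x$targets), " targets over ",
      nrow(x$thresholds), " image(s); ", nrow(x$assignments),
      " classified into ", x$model$K, " classes\n", sep = "")
  counts <- table(x$assignments$label)
  for (nm in names(counts)) cat("  ", nm, ": ", counts[[nm]], "\n", sep = "")
  invisible(x)
}
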