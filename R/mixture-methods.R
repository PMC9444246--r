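#' Tidy a fitted mixture model
#'
#' One row per component: mixing proportion, means and (co)variances.
#'
#' @param x A `tm2d_mixture`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `prior`, `mean_1..d` and
#'   `var_1..d` (diagonal of the covariance).
#' @exportS3Method generics::tidy
tidy.tm2d_mixture <- function(x, ...) {
  d <- x$d
  out <- tibble::tibble(component = x$component_names, prior = x$priors)
  for (j in seq_len(d)) {
    out[[paste0("mean_", j)]] <- vapply(x$means, `[`, 0, j)
    out[[paste0("var_", j)]] <- vapply(x$covariances, function(s) s[j, j], 0)
  }
  out
}

#' Glance at a fitted mixture model
#'
#' @param x A `tm2d_mixture`.
#' @param ... Unused.
#' @return A one-row tibble: `K`, `d`, `n`, `log_lik`, `iterations`,
#'   `converged`, `prior_mode`.
#' @exportS3Method generics::glance
glance.tm2d_mixture <- function(x, ...) {
  tibble::tibble(
    K = x$K, d = x$d, n = x$n,
    log_lik = if (length(x$loglik_trace)) max(x$loglik_trace) else NA_real_,
    iterations = length(x$loglik_trace),
    converged = x$converged, prior_mode = x$prior_mode
  )
}

#' @export
print.tm2d_mixture <- function(x, ...) {
  cat("<tm2d_mixture> K=", x$K, ", d=", x$d,
      if (length(x$loglik_trace)) {
        paste0(", loglik=", round(max(x$loglik_trace), 3),
               ", iterations=", length(x$loglik_trace),
               ", converged=", x$converged)
      } else ", not fitted", "\n", sep = "")
  print(tidy.tm2d_mixture(x))
  invisible(x)
}

#' Plot a 1D mixture fit over the ratio histogram
#'
#' Histogram of the log2 SNR ratios with the fitted per-component Gaussian
#' densities and their sum overlaid, in the style of a mixture-fit figure.
#'
#' @param object A fitted `tm2d_mixture` with `d = 1`.
#' @param X The ratio data used for the fit (vector or N x 1 matrix).
#' @param bin_width Histogram bin width (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tm2d_mixture <- function(object, X, bin_width = 0.05, ...) {
  stopifnot(object$d == 1)
  x <- as.numeric(as_ratio_matrix(X))
  n <- length(x)
  grid_x <- seq(min(x) - 2 * bin_width, max(x) + 2 * bin_width,
                length.out = 400)
  comp <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble::tibble(
      x = grid_x, component = object$component_names[k],
      density = n * bin_width * object$priors[k] *
        stats::dnorm(grid_x, object$means[[k]][1],
                     sqrt(object$covariances[[k]][1, 1]))
    )
  })
  total <- comp |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(x = x),
      ggplot2::aes(x = .data$x), binwidth = bin_width,
      fill = "grey85", colour = "grey60"
    ) +
    ggplot2::geom_line(
      data = comp,
      ggplot2::aes(x = .data$x, y = .data$density,
                   colour = .data$component),
      linetype = "dashed"
    ) +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::labs(x = "log2 SNR ratio", y = "targets per bin",
                  colour = "component") +
    ggplot2::theme_minimal()
}

#' Plot an SNR map
#'
#' Renders the maximum-intensity-projection SNR map of a search as a raster.
#'
#' @param object A `tm2d_snr_maps` object.
#' @param threshold Optional SNR threshold; detected peaks above it are
#'   circled.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tm2d_snr_maps <- function(object, threshold = NULL, ...) {
  df <- tibble::tibble(
    x = rep(0:(nrow(object$mip) - 1), ncol(object$mip)),
    y = rep(0:(ncol(object$mip) - 1), each = nrow(object$mip)),
    snr = as.numeric(object$mip)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$snr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "2DTM SNR") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    pk <- extract_peaks(object, threshold)
    if (nrow(pk)) {
      p <- p + ggplot2::geom_point(
        data = pk, ggplot2::aes(x = .data$x_px, y = .data$y_px),
        inherit.aes = FALSE, shape = 1, colour = "red", size = 3
      )
    }
  }
  p
}
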