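# TSV tables (tab-separated, header row, UTF-8, '.' decimal) for detections
# and matched targets; JSON for mixture models.

#' Write / read a detection table
#'
#' @param detections Detection tibble (see [extract_peaks()]).
#' @param path TSV file path.
#' @return `path` invisibly; `read_detections()` returns the tibble.
#' @export
write_detections <- function(detections, path) {
  readr::write_tsv(detections, path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Serialise a mixture model to JSON
#'
#' @param model A `tm2d_mixture`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_mixture_json()` returns the model.
#' @export
write_mixture_json <- function(model, path) {
  stopifnot(inherits(model, "tm2d_mixture"))
  obj <- list(
    K = model$K, d = model$d, priors = model$priors,
    means = model$means,
    covariances = lapply(model$covariances, function(s) as.numeric(s)),
    loglik_trace = model$loglik_trace,
    converged = model$converged, prior_mode = model$prior_mode,
    n = model$n, component_names = model$component_names
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture_json
#' @export
read_mixture_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$d
  means <- if (is.matrix(obj$means)) {
    lapply(seq_len(nrow(obj$means)), function(i) obj$means[i, ])
  } else {
    as.list(obj$means)
  }
  covs <- if (is.matrix(obj$covariances)) {
    lapply(seq_len(nrow(obj$covariances)), function(i) {
      matrix(obj$covariances[i, ], d, d)
    })
  } else {
    lapply(obj$covariances, function(v) matrix(v, d, d))
  }
  structure(
    list(K = obj$K, d = d, priors = obj$priors, means = means,
         covariances = covs, loglik_trace = obj$loglik_trace %||% numeric(0),
         converged = obj$converged, prior_mode = obj$prior_mode,
         n = obj$n %||% 0L,
         ridge = 0,
         component_names = obj$component_names),
    class = "tm2d_mixture"
  )
}
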