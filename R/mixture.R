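#' Multivariate Gaussian log-density
#'
#' Standard multivariate normal log-density, evaluated via the Cholesky
#' factor of the covariance. Near-singular covariances are ridge-regularised
#' with a warning.
#'
#' @param x Numeric vector of length d, or an N x d matrix of rows.
#' @param m Mean vector of length d.
#' @param sigma d x d symmetric positive-definite covariance.
#' @return Log-density (scalar or length-N vector).
#' @export
gaussian_logpdf <- function(x, m, sigma) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  d <- length(m)
  sigma <- matrix(sigma, d, d)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    warning("covariance is singular; adding a small ridge")
    ridge <- 1e-8 * mean(diag(sigma)) + 1e-12
    ch <- chol(sigma + diag(ridge, d))
  }
  centred <- sweep(x, 2, m)
  z <- backsolve(ch, t(centred), transpose = TRUE)
  quad <- colSums(z^2)
  logdet <- 2 * sum(log(diag(ch)))
  out <- -0.5 * (d * log(2 * pi) + logdet + quad)
  if (length(out) == 1L) out[[1]] else out
}

# log-sum-exp over the columns of a matrix of log-values (rowwise)
logsumexp_rows <- function(lp) {
  mx <- apply(lp, 1, max)
  mx + log(rowSums(exp(lp - mx)))
}

# N x K matrix of log(pi_k) + log N(x; M_k, Sigma_k)
component_logdens <- function(model, X) {
  K <- model$K
  lp <- vapply(seq_len(K), function(k) {
    log(model$priors[k]) +
      gaussian_logpdf(X, model$means[[k]], model$covariances[[k]])
  }, numeric(nrow(X)))
  matrix(lp, nrow = nrow(X), ncol = K)
}

as_ratio_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("ratio matrix contains NA", call. = FALSE)
  X
}

#' Fit a Gaussian mixture to log2 SNR-ratio vectors by EM
#'
#' Maximum-likelihood K-component multivariate Gaussian mixture over the
#' N x d matrix of per-target log2 SNR ratios (d = number of templates - 1).
#' The E-step computes Bayes-rule responsibilities; the M-step updates
#' priors (mean responsibility), means (responsibility-weighted mean) and
#' covariances (responsibility-weighted scatter). With
#' `prior_mode = "fixed"` the prior update is skipped and the mixing
#' proportions stay at `init_priors` (e.g. compartment-derived priors).
#' All density arithmetic is in log space.
#'
#' Initialisation is deterministic: component means at the `(k - 0.5)/K`
#' marginal quantiles, covariances at the pooled sample covariance, priors
#' at `init_priors` (or uniform).
#'
#' @param X N x d numeric matrix (or data frame / vector for d = 1).
#' @param K Number of classes (>= 1).
#' @param init_priors Optional length-K initial mixing proportions
#'   (positive, summing to 1).
#' @param prior_mode `"updated"` (full EM) or `"fixed"`.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the total log-likelihood change,
#'   scaled by N.
#' @param ridge Fraction of the pooled variance added to covariance
#'   diagonals to prevent singularity.
#' @param component_names Optional length-K labels (default `class_1`, ...).
#' @return An object of class `tm2d_mixture`: `K`, `d`, `priors`, `means`
#'   (list of d-vectors), `covariances` (list of d x d matrices),
#'   `loglik_trace`, `converged`, `prior_mode`, `n`, `component_names`.
#' @export
fit_mixture <- function(X, K = 2L, init_priors = NULL,
                        prior_mode = c("updated", "fixed"),
                        max_iter = 500L, tol = 1e-8, ridge = 1e-6,
                        component_names = NULL) {
  prior_mode <- match.arg(prior_mode)
  X <- as_ratio_matrix(X)
  N <- nrow(X); d <- ncol(X)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (N <= K * d) {
    stop("too few targets (", N, ") to fit ", K, " components in ", d,
         " dimensions", call. = FALSE)
  }
  if (is.null(init_priors)) init_priors <- rep(1 / K, K)
  if (length(init_priors) != K || any(init_priors <= 0)) {
    stop("init_priors must be K positive values", call. = FALSE)
  }
  init_priors <- init_priors / sum(init_priors)
  component_names <- component_names %||% paste0("class_", seq_len(K))

  pooled <- cov(X)
  if (d == 1 && !is.matrix(pooled)) pooled <- matrix(pooled, 1, 1)
  ridge_abs <- ridge * mean(diag(pooled)) + 1e-300
  pooled <- pooled + diag(ridge_abs, d)

  em_run <- function(means) {
    covs <- rep(list(pooled), K)
    priors <- init_priors
    loglik_trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      model <- list(K = K, d = d, priors = priors, means = means,
                    covariances = covs)
      lp <- component_logdens(model, X)
      lse <- logsumexp_rows(lp)
      loglik_trace <- c(loglik_trace, sum(lse))
      resp <- exp(lp - lse)  # N x K responsibilities
      nk <- pmax(colSums(resp), 1e-12)
      if (prior_mode == "updated") priors <- nk / N
      means <- lapply(seq_len(K), function(k) {
        colSums(X * resp[, k]) / nk[k]
      })
      covs <- lapply(seq_len(K), function(k) {
        c_ <- sweep(X, 2, means[[k]])
        s <- crossprod(c_ * resp[, k], c_) / nk[k]
        s <- (s + t(s)) / 2
        s + diag(ridge_abs, d)
      })
      if (iter > 1 &&
          abs(loglik_trace[iter] - loglik_trace[iter - 1]) < tol * N) {
        converged <- TRUE
        break
      }
    }
    list(priors = priors, means = means, covs = covs,
         loglik_trace = loglik_trace, converged = converged)
  }

  # Deterministic multi-start: a rare component can sit in either tail, so a
  # single marginal-quantile initialisation may split the dominant mode
  # instead; EM is run from each candidate and the best likelihood kept.
  q_at <- function(p) apply(X, 2, quantile, probs = p, names = FALSE, type = 7)
  prior_mass_init <- function(ord) {
    cm <- cumsum(init_priors[ord]) - init_priors[ord] / 2
    means <- vector("list", K)
    means[ord] <- lapply(cm, q_at)
    means
  }
  inits <- list(
    lapply(seq_len(K), function(k) q_at((k - 0.5) / K)),
    prior_mass_init(seq_len(K)),
    prior_mass_init(rev(seq_len(K)))
  )
  inits <- inits[!duplicated(lapply(inits, unlist))]
  fits <- lapply(inits, em_run)
  best <- fits[[which.max(vapply(fits, function(f) max(f$loglik_trace), 0))]]

  structure(
    list(K = K, d = d, priors = best$priors, means = best$means,
         covariances = best$covs, loglik_trace = best$loglik_trace,
         converged = best$converged, prior_mode = prior_mode, n = N,
         ridge = ridge_abs, component_names = component_names),
    class = "tm2d_mixture"
  )
}

#' Posterior class probabilities under a fitted mixture
#'
#' Bayes-rule posteriors
#' `P(z = k | x) = pi_k N(x; M_k, S_k) / sum_j pi_j N(x; M_j, S_j)`,
#' computed in log space.
#'
#' @param model A `tm2d_mixture`.
#' @param x A d-vector, or an N x d matrix of ratio vectors.
#' @return A length-K probability vector, or an N x K matrix.
#' @export
posterior <- function(model, x) {
  stopifnot(inherits(model, "tm2d_mixture"))
  X <- as_ratio_matrix(x)
  lp <- component_logdens(model, X)
  p <- exp(lp - logsumexp_rows(lp))
  colnames(p) <- model$component_names
  if (nrow(p) == 1L && (is.vector(x) && length(x) == model$d)) p[1, ] else p
}

#' Classify targets with a posterior confidence threshold
#'
#' Assigns each target to the class with the highest posterior probability
#' when that posterior reaches `confidence`; targets below the threshold are
#' labelled `"unassigned"`. At `confidence = 0.5` with K = 2 this reduces to
#' the equal-posterior decision boundary.
#'
#' @param model A fitted `tm2d_mixture`.
#' @param X N x d ratio matrix (or vector for d = 1).
#' @param confidence Posterior threshold in `[0.5, 1)`.
#' @param target_id Optional identifiers (default row numbers).
#' @return A tibble: `target_id`, one `p_<class>` column per component,
#'   `max_posterior`, `label`, `confidence_threshold`.
#' @export
classify <- function(model, X, confidence = 0.5, target_id = NULL) {
  stopifnot(inherits(model, "tm2d_mixture"),
            confidence >= 0.5, confidence < 1)
  X <- as_ratio_matrix(X)
  p <- posterior(model, X)
  p <- matrix(p, ncol = model$K,
              dimnames = list(NULL, model$component_names))
  imax <- max.col(p, ties.method = "first")
  pmax_ <- p[cbind(seq_len(nrow(p)), imax)]
  label <- ifelse(pmax_ >= confidence, model$component_names[imax],
                  "unassigned")
  out <- tibble::tibble(target_id = target_id %||% seq_len(nrow(p)))
  for (k in seq_len(model$K)) {
    out[[paste0("p_", model$component_names[k])]] <- p[, k]
  }
  out$max_posterior <- pmax_
  out$label <- label
  out$confidence_threshold <- confidence
  out
}

#' Histogram goodness of fit of a 1D mixture
#'
#' Coefficient of determination between observed histogram counts (fixed-
#' width bins spanning the data range) and the expected counts under the
#' fitted mixture (`N` times the bin integral of the mixture density).
#'
#' @param X Numeric vector (or N x 1 matrix) of log2 SNR ratios.
#' @param model A fitted `tm2d_mixture` with d = 1.
#' @param bin_width Histogram bin width (default 0.05).
#' @return R-squared. A warning is raised if fewer than 5 bins are occupied.
#' @export
fit_quality_r2 <- function(X, model, bin_width = 0.05) {
  stopifnot(inherits(model, "tm2d_mixture"))
  if (model$d != 1) stop("fit_quality_r2 requires a 1-dimensional model",
                         call. = FALSE)
  x <- as.numeric(as_ratio_matrix(X))
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  obs <- h$counts
  if (sum(obs > 0) < 5) {
    warning("fewer than 5 occupied histogram bins; R^2 is unstable")
  }
  cdf <- function(q) {
    Reduce(`+`, lapply(seq_len(model$K), function(k) {
      model$priors[k] * pnorm(q, model$means[[k]][1],
                              sqrt(model$covariances[[k]][1, 1]))
    }))
  }
  expd <- length(x) * diff(cdf(h$breaks))
  1 - sum((obs - expd)^2) / sum((obs - mean(obs))^2)
}

#' Draw synthetic ratio vectors from a mixture model
#'
#' Labels are drawn from the mixing proportions and vectors from the
#' corresponding Gaussian component; reproducible given `seed`.
#'
#' @param model A `tm2d_mixture` (fitted or constructed).
#' @param n Number of draws.
#' @param seed Optional RNG seed.
#' @return A list with `X` (n x d matrix) and `labels` (integer component
#'   indices).
#' @export
simulate_ratio_data <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "tm2d_mixture"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- model$d
  labels <- sample.int(model$K, n, replace = TRUE, prob = model$priors)
  X <- matrix(0, n, d)
  for (k in seq_len(model$K)) {
    idx <- which(labels == k)
    if (!length(idx)) next
    ch <- chol(matrix(model$covariances[[k]], d, d))
    z <- matrix(rnorm(length(idx) * d), ncol = d)
    X[idx, ] <- sweep(z %*% ch, 2, model$means[[k]], `+`)
  }
  list(X = X, labels = labels)
}

#' Construct a mixture model from known parameters
#'
#' Builds a `tm2d_mixture` directly (no fitting), e.g. to define a
#' generating model for simulations or to evaluate posteriors under
#' published parameters.
#'
#' @param priors Length-K mixing proportions (positive, summing to 1).
#' @param means List of K mean vectors (or numeric vector for d = 1).
#' @param covariances List of K covariance matrices (or numeric vector of
#'   variances for d = 1).
#' @param component_names Optional component labels.
#' @return A `tm2d_mixture`.
#' @export
mixture_model <- function(priors, means, covariances,
                          component_names = NULL) {
  K <- length(priors)
  if (!is.list(means)) means <- lapply(means, function(m) m)
  if (!is.list(covariances)) {
    covariances <- lapply(covariances, function(v) matrix(v, 1, 1))
  }
  stopifnot(length(means) == K, length(covariances) == K,
            all(priors > 0))
  priors <- priors / sum(priors)
  d <- length(means[[1]])
  structure(
    list(K = K, d = d, priors = priors, means = means,
         covariances = lapply(covariances, function(s) matrix(s, d, d)),
         loglik_trace = numeric(0), converged = NA,
         prior_mode = "fixed", n = 0L, ridge = 0,
         component_names = component_names %||% paste0("class_", seq_len(K))),
    class = "tm2d_mixture"
  )
}
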