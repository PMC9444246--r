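#' Define an orientation/defocus search grid
#'
#' @param out_of_plane_step Step in theta, degrees (> 0, <= 360).
#' @param in_plane_step Step in psi, degrees (> 0, <= 360).
#' @param defocus_range Full span of the defocus search in Angstrom (>= 0);
#'   planes cover +/- `defocus_range / 2` (a 200 A range at a 10 A step gives
#'   21 planes). 0 disables the defocus search.
#' @param defocus_step Defocus step in Angstrom (> 0 when `defocus_range > 0`).
#' @return An object of class `tm2d_search_grid`.
#' @export
search_grid <- function(out_of_plane_step = 2.5, in_plane_step = 1.5,
                        defocus_range = 0, defocus_step = 0) {
  if (out_of_plane_step <= 0 || in_plane_step <= 0) {
    stop("angular steps must be > 0", call. = FALSE)
  }
  if (out_of_plane_step > 360 || in_plane_step > 360) {
    stop("angular steps must be <= 360 degrees", call. = FALSE)
  }
  if (defocus_range < 0) stop("defocus_range must be >= 0", call. = FALSE)
  if (defocus_range > 0 && defocus_step <= 0) {
    stop("defocus_step must be > 0 when defocus_range > 0", call. = FALSE)
  }
  structure(
    list(out_of_plane_step = out_of_plane_step, in_plane_step = in_plane_step,
         defocus_range = defocus_range, defocus_step = defocus_step),
    class = "tm2d_search_grid"
  )
}

#' Enumerate the poses of a search grid
#'
#' Near-uniform sphere coverage: `theta` is sampled from 0 to 180 in steps of
#' `out_of_plane_step`; at each ring the number of `phi` samples is scaled by
#' `sin(theta)` (at least one), so azimuthal spacing tracks the ring
#' circumference; `psi` advances in `in_plane_step` increments over
#' `[0, 360)`. Defocus planes span `+/- defocus_range / 2` in `defocus_step`
#' increments. Ordering is deterministic: dz slowest, then theta, phi, psi.
#'
#' @param grid A [search_grid()].
#' @return A tibble with columns `phi, theta, psi, dz` (degrees, Angstrom).
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "tm2d_search_grid"))
  thetas <- seq(0, 180, by = grid$out_of_plane_step)
  n_psi <- max(1L, floor((360 - 1e-9) / grid$in_plane_step) + 1L)
  psis <- (seq_len(n_psi) - 1) * grid$in_plane_step
  ori <- purrr::map_dfr(thetas, function(th) {
    n_phi <- max(1L, ceiling(360 * sin(th * pi / 180) / grid$out_of_plane_step))
    phis <- seq(0, 360, length.out = n_phi + 1)[seq_len(n_phi)]
    tidyr::expand_grid(phi = phis, psi = psis) |>
      dplyr::mutate(theta = th, .after = "phi")
  })
  dzs <- if (grid$defocus_range > 0) {
    seq(-grid$defocus_range / 2, grid$defocus_range / 2,
        by = grid$defocus_step)
  } else 0
  tidyr::expand_grid(dz = dzs, ori) |>
    dplyr::select("phi", "theta", "psi", "dz")
}

# Project, CTF-modulate, whiten-filter and L2-normalise one template
# projection; the same preparation is used by the exhaustive search, the
# fixed-pose evaluator and the refiner, so their SNR scales are identical.
prepare_template <- function(vol, phi, theta, psi, dz, ctf, filter, fg = NULL) {
  p <- cpp_project_volume(as.numeric(vol$data), vol$box_size, phi, theta, psi)
  n <- nrow(p)
  if (is.null(fg)) fg <- frequency_grids(n, n, vol$voxel_size)
  h <- 1
  if (!is.null(ctf)) {
    ctf_dz <- ctf
    ctf_dz$defocus1 <- ctf$defocus1 + dz
    ctf_dz$defocus2 <- ctf$defocus2 + dz
    h <- ctf_value(ctf_dz, fg$g, fg$alpha)
  }
  if (!is.null(filter)) h <- h * filter_gain_at(filter, fg$g)
  t <- Re(fft(fft(p) * h, inverse = TRUE)) / length(p)
  nrm <- sqrt(sum(t^2))
  if (nrm == 0) stop("template projection has zero norm", call. = FALSE)
  t / nrm
}

#' Exhaustive 2D template matching search
#'
#' Whitens the micrograph, then for every orientation and defocus plane of
#' the grid projects the template, applies the image CTF and whitening
#' filter, L2-normalises, and cross-correlates with the whitened image (FFT,
#' circular). Because the image is whitened to a flat unit-variance spectrum
#' and each template has unit norm, pure-noise correlations are standard
#' normal, so the per-pixel values are 2DTM SNRs. Returns the per-pixel
#' maximum (MIP) and argmax pose grids.
#'
#' @param m A [micrograph()]; its `pixel_size` must match the template's
#'   `voxel_size` within 1%.
#' @param t A [volume()] template; box must fit inside the image.
#' @param grid A [search_grid()].
#' @param template_id,image_id Identifiers carried into downstream tables.
#' @return An object of class `tm2d_snr_maps`: matrices `mip`, `best_phi`,
#'   `best_theta`, `best_psi`, `best_dz`; `n_correlations`; the whitened
#'   micrograph and filter; search metadata.
#' @export
run_search <- function(m, t, grid = search_grid(), template_id = "template",
                       image_id = NULL) {
  stopifnot(inherits(m, "tm2d_micrograph"), inherits(t, "tm2d_volume"))
  if (abs(m$pixel_size - t$voxel_size) > 0.01 * m$pixel_size) {
    stop("pixel size mismatch: image ", m$pixel_size, " A vs template ",
         t$voxel_size, " A", call. = FALSE)
  }
  nx <- nrow(m$data); ny <- ncol(m$data)
  if (t$box_size > min(nx, ny)) {
    stop("template box (", t$box_size, ") exceeds image size", call. = FALSE)
  }
  wh <- whiten_image(m)
  poses <- enumerate_grid(grid)
  nt <- t$box_size
  fg <- frequency_grids(nt, nt, t$voxel_size)
  mip <- matrix(-Inf, nx, ny)
  best <- matrix(0L, nx, ny)
  chunk <- 256L
  n_pose <- nrow(poses)
  for (start in seq(1L, n_pose, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_pose)
    stack <- vapply(idx, function(i) {
      prepare_template(t, poses$phi[i], poses$theta[i], poses$psi[i],
                       poses$dz[i], m$ctf, wh$filter, fg)
    }, matrix(0, nt, nt))
    cpp_search_accumulate(wh$micrograph$data, as.numeric(stack), nt,
                          length(idx), start - 1L, mip, best)
  }
  structure(
    list(
      mip = mip,
      best_phi = matrix(poses$phi[best], nx, ny),
      best_theta = matrix(poses$theta[best], nx, ny),
      best_psi = matrix(poses$psi[best], nx, ny),
      best_dz = matrix(poses$dz[best], nx, ny),
      n_correlations = as.numeric(nx) * ny * n_pose,
      grid = grid, template_id = template_id,
      image_id = image_id %||% m$image_id,
      pixel_size = m$pixel_size, template_box = nt,
      whitened = wh
    ),
    class = "tm2d_snr_maps"
  )
}

#' SNR map at a single orientation
#'
#' Full per-pixel correlation map for one fixed orientation/defocus, with the
#' same standardisation as [run_search()]. Useful for noise-model checks.
#'
#' @inheritParams run_search
#' @param phi,theta,psi Euler angles in degrees.
#' @param dz Defocus offset in Angstrom.
#' @return Numeric matrix of SNR values, same shape as the image.
#' @export
correlation_map <- function(m, t, phi = 0, theta = 0, psi = 0, dz = 0) {
  stopifnot(inherits(m, "tm2d_micrograph"), inherits(t, "tm2d_volume"))
  wh <- whiten_image(m)
  tpl <- prepare_template(t, phi, theta, psi, dz, m$ctf, wh$filter)
  nx <- nrow(m$data); ny <- ncol(m$data)
  mip <- matrix(-Inf, nx, ny)
  best <- matrix(0L, nx, ny)
  res <- cpp_search_accumulate(wh$micrograph$data, as.numeric(tpl),
                               nrow(tpl), 1L, 0L, mip, best)
  res$mip
}

#' Detection threshold for a given expected false-positive count
#'
#' Solves `n_correlations * Q(t) = expected_false_positives` for `t`, with
#' `Q` the standard normal survival function, assuming independent
#' correlations (a conservative assumption for overlapping orientations).
#'
#' @param n_correlations Total number of correlation values searched
#'   (pixels x orientations x defocus planes).
#' @param expected_false_positives Expected false positives per image
#'   (default 1).
#' @return The SNR threshold.
#' @export
detection_threshold <- function(n_correlations, expected_false_positives = 1) {
  if (n_correlations < 1) stop("n_correlations must be >= 1", call. = FALSE)
  if (expected_false_positives <= 0) {
    stop("expected_false_positives must be > 0", call. = FALSE)
  }
  if (expected_false_positives > n_correlations / 2) {
    stop("threshold not meaningful: expected_false_positives >= half the ",
         "correlation count", call. = FALSE)
  }
  qnorm(expected_false_positives / n_correlations, lower.tail = FALSE)
}

#' Extract significant detections from SNR maps
#'
#' Local maxima of the MIP at or above the threshold, accepted greedily in
#' descending SNR with an exclusion radius, each carrying its argmax pose.
#'
#' @param maps A `tm2d_snr_maps` object from [run_search()].
#' @param threshold Minimum SNR.
#' @param min_separation Exclusion radius in pixels (>= 1); defaults to the
#'   template radius.
#' @param border Pixels near the image edge to discard (peaks closer than
#'   this to the border cannot be fully correlated); defaults to the template
#'   radius.
#' @return A tibble of detections: `image_id, template_id, x_px, y_px,
#'   phi_deg, theta_deg, psi_deg, dz_A, snr`.
#' @export
extract_peaks <- function(maps, threshold, min_separation = NULL, border = NULL) {
  stopifnot(inherits(maps, "tm2d_snr_maps"), is.finite(threshold))
  r_tpl <- floor(maps$template_box / 2)
  min_separation <- min_separation %||% r_tpl
  if (min_separation < 1) stop("min_separation must be >= 1", call. = FALSE)
  border <- border %||% r_tpl
  mip <- maps$mip
  nx <- nrow(mip); ny <- ncol(mip)
  # 8-neighbourhood local maxima (ties resolved by >= against later
  # neighbours, > against earlier, so a plateau yields one candidate)
  shift <- function(mat, dx, dy) {
    out <- matrix(-Inf, nx, ny)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    out[xs, ys] <- mat[xs - dx, ys - dy]
    out
  }
  is_max <- mip >= threshold
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    is_max <- is_max & (mip > shift(mip, d[1], d[2])) &
      (mip >= shift(mip, -d[1], -d[2]))
  }
  if (border > 0) {
    is_max[c(seq_len(border), nx - seq_len(border) + 1L), ] <- FALSE
    is_max[, c(seq_len(border), ny - seq_len(border) + 1L)] <- FALSE
  }
  idx <- which(is_max)
  if (!length(idx)) {
    return(tibble::tibble(
      image_id = character(), template_id = character(), x_px = integer(),
      y_px = integer(), phi_deg = double(), theta_deg = double(),
      psi_deg = double(), dz_A = double(), snr = double()
    ))
  }
  ord <- idx[order(mip[idx], decreasing = TRUE)]
  px <- (ord - 1L) %% nx
  py <- (ord - 1L) %/% nx
  keep <- logical(length(ord))
  kept_x <- kept_y <- numeric(0)
  for (i in seq_along(ord)) {
    if (!length(kept_x) ||
        all((kept_x - px[i])^2 + (kept_y - py[i])^2 >= min_separation^2)) {
      keep[i] <- TRUE
      kept_x <- c(kept_x, px[i]); kept_y <- c(kept_y, py[i])
    }
  }
  sel <- ord[keep]
  tibble::tibble(
    image_id = maps$image_id, template_id = maps$template_id,
    x_px = as.integer((sel - 1L) %% nx), y_px = as.integer((sel - 1L) %/% nx),
    phi_deg = maps$best_phi[sel], theta_deg = maps$best_theta[sel],
    psi_deg = maps$best_psi[sel], dz_A = maps$best_dz[sel],
    snr = maps$mip[sel]
  )
}

#' 2DTM SNR of a template at a fixed pose
#'
#' Single correlation of the template projected at exactly the given pose,
#' standardised identically to [run_search()] (no search, hence no
#' maximisation bias). This is the fixed-pose evaluation used to score
#' alternate templates at poses found with a reference template.
#'
#' @inheritParams run_search
#' @param pose A one-row pose tibble from [pose()] (or any list with fields
#'   `x, y, phi, theta, psi, dz`).
#' @param whitened Optional precomputed result of [whiten_image()] for `m`,
#'   to amortise whitening across many calls.
#' @return The SNR (scalar).
#' @export
snr_at_pose <- function(m, t, pose, whitened = NULL) {
  stopifnot(inherits(m, "tm2d_micrograph"), inherits(t, "tm2d_volume"))
  nx <- nrow(m$data); ny <- ncol(m$data)
  if (pose$x < 0 || pose$x >= nx || pose$y < 0 || pose$y >= ny) {
    stop("pose out of bounds: (", pose$x, ", ", pose$y, ") in ", nx, " x ",
         ny, " image", call. = FALSE)
  }
  wh <- whitened %||% whiten_image(m)
  tpl <- prepare_template(t, pose$phi, pose$theta, pose$psi,
                          pose$dz %||% 0, m$ctf, wh$filter)
  cpp_corr_at(wh$micrograph$data, tpl, as.integer(pose$x), as.integer(pose$y))
}

#' 2DTM SNR of a template maximised over local alignment configurations
#'
#' Evaluates the template over +/- one pixel in x and y and +/- one grid
#' step in each Euler angle around the given pose (3^5 = 243 alignment
#' configurations at the defaults) and returns the maximum SNR. An
#' exhaustively searched reference template carries an apparent noise SNR
#' from maximising over exactly this local neighbourhood; granting the
#' alternate template the same freedom equalises the overfitting bias so
#' SNR ratios between templates stay unbiased.
#'
#' @inheritParams snr_at_pose
#' @param grid A [search_grid()] whose angular steps define the +/- one-step
#'   neighbourhood.
#' @return A list with `snr` (the local maximum) and `pose` (where it was
#'   attained).
#' @export
snr_local_max <- function(m, t, pose, grid = search_grid(),
                          whitened = NULL) {
  stopifnot(inherits(m, "tm2d_micrograph"), inherits(t, "tm2d_volume"),
            inherits(grid, "tm2d_search_grid"))
  wh <- whitened %||% whiten_image(m)
  nx <- nrow(m$data); ny <- ncol(m$data)
  best <- -Inf
  best_pose <- pose
  xs <- unique(pmax(0, pmin(nx - 1, pose$x + (-1:1))))
  ys <- unique(pmax(0, pmin(ny - 1, pose$y + (-1:1))))
  for (dphi in grid$in_plane_step * (-1:1)) {
    for (dtheta in grid$out_of_plane_step * (-1:1)) {
      for (dpsi in grid$in_plane_step * (-1:1)) {
        tpl <- prepare_template(t, pose$phi + dphi, pose$theta + dtheta,
                                pose$psi + dpsi, pose$dz %||% 0, m$ctf,
                                wh$filter)
        for (x in xs) for (y in ys) {
          s <- cpp_corr_at(wh$micrograph$data, tpl, as.integer(x),
                           as.integer(y))
          if (s > best) {
            best <- s
            best_pose <- pose(x, y, pose$phi + dphi, pose$theta + dtheta,
                              pose$psi + dpsi, pose$dz %||% 0)
          }
        }
      }
    }
  }
  list(snr = best, pose = best_pose)
}

#' Refine a detection by local exhaustive search
#'
#' Searches +/- one coarse step around the detection's angles at the fine
#' grid's steps, the fine grid's defocus range, and +/- 1 pixel in x and y.
#' The input pose is always a candidate, so the refined SNR never decreases.
#'
#' @inheritParams run_search
#' @param d One detection (a one-row tibble as produced by
#'   [extract_peaks()]).
#' @param fine A [search_grid()] giving the fine angular steps and defocus
#'   range.
#' @param coarse A [search_grid()] giving the coarse steps that define the
#'   +/- search extent (defaults to the default coarse grid).
#' @param whitened Optional precomputed [whiten_image()] result.
#' @return The refined one-row detection tibble.
#' @export
refine_pose <- function(m, t, d, fine, coarse = search_grid(),
                        whitened = NULL) {
  stopifnot(inherits(m, "tm2d_micrograph"), inherits(t, "tm2d_volume"),
            inherits(fine, "tm2d_search_grid"),
            inherits(coarse, "tm2d_search_grid"))
  nx <- nrow(m$data); ny <- ncol(m$data)
  if (d$x_px < 0 || d$x_px >= nx || d$y_px < 0 || d$y_px >= ny) {
    stop("detection out of image bounds", call. = FALSE)
  }
  wh <- whitened %||% whiten_image(m)
  off <- function(half, step) {
    o <- seq(0, half + 1e-9, by = step)
    sort(unique(c(-o, o)))
  }
  d_phi <- off(coarse$in_plane_step, fine$in_plane_step)
  d_theta <- off(coarse$out_of_plane_step, fine$out_of_plane_step)
  d_psi <- d_phi
  d_dz <- if (fine$defocus_range > 0) {
    seq(-fine$defocus_range / 2, fine$defocus_range / 2,
        by = fine$defocus_step)
  } else 0
  cand <- tidyr::expand_grid(dphi = d_phi, dtheta = d_theta, dpsi = d_psi,
                             dz = d_dz)
  best <- d
  best_snr <- -Inf
  xs <- pmax(0L, pmin(nx - 1L, d$x_px + (-1:1)))
  ys <- pmax(0L, pmin(ny - 1L, d$y_px + (-1:1)))
  pxy <- tidyr::expand_grid(x = unique(xs), y = unique(ys))
  for (i in seq_len(nrow(cand))) {
    tpl <- prepare_template(t, d$phi_deg + cand$dphi[i],
                            d$theta_deg + cand$dtheta[i],
                            d$psi_deg + cand$dpsi[i],
                            (d$dz_A %||% 0) + cand$dz[i], m$ctf, wh$filter)
    for (j in seq_len(nrow(pxy))) {
      s <- cpp_corr_at(wh$micrograph$data, tpl, pxy$x[j], pxy$y[j])
      if (s > best_snr) {
        best_snr <- s
        best <- d
        best$x_px <- pxy$x[j]; best$y_px <- pxy$y[j]
        best$phi_deg <- (d$phi_deg + cand$dphi[i]) %% 360
        best$theta_deg <- d$theta_deg + cand$dtheta[i]
        best$psi_deg <- (d$psi_deg + cand$dpsi[i]) %% 360
        best$dz_A <- (d$dz_A %||% 0) + cand$dz[i]
        best$snr <- s
      }
    }
  }
  best
}

#' @export
print.tm2d_snr_maps <- function(x, ...) {
  cat("<tm2d_snr_maps> ", nrow(x$mip), " x ", ncol(x$mip), " px, template '",
      x$template_id, "', ", format(x$n_correlations, big.mark = ","),
      " correlations, max SNR ", round(max(x$mip), 2), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
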