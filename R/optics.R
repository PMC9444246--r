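# Fourier-space frequency coordinates for an n-point DFT, in cycles per
# sample: 0, 1/n, ..., then negative frequencies (unshifted order).
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# Radial frequency magnitude |g| (1/A) and azimuth (degrees) grids for an
# nx-by-ny image at the given pixel size, in unshifted DFT order.
frequency_grids <- function(nx, ny, pixel_size) {
  gx <- fft_freq(nx) / pixel_size
  gy <- fft_freq(ny) / pixel_size
  gxm <- matrix(gx, nx, ny)
  gym <- matrix(gy, nx, ny, byrow = TRUE)
  list(g = sqrt(gxm^2 + gym^2), alpha = atan2(gym, gxm) * 180 / pi)
}

#' Project a volume along z after a ZYZ rotation
#'
#' Rotates the template density by the intrinsic ZYZ Euler angles (phi about
#' z, then theta about the new y, then psi about the new z), then integrates
#' along +z. Rotation origin is the box center voxel `floor(n/2)` (0-based);
#' resampling is trilinear.
#'
#' @param vol A [volume()].
#' @param phi,theta,psi Euler angles in degrees.
#' @return An `n x n` numeric matrix (x-fastest layout), the projected
#'   density in (density units) * voxel.
#' @export
project_volume <- function(vol, phi, theta, psi) {
  if (!inherits(vol, "tm2d_volume")) stop("vol must be a tm2d_volume", call. = FALSE)
  stopifnot(is.finite(phi), is.finite(theta), is.finite(psi))
  cpp_project_volume(as.numeric(vol$data), vol$box_size, phi, theta, psi)
}

#' Evaluate the contrast transfer function
#'
#' Standard astigmatic CTF with the dark-atom sign convention: positive
#' defocus is underfocus and the value at zero frequency is
#' `-amplitude_contrast`. The aberration phase is
#' `chi(g) = pi * lambda * df(alpha) * g^2 - (pi/2) * lambda^3 * cs * g^4 +
#' phase_shift` and the returned value is
#' `-(sqrt(1 - w^2) * sin(chi) + w * cos(chi))`.
#'
#' @param ctf A [ctf_params()] object.
#' @param g Spatial frequency magnitude in 1/Angstrom (>= 0); vectorised.
#' @param alpha Azimuth in degrees; vectorised (recycled against `g`).
#' @return CTF values in `[-1, 1]`.
#' @export
ctf_value <- function(ctf, g, alpha = 0) {
  stopifnot(inherits(ctf, "tm2d_ctf"), all(g >= 0))
  lambda <- electron_wavelength(ctf$voltage)
  df_mean <- (ctf$defocus1 + ctf$defocus2) / 2
  df_diff <- (ctf$defocus1 - ctf$defocus2) / 2
  df <- df_mean + df_diff * cos(2 * (alpha - ctf$astig_angle) * pi / 180)
  cs_A <- ctf$cs * 1e7  # mm -> Angstrom
  chi <- pi * lambda * df * g^2 - (pi / 2) * lambda^3 * cs_A * g^4 +
    ctf$phase_shift
  w <- ctf$amplitude_contrast
  -(sqrt(1 - w^2) * sin(chi) + w * cos(chi))
}

#' Apply a CTF to a square image
#'
#' Multiplies the image by the CTF in the Fourier domain. Linear in the
#' input; the result is real-valued.
#'
#' @param image Square numeric matrix (x-fastest layout).
#' @param ctf A [ctf_params()] object.
#' @param pixel_size Pixel size in Angstrom.
#' @param dz Extra defocus offset in Angstrom added to both defocus axes.
#' @return Filtered image, same shape.
#' @export
apply_ctf <- function(image, ctf, pixel_size, dz = 0) {
  if (!is.matrix(image) || nrow(image) != ncol(image)) {
    stop("apply_ctf expects a square image, got ",
         paste(dim(image), collapse = " x "), call. = FALSE)
  }
  n <- nrow(image)
  fg <- frequency_grids(n, n, pixel_size)
  ctf_dz <- ctf
  ctf_dz$defocus1 <- ctf$defocus1 + dz
  ctf_dz$defocus2 <- ctf$defocus2 + dz
  h <- ctf_value(ctf_dz, fg$g, fg$alpha)
  Re(fft(fft(image) * h, inverse = TRUE)) / length(image)
}

# Evaluate a whitening filter's radial gain at arbitrary frequencies (1/A),
# linear interpolation, clamped at the end bins.
filter_gain_at <- function(filter, g) {
  matrix(approx(filter$freq, filter$gain, xout = as.numeric(g),
                rule = 2)$y, nrow = nrow(g))
}

# Multiply an image by the radial whitening gain in the Fourier domain.
apply_whitening_filter <- function(image, filter, pixel_size) {
  fg <- frequency_grids(nrow(image), ncol(image), pixel_size)
  gain <- filter_gain_at(filter, fg$g)
  Re(fft(fft(image) * gain, inverse = TRUE)) / length(image)
}

#' Whiten a micrograph
#'
#' Estimates the rotationally averaged power spectrum in radial bins and
#' multiplies each Fourier component by `1/sqrt(power)` so that the output
#' power spectrum is radially flat, then rescales to unit sample variance
#' (and zero mean). The radial filter is returned so that template
#' projections can be filtered identically, which is what makes pure-noise
#' matched-filter correlations standard normal.
#'
#' @param m A [micrograph()].
#' @param n_bins Number of radial frequency bins (>= 32).
#' @return A list with `micrograph` (whitened copy) and `filter` (class
#'   `tm2d_whitening_filter`: radial frequencies `freq` in 1/A and the
#'   multiplicative `gain`, including the final variance normalisation).
#' @export
whiten_image <- function(m, n_bins = 64) {
  stopifnot(inherits(m, "tm2d_micrograph"))
  n_bins <- max(32L, as.integer(n_bins))
  x <- m$data - mean(m$data)
  if (sd(x) == 0) stop("cannot whiten a zero-variance image", call. = FALSE)
  nx <- nrow(x); ny <- ncol(x)
  Fx <- fft(x)
  pw <- Mod(Fx)^2 / length(x)
  fg <- frequency_grids(nx, ny, m$pixel_size)
  g_max <- 0.5 * sqrt(2) / m$pixel_size
  edges <- seq(0, g_max, length.out = n_bins + 1)
  bin <- findInterval(fg$g, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
  mean_pw <- tapply(as.numeric(pw), as.numeric(bin), mean)
  psd <- rep(NA_real_, n_bins)
  psd[as.integer(names(mean_pw))] <- mean_pw
  # empty or zero-power bins: floor at a small fraction of the median power
  floor_pw <- 1e-12 * stats::median(psd, na.rm = TRUE)
  psd[is.na(psd) | psd < floor_pw] <- floor_pw
  gain <- 1 / sqrt(psd)
  freq <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  filt <- structure(list(freq = freq, gain = gain), class = "tm2d_whitening_filter")
  w <- apply_whitening_filter(x, filt, m$pixel_size)
  scale <- 1 / sd(w)
  w <- w * scale
  filt$gain <- filt$gain * scale
  out <- m
  out$data <- w
  list(micrograph = out, filter = filt)
}
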