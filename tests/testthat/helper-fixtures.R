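# Shared fixtures and independent oracles. Everything is generated in code;
# heavier objects are built once per test run and cached in this environment.

fixture_env <- new.env()

fixture_volumes <- function(appendage_fraction = 0.2) {
  key <- paste0("vols_", appendage_fraction)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <-
      make_class_volumes(two_class_phantom_spec(
        appendage_fraction = appendage_fraction))
  }
  fixture_env[[key]]
}

noise_micrograph <- function(n = 128, seed = 1, sd = 1, pixel_size = 4,
                             ctf = NULL) {
  set.seed(seed)
  micrograph(matrix(rnorm(n * n, 0, sd), n, n), pixel_size, ctf = ctf)
}

# --- independent oracles -------------------------------------------------

# Brute-force nearest-neighbour rotation + z-sum projection; same ZYZ
# intrinsic convention as the package, implemented independently in R.
oracle_project_nn <- function(vol, phi, theta, psi) {
  n <- vol$box_size
  d2r <- pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                           3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)),
                           3, 3)
  R <- rz(phi * d2r) %*% ry(theta * d2r) %*% rz(psi * d2r)
  ctr <- floor(n / 2)
  out <- matrix(0, n, n)
  for (z in 0:(n - 1)) for (y in 0:(n - 1)) for (x in 0:(n - 1)) {
    s <- t(R) %*% c(x - ctr, y - ctr, z - ctr) + ctr
    s <- round(s)
    if (all(s >= 0) && all(s <= n - 1)) {
      out[x + 1, y + 1] <- out[x + 1, y + 1] +
        vol$data[s[1] + 1, s[2] + 1, s[3] + 1]
    }
  }
  out
}

# Direct per-frequency CTF multiplication with its own wavelength and phase
# computation (loop form, no shared helpers).
oracle_apply_ctf <- function(image, defocus1, defocus2, astig_deg,
                             voltage_kev, cs_mm, w, pixel_size) {
  n <- nrow(image)
  v <- voltage_kev * 1000
  lambda <- 12.2639 / sqrt(v + 0.97845e-6 * v^2)
  Fim <- fft(image)
  H <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    fx <- (i - 1); if (fx > n / 2) fx <- fx - n
    fy <- (j - 1); if (fy > n / 2) fy <- fy - n
    gx <- fx / (n * pixel_size); gy <- fy / (n * pixel_size)
    g <- sqrt(gx^2 + gy^2)
    al <- atan2(gy, gx)
    df <- (defocus1 + defocus2) / 2 +
      (defocus1 - defocus2) / 2 * cos(2 * (al - astig_deg * pi / 180))
    chi <- pi * lambda * df * g^2 - pi / 2 * lambda^3 * (cs_mm * 1e7) * g^4
    H[i, j] <- -(sqrt(1 - w^2) * sin(chi) + w * cos(chi))
  }
  Re(fft(Fim * H, inverse = TRUE)) / n^2
}

# Independent re-statement of the sphere-coverage enumeration rule.
oracle_grid_count <- function(oop, ip) {
  total <- 0
  for (th in seq(0, 180, by = oop)) {
    n_phi <- max(1, ceiling(360 * sin(th * pi / 180) / oop))
    n_psi <- max(1, length(seq(0, 360, by = ip)) -
                   (360 %% ip < 1e-9))  # psi strictly below 360
    total <- total + n_phi * n_psi
  }
  total
}

# Scalar Bayes posterior for a two-component 1-d mixture, plain arithmetic.
oracle_bayes_1d <- function(x, pi1, m1, s1, pi2, m2, s2) {
  a <- pi1 * exp(-(x - m1)^2 / (2 * s1^2)) / s1
  b <- pi2 * exp(-(x - m2)^2 / (2 * s2^2)) / s2
  c(a, b) / (a + b)
}
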