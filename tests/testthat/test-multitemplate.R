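test_that("coordinate matching is one-to-one, symmetric and bounded by tol", {
  det <- function(x, y) {
    tibble::tibble(x_px = x, y_px = y)
  }
  a <- det(c(10, 50, 90), c(10, 50, 90))
  # identical lists: all matched at distance 0
  m0 <- match_coordinates(a, a, tol = 5)
  expect_equal(nrow(m0$pairs), 3)
  expect_equal(m0$pairs$distance, rep(0, 3))
  expect_length(m0$unmatched_a, 0)

  # offset by 2 * tol: nothing matches
  b <- det(a$x_px + 10, a$y_px)
  m1 <- match_coordinates(a, b, tol = 5)
  expect_equal(nrow(m1$pairs), 0)
  expect_equal(m1$unmatched_a, 1:3)

  # jittered copy plus decoys: the true pairs are recovered
  set.seed(71)
  n <- 100
  ax <- runif(n, 0, 1000); ay <- runif(n, 0, 1000)
  a2 <- det(ax, ay)
  b2 <- det(c(ax + runif(n, -1, 1), runif(20, 0, 1000)),
            c(ay + runif(n, -1, 1), runif(20, 0, 1000)))
  m2 <- match_coordinates(a2, b2, tol = 5)
  correct <- sum(m2$pairs$idx_a == m2$pairs$idx_b & m2$pairs$idx_b <= n)
  expect_gte(correct, 95)
  expect_true(all(m2$pairs$distance <= 5))
  # symmetry
  m2r <- match_coordinates(b2, a2, tol = 5)
  swapped <- m2$pairs[order(m2$pairs$idx_a), c("idx_a", "idx_b")]
  back <- m2r$pairs[order(m2r$pairs$idx_b), c("idx_b", "idx_a")]
  expect_equal(unname(as.matrix(swapped)), unname(as.matrix(back)))
})

test_that("ratio vectors follow the log2 reference convention", {
  expect_equal(ratio_vector(c(8, 8)), 0)
  expect_equal(ratio_vector(c(10, 5)), 1)
  expect_equal(ratio_vector(c(7.85, 6.20, 9.10)),
               c(log2(7.85 / 6.20), log2(7.85 / 9.10)))
  expect_equal(round(ratio_vector(c(7.85, 6.20, 9.10)), 4),
               c(0.3404, -0.2132))
  # scale invariance
  s <- c(7.85, 6.20, 9.10)
  expect_equal(ratio_vector(3.7 * s), ratio_vector(s))
  expect_error(ratio_vector(c(5, -1)), "positive")
})

test_that("overfitting noise-bias arithmetic matches the extreme-value model", {
  expect_equal(alignment_configurations(2, 3, 3), 243)
  expect_equal(alignment_configurations(0, 0, 3), 1)
  expect_equal(alignment_configurations(2, 3, 5), 3125)
  expect_equal(round(noise_snr(243), 2), 3.31)
  expect_equal(noise_snr(1), 0)
  expect_equal(round(noise_snr(10000), 2), 4.29)
  expect_equal(round(signal_snr(7.85, 243), 2), 4.54)
  expect_equal(round(signal_snr(noise_snr(243), 243), 2), 0)
  expect_equal(signal_snr(10, 1), 10)
  expect_warning(s <- signal_snr(2, 243), "noise floor")
  expect_equal(s, 0)
})

test_that("particle densities and per-cell extrapolation are plain arithmetic", {
  det <- tibble::tibble(x_px = 1:100)
  expect_equal(particle_density(det, 1, 0.15), 100 / 0.15, tolerance = 1e-12)
  expect_equal(round(particle_density(det, 1, 0.15), 1), 666.7)
  expect_equal(particle_density(det[0, ], 2, 0.1), 0)
  expect_equal(per_cell_count(6500, 42, 0.65), 177450)
  expect_equal(per_cell_count(6500, 42, 0), 0)
  expect_equal(per_cell_count(1, 1, 1), 1)
  # Poisson consistency with a simulated density
  set.seed(72)
  lam <- 80
  n <- rpois(1, lam)
  est <- particle_density(tibble::tibble(i = seq_len(n)), 4, 0.1)
  expect_lt(abs(est - lam / 0.4), 3 * sqrt(n) / 0.4)
})

test_that("region histograms are per-region, sub-threshold and deterministic", {
  mk_maps <- function(mip) {
    z <- matrix(0, nrow(mip), ncol(mip))
    structure(list(mip = mip, best_phi = z, best_theta = z, best_psi = z,
                   best_dz = z, n_correlations = length(mip),
                   template_id = "t", image_id = "i", template_box = 4),
              class = "tm2d_snr_maps")
  }
  set.seed(73)
  mip <- matrix(rnorm(128 * 128), 128)
  mask <- compartment_mask(128, 128, boundary = 64)
  h <- region_histogram(mk_maps(mip), mask, box = 48, bin_width = 0.05,
                        threshold = 2)
  expect_setequal(unique(h$region), c("nucleus", "cytoplasm"))
  expect_true(all(h$bin_right <= 2 + 0.05))
  expect_equal(h$bin_right - h$bin_left, rep(0.05, nrow(h)))
  # each region histogram holds every sub-threshold value of one 48x48 box
  sums <- tapply(h$count, h$region, sum)
  expect_true(all(sums <= 48 * 48))
  expect_true(all(sums >= 0.9 * 48 * 48))  # few values above 2 sigma

  # threshold below every value: empty histograms
  h0 <- region_histogram(mk_maps(mip), mask, box = 48, bin_width = 0.05,
                         threshold = -Inf)
  expect_equal(nrow(h0), 0)

  # a region too small for the box is skipped with a warning
  mask2 <- compartment_mask(128, 128, boundary = 8)
  expect_warning(
    h2 <- region_histogram(mk_maps(mip), mask2, box = 48, bin_width = 0.05,
                           threshold = 2),
    "skipped")
  expect_equal(unique(h2$region), "cytoplasm")
})

test_that("identical-noise regions give statistically indistinguishable histograms", {
  mk_maps <- function(mip) {
    structure(list(mip = mip, template_box = 4), class = "tm2d_snr_maps")
  }
  nonsig <- vapply(1:10, function(s) {
    set.seed(400 + s)
    mip <- matrix(rnorm(160 * 160), 160)
    mask <- compartment_mask(160, 160, boundary = 80)
    h <- region_histogram(mk_maps(mip), mask, box = 64, bin_width = 0.05,
                          threshold = Inf)
    expand_h <- function(reg) {
      hh <- h[h$region == reg, ]
      rep(hh$bin_mid, hh$count)
    }
    suppressWarnings(
      ks.test(expand_h("nucleus"), expand_h("cytoplasm"))$p.value) > 0.01
  }, TRUE)
  expect_gte(mean(nonsig), 0.9)
})

test_that("sub-threshold noise MIP values follow the max-of-search distribution", {
  vols <- fixture_volumes()
  g <- search_grid(120, 180)  # small orientation set
  n_ori <- nrow(enumerate_grid(g))
  m <- noise_micrograph(128, seed = 74)
  maps <- run_search(m, vols$mature, g)
  mask <- matrix("all", 128, 128)
  h <- region_histogram(maps, mask, box = 100, bin_width = 0.05,
                        threshold = Inf)
  obs_mean <- sum(h$bin_mid * h$count) / sum(h$count)
  # Monte-Carlo reference: max of n_ori correlated-free standard normals
  set.seed(75)
  mc <- matrix(rnorm(1e5 * n_ori), ncol = n_ori)
  ref <- rowMaxs <- apply(mc, 1, max)
  se <- sd(ref) / sqrt(sum(h$count)) + sd(ref) / sqrt(length(ref))
  # orientations are correlated, so the observed mean cannot exceed the
  # independent-max reference; it must sit between E[max of 1] = 0 and it
  expect_lt(obs_mean, mean(ref) + 3 * se)
  expect_gt(obs_mean, 0)
})

test_that("log2 ratios are invariant to the image noise level at high SNR", {
  vols <- fixture_volumes(appendage_fraction = 0.3)
  mean_ratio <- function(noise_sd, seeds, snr = 15) {
    rr <- c()
    for (s in seeds) {
      sim <- simulate_micrograph(vols["immature"], c(immature = 10), 300,
                                 noise_sd = noise_sd, signal_snr = snr,
                                 seed = s)
      wh <- whiten_image(sim$micrograph)
      for (i in seq_len(nrow(sim$truth))) {
        tr <- sim$truth[i, ]
        p <- pose(tr$x_px, tr$y_px, tr$phi_deg, tr$theta_deg, tr$psi_deg)
        a <- snr_at_pose(sim$micrograph, vols$immature, p, whitened = wh)
        b <- snr_at_pose(sim$micrograph, vols$mature, p, whitened = wh)
        if (a > 0 && b > 0) rr <- c(rr, log2(a / b))
      }
    }
    mean(rr)
  }
  # doubling the noise VARIANCE multiplies sd by sqrt(2); planted signal SNR
  # is held at >= 15 in both conditions (amplitude scales with noise)
  r1 <- mean_ratio(1, 1:4)
  r2 <- mean_ratio(sqrt(2), 1:4)
  expect_lt(abs(r1 - r2), 0.05)
})

test_that("ratios shrink toward 0 as targets approach the detection limit", {
  vols <- fixture_volumes(appendage_fraction = 0.3)
  tier_ratio <- function(snr) {
    rr <- c()
    for (s in 1:3) {
      sim <- simulate_micrograph(vols["immature"], c(immature = 10), 300,
                                 noise_sd = 1, signal_snr = snr, seed = s)
      wh <- whiten_image(sim$micrograph)
      for (i in seq_len(nrow(sim$truth))) {
        tr <- sim$truth[i, ]
        p <- pose(tr$x_px, tr$y_px, tr$phi_deg, tr$theta_deg, tr$psi_deg)
        a <- snr_at_pose(sim$micrograph, vols$immature, p, whitened = wh)
        b <- snr_at_pose(sim$micrograph, vols$mature, p, whitened = wh)
        if (a > 0 && b > 0) rr <- c(rr, log2(a / b))
      }
    }
    mean(rr)
  }
  tiers <- vapply(c(6, 10, 20), tier_ratio, 0)
  expect_true(all(diff(tiers) > 0))  # |mean ratio| grows with signal SNR
  expect_true(all(tiers > 0))
})

test_that("ratio columns join per-template SNRs into the target table", {
  df <- tibble::tibble(target_id = 1:3,
                       snr_m = c(10, 8, 7.85),
                       snr_l = c(5, 8, 9.1),
                       snr_bad = c(2, -1, 3))
  out <- add_ratio_columns(df, c("m", "l"))
  expect_equal(out$x_l, log2(df$snr_m / df$snr_l))
  out2 <- add_ratio_columns(df, c("m", "l", "bad"))
  expect_true(is.na(out2$x_bad[2]))
  expect_error(add_ratio_columns(df, c("m", "zzz")), "missing SNR")
})
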