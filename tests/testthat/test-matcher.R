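test_that("grid enumeration covers the sphere with the stated counts", {
  # degenerate grid: only the poles, one psi
  g0 <- enumerate_grid(search_grid(180, 360))
  expect_equal(nrow(g0), 2)
  expect_equal(sort(unique(g0$theta)), c(0, 180))
  expect_equal(unique(g0$psi), 0)

  # independent enumeration of the same rule
  g1 <- enumerate_grid(search_grid(90, 90))
  expect_equal(nrow(g1), oracle_grid_count(90, 90))

  # defocus planes: 200 A range in 10 A steps = 21 planes per orientation
  g2 <- enumerate_grid(search_grid(90, 90, defocus_range = 200,
                                   defocus_step = 10))
  expect_equal(length(unique(g2$dz)), 21)
  expect_equal(nrow(g2), 21 * nrow(g1))

  expect_error(search_grid(400, 90), "<= 360")
})

test_that("pure-noise correlations are standard normal", {
  vols <- fixture_volumes()
  vals <- c()
  for (s in 1:4) {
    m <- noise_micrograph(512, seed = 100 + s)
    cm <- correlation_map(m, vols$mature, 15 * s, 40 + 10 * s, 60 * s)
    vals <- c(vals, as.numeric(cm))
  }
  expect_gte(length(vals), 1e6)
  expect_lt(abs(mean(vals)), 0.01)
  expect_lt(abs(var(vals) - 1), 0.02)
})

test_that("SNR is invariant to rescaling the raw image", {
  vols <- fixture_volumes()
  m <- noise_micrograph(64, seed = 21)
  m5 <- m
  m5$data <- 5 * m$data
  g <- search_grid(90, 180)
  a <- run_search(m, vols$mature, g)
  b <- run_search(m5, vols$mature, g)
  expect_equal(a$mip, b$mip, tolerance = 1e-9)
})

test_that("the MIP equals the pixelwise max over enumerated orientations", {
  vols <- fixture_volumes()
  m <- noise_micrograph(64, seed = 22)
  g <- search_grid(120, 360)
  poses <- enumerate_grid(g)
  maps <- run_search(m, vols$mature, g)
  manual <- Reduce(pmax, lapply(seq_len(nrow(poses)), function(i) {
    correlation_map(m, vols$mature, poses$phi[i], poses$theta[i],
                    poses$psi[i])
  }))
  expect_equal(maps$mip, manual, tolerance = 1e-9)
  expect_equal(maps$n_correlations, 64 * 64 * nrow(poses))
})

test_that("a planted projection at a grid pose is recovered exactly", {
  vols <- fixture_volumes()
  g <- search_grid(45, 60)
  ori <- enumerate_grid(g)
  k <- 40
  p <- project_volume(vols$mature, ori$phi[k], ori$theta[k], ori$psi[k])
  set.seed(23)
  img <- matrix(rnorm(128 * 128, 0, 1e-3), 128, 128)
  c0 <- 16
  img[64 - c0 + 1:32, 64 - c0 + 1:32] <-
    img[64 - c0 + 1:32, 64 - c0 + 1:32] + p
  maps <- run_search(micrograph(img, 4), vols$mature, g)
  peak <- which(maps$mip == max(maps$mip), arr.ind = TRUE)
  expect_lte(max(abs(unname(peak[1, ]) - c(65, 65))), 1)
  i <- peak[1, 1]; j <- peak[1, 2]
  expect_equal(maps$best_phi[i, j], ori$phi[k])
  expect_equal(maps$best_theta[i, j], ori$theta[k])
  expect_equal(maps$best_psi[i, j], ori$psi[k])
})

test_that("planted signal SNR 10 is recovered within [8, 12] on average", {
  vols <- fixture_volumes()
  g <- search_grid(45, 60)
  ori <- enumerate_grid(g)
  rec <- vapply(1:20, function(s) {
    set.seed(s)
    k <- sample.int(nrow(ori), 1)
    p <- project_volume(vols$mature, ori$phi[k], ori$theta[k], ori$psi[k])
    img <- matrix(rnorm(256 * 256), 256, 256)
    amp <- 10 / sqrt(sum(p^2))
    c0 <- 16
    img[128 - c0 + 1:32, 128 - c0 + 1:32] <-
      img[128 - c0 + 1:32, 128 - c0 + 1:32] + amp * p
    maps <- run_search(micrograph(img, 4), vols$mature, g)
    max(maps$mip[123:133, 123:133])
  }, 0)
  expect_gte(mean(rec), 8)
  expect_lte(mean(rec), 12)
})

test_that("detection_threshold inverts the Gaussian tail", {
  expect_equal(detection_threshold(1e7, 1), 5.199, tolerance = 1e-3)
  expect_equal(detection_threshold(10, 5), 0)
  # the working threshold 7.85 corresponds to Q ~ 2.1e-15 (n ~ 4.8e14)
  q <- pnorm(7.85, lower.tail = FALSE)
  expect_equal(q, 2.0e-15, tolerance = 0.06)
  expect_equal(1 / q, 4.9e14, tolerance = 0.06)
  expect_equal(detection_threshold(1 / q, 1), 7.85, tolerance = 1e-3)
  # monotone in n
  expect_gt(detection_threshold(1e9, 1), detection_threshold(1e6, 1))
  expect_error(detection_threshold(10, 6), "not meaningful")
})

test_that("peak extraction applies threshold, exclusion and argmax poses", {
  # synthetic maps object with two close peaks
  mk_maps <- function(mip) {
    z <- matrix(0, nrow(mip), ncol(mip))
    structure(list(mip = mip, best_phi = z, best_theta = z, best_psi = z,
                   best_dz = z, n_correlations = length(mip),
                   template_id = "t", image_id = "i", template_box = 4),
              class = "tm2d_snr_maps")
  }
  empty <- extract_peaks(mk_maps(matrix(0, 32, 32)), threshold = 1,
                         border = 0)
  expect_equal(nrow(empty), 0)

  mip <- matrix(0, 32, 32)
  mip[15, 15] <- 9
  mip[18, 15] <- 8  # 3 px away
  det <- extract_peaks(mk_maps(mip), threshold = 5, min_separation = 5,
                       border = 0)
  expect_equal(nrow(det), 1)
  expect_equal(c(det$x_px, det$y_px, det$snr), c(14, 14, 9))

  det2 <- extract_peaks(mk_maps(mip), threshold = 5, min_separation = 2,
                        border = 0)
  expect_equal(nrow(det2), 2)
})

test_that("all planted particles are found, each within 1 px", {
  # asymmetric pseudo-atomic template: no near-degenerate views, so the
  # argmax orientation is the planted one and localisation is sharp
  tpl <- pseudo_atomic_phantom(atom_sigma = 0.6, n_atoms = 200)
  g <- search_grid(45, 60)
  ori <- enumerate_grid(g)
  set.seed(31)
  slots <- expand.grid(x = seq(48, 464, by = 52), y = seq(48, 464, by = 52))
  slots <- slots[sample.int(nrow(slots), 20), ]
  img <- matrix(rnorm(512 * 512), 512, 512)
  c0 <- 16
  for (i in 1:20) {
    k <- sample.int(nrow(ori), 1)
    p <- project_volume(tpl, ori$phi[k], ori$theta[k], ori$psi[k])
    amp <- 15 / sqrt(sum(p^2))
    xs <- slots$x[i] - c0 + 1:32
    ys <- slots$y[i] - c0 + 1:32
    img[xs, ys] <- img[xs, ys] + amp * p
  }
  maps <- run_search(micrograph(img, 4), tpl, g)
  thr <- detection_threshold(maps$n_correlations, 1)
  det <- extract_peaks(maps, thr)
  expect_equal(nrow(det), 20)
  d2 <- outer(det$x_px, slots$x, "-")^2 + outer(det$y_px, slots$y, "-")^2
  expect_true(all(apply(d2, 2, min) <= 2))
})

test_that("false-positive calibration: about one noise peak per image", {
  tpl <- pseudo_atomic_phantom(atom_sigma = 0.45, n_atoms = 150)
  ctf <- ctf_params(15000)
  g <- search_grid(60, 90)
  cnt <- vapply(1:20, function(s) {
    m <- noise_micrograph(128, seed = 300 + s, ctf = ctf)
    maps <- run_search(m, tpl, g)
    thr <- detection_threshold(maps$n_correlations, 1)
    nrow(extract_peaks(maps, thr, min_separation = 2, border = 0))
  }, 0)
  expect_lt(abs(mean(cnt) - 1), 0.7)
})

test_that("snr_at_pose agrees with the MIP and is small on pure noise", {
  vols <- fixture_volumes()
  sim <- simulate_micrograph(vols["mature"], c(mature = 3), 200,
                             noise_sd = 1, signal_snr = 12, seed = 41)
  maps <- run_search(sim$micrograph, vols$mature, search_grid(45, 60))
  det <- extract_peaks(maps, 7)
  expect_gt(nrow(det), 0)
  for (i in seq_len(nrow(det))) {
    p <- pose(det$x_px[i], det$y_px[i], det$phi_deg[i], det$theta_deg[i],
              det$psi_deg[i], det$dz_A[i])
    expect_equal(snr_at_pose(sim$micrograph, vols$mature, p), det$snr[i],
                 tolerance = 1e-6)
  }
  # pure-noise poses are standard normal: |snr| < 5 w.h.p.
  m <- noise_micrograph(128, seed = 42)
  wh <- whiten_image(m)
  vals <- vapply(1:50, function(i) {
    snr_at_pose(m, vols$mature,
                pose(20 + 2 * i, 100 - i, 7 * i, 3 * i, 11 * i),
                whitened = wh)
  }, 0)
  expect_true(all(abs(vals) < 5))
  expect_error(snr_at_pose(m, vols$mature, pose(500, 10, 0, 0, 0)),
               "out of bounds")
})

test_that("the wrong template scores lower at the right template's pose", {
  vols <- fixture_volumes(appendage_fraction = 0.3)
  sim <- simulate_micrograph(vols["immature"], c(immature = 15), 360,
                             noise_sd = 1, signal_snr = 12, seed = 9)
  wh <- whiten_image(sim$micrograph)
  wins <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    p <- pose(tr$x_px, tr$y_px, tr$phi_deg, tr$theta_deg, tr$psi_deg)
    snr_at_pose(sim$micrograph, vols$immature, p, whitened = wh) >
      snr_at_pose(sim$micrograph, vols$mature, p, whitened = wh)
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("refinement is idempotent on grid detections and monotone in SNR", {
  vols <- fixture_volumes()
  g <- search_grid(45, 60)
  sim <- simulate_micrograph(vols["mature"], c(mature = 5), 256,
                             noise_sd = 1, signal_snr = 12, seed = 51)
  maps <- run_search(sim$micrograph, vols$mature, g)
  det <- extract_peaks(maps, 7)
  expect_gt(nrow(det), 2)
  wh <- maps$whitened
  # fine grid = coarse grid: the argmax cannot move
  r0 <- refine_pose(sim$micrograph, vols$mature, det[1, ], fine = g,
                    coarse = g, whitened = wh)
  expect_equal(r0$snr, det$snr[1], tolerance = 1e-9)
  expect_equal(
    unlist(r0[c("x_px", "y_px", "phi_deg", "theta_deg", "psi_deg")]),
    unlist(det[1, c("x_px", "y_px", "phi_deg", "theta_deg", "psi_deg")]))
  # finer steps never lower the SNR
  fine <- search_grid(15, 20)
  for (i in seq_len(nrow(det))) {
    r <- refine_pose(sim$micrograph, vols$mature, det[i, ], fine = fine,
                     coarse = g, whitened = wh)
    expect_gte(r$snr, det$snr[i])
  }
})

test_that("refinement pulls an off-grid orientation toward the truth", {
  # plant an off-grid pose, start from the nearest grid point (one coarse
  # step off) and refine; pseudo-atomic template avoids degenerate views
  tpl <- pseudo_atomic_phantom(atom_sigma = 0.6, n_atoms = 200)
  truth <- c(120 + 9, 90 + 8, 240 - 10)
  p <- project_volume(tpl, truth[1], truth[2], truth[3])
  set.seed(52)
  img <- matrix(rnorm(160 * 160, 0, 1e-3), 160, 160)
  c0 <- 16
  img[80 - c0 + 1:32, 80 - c0 + 1:32] <-
    img[80 - c0 + 1:32, 80 - c0 + 1:32] + p
  m <- micrograph(img, 4)
  det <- tibble::tibble(image_id = "i", template_id = "t", x_px = 80L,
                        y_px = 80L, phi_deg = 120, theta_deg = 90,
                        psi_deg = 240, dz_A = 0, snr = 0)
  det$snr <- snr_at_pose(m, tpl, pose(80, 80, 120, 90, 240))
  # offsets of +/- 12 degrees at 3-degree steps cover the planted offset
  r <- refine_pose(m, tpl, det, fine = search_grid(3, 3),
                   coarse = search_grid(12, 12))
  expect_lte(abs(r$phi_deg - truth[1] %% 360), 3 + 1e-9)
  expect_lte(abs(r$theta_deg - truth[2]), 3 + 1e-9)
  expect_lte(abs(r$psi_deg - truth[3] %% 360), 3 + 1e-9)
  expect_gte(r$snr, det$snr)
})

test_that("pixel-size mismatch and oversized templates are rejected", {
  vols <- fixture_volumes()
  m <- noise_micrograph(64, seed = 61, pixel_size = 5)
  expect_error(run_search(m, vols$mature, search_grid(90, 180)), "mismatch")
  m2 <- noise_micrograph(16, seed = 62, pixel_size = 4)
  expect_error(run_search(m2, vols$mature, search_grid(90, 180)),
               "exceeds image")
})
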