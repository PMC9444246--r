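#' Specify a class-structured phantom
#'
#' Defines a family of phantom densities built from isotropic 3D Gaussian
#' blobs: a shared core plus, per class, labelled blob sets that are added
#' to the core (emulating structurally related complexes such as maturation
#' states sharing a core and differing by bound factors). All classes share
#' the identical core at identical voxels, so the volumes are pairwise
#' aligned by construction.
#'
#' @param box_size Voxels per edge (>= 8).
#' @param voxel_size Angstrom per voxel.
#' @param core List of blobs, each `list(center = c(x, y, z), radius, amplitude)`
#'   with `center` in 0-based voxel coordinates, `radius` the Gaussian sigma
#'   in voxels.
#' @param class_variants Named list: class name -> named list of component
#'   label -> list of blobs added to the core for that class. May include a
#'   class with no variants (core only), using `list()`.
#' @return An object of class `tm2d_phantom_spec`.
#' @export
phantom_spec <- function(box_size, voxel_size, core, class_variants) {
  stopifnot(box_size >= 8, voxel_size > 0, is.list(core),
            is.list(class_variants), !is.null(names(class_variants)))
  all_blobs <- c(core, unlist(unname(lapply(class_variants, unname)),
                              recursive = FALSE))
  for (b in all_blobs) {
    if (any(b$center < 0) || any(b$center > box_size - 1)) {
      stop("blob center outside the box", call. = FALSE)
    }
  }
  structure(
    list(box_size = box_size, voxel_size = voxel_size, core = core,
         class_variants = class_variants),
    class = "tm2d_phantom_spec"
  )
}

# rasterise a list of Gaussian blobs onto an n^3 grid (0-based coords)
rasterise_blobs <- function(blobs, n) {
  out <- array(0, c(n, n, n))
  if (!length(blobs)) return(out)
  ax <- 0:(n - 1)
  for (b in blobs) {
    dx2 <- (ax - b$center[1])^2
    dy2 <- (ax - b$center[2])^2
    dz2 <- (ax - b$center[3])^2
    g <- exp(-outer(outer(dx2, dy2, `+`), dz2, `+`) / (2 * b$radius^2))
    out <- out + b$amplitude * g
  }
  out
}

# minimum sigma-normalised distance from each voxel to a blob set
blob_norm_dist <- function(blobs, n) {
  ax <- 0:(n - 1)
  nd <- array(Inf, c(n, n, n))
  for (b in blobs) {
    d2 <- outer(outer((ax - b$center[1])^2, (ax - b$center[2])^2, `+`),
                (ax - b$center[3])^2, `+`)
    nd <- pmin(nd, sqrt(d2) / b$radius)
  }
  nd
}

#' Build the class volumes of a phantom spec
#'
#' Deterministic: each class volume is the shared core plus its labelled
#' variant blob sets; component label voxel sets (within 3 sigma of the
#' set's blobs) are recorded on the volume for use by
#' [truncate_template()].
#'
#' @param spec A [phantom_spec()].
#' @return A named list of [volume()] objects, one per class.
#' @export
make_class_volumes <- function(spec) {
  stopifnot(inherits(spec, "tm2d_phantom_spec"))
  n <- spec$box_size
  core <- rasterise_blobs(spec$core, n)
  core_nd <- blob_norm_dist(spec$core, n)
  lapply(spec$class_variants, function(variants) {
    data <- core
    # voxels within 3 sigma of any set; contested voxels go to the set
    # whose blob is closest in sigma-normalised distance
    nds <- list(core = core_nd)
    for (lab in names(variants)) {
      data <- data + rasterise_blobs(variants[[lab]], n)
      nds[[lab]] <- blob_norm_dist(variants[[lab]], n)
    }
    nd_mat <- vapply(nds, as.numeric, numeric(n^3))
    nearest <- max.col(-nd_mat, ties.method = "first")
    in_any <- apply(nd_mat, 1, min) <= 3
    labels <- lapply(seq_along(nds), function(j) {
      which(in_any & nearest == j)
    })
    names(labels) <- names(nds)
    volume(data, spec$voxel_size, component_labels = labels)
  })
}

# deterministic atom cloud: spherical Fibonacci directions with cube-root
# radial spacing fill a ball of radius R around `center` with n atoms
atom_cloud <- function(center, R, n, sigma, amplitude) {
  k <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (k - 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  th <- golden * k
  r <- R * ((k - 0.5) / n)^(1 / 3)
  lapply(k, function(i) {
    list(center = center + r[i] * c(rho[i] * cos(th[i]),
                                    rho[i] * sin(th[i]), z[i]),
         radius = sigma, amplitude = amplitude)
  })
}

#' A ready-made two-class phantom
#'
#' Two classes sharing an identical core modelled as a deterministic cloud
#' of small Gaussian "atoms" (fine structural texture, so mismatched
#' orientations decorrelate as they do for real macromolecules). Class
#' `"immature"` additionally carries a labelled `"appendage"`: three atom
#' clusters spread around the core surface, akin to the several biogenesis
#' factors bound to a precursor and absent from the mature complex. Class
#' `"mature"` carries a smaller private `"stalk"` cluster (mature complexes
#' also gain parts their precursors lack). The appendage-to-core mass ratio
#' is the separability dial for downstream searches; the stalk is half that
#' fraction. Construction is fully deterministic (no RNG).
#'
#' @param box_size Voxels per edge.
#' @param voxel_size Angstrom per voxel.
#' @param appendage_fraction Appendage-to-core mass ratio (default 0.2).
#' @return A [phantom_spec()] with classes `"mature"` and `"immature"`.
#' @export
two_class_phantom_spec <- function(box_size = 32, voxel_size = 4,
                                   appendage_fraction = 0.2) {
  c0 <- floor(box_size / 2)
  r <- box_size / 10
  n_core <- 60
  sig <- 1
  core <- atom_cloud(c(c0, c0, c0), 2.2 * r, n_core, sig, 1)
  n_app <- max(3, round(appendage_fraction * n_core))
  app_centers <- list(c(c0, c0 - 2.9 * r, c0 + 1.4 * r),
                      c(c0 + 2.6 * r, c0 + 2.2 * r, c0 - 1.2 * r),
                      c(c0 - 2.8 * r, c0 + 0.6 * r, c0 + 2.4 * r))
  per <- diff(round(seq(0, n_app, length.out = 4)))
  appendage <- do.call(c, lapply(1:3, function(j) {
    atom_cloud(app_centers[[j]], 0.8 * r, per[j], sig, 1)
  }))
  n_stalk <- max(2, round(appendage_fraction / 2 * n_core))
  stalk <- atom_cloud(c(c0 - 2.4 * r, c0 - 2.4 * r, c0 - 1.8 * r),
                      0.8 * r, n_stalk, sig, 1)
  phantom_spec(
    box_size, voxel_size, core,
    class_variants = list(
      mature = list(stalk = stalk),
      immature = list(appendage = appendage)
    )
  )
}

#' Build a two-region compartment mask
#'
#' Simple geometric compartment masks mimicking a nuclear-envelope boundary:
#' either a half-plane split along x, or an ellipse.
#'
#' @param nx,ny Image dimensions in pixels.
#' @param type `"halfplane"` or `"ellipse"`.
#' @param boundary For `"halfplane"`: the x coordinate of the split; pixels
#'   with `x < boundary` get `labels[1]`.
#' @param center,radii For `"ellipse"`: center `c(x, y)` and radii
#'   `c(rx, ry)` in pixels; inside gets `labels[1]`.
#' @param labels Two region labels, default `c("nucleus", "cytoplasm")`.
#' @return A character matrix of labels, x-fastest layout.
#' @export
compartment_mask <- function(nx, ny, type = c("halfplane", "ellipse"),
                             boundary = nx / 2, center = c(nx / 2, ny / 2),
                             radii = c(nx / 4, ny / 4),
                             labels = c("nucleus", "cytoplasm")) {
  type <- match.arg(type)
  x <- matrix(0:(nx - 1), nx, ny)
  y <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  inside <- if (type == "halfplane") {
    x < boundary
  } else {
    ((x - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 <= 1
  }
  out <- matrix(labels[2], nx, ny)
  out[inside] <- labels[1]
  out
}

#' Simulate a micrograph with planted particles
#'
#' Plants particles of the given classes at uniform-random in-bounds,
#' non-overlapping positions and uniform-random orientations into white
#' Gaussian noise, after projecting and CTF-modulating each particle.
#' "Planted signal SNR s" is calibrated so that the noiseless particle's
#' whitened, unit-norm-template correlation at its true pose is s (for white
#' noise the whitening filter is flat, so the amplitude is
#' `s * noise_sd / ||ctf-modulated projection||`); the expected recovered
#' 2DTM SNR at the true pose is then s.
#'
#' @param volumes Named list of class [volume()]s (shared voxel size).
#' @param counts Named integer vector: particles per class.
#' @param image_size `c(nx, ny)` in pixels (scalar for square).
#' @param ctf Optional [ctf_params()] applied to every particle and recorded
#'   on the micrograph.
#' @param noise_sd Standard deviation of the white Gaussian background.
#' @param signal_snr Planted signal SNR, scalar or named per class
#'   (default 10).
#' @param mask Optional compartment label matrix (see
#'   [compartment_mask()]) recorded on the micrograph and used to annotate
#'   the truth table.
#' @param seed Optional RNG seed (reproducible truth and noise).
#' @param image_id Identifier for the micrograph.
#' @param max_tries Rejection-sampling attempts per particle before a
#'   packing error.
#' @return A list with `micrograph` and `truth` (tibble: `particle_id,
#'   class, x_px, y_px, phi_deg, theta_deg, psi_deg, dz_A, signal_snr,
#'   compartment`).
#' @export
simulate_micrograph <- function(volumes, counts, image_size, ctf = NULL,
                                noise_sd = 1, signal_snr = 10, mask = NULL,
                                seed = NULL, image_id = "sim",
                                max_tries = 200L) {
  stopifnot(is.list(volumes), length(volumes) >= 1,
            !is.null(names(volumes)), noise_sd > 0)
  if (!is.null(seed)) set.seed(seed)
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  nx <- image_size[1]; ny <- image_size[2]
  vs <- unique(vapply(volumes, `[[`, 0, "voxel_size"))
  if (length(vs) != 1L) stop("all volumes must share a voxel size", call. = FALSE)
  nt <- volumes[[1]]$box_size
  margin <- floor(nt / 2) + 1L
  if (nx - 2 * margin <= 0 || ny - 2 * margin <= 0) {
    stop("image too small for the template box", call. = FALSE)
  }
  counts <- counts[counts > 0]
  total <- sum(counts)
  snr_of <- function(cls) {
    if (length(signal_snr) == 1L && is.null(names(signal_snr))) {
      signal_snr
    } else {
      signal_snr[[cls]]
    }
  }
  img <- matrix(rnorm(nx * ny, 0, noise_sd), nx, ny)
  # non-overlapping positions: center distance > template diameter
  xs <- ys <- numeric(0)
  if (total > 0) {
    for (i in seq_len(total)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        px <- runif(1, margin, nx - margin - 1)
        py <- runif(1, margin, ny - margin - 1)
        if (!length(xs) || all((xs - px)^2 + (ys - py)^2 > nt^2)) {
          xs <- c(xs, px); ys <- c(ys, py); placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", total, " non-overlapping particles in a ",
             nx, " x ", ny, " image", call. = FALSE)
      }
    }
  }
  xs <- round(xs); ys <- round(ys)
  truth <- tibble::tibble(
    particle_id = seq_len(total),
    class = rep(names(counts), counts),
    x_px = as.integer(xs), y_px = as.integer(ys),
    phi_deg = runif(total, 0, 360),
    theta_deg = acos(runif(total, -1, 1)) * 180 / pi,
    psi_deg = runif(total, 0, 360),
    dz_A = 0,
    signal_snr = vapply(rep(names(counts), counts), snr_of, 0,
                        USE.NAMES = FALSE)
  )
  for (i in seq_len(total)) {
    v <- volumes[[truth$class[i]]]
    p <- cpp_project_volume(as.numeric(v$data), nt, truth$phi_deg[i],
                            truth$theta_deg[i], truth$psi_deg[i])
    if (!is.null(ctf)) p <- apply_ctf(p, ctf, vs)
    amp <- truth$signal_snr[i] * noise_sd / sqrt(sum(p^2))
    c0 <- floor(nt / 2)
    x0 <- truth$x_px[i] - c0; y0 <- truth$y_px[i] - c0
    img[x0 + seq_len(nt), y0 + seq_len(nt)] <-
      img[x0 + seq_len(nt), y0 + seq_len(nt)] + amp * p
  }
  truth$compartment <- if (!is.null(mask)) {
    mask[cbind(truth$x_px + 1L, truth$y_px + 1L)]
  } else {
    NA_character_
  }
  m <- micrograph(img, pixel_size = vs, ctf = ctf, mask = mask,
                  image_id = image_id)
  list(micrograph = m, truth = truth)
}

#' Pseudo-atomic phantom volume
#'
#' A cloud of small Gaussian "atoms" scattered uniformly inside a sphere,
#' emulating the fine structural detail of a macromolecular template. Unlike
#' smooth-blob phantoms, its projections have near-flat spectra after
#' whitening, so search correlation fields decorrelate over about a pixel --
#' the regime in which the independence assumption behind
#' [detection_threshold()] holds.
#'
#' @param box_size Voxels per edge.
#' @param voxel_size Angstrom per voxel.
#' @param n_atoms Number of atoms (default 200).
#' @param radius_fraction Sphere radius as a fraction of the half-box
#'   (default 0.6).
#' @param atom_sigma Atom Gaussian sigma in voxels (default 0.8).
#' @param seed RNG seed for the atom positions (deterministic volume).
#' @return A [volume()].
#' @export
pseudo_atomic_phantom <- function(box_size = 32, voxel_size = 4,
                                  n_atoms = 200, radius_fraction = 0.6,
                                  atom_sigma = 0.8, seed = 1) {
  set.seed(seed)
  c0 <- floor(box_size / 2)
  rmax <- radius_fraction * box_size / 2
  # uniform in a sphere via rejection
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n_atoms) {
    cand <- matrix(runif(3 * 2 * n_atoms, -rmax, rmax), ncol = 3)
    cand <- cand[rowSums(cand^2) <= rmax^2, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- pts[seq_len(n_atoms), , drop = FALSE] + c0
  blobs <- lapply(seq_len(n_atoms), function(i) {
    list(center = pts[i, ], radius = atom_sigma, amplitude = 1)
  })
  volume(rasterise_blobs(blobs, box_size), voxel_size)
}
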