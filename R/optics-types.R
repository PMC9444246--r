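#' Create a density volume
#'
#' A cubic 3D density grid with a physical voxel size, used as the source of
#' template projections. Components of the density (for example an rRNA core
#' or a biogenesis-factor appendage) can be labelled as voxel index sets so
#' that templates can later be truncated component-wise.
#'
#' @param data Numeric 3D array, cubic (`n >= 8` voxels per edge), all finite.
#'   Stored x-fastest: element `(x, y, z)` (0-based) is `data[x+1, y+1, z+1]`.
#' @param voxel_size Voxel edge length in Angstrom (> 0).
#' @param component_labels Optional named list of integer vectors of linear
#'   voxel indices (1-based into `data`). Sets must be pairwise disjoint.
#' @return An object of class `tm2d_volume` with fields `data`, `voxel_size`,
#'   `box_size`, `component_labels`.
#' @export
volume <- function(data, voxel_size, component_labels = NULL) {
  d <- dim(data)
  if (length(d) != 3L || length(unique(d)) != 1L) {
    stop("volume data must be a cubic 3D array, got dimensions [",
         paste(d, collapse = " x "), "]", call. = FALSE)
  }
  if (d[1] < 8L) stop("box_size must be >= 8 voxels", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("voxel_size must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("volume contains non-finite values", call. = FALSE)
  if (!is.null(component_labels)) {
    stopifnot(is.list(component_labels), !is.null(names(component_labels)))
    idx <- unlist(component_labels, use.names = FALSE)
    if (length(idx) && (anyDuplicated(idx) || any(idx < 1L | idx > length(data)))) {
      stop("component label sets must be disjoint subsets of the grid", call. = FALSE)
    }
  }
  structure(
    list(data = data, voxel_size = voxel_size, box_size = d[1],
         component_labels = component_labels),
    class = "tm2d_volume"
  )
}

#' Create a micrograph
#'
#' A 2D cryo-EM image with a pixel size, optional CTF parameters, an optional
#' per-pixel compartment mask (e.g. nucleus / cytoplasm / vacuole) and an
#' optional sample thickness.
#'
#' @param data Numeric matrix, all finite. Stored x-fastest: pixel `(x, y)`
#'   (0-based) is `data[x+1, y+1]`.
#' @param pixel_size Pixel size in Angstrom (> 0).
#' @param ctf Optional [ctf_params()] object.
#' @param mask Optional character matrix of compartment labels, same shape as
#'   `data`.
#' @param thickness_nm Optional sample thickness in nm.
#' @param image_id Optional identifier carried into detection tables.
#' @return An object of class `tm2d_micrograph`.
#' @export
micrograph <- function(data, pixel_size, ctf = NULL, mask = NULL,
                       thickness_nm = NULL, image_id = "image") {
  stopifnot(is.matrix(data))
  if (!all(is.finite(data))) stop("micrograph contains non-finite values", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single positive number", call. = FALSE)
  }
  if (!is.null(mask) && !identical(dim(mask), dim(data))) {
    stop("mask must have the same shape as the image data", call. = FALSE)
  }
  if (!is.null(ctf) && !inherits(ctf, "tm2d_ctf")) {
    stop("ctf must be a ctf_params() object", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size = pixel_size, ctf = ctf, mask = mask,
         thickness_nm = thickness_nm, image_id = image_id),
    class = "tm2d_micrograph"
  )
}

#' Contrast transfer function parameters
#'
#' @param defocus1,defocus2 Defocus along the major/minor astigmatism axes in
#'   Angstrom; positive values mean underfocus. `defocus2` defaults to
#'   `defocus1` (no astigmatism).
#' @param astig_angle Astigmatism axis angle in degrees.
#' @param voltage Acceleration voltage in keV (> 0).
#' @param cs Spherical aberration in mm (>= 0).
#' @param amplitude_contrast Amplitude contrast fraction in `[0, 1]`.
#' @param phase_shift Additional phase shift in radians.
#' @return An object of class `tm2d_ctf`.
#' @export
ctf_params <- function(defocus1, defocus2 = defocus1, astig_angle = 0,
                       voltage = 300, cs = 2.7, amplitude_contrast = 0.07,
                       phase_shift = 0) {
  if (voltage <= 0) stop("voltage must be > 0", call. = FALSE)
  if (cs < 0) stop("cs must be >= 0", call. = FALSE)
  if (amplitude_contrast < 0 || amplitude_contrast > 1) {
    stop("amplitude_contrast must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(defocus1 = defocus1, defocus2 = defocus2, astig_angle = astig_angle,
         voltage = voltage, cs = cs, amplitude_contrast = amplitude_contrast,
         phase_shift = phase_shift),
    class = "tm2d_ctf"
  )
}

#' Relativistic electron wavelength
#'
#' @param voltage Acceleration voltage in keV.
#' @return Wavelength in Angstrom (about 0.0197 A at 300 keV).
#' @export
electron_wavelength <- function(voltage) {
  v <- voltage * 1000
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Create a template pose
#'
#' Position, orientation and defocus offset of one template placement in a
#' micrograph. Angles follow the ZYZ intrinsic Euler convention (phi, theta,
#' psi, degrees) applied to the template before projection along +z, and are
#' canonicalised to `phi, psi` in `[0, 360)` and `theta` in `[0, 180]`.
#'
#' @param x,y 0-based pixel coordinates (x = column, y = row).
#' @param phi,theta,psi Euler angles in degrees.
#' @param dz Defocus offset in Angstrom relative to the micrograph CTF.
#' @return A one-row tibble with columns `x, y, phi, theta, psi, dz`.
#' @export
pose <- function(x, y, phi = 0, theta = 0, psi = 0, dz = 0) {
  theta <- theta %% 360
  if (theta > 180) {
    theta <- 360 - theta
    phi <- phi + 180
    psi <- psi + 180
  }
  tibble::tibble(x = x, y = y, phi = phi %% 360, theta = theta,
                 psi = psi %% 360, dz = dz)
}

#' @export
print.tm2d_volume <- function(x, ...) {
  cat("<tm2d_volume> ", x$box_size, "^3 voxels, ", x$voxel_size, " A/voxel",
      sep = "")
  if (!is.null(x$component_labels)) {
    cat(", components: ", paste(names(x$component_labels), collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.tm2d_micrograph <- function(x, ...) {
  d <- dim(x$data)
  cat("<tm2d_micrograph> ", d[1], " x ", d[2], " px, ", x$pixel_size,
      " A/px", if (!is.null(x$ctf)) ", CTF set" else "",
      if (!is.null(x$mask)) ", masked" else "", "\n", sep = "")
  invisible(x)
}
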