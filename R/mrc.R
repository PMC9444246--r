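# MRC2014 (mode 2, float32, little-endian) reader/writer. The x axis is the
# fastest-varying axis in the file, matching this package's x-first array
# layout, so data pass through without permutation.

#' Write a volume or micrograph to an MRC2014 file
#'
#' Mode-2 (float32) MRC2014 with the voxel size recorded in the cell
#' dimensions (`cella = m * voxel_size`).
#'
#' @param obj A [volume()] or [micrograph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(obj, path) {
  if (inherits(obj, "tm2d_volume")) {
    data <- obj$data
    dims <- dim(data)
    vox <- obj$voxel_size
  } else if (inherits(obj, "tm2d_micrograph")) {
    data <- obj$data
    dims <- c(dim(data), 1L)
    vox <- obj$pixel_size
  } else {
    stop("write_mrc expects a tm2d_volume or tm2d_micrograph", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                    # nx ny nz
  wi(2L)                      # mode 2 = float32
  wi(c(0L, 0L, 0L))           # nxstart nystart nzstart
  wi(dims)                    # mx my mz
  wf(dims * vox)              # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))  # dmin dmax dmean
  wi(c(if (dims[3] > 1L) 1L else 0L, 0L))  # ispg, nsymbt
  writeBin(raw(100), con)     # extra (words 25-49)
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(data))                # rms
  wi(0L)                      # nlabl
  writeBin(raw(800), con)     # labels
  wf(data)
  invisible(path)
}

#' Read an MRC2014 file as a volume or micrograph
#'
#' Mode-2 files only. A file with `nz > 1` is returned as a [volume()] (and
#' must be cubic); `nz = 1` yields a [micrograph()]. The voxel size is taken
#' from `cella / mx`.
#'
#' @param path MRC file path.
#' @param ... Passed to the [volume()] or [micrograph()] constructor
#'   (e.g. `ctf`, `component_labels`).
#' @return A `tm2d_volume` or `tm2d_micrograph`.
#' @export
read_mrc <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (any(dims < 1) || any(dims > 1e5)) {
    stop("malformed MRC header at offset 0: implausible dimensions [",
         paste(dims, collapse = " x "), "]", call. = FALSE)
  }
  if (mode != 2L) {
    stop("unsupported MRC mode ", mode, " at offset 12 (only mode 2, ",
         "float32, is supported)", call. = FALSE)
  }
  ri(3)               # nxstart..
  m <- ri(3)          # mx my mz
  cella <- rf(3)
  seek(con, 208)
  map_tag <- readChar(con, 4, useBytes = TRUE)
  if (!identical(map_tag, "MAP ")) {
    stop("malformed MRC header at offset 208: missing 'MAP ' tag",
         call. = FALSE)
  }
  vox <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  seek(con, 1024)
  n_vals <- prod(as.numeric(dims))
  data <- readBin(con, "numeric", n_vals, size = 4, endian = "little")
  if (length(data) < n_vals) {
    stop("truncated MRC data block: expected ", n_vals, " values, got ",
         length(data), call. = FALSE)
  }
  if (dims[3] > 1L) {
    if (length(unique(dims)) != 1L) {
      stop("non-cubic volume: dimensions [", paste(dims, collapse = " x "),
           "]; templates must be cubic", call. = FALSE)
    }
    volume(array(data, dims), voxel_size = vox, ...)
  } else {
    micrograph(matrix(data, dims[1], dims[2]), pixel_size = vox, ...)
  }
}
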