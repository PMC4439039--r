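#' 3D intensity volume
#'
#' A `brain_volume` wraps a numeric 3D array in storage order (z, y, x)
#' together with its physical voxel pitch in micrometres per axis and a
#' channel tag. The axis convention throughout the package is: illumination
#' propagates along +y (the light sheet enters the sample from the -y side)
#' and detection is along +z (the camera faces the +z side), matching the
#' lateral-illumination / dorsal-detection geometry of a light-sheet
#' microscope recording of a cleared brain.
#'
#' @param data numeric 3D array, dimensions (z, y, x).
#' @param pitch numeric length-3 voxel pitch in micrometres, order (z, y, x).
#'   The default (3.23, 1.61, 1.61) is a typical high-resolution light-sheet
#'   sampling (xy pixel 1.61 um, z step 3.23 um).
#' @param channel channel tag, e.g. `"green"` or `"red"`.
#' @return an object of class `brain_volume`.
#' @export
brain_volume <- function(data, pitch = c(3.23, 1.61, 1.61), channel = "green") {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3, length(pitch) == 3, all(pitch > 0))
  structure(list(data = data, pitch = as.numeric(pitch), channel = channel),
            class = "brain_volume")
}

#' @export
dim.brain_volume <- function(x) dim(x$data)

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_volume> %d x %d x %d (z,y,x), pitch %s um, channel %s\n",
              d[1], d[2], d[3], paste(signif(x$pitch, 4), collapse = " x "),
              x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

check_congruent <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data %||% a), dim(b$data %||% b)))
    stop("shape mismatch between ", what, call. = FALSE)
  invisible(TRUE)
}

#' Read / write a volume as a multi-page TIFF
#'
#' One TIFF page per z-plane. Intensities are stored as 16-bit samples scaled
#' by `full_scale` (the 12-bit camera ceiling by default); pitch, channel and
#' scale are recorded in a JSON sidecar (`<file>.json`) so that a round trip
#' restores the volume.
#'
#' @param vol a [brain_volume()].
#' @param path output `.tif` path.
#' @param full_scale intensity value mapped to the top of the 16-bit range.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [brain_volume()].
#' @export
write_volume <- function(vol, path, full_scale = 4095) {
  stopifnot(inherits(vol, "brain_volume"))
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(i) {
    m <- vol$data[i, , ] / full_scale
    matrix(pmin(pmax(m, 0), 1), d[2], d[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(pitch_um = vol$pitch, channel = vol$channel,
                  full_scale = full_scale, dim_zyx = d)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  full_scale <- meta$full_scale %||% 4095
  d <- c(length(pages), dim(pages[[1]]))
  a <- array(0, d)
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]] * full_scale
  pitch <- as.numeric(unlist(meta$pitch_um %||% c(3.23, 1.61, 1.61)))
  brain_volume(a, pitch = pitch, channel = meta$channel %||% "green")
}

# Physical coordinates (um) of voxel centres along one axis: centre of voxel i
# is at (i - 0.5) * pitch.
axis_centers <- function(n, pitch) (seq_len(n) - 0.5) * pitch
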