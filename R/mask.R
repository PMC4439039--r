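#' Background-window intensity threshold
#'
#' Determines the tissue/background threshold from a rectangular image window
#' known to lie outside the sample: the threshold is the intensity that the
#' brightest 1% of window voxels exceed, i.e. the 99th percentile of the
#' window intensities, computed over all z-planes of the window footprint.
#' The percentile uses the linear-interpolation definition between order
#' statistics (R quantile type 7).
#'
#' @param vol a [brain_volume()].
#' @param window integer list/vector giving the window bounds as voxel index
#'   ranges `list(z = c(z0, z1), y = c(y0, y1), x = c(x0, x1))` (1-based,
#'   inclusive). `z` may be omitted to use the full z extent.
#' @param percentile upper-tail fraction selected; default 0.01 (upper 1%).
#' @param min_area minimum window footprint in pixels (y extent times x
#'   extent); the default reflects the >500x500 px recommendation for real
#'   recordings and can be lowered for small synthetic volumes.
#' @param mask optional previously computed tissue mask; a warning is issued
#'   if the window intersects it.
#' @return numeric threshold, with attributes `window` and `percentile`.
#' @export
background_threshold <- function(vol, window, percentile = 0.01,
                                 min_area = 500 * 500, mask = NULL) {
  stopifnot(inherits(vol, "brain_volume"))
  d <- dim(vol$data)
  if (is.null(window$z)) window$z <- c(1L, d[1])
  zr <- window$z[1]:window$z[2]
  yr <- window$y[1]:window$y[2]
  xr <- window$x[1]:window$x[2]
  if (length(yr) * length(xr) < min_area)
    stop("background window footprint smaller than min_area (",
         length(yr) * length(xr), " < ", min_area, ")")
  if (!is.null(mask) && any(mask$data[zr, yr, xr] > 0))
    warning("background window overlaps detected tissue")
  vals <- vol$data[zr, yr, xr]
  if (max(vals) == min(vals)) {
    warning("degenerate (constant) background window; threshold equals it")
    thr <- vals[1]
  } else {
    thr <- unname(stats::quantile(vals, probs = 1 - percentile, type = 7))
  }
  structure(thr, window = window, percentile = percentile)
}

#' Binary 3D tissue mask
#'
#' Tissue is every voxel strictly brighter than the background threshold.
#' Optionally (default on) only the largest 6-connected component is kept,
#' discarding isolated bright specks outside the sample, and fully enclosed
#' background cavities up to a size limit are closed (cleared internal
#' cavities still count as tissue occupancy for masking purposes, although
#' they contribute no attenuation path; see [compute_path_lengths()]).
#'
#' @param vol a [brain_volume()].
#' @param threshold threshold from [background_threshold()] (or a number).
#' @param largest_component keep only the largest connected component.
#' @param close_cavities fill enclosed background cavities.
#' @param max_cavity_voxels only cavities up to this many voxels are closed.
#' @return a `tissue_mask`: list with logical array `data`, the `threshold`
#'   used and provenance fields.
#' @export
compute_tissue_mask <- function(vol, threshold, largest_component = TRUE,
                                close_cavities = TRUE,
                                max_cavity_voxels = Inf) {
  stopifnot(inherits(vol, "brain_volume"), is.finite(threshold))
  m <- vol$data > as.numeric(threshold)
  if (!any(m)) stop("empty mask: no voxel exceeds the threshold")
  if (largest_component) {
    lab <- label_components3(m)
    keep <- which.max(tabulate(lab[lab > 0L]))
    m <- lab == keep
  }
  if (close_cavities) {
    bg <- label_components3(!m)
    d <- dim(m)
    border_labels <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                              bg[, , c(1, d[3])]))
    sizes <- tabulate(bg[bg > 0L])
    enclosed <- setdiff(which(sizes <= max_cavity_voxels), border_labels)
    if (length(enclosed)) m[bg %in% enclosed] <- TRUE
  }
  structure(list(data = m, threshold = as.numeric(threshold),
                 channel = vol$channel, pitch = vol$pitch,
                 provenance = list(window = attr(threshold, "window"),
                                   percentile = attr(threshold, "percentile"))),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tissue_mask> %d x %d x %d (z,y,x), %d tissue voxels (%.1f%%), threshold %.4g\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data), x$threshold))
  invisible(x)
}
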