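# Longitudinal comparison machinery: affine re-registration on corresponding
# landmark sets with isotropic scale-change reporting, excitation-power /
# display-range intensity normalisation, and an overlap score for re-imaged
# volumes.

#' Least-squares affine map between corresponding point sets
#'
#' Fits the affine map (3x3 linear part plus translation) minimising the sum
#' of squared residuals over corresponding landmark pairs, e.g. cell-body
#' annotations re-identified in a re-imaged dataset. The isotropic scale
#' change is summarised as `(|det A|^(1/3) - 1) * 100` percent, the single
#' number by which the sample has uniformly grown or shrunk between
#' sessions.
#'
#' @param moving n x 3 matrix of landmark positions (um) in the moving
#'   dataset.
#' @param fixed n x 3 matrix of the same landmarks in the fixed dataset.
#' @return an `affine_map`: list with `A` (3x3), `t` (length 3),
#'   `scale_change_percent`, `rms_residual`, `n_points`.
#' @export
estimate_affine <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(ncol(moving) == 3, ncol(fixed) == 3,
            nrow(moving) == nrow(fixed))
  if (nrow(moving) < 4)
    stop("at least 4 non-coplanar point pairs required")
  X <- cbind(moving, 1)
  qx <- qr(X)
  if (qx$rank < 4)
    stop("degenerate landmark configuration (coplanar or collinear points)")
  B <- qr.coef(qx, fixed)              # 4 x 3: rows = (x,y,z,1) coefficients
  A <- t(B[1:3, , drop = FALSE])
  tvec <- as.numeric(B[4, ])
  if (det(A) <= 0)
    stop("fitted affine map is orientation-reversing (determinant <= 0)")
  res <- fixed - (X %*% B)
  structure(list(A = A, t = tvec,
                 scale_change_percent = (abs(det(A))^(1 / 3) - 1) * 100,
                 rms_residual = sqrt(mean(rowSums(res^2))),
                 n_points = nrow(moving)),
            class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat(sprintf("<affine_map> %d landmarks, scale change %+.3f%%, RMS residual %.4g um\n",
              x$n_points, x$scale_change_percent, x$rms_residual))
  invisible(x)
}

#' Apply an affine map to points
#'
#' @param map an `affine_map`.
#' @param points n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_affine <- function(map, points) {
  points <- as.matrix(points)
  t(map$A %*% t(points) + map$t)
}

#' Write / read an affine map as JSON
#'
#' Row-major 3x3 linear part, translation and derived scale change.
#'
#' @param map an `affine_map`; `path` a JSON path.
#' @return `read_affine` returns an `affine_map`.
#' @export
write_affine <- function(map, path) {
  jsonlite::write_json(list(A_row_major = as.numeric(t(map$A)), t = map$t,
                            scale_change_percent = map$scale_change_percent,
                            rms_residual = map$rms_residual,
                            n_points = map$n_points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(A = matrix(j$A_row_major, 3, 3, byrow = TRUE),
                 t = as.numeric(j$t),
                 scale_change_percent = j$scale_change_percent,
                 rms_residual = j$rms_residual, n_points = j$n_points),
            class = "affine_map")
}

#' Display range of a recording
#'
#' An intensity display range (low = image background outside the tissue,
#' high = display ceiling) together with the excitation dose the recording
#' was taken at (microjoule per mm of light-sheet width), as used to put two
#' recordings taken at different excitation powers on a common scale.
#'
#' @param low,high intensity bounds, `high > low >= 0`.
#' @param dose_uJ_mm optional excitation dose.
#' @return a `display_range`.
#' @export
display_range <- function(low, high, dose_uJ_mm = NULL) {
  stopifnot(high > low, low >= 0)
  structure(list(low = low, high = high, dose_uJ_mm = dose_uJ_mm),
            class = "display_range")
}

#' Map intensities between display ranges
#'
#' Returns the linear mapping of intensities recorded under range `b` onto
#' the scale of range `a`: `x -> (x - low_b) / (high_b - low_b) *
#' (high_a - low_a) + low_a`. When both ranges carry excitation doses, the
#' ratio of range widths is checked against the dose ratio: within
#' `tolerance` (relative) the mapping is flagged `"consistent"`, otherwise a
#' warning status is returned — a sanity check that the display-range
#' adjustment really reflects the excitation-power difference and not signal
#' loss.
#'
#' @param range_a,range_b [display_range()] objects.
#' @param tolerance relative tolerance for the dose-consistency check.
#' @return list `map` (a function), `width_ratio`, `dose_ratio` (or `NULL`),
#'   `status` (`"consistent"`, `"warning"` or `"unchecked"`).
#' @export
normalize_intensity <- function(range_a, range_b, tolerance = 0.1) {
  wa <- range_a$high - range_a$low
  wb <- range_b$high - range_b$low
  map <- function(x) (x - range_b$low) / wb * wa + range_a$low
  width_ratio <- wa / wb
  dose_ratio <- NULL
  status <- "unchecked"
  if (!is.null(range_a$dose_uJ_mm) && !is.null(range_b$dose_uJ_mm)) {
    dose_ratio <- range_a$dose_uJ_mm / range_b$dose_uJ_mm
    status <- if (abs(width_ratio / dose_ratio - 1) <= tolerance)
      "consistent" else "warning"
    if (status == "warning")
      warning(sprintf("display-range width ratio %.3f deviates from excitation dose ratio %.3f by more than %.0f%%",
                      width_ratio, dose_ratio, 100 * tolerance))
  }
  list(map = map, width_ratio = width_ratio, dose_ratio = dose_ratio,
       status = status)
}

#' Overlap score of two aligned volumes
#'
#' Pearson correlation of the two volumes over the union of their tissue
#' masks — a scalar summary of how well a re-imaged, re-aligned dataset
#' overlays the original.
#'
#' @param vol_a,vol_b congruent [brain_volume()]s.
#' @param mask_a,mask_b optional `tissue_mask`s; default: voxels > 0.
#' @return correlation in `[-1, 1]`.
#' @export
overlap_score <- function(vol_a, vol_b, mask_a = NULL, mask_b = NULL) {
  check_congruent(vol_a, vol_b)
  ma <- if (is.null(mask_a)) vol_a$data > 0 else mask_a$data
  mb <- if (is.null(mask_b)) vol_b$data > 0 else mask_b$data
  joint <- ma | mb
  if (!any(joint)) stop("empty joint mask")
  stats::cor(vol_a$data[joint], vol_b$data[joint])
}
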