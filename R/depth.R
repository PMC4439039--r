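#' Attenuation model
#'
#' Beer-Lambert attenuation coefficients along the illumination axis (`ky`,
#' excitation, per micrometre of tissue traversed in y) and the detection
#' axis (`kz`, emission, per micrometre in z), plus fit diagnostics when the
#' model was estimated from data.
#'
#' @param ky,kz absorption coefficients in 1/um; must be finite and >= 0.
#' @param diagnostics optional list (per-axis R^2, depth range used).
#' @return an `attenuation_model` object.
#' @export
attenuation_model <- function(ky, kz, diagnostics = NULL) {
  stopifnot(is.finite(ky), is.finite(kz), ky >= 0, kz >= 0)
  structure(list(ky = ky, kz = kz, diagnostics = diagnostics),
            class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat(sprintf("<attenuation_model> ky = %.4g /um, kz = %.4g /um\n", x$ky, x$kz))
  if (!is.null(x$diagnostics)) {
    r2 <- x$diagnostics
    cat(sprintf("  fit R^2: y = %s, z = %s\n",
                format(r2$r2_y %||% NA), format(r2$r2_z %||% NA)))
  }
  invisible(x)
}

# Column-wise cumulative sum of a matrix, fully vectorised.
colcumsum <- function(m) {
  n <- nrow(m); k <- ncol(m)
  cs <- matrix(cumsum(m), n, k)
  if (k > 1) cs <- cs - rep(c(0, cs[n, -k]), each = n)
  cs
}

# Cumulative sum of a 3D array along one axis, in the direction given by
# `decreasing` (FALSE: ascending index).
cumsum_axis <- function(a, axis, decreasing = FALSE) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  if (decreasing) ap <- ap[dp[1]:1, , , drop = FALSE]
  m <- colcumsum(matrix(ap, dp[1], dp[2] * dp[3]))
  res <- array(m, dp)
  if (decreasing) res <- res[dp[1]:1, , , drop = FALSE]
  aperm(res, order(perm))
}

#' Cumulative tissue path lengths
#'
#' For every voxel, the cumulative tissue path length (in micrometres)
#' traversed by the excitation light from its tissue entry on the -y face to
#' the voxel (`dy`), and by the emission light between the voxel and the
#' detection-side (+z) tissue boundary (`dz`). Only in-mask voxels count:
#' cleared cavities (mask holes) contribute zero path. The half-voxel
#' convention places the entry face at zero path, so the n-th tissue voxel
#' along a ray has path (n - 1/2) times the axis pitch. Out-of-mask voxels
#' have zero path.
#'
#' @param mask a `tissue_mask` from [compute_tissue_mask()] (or any object
#'   with a logical 3D `data` array and `pitch`).
#' @param pitch voxel pitch (z, y, x) in um; defaults to the mask's.
#' @return a `depth_maps` object: list of arrays `dy`, `dz` (um) and `pitch`.
#' @export
compute_path_lengths <- function(mask, pitch = mask$pitch) {
  m <- mask$data
  stopifnot(length(dim(m)) == 3, any(m))
  mnum <- array(as.numeric(m), dim(m))
  dy <- (cumsum_axis(mnum, 2, decreasing = FALSE) - 0.5) * pitch[2] * mnum
  dz <- (cumsum_axis(mnum, 1, decreasing = TRUE) - 0.5) * pitch[1] * mnum
  structure(list(dy = dy, dz = dz, pitch = pitch), class = "depth_maps")
}

#' Apply forward Beer-Lambert attenuation
#'
#' Multiplies each voxel by `exp(-ky * dy) * exp(-kz * dz)`, the forward model
#' of depth-dependent signal loss in tissue: excitation is attenuated over the
#' tissue path along the illumination axis (y) and emission over the tissue
#' path towards the detector (+z). Voxels with zero tissue path are unchanged.
#' This is the exact inverse of [apply_correction()] with the same model, no
#' smoothing and no clamping.
#'
#' @param vol a [brain_volume()].
#' @param mask congruent `tissue_mask`.
#' @param model an [attenuation_model()].
#' @param depths optional precomputed [compute_path_lengths()] result.
#' @return attenuated [brain_volume()].
#' @export
apply_attenuation <- function(vol, mask, model, depths = NULL) {
  check_congruent(vol, mask, "volume and mask")
  if (is.null(depths)) depths <- compute_path_lengths(mask, vol$pitch)
  att <- exp(-model$ky * depths$dy - model$kz * depths$dz)
  brain_volume(vol$data * att, pitch = vol$pitch, channel = vol$channel)
}

#' Estimate absorption coefficients from depth profiles
#'
#' Automates the manual tuning of the attenuation coefficients from intensity
#' gradient profiles: for each axis, in-mask voxels are restricted to the
#' lowest tercile of the *other* axis's depth (so the two exponentials do not
#' confound each other), binned by depth, and the log of the mean intensity
#' per bin is regressed on depth; the negated slope is the coefficient.
#' One refinement pass then divides out the current estimate of the other
#' axis's attenuation and re-fits over the full depth range, which removes
#' the residual cross-axis bias of the tercile restriction. Negative
#' estimates are clamped to zero with a warning. Per-axis R^2 of the profile
#' fit is reported in the diagnostics.
#'
#' @param vol observed [brain_volume()].
#' @param mask `tissue_mask`.
#' @param depths [compute_path_lengths()] result (computed if `NULL`).
#' @param min_bins minimum number of distinct depth bins required per axis.
#' @param min_bin_voxels bins with fewer voxels are dropped.
#' @param refine number of cross-axis refinement passes (0 = plain tercile
#'   profile fit).
#' @return an [attenuation_model()] with diagnostics.
#' @export
estimate_coefficients <- function(vol, mask, depths = NULL, min_bins = 10,
                                  min_bin_voxels = 20, refine = 2) {
  check_congruent(vol, mask, "volume and mask")
  if (is.null(depths)) depths <- compute_path_lengths(mask, vol$pitch)
  inm <- which(mask$data & vol$data > 0)
  v <- vol$data[inm]
  dyv <- depths$dy[inm]
  dzv <- depths$dz[inm]

  fit_axis <- function(depth, other, restrict_other, correction, axis_name) {
    sel <- if (restrict_other) {
      other <= stats::quantile(other, 1 / 3)
    } else rep(TRUE, length(depth))
    d <- depth[sel]
    i <- v[sel] * correction[sel]
    if (length(unique(d)) < min_bins)
      stop("insufficient distinct depth bins along ", axis_name)
    means <- tapply(i, d, mean)
    counts <- tapply(i, d, length)
    keep <- counts >= min_bin_voxels & means > 0
    if (sum(keep) < min_bins)
      stop("insufficient depth range along ", axis_name,
           " after dropping sparse bins")
    db <- as.numeric(names(means))[keep]
    ly <- log(as.numeric(means)[keep])
    fit <- stats::lm.fit(cbind(1, db), ly)
    slope <- fit$coefficients[2]
    r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
    list(k = -slope, r2 = r2, range = range(db))
  }

  fy <- fit_axis(dyv, dzv, TRUE, rep(1, length(v)), "y")
  fz <- fit_axis(dzv, dyv, TRUE, rep(1, length(v)), "z")
  ky <- fy$k; kz <- fz$k
  for (it in seq_len(refine)) {
    fy <- fit_axis(dyv, dzv, FALSE, exp(max(kz, 0) * dzv), "y")
    fz <- fit_axis(dzv, dyv, FALSE, exp(max(fy$k, 0) * dyv), "z")
    ky <- fy$k; kz <- fz$k
  }
  if (ky < 0 || kz < 0)
    warning("negative attenuation estimate clamped to 0 (",
            if (ky < 0) "ky " else "", if (kz < 0) "kz" else "", ")")
  attenuation_model(max(ky, 0), max(kz, 0),
                    diagnostics = list(r2_y = fy$r2, r2_z = fz$r2,
                                       depth_range_y = fy$range,
                                       depth_range_z = fz$range))
}

#' Multiplicative intensity-correction field
#'
#' The per-voxel correction factor `1 / (exp(-ky*dy) * exp(-kz*dz))`, clamped
#' at `clamp` (deep voxels below the noise floor would otherwise be amplified
#' without bound), set to 1 outside the mask, and then smoothed with a 3D
#' Gaussian (sigma in voxels, default 2 on every axis). Smoothing operates on
#' the factor field itself, not its logarithm, matching the order: correction
#' factors, then Gaussian filtering, then multiplication with the data.
#'
#' @param mask `tissue_mask`.
#' @param depths [compute_path_lengths()] result.
#' @param model [attenuation_model()].
#' @param sigma Gaussian sigma in voxels, (z, y, x); 0 disables smoothing.
#' @param clamp ceiling on the correction factor; must be >= 1.
#' @return a `correction_field`: list with array `factors`, `sigma`, `clamp`,
#'   `clamp_hits` (voxels at the ceiling before smoothing) and the model.
#' @export
correction_field <- function(mask, depths, model, sigma = c(2, 2, 2),
                             clamp = 20) {
  if (clamp < 1) stop("clamp ceiling must be >= 1")
  f <- exp(model$ky * depths$dy + model$kz * depths$dz)
  f[!mask$data] <- 1
  hits <- sum(f > clamp)
  f <- pmin(f, clamp)
  f <- array(f, dim(mask$data))
  if (any(sigma > 0)) f <- gaussian_filter3(f, sigma)
  structure(list(factors = f, sigma = sigma, clamp = clamp,
                 clamp_hits = hits, model = model),
            class = "correction_field")
}

#' Apply a correction field to a volume
#'
#' Voxelwise product of the volume with the (smoothed) correction factors.
#' The result is kept at floating precision and not re-clipped to the camera
#' bit depth.
#'
#' @param vol [brain_volume()].
#' @param field a `correction_field`.
#' @return corrected [brain_volume()].
#' @export
apply_correction <- function(vol, field) {
  if (!identical(dim(vol$data), dim(field$factors)))
    stop("shape mismatch between volume and correction field")
  brain_volume(vol$data * field$factors, pitch = vol$pitch,
               channel = vol$channel)
}
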