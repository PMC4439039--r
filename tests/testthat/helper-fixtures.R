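# Shared fixtures: small, fast phantoms and independent brute-force oracles.

# A small noise-free phantom with no cells/rim: pure attenuated background,
# the workhorse for correction and estimation tests.
plain_phantom <- function(shape = c(32, 48, 48), ky = 5e-4, kz = 3e-4,
                          seed = 1, ...) {
  generate_phantom(phantom_spec(shape = shape, cells = list(), rim_um = 0,
                                rim_gain = 0, ky = ky, kz = kz,
                                poisson_gain = 0, read_sd = 0, seed = seed,
                                ...))
}

# Brute-force tissue path length along one axis of a logical mask vector
# under the half-voxel convention: walk the ray, count in-mask voxels up to
# and including the target, subtract half, times pitch.
oracle_path <- function(mask_line, i, pitch) {
  if (!mask_line[i]) return(0)
  (sum(mask_line[seq_len(i)]) - 0.5) * pitch
}

# Brute-force shadow oracle: per-voxel ray march from the -y face along a
# tilted ray with trilinear (here bilinear in the y-x plane, absorbers are
# z-symmetric in the fixtures) sampling of the absorbance field.
oracle_shadow_plane <- function(af_plane, pitch_yx, theta_deg, n_steps = 400) {
  th <- theta_deg * pi / 180
  d <- dim(af_plane)   # (y, x)
  out <- matrix(0, d[1], d[2])
  for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) {
    # physical target position (voxel centre)
    py <- (iy - 0.5) * pitch_yx[1]
    px <- (ix - 0.5) * pitch_yx[2]
    # march from entry (y = 0 plane along the ray) to the voxel
    total_len <- py / cos(th)
    step <- total_len / n_steps
    s <- (seq_len(n_steps) - 0.5) * step
    ys <- py - s * cos(th)
    xs <- px - s * sin(th)
    gy <- ys / pitch_yx[1] + 0.5
    gx <- xs / pitch_yx[2] + 0.5
    i0 <- floor(gy); j0 <- floor(gx)
    fy <- gy - i0; fx <- gx - j0
    val <- function(ii, jj) {
      ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
      v <- numeric(length(ii)); v[ok] <- af_plane[cbind(ii[ok], jj[ok])]
      v
    }
    ab <- val(i0, j0) * (1 - fy) * (1 - fx) + val(i0 + 1, j0) * fy * (1 - fx) +
      val(i0, j0 + 1) * (1 - fy) * fx + val(i0 + 1, j0 + 1) * fy * fx
    out[iy, ix] <- exp(-sum(ab) * step)
  }
  out
}

# Independent tally: group-by recount of a node set against an atlas region
# table, used to cross-check aggregate_counts.
oracle_tally <- function(nodes, atlas) {
  df <- as.data.frame(nodes)
  df <- df[df$channel %in% c("green", "both") & !is.na(df$region_id), ]
  reg <- atlas$regions
  df$group <- reg$group[match(df$region_id, reg$id)]
  df$hemisphere <- reg$hemisphere[match(df$region_id, reg$id)]
  df$injection <- reg$injection_site[match(df$region_id, reg$id)]
  tapply(rep(1, nrow(df)),
         list(df$group, paste0(df$hemisphere, ifelse(df$injection, "_inj", "")),
              df$class), sum, default = 0)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
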