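#' Cut a volume into an overlapping tile mosaic
#'
#' Fixture generator for the stitcher: crops the source volume on a regular
#' grid of tiles with a nominal overlap fraction, optionally jittering each
#' tile's position by integer voxels (rounded Gaussian) to emulate stage
#' positioning error. The true integer offsets are returned alongside the
#' tiles. The union of tiles always covers the volume; a jitter draw larger
#' than the overlap would break that guarantee and is refused.
#'
#' @param vol source [brain_volume()].
#' @param tile_shape tile shape in voxels (z, y, x), each <= the volume shape.
#' @param overlap nominal overlap fraction in (0, 0.5].
#' @param jitter_sd SD of the integer offset jitter, in voxels.
#' @param seed RNG seed for the jitter.
#' @return a `tile_set`: list with `tiles` (list of [brain_volume()]),
#'   `grid_index` (0-based integer matrix), `nominal_offsets` and
#'   `true_offsets` (0-based voxel offsets, rows = tiles, cols = z,y,x),
#'   `overlap`, `pitch`, `channel`.
#' @export
render_tiles <- function(vol, tile_shape, overlap = 0.1, jitter_sd = 0,
                         seed = 1) {
  stopifnot(inherits(vol, "brain_volume"), overlap > 0, overlap <= 0.5)
  d <- dim(vol$data)
  tile_shape <- as.integer(tile_shape)
  stopifnot(all(tile_shape <= d), all(tile_shape >= 1))
  ov_vox <- pmax(1L, as.integer(round(overlap * tile_shape)))
  step <- tile_shape - ov_vox
  ntiles <- pmax(1L, as.integer(ceiling((d - tile_shape) / step)) + 1L)
  # only axes with interior (unpinned) tiles carry jitter
  jittered_axes <- which(ntiles >= 3L)
  if (jitter_sd > 0 && length(jittered_axes) &&
      3 * jitter_sd > min(ov_vox[jittered_axes]))
    stop("offset jitter exceeds the tile overlap; fixture would be unstitchable")

  grid <- as.matrix(expand.grid(z = seq_len(ntiles[1]) - 1L,
                                y = seq_len(ntiles[2]) - 1L,
                                x = seq_len(ntiles[3]) - 1L))
  nominal <- t(apply(grid, 1, function(g) pmin(g * step, d - tile_shape)))
  true_off <- with_seed(seed, {
    jit <- matrix(as.integer(round(stats::rnorm(length(nominal), 0,
                                                jitter_sd))),
                  nrow(nominal), 3)
    # tiles on the volume boundary are pinned there (the stage starts and
    # ends its scan at the sample edges), so the tile union always covers
    # the volume; interior tiles carry the positioning jitter
    for (ax in 1:3) {
      jit[grid[, ax] == 0L, ax] <- 0L
      jit[grid[, ax] == ntiles[ax] - 1L, ax] <- 0L
    }
    if (any(abs(jit) >= ov_vox[col(jit)]))
      stop("offset jitter exceeds the tile overlap; fixture would be unstitchable")
    off <- nominal + jit
    off[] <- pmin(pmax(off, 0L), rep(d - tile_shape, each = nrow(off)))
    off
  })
  tiles <- lapply(seq_len(nrow(true_off)), function(i) {
    o <- true_off[i, ]
    brain_volume(vol$data[o[1] + seq_len(tile_shape[1]),
                          o[2] + seq_len(tile_shape[2]),
                          o[3] + seq_len(tile_shape[3]), drop = FALSE],
                 pitch = vol$pitch, channel = vol$channel)
  })
  structure(list(tiles = tiles, grid_index = grid, nominal_offsets = nominal,
                 true_offsets = true_off, overlap = overlap, pitch = vol$pitch,
                 channel = vol$channel, source_dim = d),
            class = "tile_set")
}
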