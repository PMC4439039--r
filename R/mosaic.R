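# Mosaic stitching: translation-only registration of overlapping tile
# stacks by normalised cross-correlation, global least-squares consistency
# over the tile graph, and feathered fusion.

#' Estimate the translation offset between two overlapping tiles
#'
#' Searches integer offsets within `search_radius` voxels of the nominal
#' offset for the one maximising the Pearson correlation between the two
#' tiles over a central crop of their overlap region (a central crop resists
#' the smooth intensity ramp that depth attenuation superimposes on both
#' tiles). Ties are broken by smallest Euclidean deviation from the nominal
#' offset, then lexicographically in (z, y, x). Offsets are integer-voxel
#' only; no subpixel refinement is attempted.
#'
#' @param tile_a,tile_b [brain_volume()] tiles of identical shape.
#' @param nominal integer length-3 nominal offset of `b` relative to `a`
#'   (position of b's origin in a's voxel frame, 0-based, order z,y,x).
#' @param search_radius search half-width in voxels; length 1 (all axes) or
#'   3 (per axis, z/y/x — thin stacks warrant a smaller z search).
#' @param min_overlap minimum overlap (in voxels) required at the nominal
#'   offset; defaults to 32^3 as appropriate for full-size recordings and
#'   should be lowered for small volumes.
#' @param score_floor correlations below this are flagged unreliable.
#' @param crop_max maximum per-axis extent of the central correlation crop.
#' @return list `offset` (integer, z,y,x), `score` in `[-1, 1]`, `reliable`.
#' @export
estimate_pairwise_offset <- function(tile_a, tile_b, nominal,
                                     search_radius = 10, min_overlap = 32^3,
                                     score_floor = 0.3, crop_max = 32L) {
  stopifnot(identical(dim(tile_a$data), dim(tile_b$data)))
  d <- dim(tile_a$data)
  nominal <- as.integer(round(nominal))
  r <- rep_len(as.integer(search_radius), 3)

  # overlap region in a's frame at the nominal offset
  lo <- pmax(1L, nominal + 1L)
  hi <- pmin(d, nominal + d)
  if (any(hi < lo) || prod(hi - lo + 1L) < min_overlap)
    stop("tiles do not overlap by at least min_overlap voxels at the nominal offset")

  # central crop of the overlap, shrunk so that every candidate offset keeps
  # both windows in bounds
  ctr <- (lo + hi) %/% 2L
  half <- pmin((hi - lo) %/% 2L, crop_max %/% 2L)
  a_lo <- pmax(ctr - half, lo)
  a_hi <- pmin(ctr + half, hi)
  # b-frame index = a-frame index - offset; offsets range nominal +/- r
  a_lo <- pmax(a_lo, nominal + r + 1L)       # b index >= 1 for all offsets
  a_hi <- pmin(a_hi, nominal - r + d)        # b index <= d for all offsets
  a_lo <- pmax(a_lo, 1L)
  a_hi <- pmin(a_hi, d)
  if (any(a_hi < a_lo))
    stop("search radius too large for the available overlap")
  avals <- as.numeric(tile_a$data[a_lo[1]:a_hi[1], a_lo[2]:a_hi[2],
                                  a_lo[3]:a_hi[3]])
  if (stats::sd(avals) == 0)
    return(list(offset = nominal, score = 0, reliable = FALSE))

  best <- NULL
  for (oz in (nominal[1] - r[1]):(nominal[1] + r[1]))
    for (oy in (nominal[2] - r[2]):(nominal[2] + r[2]))
      for (ox in (nominal[3] - r[3]):(nominal[3] + r[3])) {
        o <- c(oz, oy, ox)
        bvals <- as.numeric(tile_b$data[(a_lo[1]:a_hi[1]) - o[1],
                                        (a_lo[2]:a_hi[2]) - o[2],
                                        (a_lo[3]:a_hi[3]) - o[3]])
        s <- if (stats::sd(bvals) == 0) 0 else stats::cor(avals, bvals)
        dev <- sum((o - nominal)^2)
        # loop order is lexicographic ascending in (z, y, x), so keeping the
        # first candidate on a full tie realises the documented tie-break
        if (is.null(best) || s > best$s + 1e-12 ||
            (abs(s - best$s) <= 1e-12 && dev < best$dev)) {
          best <- list(o = o, s = s, dev = dev)
        }
      }
  list(offset = as.integer(best$o), score = best$s,
       reliable = best$s >= score_floor)
}

#' Globally consistent tile positions from pairwise offsets
#'
#' Solves, per axis, the least-squares problem over the translation graph
#' (position of b minus position of a equals the estimated pairwise offset
#' for every edge), anchoring the first tile at the origin. Requires a
#' connected graph after unreliable edges have been removed.
#'
#' @param edges data frame with columns `a`, `b` (1-based tile indices) and
#'   `dz`, `dy`, `dx` (offset of b relative to a).
#' @param n_tiles number of tiles.
#' @return list `positions` (n x 3 integer matrix, z,y,x; anchor at 0) and
#'   `residuals` (per-edge max-norm residual of the solved system).
#' @export
globalize_offsets <- function(edges, n_tiles) {
  stopifnot(nrow(edges) >= 1, all(c(edges$a, edges$b) <= n_tiles))
  # connectivity check
  comp <- seq_len(n_tiles)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      ca <- comp[edges$a[i]]; cb <- comp[edges$b[i]]
      if (ca != cb) { comp[comp == max(ca, cb)] <- min(ca, cb); changed <- TRUE }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1)
    stop("tile overlap graph is disconnected; components: ",
         paste(sapply(split(seq_len(n_tiles), comp), paste, collapse = ","),
               collapse = " | "))
  m <- nrow(edges)
  A <- matrix(0, m + 1, n_tiles)
  A[cbind(seq_len(m), edges$a)] <- -1
  A[cbind(seq_len(m), edges$b)] <- A[cbind(seq_len(m), edges$b)] + 1
  A[m + 1, 1] <- 1  # anchor
  rhs <- cbind(c(edges$dz, 0), c(edges$dy, 0), c(edges$dx, 0))
  sol <- qr.solve(qr(A), rhs)
  pos <- round(sol - rep(sol[1, ], each = n_tiles))
  res <- abs(pos[edges$b, , drop = FALSE] - pos[edges$a, , drop = FALSE] -
               as.matrix(edges[, c("dz", "dy", "dx")]))
  list(positions = matrix(as.integer(pos), n_tiles, 3,
                          dimnames = list(NULL, c("z", "y", "x"))),
       residuals = apply(res, 1, max))
}

#' Fuse tiles into one volume
#'
#' Places every tile at its solved position on a grid spanning their union
#' and blends overlap voxels by linear feathering: each tile contributes with
#' a weight that ramps linearly from its faces inward (the minimum over axes
#' of the distance to the nearest tile face), so seams fade smoothly while
#' voxels covered by a single tile are copied verbatim. Voxels outside all
#' tiles are zero.
#'
#' @param tiles a `tile_set` (or plain list of [brain_volume()]).
#' @param positions n x 3 integer matrix of tile origins (0-based, z,y,x).
#' @return fused [brain_volume()].
#' @export
fuse_tiles <- function(tiles, positions) {
  tl <- if (inherits(tiles, "tile_set")) tiles$tiles else tiles
  positions <- matrix(as.integer(positions), length(tl), 3)
  td <- dim(tl[[1]]$data)
  positions <- positions - rep(apply(positions, 2, min), each = nrow(positions))
  out_dim <- apply(positions, 2, max) + td
  acc <- array(0, out_dim)
  wacc <- array(0, out_dim)
  w1 <- function(n) pmin(seq_len(n), n:1)
  wt <- outer(outer(w1(td[1]), w1(td[2]), pmin), w1(td[3]), pmin)
  for (i in seq_along(tl)) {
    o <- positions[i, ]
    zi <- o[1] + seq_len(td[1]); yi <- o[2] + seq_len(td[2])
    xi <- o[3] + seq_len(td[3])
    acc[zi, yi, xi] <- acc[zi, yi, xi] + wt * tl[[i]]$data
    wacc[zi, yi, xi] <- wacc[zi, yi, xi] + wt
  }
  covered <- wacc > 0
  acc[covered] <- acc[covered] / wacc[covered]
  v1 <- tl[[1]]
  brain_volume(acc, pitch = v1$pitch, channel = v1$channel)
}

#' Stitch a tile set end to end
#'
#' Estimates pairwise offsets for every grid-adjacent tile pair, drops
#' unreliable edges (falling back to the nominal offset if that would
#' disconnect the graph), solves for global positions and fuses.
#'
#' @param tileset a `tile_set` from [render_tiles()].
#' @param search_radius,min_overlap,score_floor passed to
#'   [estimate_pairwise_offset()].
#' @return list `volume` (fused [brain_volume()]), `positions`, `edges`
#'   (data frame: a, b, dz, dy, dx, score, reliable), `residuals`.
#' @export
stitch_tiles <- function(tileset, search_radius = 10, min_overlap = 32^3,
                         score_floor = 0.3) {
  stopifnot(inherits(tileset, "tile_set"))
  g <- tileset$grid_index
  n <- nrow(g)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sum(abs(g[i, ] - g[j, ])) != 1) next   # grid neighbours only
    nominal <- tileset$nominal_offsets[j, ] - tileset$nominal_offsets[i, ]
    est <- estimate_pairwise_offset(tileset$tiles[[i]], tileset$tiles[[j]],
                                    nominal, search_radius = search_radius,
                                    min_overlap = min_overlap,
                                    score_floor = score_floor)
    off <- if (est$reliable) est$offset else as.integer(nominal)
    edges <- rbind(edges, data.frame(a = i, b = j, dz = off[1], dy = off[2],
                                     dx = off[3], score = est$score,
                                     reliable = est$reliable))
  }
  glob <- globalize_offsets(edges, n)
  list(volume = fuse_tiles(tileset, glob$positions),
       positions = glob$positions, edges = edges, residuals = glob$residuals)
}
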