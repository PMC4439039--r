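# Internal numerical helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Shift a 3D array by `k` voxels along `axis` (1 = z, 2 = y, 3 = x), clamping
# indices at the edges (nearest-neighbour padding).
shift_clamped <- function(a, k, axis) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + k, 1L), d[axis])
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Separable 3D Gaussian filter
#'
#' Filters a 3D array with an axis-separable Gaussian kernel using
#' nearest-edge padding, so a constant array is a fixed point of the filter.
#' Sigma is given in voxel units per axis in storage order (z, y, x);
#' a sigma of 0 on an axis skips that axis.
#'
#' @param a numeric 3D array.
#' @param sigma numeric length-3 (or length-1, recycled) standard deviation in
#'   voxels for the (z, y, x) axes.
#' @return filtered array of the same shape.
#' @export
gaussian_filter3 <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3)
  sigma <- rep_len(as.numeric(sigma), 3)
  for (axis in 1:3) {
    if (sigma[axis] <= 0) next
    k <- gaussian_kernel_1d(sigma[axis])
    r <- (length(k) - 1L) %/% 2L
    out <- array(0, dim(a))
    for (j in seq_along(k)) {
      out <- out + k[j] * shift_clamped(a, j - r - 1L, axis)
    }
    a <- out
  }
  a
}

# 6-connected component labelling of a logical 3D array by vectorised
# breadth-first expansion over linear indices. Returns an integer array of
# component labels (0 = background).
label_components3 <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  lab <- integer(n)
  mvec <- as.logical(mask)
  remaining <- which(mvec)
  nz <- d[1]; ny <- d[2]
  # neighbour offsets in linear index space, with validity predicates
  zi <- function(i) (i - 1L) %% nz + 1L
  yi <- function(i) ((i - 1L) %/% nz) %% ny + 1L
  xi <- function(i) (i - 1L) %/% (nz * ny) + 1L
  comp <- 0L
  seen <- logical(n)
  while (length(remaining) > 0L) {
    comp <- comp + 1L
    frontier <- remaining[1L]
    seen[frontier] <- TRUE
    lab[frontier] <- comp
    while (length(frontier) > 0L) {
      cand <- c(
        frontier[zi(frontier) > 1L] - 1L,
        frontier[zi(frontier) < nz] + 1L,
        frontier[yi(frontier) > 1L] - nz,
        frontier[yi(frontier) < ny] + nz,
        frontier[xi(frontier) > 1L] - nz * ny,
        frontier[xi(frontier) < d[3]] + nz * ny
      )
      cand <- unique(cand)
      cand <- cand[mvec[cand] & !seen[cand]]
      seen[cand] <- TRUE
      lab[cand] <- comp
      frontier <- cand
    }
    remaining <- remaining[!seen[remaining]]
  }
  array(lab, d)
}

# round() is round-half-even in R; fixed here as the documented convention
# for reported percentages.
round_pct <- function(x, digits = 1) round(x, digits)

`%||%` <- function(a, b) if (is.null(a)) b else a
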