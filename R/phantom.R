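#' Phantom brain specification
#'
#' Describes a synthetic cleared-brain volume with known ground truth: an
#' ellipsoidal "brain" of uniform autofluorescent background with a brighter
#' peripheral rim, soma-like labelled cells of two morphological classes
#' (compact bright neurons with up to two thin neurites; glia as a faint soma
#' surrounded by a bushy cluster of small lobes) planted in a toy atlas of
#' ellipsoid octants named `"A"`-`"H"`, forward Beer-Lambert attenuation along
#' the illumination (y) and detection (z) axes, and a CCD-style noise model
#' (Poisson shot noise on gain-scaled intensity plus additive Gaussian read
#' noise, clipped to the 12-bit range).
#'
#' The default voxel pitch (3.23, 1.61, 1.61) um matches a typical
#' high-resolution light-sheet recording. The default attenuation
#' coefficients of 5e-4 per um are an arbitrary but plausible placeholder:
#' no measured per-axis coefficients for cleared brain tissue are available,
#' so phantoms should not be read as optically calibrated.
#'
#' @param shape grid shape in voxels, order (z, y, x).
#' @param pitch voxel pitch in um, order (z, y, x).
#' @param center_um ellipsoid centre in um; default: grid centre.
#' @param semiaxes_um ellipsoid semi-axes in um, order (z, y, x); default 38%
#'   of the physical grid extent per axis.
#' @param rim_um rim thickness in um (0 disables the rim).
#' @param rim_gain multiplicative intensity gain of the rim over background.
#' @param cells named list per class (`neuron`, `glia`) of named integer
#'   vectors: cells per octant region, e.g. `list(neuron = c(A = 10))`.
#' @param soma_radius_um named list per class of c(min, max) soma radius um.
#' @param ky,kz true attenuation coefficients (1/um).
#' @param background mean background (autofluorescence) intensity in tissue.
#' @param poisson_gain intensity units per photon for shot noise (0 = off).
#' @param read_sd Gaussian read noise SD in intensity units (0 = off).
#' @param full_scale camera full scale (12-bit default, 4095).
#' @param channels channel tags to render.
#' @param seed RNG seed recorded in the output metadata.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48, 96, 96), pitch = c(3.23, 1.61, 1.61),
                         center_um = NULL, semiaxes_um = NULL, rim_um = 10,
                         rim_gain = 3,
                         cells = list(neuron = c(A = 10), glia = c(B = 5)),
                         soma_radius_um = list(neuron = c(4, 7),
                                               glia = c(2.5, 4)),
                         ky = 5e-4, kz = 5e-4, background = 600,
                         poisson_gain = 1, read_sd = 4, full_scale = 4095,
                         channels = "green", seed = 1) {
  stopifnot(all(pitch > 0), ky >= 0, kz >= 0, rim_um >= 0, background >= 0)
  extent <- shape * pitch
  if (is.null(center_um)) center_um <- extent / 2
  if (is.null(semiaxes_um)) semiaxes_um <- 0.38 * extent
  if (any(center_um - semiaxes_um < 0) || any(center_um + semiaxes_um > extent))
    stop("brain ellipsoid does not fit inside the grid")
  spec <- list(shape = as.integer(shape), pitch = pitch, center_um = center_um,
               semiaxes_um = semiaxes_um, rim_um = rim_um, rim_gain = rim_gain,
               cells = cells, soma_radius_um = soma_radius_um, ky = ky,
               kz = kz, background = background, poisson_gain = poisson_gain,
               read_sd = read_sd, full_scale = full_scale, channels = channels,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Normalised ellipsoid radius^2 of voxel-centre coordinate arrays.
ellipsoid_r2 <- function(spec) {
  d <- spec$shape
  zc <- axis_centers(d[1], spec$pitch[1])
  yc <- axis_centers(d[2], spec$pitch[2])
  xc <- axis_centers(d[3], spec$pitch[3])
  uz <- (zc - spec$center_um[1]) / spec$semiaxes_um[1]
  uy <- (yc - spec$center_um[2]) / spec$semiaxes_um[2]
  ux <- (xc - spec$center_um[3]) / spec$semiaxes_um[3]
  outer(outer(uz^2, uy^2, `+`), ux^2, `+`)
}

# Octant region label ("A".."H") of a physical position relative to the
# ellipsoid centre; the phantom's toy atlas.
octant_region <- function(pos_um, center_um) {
  idx <- 1 + (pos_um[3] > center_um[3]) + 2 * (pos_um[2] > center_um[2]) +
    4 * (pos_um[1] > center_um[1])
  LETTERS[idx]
}

# Add a solid sphere of given amplitude to `a` (modified in place by value).
add_sphere <- function(a, spec, center_um, radius_um, amp) {
  d <- dim(a)
  lo <- pmax(1L, floor((center_um - radius_um) / spec$pitch))
  hi <- pmin(d, ceiling((center_um + radius_um) / spec$pitch) + 1L)
  if (any(hi < lo)) return(a)   # sphere entirely outside the grid
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz <- (axis_centers(d[1], spec$pitch[1])[zi] - center_um[1])^2
  dy <- (axis_centers(d[2], spec$pitch[2])[yi] - center_um[2])^2
  dx <- (axis_centers(d[3], spec$pitch[3])[xi] - center_um[3])^2
  r2 <- outer(outer(dz, dy, `+`), dx, `+`)
  sub <- a[zi, yi, xi, drop = FALSE]
  sub[r2 <= radius_um^2] <- sub[r2 <= radius_um^2] + amp
  a[zi, yi, xi] <- sub
  a
}

#' Generate a phantom brain volume with ground truth
#'
#' Renders the clean (noise-free, unattenuated) volume per channel, applies
#' the forward attenuation model and the noise model, and returns the
#' observed volumes together with the ground-truth tissue mask and a truth
#' record (planted cells, true coefficients, clean volumes, seed). Identical
#' spec and seed give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `channels` (named list of observed
#'   [brain_volume()]s), `mask` (ground-truth `tissue_mask`), and `truth`
#'   (list: `cells` data frame, `model`, `clean` volumes, `spec`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  r2 <- ellipsoid_r2(spec)
  inside <- r2 <= 1
  if (!any(inside)) stop("ellipsoid contains no voxels")
  # rim: shell inside the ellipsoid within rim_um of the surface (measured
  # on the normalised radius, scaled by the smallest semi-axis)
  rim_frac <- spec$rim_um / min(spec$semiaxes_um)
  rim <- inside & r2 > (1 - rim_frac)^2

  with_seed(spec$seed, {
    # ---- plant cells -------------------------------------------------
    cells <- list()
    placed <- matrix(numeric(0), ncol = 3)
    placed_r <- numeric(0)
    cid <- 0L
    for (cls in names(spec$cells)) {
      counts <- spec$cells[[cls]]
      rr <- spec$soma_radius_um[[cls]]
      for (region in names(counts)) {
        n <- counts[[region]]
        if (n == 0) next
        for (i in seq_len(n)) {
          # sample directly inside the requested octant: draw from the unit
          # ball, fold into the positive octant, then apply the octant signs
          ridx <- match(region, LETTERS[1:8]) - 1L
          signs <- c(if (bitwAnd(ridx, 4L)) 1 else -1,   # z
                     if (bitwAnd(ridx, 2L)) 1 else -1,   # y
                     if (bitwAnd(ridx, 1L)) 1 else -1)   # x
          ok <- FALSE
          for (try in seq_len(200L)) {
            u <- stats::runif(3, -1, 1)
            if (sum(u^2) > 1) next
            u <- abs(u) * signs
            pos <- spec$center_um +
              u * spec$semiaxes_um * max(0.2, 1 - 1.2 * rim_frac)
            rad <- stats::runif(1, rr[1], rr[2])
            if (nrow(placed) > 0) {
              sep <- sqrt(colSums((t(placed) - pos)^2))
              if (any(sep < placed_r + rad)) next
            }
            ok <- TRUE
            break
          }
          if (!ok) stop("could not place ", cls, " in region ", region,
                        " without overlap after bounded retries")
          cid <- cid + 1L
          placed <- rbind(placed, pos)
          placed_r <- c(placed_r, rad)
          cells[[cid]] <- data.frame(id = cid, class = cls, region = region,
                                     z_um = pos[1], y_um = pos[2],
                                     x_um = pos[3], radius_um = rad)
        }
      }
    }
    cells <- if (length(cells)) do.call(rbind, cells) else
      data.frame(id = integer(), class = character(), region = character(),
                 z_um = numeric(), y_um = numeric(), x_um = numeric(),
                 radius_um = numeric())

    # ---- render clean volumes per channel ----------------------------
    base <- array(0, d)
    base[inside] <- spec$background
    clean <- list()
    for (ch in spec$channels) {
      a <- base
      if (spec$rim_gain > 0 && any(rim)) {
        gain <- if (ch == "red") spec$rim_gain else spec$rim_gain / 2
        a[rim] <- spec$background * pmax(gain, 1)
      }
      if (ch == "green" && nrow(cells) > 0) {
        for (i in seq_len(nrow(cells))) {
          ci <- cells[i, ]
          pos <- c(ci$z_um, ci$y_um, ci$x_um)
          if (ci$class == "neuron") {
            a <- add_sphere(a, spec, pos, ci$radius_um, 2.5 * spec$background)
            for (nn in seq_len(stats::rbinom(1, 2, 0.7))) {
              dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
              for (s in seq(ci$radius_um, 6 * ci$radius_um, by = 1.5))
                a <- add_sphere(a, spec, pos + s * dir, 1.2, spec$background)
            }
          } else {
            a <- add_sphere(a, spec, pos, ci$radius_um, 0.8 * spec$background)
            for (lb in seq_len(sample.int(5, 1) + 4L)) {
              dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
              off <- stats::runif(1, ci$radius_um, 2 * ci$radius_um)
              a <- add_sphere(a, spec, pos + off * dir, ci$radius_um / 2,
                              2 * spec$background)
            }
          }
        }
      }
      clean[[ch]] <- brain_volume(a, pitch = spec$pitch, channel = ch)
    }

    mask <- structure(list(data = inside, threshold = 0, channel = "truth",
                           pitch = spec$pitch,
                           provenance = list(source = "phantom ground truth")),
                      class = "tissue_mask")
    model <- attenuation_model(spec$ky, spec$kz)
    depths <- compute_path_lengths(mask, spec$pitch)

    observed <- lapply(clean, function(v) {
      o <- apply_attenuation(v, mask, model, depths)$data
      if (spec$poisson_gain > 0)
        o <- stats::rpois(length(o), o / spec$poisson_gain) * spec$poisson_gain
      if (spec$read_sd > 0)
        o <- o + stats::rnorm(length(o), 0, spec$read_sd)
      o <- pmin(pmax(o, 0), spec$full_scale)
      brain_volume(array(o, d), pitch = spec$pitch, channel = v$channel)
    })

    list(channels = observed, mask = mask,
         truth = list(cells = cells, model = model, clean = clean,
                      depths = depths, seed = spec$seed, spec = spec))
  })
}

#' Write a phantom to disk
#'
#' One multi-page TIFF per channel plus a JSON sidecar with pitch, seed and a
#' truth summary, and the planted-cell list as CSV.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(phantom$channels))
    write_volume(phantom$channels[[ch]], file.path(dir, paste0(ch, ".tif")),
                 full_scale = phantom$truth$spec$full_scale)
  cells <- phantom$truth$cells
  utils::write.csv(cells[, c("id", "class", "region", "x_um", "y_um", "z_um")],
                   file.path(dir, "truth_cells.csv"), row.names = FALSE)
  meta <- list(seed = phantom$truth$seed,
               pitch_um = phantom$truth$spec$pitch,
               ky = phantom$truth$model$ky, kz = phantom$truth$model$kz,
               n_cells = nrow(cells))
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
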