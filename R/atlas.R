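# Toy brain atlas: a labelled region volume with the region hierarchy used
# by the monosynaptic-tracing count tables (group, hemisphere, injection-site
# flag), plus the published cell-count table encoded as package data.

# Leaf regions of the count table, in printed order, with their group and
# whether the ipsilateral region belongs to the injection site (the
# entorhinal-cortex cluster: ECT, PRh, LEnt, MEnt). Counts are the published
# EGFP-positive cell counts per region, hemisphere and morphological class.
table2_counts <- function() {
  tab <- read.csv(text = 'region,group,injection_site,ipsi_neurons,ipsi_glia,contra_neurons,contra_glia
Cortex,cortical,FALSE,235,0,13,0
Piriform Cortex,cortical,FALSE,2093,17,34,0
Ectorhinal Cortex,cortical,TRUE,41,0,0,0
Perirhinal Cortex,cortical,TRUE,101,1,1,0
Lateral Entorhinal Cortex,cortical,TRUE,1536,3,6,0
Medial Entorhinal Cortex,cortical,TRUE,641,28,4,0
Agranular Insular Cortex,cortical,FALSE,1,0,0,0
Dorsal Endopiriform Nucleus,cortical,FALSE,42,0,0,0
Olfactory Nucleus,cortical,FALSE,8,0,0,0
Ventral Orbital Cortex,cortical,FALSE,4,0,0,0
Dorsal Peduncular Cortex,cortical,FALSE,2,0,0,0
MCPO,subcortical,FALSE,8,0,0,0
Thalamic Nuclei,subcortical,FALSE,60,0,0,0
Lateral Hypothalamic Nuclei,subcortical,FALSE,7,0,0,0
Medial Septum,subcortical,FALSE,68,0,21,0
HDB,subcortical,FALSE,65,0,0,0
VDB,subcortical,FALSE,42,0,0,0
Nucleus Accumbens,subcortical,FALSE,0,1,0,0
Amygdaloid Nuclei,subcortical,FALSE,74,2,0,0
Striatum,subcortical,FALSE,1,2,0,0
Corpus Callosum,subcortical,FALSE,0,0,1,0
Subiculum,hippocampal,FALSE,204,80,1,0
Hippocampal alveus,hippocampal,FALSE,0,27,0,0
External Capsule,hippocampal,FALSE,103,8,0,0
CA1 Stratum pyramidale,hippocampal,FALSE,191,0,0,0
CA1 Stratum oriens,hippocampal,FALSE,42,0,0,0
CA1 Stratum radiatum,hippocampal,FALSE,62,0,0,0
CA3 Stratum pyramidale,hippocampal,FALSE,131,0,0,0
CA3 Stratum oriens,hippocampal,FALSE,20,0,3,0
CA3 Stratum radiatum,hippocampal,FALSE,54,0,0,0
Dentate Gyrus,hippocampal,FALSE,30,487,1,0
Stratum lacunosum moleculare,hippocampal,FALSE,26,278,0,0
Glomerular Layer,olfactory,FALSE,1,0,0,0
Mitral Cell Layer,olfactory,FALSE,109,1,0,0
', stringsAsFactors = FALSE)
  tab
}

#' Toy brain atlas
#'
#' A small deterministic labelled volume standing in for a real reference
#' atlas: every leaf region of the connectivity count table occupies a
#' rectangular block of voxels, the two hemispheres side by side along x
#' (ipsilateral first), with a one-voxel background border. The region table
#' carries id, name, group (cortical / subcortical / hippocampal /
#' olfactory), hemisphere and the injection-site flag (the
#' entorhinal-cortex cluster on the ipsilateral side only).
#'
#' @param pitch isotropic voxel pitch in um.
#' @return an `atlas`: list with integer label array `labels` (0 = outside),
#'   `pitch` (z, y, x), and `regions` data frame.
#' @export
toy_atlas <- function(pitch = 10) {
  tab <- table2_counts()
  nreg <- nrow(tab)
  slab <- 3L; wx <- 6L
  dimzyx <- c(4L, 2L + nreg * slab, 3L + 2L * wx)
  labels <- array(0L, dimzyx)
  regions <- NULL
  for (hemi in c("ipsilateral", "contralateral")) {
    xoff <- if (hemi == "ipsilateral") 1L else 2L + wx
    for (r in seq_len(nreg)) {
      id <- r + if (hemi == "ipsilateral") 0L else nreg
      labels[2:3, (2L + (r - 1L) * slab):(1L + r * slab),
             (xoff + 1L):(xoff + wx)] <- id
      regions <- rbind(regions, data.frame(
        id = id, region = tab$region[r], group = tab$group[r],
        hemisphere = hemi,
        injection_site = tab$injection_site[r] && hemi == "ipsilateral"))
    }
  }
  structure(list(labels = labels, pitch = rep(pitch, 3), regions = regions),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<atlas> %d x %d x %d (z,y,x), pitch %g um, %d regions\n",
              d[1], d[2], d[3], x$pitch[1], nrow(x$regions)))
  invisible(x)
}

#' Write / read an atlas
#'
#' The label volume goes to a multi-page TIFF (16-bit labels) and the region
#' table to a CSV next to it.
#'
#' @param atlas an `atlas`.
#' @param dir directory (created if needed).
#' @return `dir` / the `atlas`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(atlas$labels)
  pages <- lapply(seq_len(d[1]), function(i)
    matrix(atlas$labels[i, , ] / 65535, d[2], d[3]))
  tiff::writeTIFF(pages, file.path(dir, "labels.tif"), bits.per.sample = 16L)
  utils::write.csv(atlas$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(pitch_um = atlas$pitch),
                       file.path(dir, "atlas.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  pages <- tiff::readTIFF(file.path(dir, "labels.tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  labels <- array(0L, d)
  for (i in seq_along(pages)) labels[i, , ] <- as.integer(round(pages[[i]] * 65535))
  regions <- utils::read.csv(file.path(dir, "regions.csv"),
                             stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"))
  structure(list(labels = labels,
                 pitch = as.numeric(unlist(meta$pitch_um)),
                 regions = regions), class = "atlas")
}

#' Published-count annotation fixture
#'
#' Builds the published skeleton-annotation dataset as a node set: one node
#' per counted EGFP-positive cell, with its morphological class and a
#' synthetic deterministic position inside the matching toy-atlas region
#' block, such that per-region counts reproduce the printed table exactly.
#'
#' @param atlas the [toy_atlas()] the positions refer to (built if omitted).
#' @return a `node_set` data frame (see [node_set()]) with a `region_id`
#'   column recording the generating region.
#' @export
table2_fixture <- function(atlas = toy_atlas()) {
  tab <- table2_counts()
  nreg <- nrow(tab)
  lab <- atlas$labels
  pitch <- atlas$pitch
  rows <- list()
  nid <- 0L
  for (hemi in c("ipsilateral", "contralateral")) {
    for (r in seq_len(nreg)) {
      id <- r + if (hemi == "ipsilateral") 0L else nreg
      vox <- which(lab == id, arr.ind = TRUE)  # columns z, y, x
      for (cls in c("neuron", "glia")) {
        n <- if (hemi == "ipsilateral") {
          if (cls == "neuron") tab$ipsi_neurons[r] else tab$ipsi_glia[r]
        } else {
          if (cls == "neuron") tab$contra_neurons[r] else tab$contra_glia[r]
        }
        if (n == 0) next
        vi <- ((seq_len(n) - 1L) %% nrow(vox)) + 1L
        pos <- (vox[vi, , drop = FALSE] - 0.5) * rep(pitch, each = n)
        rows[[length(rows) + 1L]] <- data.frame(
          id = nid + seq_len(n), x_um = pos[, 3], y_um = pos[, 2],
          z_um = pos[, 1], class = cls, channel = "green",
          region_id = id)
        nid <- nid + n
      }
    }
  }
  nodes <- do.call(rbind, rows)
  nodes$extra <- ""
  node_set(nodes)
}
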