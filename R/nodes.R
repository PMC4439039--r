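# Annotated 3D cell-body locations (skeleton nodes) and their file formats:
# KNOSSOS-style .nml skeletons and plain CSV tables.

#' Node set of annotated cell bodies
#'
#' A data frame of 3D cell-body annotations in the dataset frame: one row
#' per marked cell with micron coordinates, fluorescence channel flags
#' (`"green"`, `"red"` or `"both"`; EGFP is green, the AAV marker red) and a
#' morphological class (`"neuron"` or `"glia"`). The class is an input
#' annotation, never inferred from images. `region_id` is `NA` until
#' assigned by [assign_regions()].
#'
#' @param df data frame with columns `id`, `x_um`, `y_um`, `z_um`, `class`,
#'   `channel`; optional `region_id` and `extra` (free-form tag text
#'   preserved verbatim through file round trips).
#' @return the data frame with class `node_set`.
#' @export
node_set <- function(df = NULL) {
  if (is.null(df))
    df <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                     z_um = numeric(), class = character(),
                     channel = character())
  need <- c("id", "x_um", "y_um", "z_um", "class", "channel")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$region_id)) df$region_id <- rep(NA_integer_, nrow(df))
  if (is.null(df$extra)) df$extra <- rep("", nrow(df))
  stopifnot(all(is.finite(df$x_um)), all(is.finite(df$y_um)),
            all(is.finite(df$z_um)),
            all(df$channel %in% c("green", "red", "both")))
  df <- df[, c(need, "region_id", "extra")]
  class(df) <- c("node_set", "data.frame")
  df
}

#' Read and write node sets (.nml / .csv)
#'
#' `.nml` is the KNOSSOS XML skeleton dialect: `<node>` elements with
#' `x`/`y`/`z` attributes (here in micrometres) inside one `<thing>`, and a
#' `<comments>` section whose entries carry `class=` and `channel=` tags
#' (plus any other `key=value` pairs, preserved verbatim). `.csv` is the flat
#' table of [node_set()] columns. A write-then-read round trip is the
#' identity on all fields; nodes missing a class tag are loaded with class
#' `NA` and reported via a warning.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"nml"` or `"csv"`.
#' @param nodes a `node_set`.
#' @return `read_nodes` returns a `node_set`.
#' @export
read_nodes <- function(path, format = tools::file_ext(path)) {
  format <- tolower(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!is.null(df$extra)) {
      df$extra <- as.character(df$extra)
      df$extra[is.na(df$extra)] <- ""
    }
    return(node_set(df))
  }
  if (format != "nml") stop("unknown node format: ", format)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed .nml file '", path,
                                           "': ", conditionMessage(e)))
  node_el <- xml2::xml_find_all(doc, ".//node")
  if (length(node_el) == 0)
    return(node_set())
  ids <- as.integer(xml2::xml_attr(node_el, "id"))
  pos <- vapply(c("x", "y", "z"), function(a)
    as.numeric(xml2::xml_attr(node_el, a)), numeric(length(node_el)))
  pos <- matrix(pos, ncol = 3)
  if (any(!is.finite(pos)))
    stop("malformed .nml: non-finite node coordinate (node id ",
         ids[which(!is.finite(rowSums(pos)))[1]], ")")
  com_el <- xml2::xml_find_all(doc, ".//comments/comment")
  com <- stats::setNames(xml2::xml_attr(com_el, "content"),
                         xml2::xml_attr(com_el, "node"))
  parse_tags <- function(txt) {
    if (is.na(txt) || txt == "") return(list(tags = list(), rest = ""))
    parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
    kv <- grepl("=", parts, fixed = TRUE)
    tags <- strsplit(parts[kv], "=", fixed = TRUE)
    list(tags = stats::setNames(lapply(tags, `[`, 2),
                                vapply(tags, `[`, "", 1)),
         rest = paste(parts[!kv], collapse = ";"))
  }
  cls <- chn <- reg <- extra <- character(length(ids))
  for (i in seq_along(ids)) {
    p <- parse_tags(unname(com[as.character(ids[i])]))
    cls[i] <- p$tags[["class"]] %||% NA_character_
    chn[i] <- p$tags[["channel"]] %||% "green"
    reg[i] <- p$tags[["region_id"]] %||% NA_character_
    known <- names(p$tags) %in% c("class", "channel", "region_id")
    kept <- p$tags[!known]
    extra[i] <- paste(c(sprintf("%s=%s", names(kept), unlist(kept)),
                        if (nzchar(p$rest)) p$rest), collapse = ";")
  }
  if (anyNA(cls))
    warning(sum(is.na(cls)), " node(s) loaded without a class tag")
  node_set(data.frame(id = ids, x_um = pos[, 1], y_um = pos[, 2],
                      z_um = pos[, 3], class = cls, channel = chn,
                      region_id = as.integer(reg), extra = extra))
}

#' @rdname read_nodes
#' @export
write_nodes <- function(nodes, path, format = tools::file_ext(path)) {
  nodes <- node_set(as.data.frame(nodes))
  format <- tolower(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(nodes), path, row.names = FALSE)
    return(invisible(path))
  }
  if (format != "nml") stop("unknown node format: ", format)
  doc <- xml2::xml_new_root("things")
  params <- xml2::xml_add_child(doc, "parameters")
  xml2::xml_add_child(params, "scale", x = "1", y = "1", z = "1",
                      unit = "um")
  thing <- xml2::xml_add_child(doc, "thing", id = "1", comment = "cells")
  nodes_el <- xml2::xml_add_child(thing, "nodes")
  for (i in seq_len(nrow(nodes))) {
    xml2::xml_add_child(nodes_el, "node",
                        id = as.character(nodes$id[i]),
                        x = format(nodes$x_um[i], digits = 15),
                        y = format(nodes$y_um[i], digits = 15),
                        z = format(nodes$z_um[i], digits = 15),
                        radius = "1")
  }
  xml2::xml_add_child(thing, "edges")
  com <- xml2::xml_add_child(doc, "comments")
  for (i in seq_len(nrow(nodes))) {
    tags <- c(
      if (!is.na(nodes$class[i])) sprintf("class=%s", nodes$class[i]),
      sprintf("channel=%s", nodes$channel[i]),
      if (!is.na(nodes$region_id[i]))
        sprintf("region_id=%d", nodes$region_id[i]),
      if (nzchar(nodes$extra[i])) nodes$extra[i])
    xml2::xml_add_child(com, "comment", node = as.character(nodes$id[i]),
                        content = paste(tags, collapse = ";"))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Assign nodes to atlas regions
#'
#' Each node is assigned the label of the atlas voxel containing it, using
#' 0-based floor indexing on half-open voxel intervals (a node at exactly a
#' voxel boundary belongs to the higher voxel). Nodes outside the atlas
#' bounds or over background (label 0) stay unassigned and are listed in the
#' `report` attribute. Assignment is deterministic.
#'
#' @param nodes a `node_set`.
#' @param atlas an `atlas`.
#' @return the `node_set` with `region_id` filled in; attribute `report`
#'   holds the ids of unassigned nodes.
#' @export
assign_regions <- function(nodes, atlas) {
  nodes <- node_set(as.data.frame(nodes))
  d <- dim(atlas$labels)
  iz <- floor(nodes$z_um / atlas$pitch[1]) + 1
  iy <- floor(nodes$y_um / atlas$pitch[2]) + 1
  ix <- floor(nodes$x_um / atlas$pitch[3]) + 1
  inb <- iz >= 1 & iz <= d[1] & iy >= 1 & iy <= d[2] & ix >= 1 & ix <= d[3]
  lab <- rep(0L, nrow(nodes))
  lab[inb] <- atlas$labels[cbind(iz[inb], iy[inb], ix[inb])]
  nodes$region_id <- ifelse(lab > 0L, lab, NA_integer_)
  attr(nodes, "report") <- list(unassigned = nodes$id[is.na(nodes$region_id)],
                                out_of_bounds = nodes$id[!inb])
  nodes
}
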