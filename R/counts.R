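# Region count tables: the per-region aggregation of assigned cell-body
# annotations, the published-table-style rollups, and derived connectivity
# fractions.

#' Aggregate assigned nodes into a region count table
#'
#' Counts EGFP-positive cells (channel `green` or `both`; red-only cells are
#' retained in the data model but excluded from these tables) per leaf
#' region and morphological class, and rolls them up by group and
#' hemisphere. Ipsilateral injection-site regions (the entorhinal-cortex
#' cluster) are reported in their own columns and excluded from the
#' ipsilateral rollups, mirroring the "ipsilateral without injection site"
#' accounting of retrograde-tracing input counts. Conservation (every rollup
#' equals the sum of its leaves) is asserted on every build.
#'
#' @param nodes a `node_set` with `region_id` assigned (see
#'   [assign_regions()]).
#' @param atlas the `atlas` defining regions, groups and hemispheres.
#' @param allow_unassigned if `FALSE` (default), unassigned counted nodes are
#'   an error; if `TRUE` they are excluded and tallied in the attribute
#'   `excluded`.
#' @return a `region_count_table`: list with data frames `leaves` (one row
#'   per region: inj/ipsi/contra neurons and glia), `rollups` (per group)
#'   and `totals`.
#' @export
aggregate_counts <- function(nodes, atlas, allow_unassigned = FALSE) {
  nodes <- node_set(as.data.frame(nodes))
  egfp <- nodes[nodes$channel %in% c("green", "both"), ]
  n_unassigned <- sum(is.na(egfp$region_id))
  if (n_unassigned > 0) {
    if (!allow_unassigned)
      stop(n_unassigned, " counted node(s) unassigned; assign regions first ",
           "or set allow_unassigned = TRUE")
    egfp <- egfp[!is.na(egfp$region_id), ]
  }
  stopifnot(all(egfp$class %in% c("neuron", "glia")))
  reg <- atlas$regions
  stopifnot(all(egfp$region_id %in% reg$id))

  cnt <- function(ids, cls)
    vapply(ids, function(i) sum(egfp$region_id == i & egfp$class == cls), 0)
  ipsi <- reg[reg$hemisphere == "ipsilateral", ]
  contra <- reg[reg$hemisphere == "contralateral", ]
  contra <- contra[match(ipsi$region, contra$region), ]
  leaves <- data.frame(
    region = ipsi$region, group = ipsi$group,
    injection_site = ipsi$injection_site,
    inj_neurons = ifelse(ipsi$injection_site, cnt(ipsi$id, "neuron"), 0),
    inj_glia = ifelse(ipsi$injection_site, cnt(ipsi$id, "glia"), 0),
    ipsi_neurons = ifelse(ipsi$injection_site, 0, cnt(ipsi$id, "neuron")),
    ipsi_glia = ifelse(ipsi$injection_site, 0, cnt(ipsi$id, "glia")),
    contra_neurons = cnt(contra$id, "neuron"),
    contra_glia = cnt(contra$id, "glia"))

  count_cols <- c("inj_neurons", "inj_glia", "ipsi_neurons", "ipsi_glia",
                  "contra_neurons", "contra_glia")
  rollups <- do.call(rbind, lapply(
    c("cortical", "subcortical", "hippocampal", "olfactory"), function(g) {
      s <- leaves[leaves$group == g, count_cols]
      cbind(data.frame(group = g), as.data.frame(as.list(colSums(s))))
    }))
  totals <- as.data.frame(as.list(colSums(leaves[, count_cols])))

  # conservation assertions
  stopifnot(identical(colSums(rollups[, count_cols]),
                      colSums(leaves[, count_cols])))
  stopifnot(all(unlist(totals) == colSums(rollups[, count_cols])))

  out <- structure(list(leaves = leaves, rollups = rollups, totals = totals),
                   class = "region_count_table")
  attr(out, "excluded") <- list(unassigned = n_unassigned,
                                red_only = sum(nodes$channel == "red"))
  out
}

#' @export
print.region_count_table <- function(x, ...) {
  cat("<region_count_table>\n")
  print(x$rollups, row.names = FALSE)
  cat("totals:\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Derived connectivity fractions
#'
#' From a built region count table:
#' * `hippocampal_glia_pct` — glia among all EGFP-labelled ipsilateral
#'   hippocampal cells, `100 * g / (g + n)`;
#' * `extra_hippocampal_glia_pct` — the same fraction over ipsilateral
#'   non-injection cells outside the hippocampus;
#' * `contralateral_input_pct` — contralateral neurons as a share of all
#'   monosynaptic input neurons,
#'   `100 * contra / (ipsi_non_injection + contra)`.
#'
#' Percentages are rounded to one decimal (round-half-even). A zero
#' denominator yields `NA` (undefined, not 0) with a note in the result.
#'
#' @param table a `region_count_table`.
#' @return list of the three percentages plus the raw counts behind them.
#' @export
derived_fractions <- function(table) {
  r <- table$rollups
  pick <- function(g, col) r[r$group == g, col]
  frac <- function(num, den) {
    if (den == 0) return(NA_real_)
    round_pct(100 * num / den)
  }
  hip_g <- pick("hippocampal", "ipsi_glia")
  hip_n <- pick("hippocampal", "ipsi_neurons")
  ext_g <- sum(r$ipsi_glia) - hip_g
  ext_n <- sum(r$ipsi_neurons) - hip_n
  contra_n <- sum(r$contra_neurons)
  ipsi_n <- sum(r$ipsi_neurons)
  list(
    hippocampal_glia_pct = frac(hip_g, hip_g + hip_n),
    extra_hippocampal_glia_pct = frac(ext_g, ext_g + ext_n),
    contralateral_input_pct = frac(contra_n, ipsi_n + contra_n),
    counts = list(hippocampal_glia = hip_g, hippocampal_neurons = hip_n,
                  extra_hippocampal_glia = ext_g,
                  extra_hippocampal_neurons = ext_n,
                  contralateral_neurons = contra_n,
                  ipsilateral_neurons = ipsi_n),
    notes = c(if (hip_g + hip_n == 0) "hippocampal fraction undefined",
              if (ext_g + ext_n == 0) "extra-hippocampal fraction undefined",
              if (ipsi_n + contra_n == 0) "contralateral fraction undefined"))
}

#' Write a region count report
#'
#' Writes the table as TSV mirroring the published layout (leaf rows in
#' printed order, group rollup rows, a grand-total row), in a deterministic
#' column order, and returns a markdown rendering. Re-parsing the TSV with
#' [read_region_report()] rebuilds an identical table.
#'
#' @param table a `region_count_table`.
#' @param stats optional [derived_fractions()] result appended as comment
#'   lines in the markdown rendering.
#' @param path TSV output path (`NULL` to skip writing).
#' @return character vector of markdown lines, invisibly.
#' @export
report_counts <- function(table, stats = NULL, path = NULL) {
  count_cols <- c("inj_neurons", "inj_glia", "ipsi_neurons", "ipsi_glia",
                  "contra_neurons", "contra_glia")
  leaf <- cbind(row_type = "leaf", table$leaves[, c("region", "group",
                                                    count_cols)])
  roll <- cbind(row_type = "rollup", region = "", table$rollups)
  tot <- cbind(row_type = "total", region = "", group = "", table$totals)
  all <- rbind(leaf, roll[, names(leaf)], tot[, names(leaf)])
  if (!is.null(path))
    utils::write.table(all, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  md <- c("| Region | Group | Inj N | Inj G | Ipsi N | Ipsi G | Contra N | Contra G |",
          "|---|---|---|---|---|---|---|---|",
          apply(all[all$row_type == "leaf" &
                      rowSums(all[, count_cols]) > 0, -1], 1, function(r)
            paste0("| ", paste(r, collapse = " | "), " |")),
          apply(roll[, c("group", count_cols)], 1, function(r)
            paste0("| **", r[1], "** |  | ",
                   paste(r[-1], collapse = " | "), " |")),
          paste0("| **Total** |  | ",
                 paste(unlist(table$totals), collapse = " | "), " |"))
  if (!is.null(stats))
    md <- c(md, "",
            sprintf("Hippocampal glia: %.1f%%; extra-hippocampal glia: %.1f%%; contralateral input: %.1f%%",
                    stats$hippocampal_glia_pct,
                    stats$extra_hippocampal_glia_pct,
                    stats$contralateral_input_pct))
  invisible(md)
}

#' @rdname report_counts
#' @export
read_region_report <- function(path) {
  all <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  count_cols <- c("inj_neurons", "inj_glia", "ipsi_neurons", "ipsi_glia",
                  "contra_neurons", "contra_glia")
  leaves <- all[all$row_type == "leaf",
                c("region", "group", count_cols)]
  leaves$injection_site <- leaves$inj_neurons + leaves$inj_glia > 0 |
    leaves$region %in% c("Ectorhinal Cortex", "Perirhinal Cortex",
                         "Lateral Entorhinal Cortex",
                         "Medial Entorhinal Cortex")
  rollups <- all[all$row_type == "rollup", c("group", count_cols)]
  totals <- all[all$row_type == "total", count_cols]
  rownames(leaves) <- rownames(rollups) <- rownames(totals) <- NULL
  stopifnot(identical(colSums(rollups[, count_cols]),
                      colSums(leaves[, count_cols])))
  structure(list(leaves = leaves[, c("region", "group", "injection_site",
                                     count_cols)],
                 rollups = rollups, totals = totals),
            class = "region_count_table")
}
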