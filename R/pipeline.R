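# Workbench: configuration, orchestration and output validation for the
# end-to-end demo pipeline (simulate -> stitch -> mask/correct -> assign ->
# stats).

pipeline_known_keys <- c("schema_version", "seed", "stages", "phantom",
                         "tiles", "stitch", "correct", "stats")

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Unknown keys
#' are rejected before any stage runs. Every run writes the fully resolved
#' configuration next to its outputs.
#'
#' @param ... configuration entries; recognised keys: `schema_version`,
#'   `seed`, `stages` (subset of `simulate`, `stitch`, `correct`, `stats`),
#'   `phantom` (arguments to [phantom_spec()]), `tiles` (arguments to
#'   [render_tiles()]: `tile_shape`, `overlap`, `jitter_sd`), `stitch`
#'   (arguments to [stitch_tiles()]), `correct` (list: `window`, `sigma`,
#'   `clamp`, `ky`, `kz`, `percentile`, `min_area`; `ky`/`kz` `"auto"` or a
#'   number).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.null(names(cfg)) && is.list(cfg[[1]]))
    cfg <- cfg[[1]]
  unknown <- setdiff(names(cfg), pipeline_known_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg$schema_version <- cfg$schema_version %||% 1L
  cfg$seed <- cfg$seed %||% 42L
  cfg$stages <- cfg$stages %||% c("simulate", "stitch", "correct", "stats")
  bad <- setdiff(cfg$stages, c("simulate", "stitch", "correct", "stats"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$phantom <- cfg$phantom %||% list()
  cfg$tiles <- cfg$tiles %||% list(overlap = 0.15, jitter_sd = 1)
  cfg$stitch <- cfg$stitch %||% list(search_radius = 4, min_overlap = 1024)
  cfg$correct <- cfg$correct %||% list(sigma = c(2, 2, 2), clamp = 20,
                                       ky = "auto", kz = "auto",
                                       percentile = 0.01)
  structure(cfg, class = "pipeline_config")
}

log_line <- function(log_path, stage, ...) {
  kv <- c(...)
  line <- paste0("stage=", stage,
                 if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                                   collapse = " ")))
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the demo pipeline
#'
#' Executes the enabled stages in order — phantom simulation, mosaic
#' stitching, tissue masking and attenuation correction, annotation
#' aggregation — into a deterministic artifact directory: `fused.tif`,
#' `corrected.tif`, `correction.json`, `assigned.csv`, `table2.tsv`,
#' `stats.json`, `run.log`, `resolved_config.json`. A rerun with the same
#' configuration and seed is bit-identical. Any stage error aborts with the
#' stage name; partial outputs and the log are kept.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @return `out_dir`, invisibly; the log records derived quantities
#'   (threshold, coefficient estimates, offsets).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(out_dir,
                                                  "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)  # truncate
  stage <- "init"
  result <- tryCatch({
    fused <- NULL
    phantom <- NULL
    if ("simulate" %in% config$stages) {
      stage <- "simulate"
      spec <- do.call(phantom_spec, c(config$phantom,
                                      list(seed = config$seed)))
      phantom <- generate_phantom(spec)
      log_line(log_path, stage, n_cells = nrow(phantom$truth$cells),
               ky_true = spec$ky, kz_true = spec$kz)
      fused <- phantom$channels[[1]]
    }
    if ("stitch" %in% config$stages) {
      stage <- "stitch"
      if (is.null(fused)) stop("stitch stage requires the simulate stage")
      tile_shape <- config$tiles$tile_shape %||%
        pmax(dim(fused$data) %/% 2 + 8L, 16L)
      ts <- render_tiles(fused, tile_shape,
                         overlap = config$tiles$overlap %||% 0.15,
                         jitter_sd = config$tiles$jitter_sd %||% 1,
                         seed = config$seed + 1L)
      st <- do.call(stitch_tiles, c(list(ts), config$stitch))
      for (i in seq_len(nrow(st$edges)))
        log_line(log_path, stage, edge = paste0(st$edges$a[i], "-",
                                                st$edges$b[i]),
                 dz = st$edges$dz[i], dy = st$edges$dy[i],
                 dx = st$edges$dx[i], score = signif(st$edges$score[i], 4))
      fused <- st$volume
      utils::write.table(st$edges, file.path(out_dir, "offsets.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(fused)) write_volume(fused, file.path(out_dir, "fused.tif"))
    if ("correct" %in% config$stages) {
      stage <- "correct"
      if (is.null(fused)) stop("correct stage requires an input volume")
      cc <- config$correct
      window <- cc$window %||% list(y = c(1, 8), x = c(1, 8))
      thr <- background_threshold(fused, window,
                                  percentile = cc$percentile %||% 0.01,
                                  min_area = cc$min_area %||% 64)
      mask <- compute_tissue_mask(fused, thr)
      depths <- compute_path_lengths(mask, fused$pitch)
      model <- if (identical(cc$ky, "auto") || identical(cc$kz, "auto")) {
        estimate_coefficients(fused, mask, depths)
      } else attenuation_model(cc$ky, cc$kz)
      field <- correction_field(mask, depths, model,
                                sigma = cc$sigma %||% c(2, 2, 2),
                                clamp = cc$clamp %||% 20)
      corrected <- apply_correction(fused, field)
      write_volume(corrected, file.path(out_dir, "corrected.tif"),
                   full_scale = max(corrected$data))
      jsonlite::write_json(
        list(threshold = as.numeric(thr), ky = model$ky, kz = model$kz,
             r2 = model$diagnostics, clamp = field$clamp,
             clamp_hits = field$clamp_hits, sigma = field$sigma),
        file.path(out_dir, "correction.json"), auto_unbox = TRUE,
        digits = NA, null = "null")
      log_line(log_path, stage, threshold = signif(as.numeric(thr), 6),
               ky = signif(model$ky, 6), kz = signif(model$kz, 6),
               clamp_hits = field$clamp_hits)
    }
    if ("stats" %in% config$stages) {
      stage <- "stats"
      atlas <- toy_atlas()
      nodes <- table2_fixture(atlas)
      nodes$region_id <- NA_integer_
      nodes <- assign_regions(nodes, atlas)
      write_nodes(nodes, file.path(out_dir, "assigned.csv"))
      tab <- aggregate_counts(nodes, atlas)
      stats <- derived_fractions(tab)
      report_counts(tab, stats, path = file.path(out_dir, "table2.tsv"))
      jsonlite::write_json(stats[c("hippocampal_glia_pct",
                                   "extra_hippocampal_glia_pct",
                                   "contralateral_input_pct")],
                           file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line(log_path, stage, n_nodes = nrow(nodes),
               hippocampal_glia_pct = stats$hippocampal_glia_pct)
    }
    TRUE
  }, error = function(e) {
    log_line(log_path, stage, error = shQuote(conditionMessage(e)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out_dir)
}

#' Validate a pipeline artifact directory
#'
#' Re-checks the invariants of a finished run: the resolved configuration is
#' present and parseable, the count table re-parses with its conservation
#' invariants intact and matches the derived fractions in `stats.json`, and
#' volume outputs are readable. Returns a checklist; `pass` is the
#' conjunction.
#'
#' @param dir artifact directory from [run_pipeline()].
#' @return list `pass` (logical) and `checks` (data frame name/pass/note).
#' @export
validate_outputs <- function(dir) {
  checks <- list()
  add <- function(name, pass, note = "")
    checks[[length(checks) + 1L]] <<- data.frame(name = name, pass = pass,
                                                 note = note)
  cfgp <- file.path(dir, "resolved_config.json")
  cfg_ok <- file.exists(cfgp) &&
    !inherits(try(jsonlite::read_json(cfgp), silent = TRUE), "try-error")
  add("resolved_config", cfg_ok)
  t2 <- file.path(dir, "table2.tsv")
  if (file.exists(t2)) {
    tab <- tryCatch(read_region_report(t2), error = function(e) NULL)
    add("table2_parses", !is.null(tab))
    if (!is.null(tab)) {
      count_cols <- c("inj_neurons", "inj_glia", "ipsi_neurons",
                      "ipsi_glia", "contra_neurons", "contra_glia")
      cons <- all(colSums(tab$leaves[, count_cols]) ==
                    unlist(tab$totals[, count_cols]))
      add("table2_conservation", cons)
      sj <- file.path(dir, "stats.json")
      if (file.exists(sj)) {
        st <- jsonlite::read_json(sj)
        fr <- derived_fractions(tab)
        add("stats_match_table",
            isTRUE(all.equal(st$hippocampal_glia_pct,
                             fr$hippocampal_glia_pct)) &&
              isTRUE(all.equal(st$contralateral_input_pct,
                               fr$contralateral_input_pct)))
      }
    }
  }
  for (f in c("fused.tif", "corrected.tif")) {
    p <- file.path(dir, f)
    if (file.exists(p))
      add(paste0(f, "_readable"),
          !inherits(try(read_volume(p), silent = TRUE), "try-error"))
  }
  checks <- do.call(rbind, checks)
  list(pass = all(checks$pass), checks = checks)
}
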