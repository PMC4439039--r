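# Plate-reader assay: simulation of replicate-structured fluorescence decay
# series and the background-corrected percent-of-initial quantification.

#' Simulate a fluorescence-preservation plate assay
#'
#' Emulates the in vitro preservation assay: for each condition (for example
#' a dehydration alcohol at a given pH) a fluorophore-expressing sample is
#' carried through a series of treatment steps and read on a plate reader,
#' with positive replicates (fluorophore present) and control replicates
#' (no fluorophore, background only). Readings are
#' `background + retention(step) * signal` for positives and `background`
#' for controls, plus Gaussian reader noise. The first step is the initial
#' (PBS) reading that later quantification is normalised to. Ground-truth
#' retention is stored alongside the readings.
#'
#' @param retention named list: per condition, a numeric vector of true
#'   retention fractions per step (first step is the initial PBS reading,
#'   conventionally 1). Negative retentions are refused.
#' @param steps character vector of step labels (default `"PBS"`, then
#'   `"step2"`, ...).
#' @param n_pos,n_ctrl positive and control replicates per condition
#'   (quintuplicate positives, triplicate controls by default).
#' @param background mean background reading.
#' @param signal initial fluorophore signal above background.
#' @param noise_sd reader noise SD in reading units (applied to every well).
#' @param seed RNG seed.
#' @return a `plate_assay`: list with `readings` data frame (condition, step,
#'   replicate, role, reading), `truth` (the retention list), and metadata.
#' @export
generate_plate_assay <- function(retention, steps = NULL, n_pos = 5,
                                 n_ctrl = 3, background = 100, signal = 1000,
                                 noise_sd = 0, seed = 1) {
  stopifnot(is.list(retention), length(retention) >= 1)
  if (any(unlist(retention) < 0)) stop("negative retention requested")
  n_steps <- length(retention[[1]])
  stopifnot(all(lengths(retention) == n_steps))
  if (is.null(steps)) steps <- c("PBS", paste0("step", seq_len(n_steps))[-1])
  stopifnot(length(steps) == n_steps)
  rows <- with_seed(seed, {
    out <- list()
    for (cond in names(retention)) for (s in seq_len(n_steps)) {
      pos <- background + retention[[cond]][s] * signal +
        stats::rnorm(n_pos, 0, noise_sd)
      ctl <- background + stats::rnorm(n_ctrl, 0, noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, step = steps[s],
        replicate = c(seq_len(n_pos), seq_len(n_ctrl)),
        role = rep(c("positive", "control"), c(n_pos, n_ctrl)),
        reading = c(pos, ctl))
    }
    do.call(rbind, out)
  })
  rows$reading <- pmax(rows$reading, 0)
  structure(list(readings = rows, steps = steps, truth = retention,
                 n_pos = n_pos, n_ctrl = n_ctrl, seed = seed),
            class = "plate_assay")
}

#' Read / write a plate assay as CSV
#'
#' Long-format CSV with columns condition, step, replicate, role, reading.
#'
#' @param assay a `plate_assay` (or bare readings data frame).
#' @param path CSV path.
#' @return `read_plate_assay` returns a `plate_assay` (without ground truth).
#' @export
write_plate_assay <- function(assay, path) {
  df <- if (inherits(assay, "plate_assay")) assay$readings else assay
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_assay
#' @export
read_plate_assay <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("condition", "step", "replicate", "role", "reading")
                %in% names(df)))
  structure(list(readings = df, steps = unique(df$step), truth = NULL,
                 n_pos = sum(df$role == "positive" & df$step == df$step[1] &
                               df$condition == df$condition[1]),
                 n_ctrl = sum(df$role == "control" & df$step == df$step[1] &
                                df$condition == df$condition[1])),
            class = "plate_assay")
}

#' Quantify a plate assay as percent of initial fluorescence
#'
#' For every condition and step, the mean of the positive replicates is
#' corrected for background by subtracting the mean of the control
#' replicates; the corrected value is expressed as a percentage of the
#' corrected initial (first-step, PBS) value. Standard deviations are
#' propagated to the percentage by the first-order delta method, treating
#' the step and the initial corrected means as independent. Negative
#' corrected values are reported as-is (not clipped); a condition whose
#' initial corrected value is not positive is flagged unquantifiable.
#' The quantification is invariant under an affine rescaling of the plate
#' reader (gain times reading plus offset applied to all wells), since the
#' offset cancels in the background correction and the gain in the ratio.
#'
#' @param assay a `plate_assay`.
#' @param initial_step label of the initial step; default: first step seen.
#' @return data frame: condition, step, corrected, percent, sd_percent,
#'   quantifiable.
#' @export
quantify_assay <- function(assay, initial_step = NULL) {
  df <- assay$readings
  steps <- if (!is.null(assay$steps)) assay$steps else unique(df$step)
  if (is.null(initial_step)) initial_step <- steps[1]
  if (!initial_step %in% df$step)
    stop("initial step '", initial_step, "' not present in the assay")
  out <- list()
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, ]
    stat <- function(s, role) {
      x <- sub$reading[sub$step == s & sub$role == role]
      c(mean = mean(x), var_mean = stats::var(x) / length(x))
    }
    corr <- sapply(steps, function(s) {
      p <- stat(s, "positive"); ctl <- stat(s, "control")
      c(value = unname(p["mean"] - ctl["mean"]),
        var = unname(p["var_mean"] + ctl["var_mean"]))
    })
    c0 <- corr["value", initial_step]
    v0 <- corr["var", initial_step]
    quantifiable <- is.finite(c0) && c0 > 0
    if (!quantifiable)
      warning("condition '", cond,
              "' unquantifiable: non-positive initial corrected value")
    for (s in steps) {
      ci <- corr["value", s]; vi <- corr["var", s]
      pct <- if (quantifiable) 100 * ci / c0 else NA_real_
      sdp <- if (quantifiable)
        abs(pct) * sqrt(vi / ci^2 + v0 / c0^2) else NA_real_
      if (quantifiable && ci == 0) sdp <- 100 * sqrt(vi) / c0
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, step = s, corrected = ci, percent = pct,
        sd_percent = sdp, quantifiable = quantifiable)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
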