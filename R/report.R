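#' JSON run report
#'
#' Collects the outputs of executed stages into one reproducible report:
#' configuration echo (including the seed), software version, per-type /
#' per-category site counts, noise rates, and whatever stage summaries are
#' supplied. When a simulator `truth` is given, precision and recall of the
#' calls against the ground truth are included.
#'
#' @param detection Output of [detect_sites] (optional).
#' @param truth Simulator truth list (optional; enables precision/recall).
#' @param tissue Output of [compare_tissues] (optional).
#' @param recoding Output of [recoding_summary] (optional).
#' @param junctions Output of [infer_junctions] (optional).
#' @param config Configuration object(s) to echo (list).
#' @param seed Seed to echo.
#' @param path Optional file to write the JSON to.
#' @return The report as a list (invisibly if `path` given).
#' @export
run_report <- function(detection = NULL, truth = NULL, tissue = NULL,
                       recoding = NULL, junctions = NULL, config = list(),
                       seed = NULL, path = NULL) {
  rep <- list(
    tool = "editcall",
    version = as.character(utils::packageVersion("editcall")),
    seed = seed,
    config = lapply(config, function(x) unclass(x)))
  if (!is.null(detection)) {
    rep$detection <- list(
      n_sites = nrow(detection$sites),
      summary = as.data.frame(detection$summary),
      noise_rates = detection$noise_rates)
    if (!is.null(truth)) {
      pr <- detection_performance(detection$sites, truth)
      rep$detection$performance <- pr
    }
  }
  if (!is.null(tissue))
    rep$tissue <- list(n_tests = tissue$n_tests,
                       variable_fraction = tissue$variable_fraction)
  if (!is.null(recoding))
    rep$recoding <- list(
      n_orfs = nrow(recoding),
      edited_fraction = mean(recoding$n_recoding_sites >= 1),
      heavily_edited_fraction = mean(recoding$heavily_edited))
  if (!is.null(junctions))
    rep$junctions <- list(n_junctions = nrow(junctions))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}

#' Precision and recall of calls against simulator truth
#'
#' A called A-to-G site is a true positive when the simulator placed an
#' editing site at its (ORF, position). Recall is restricted to sites with
#' true level at or above `min_level` (weakly edited sites are undetectable
#' at finite coverage by design).
#'
#' @param sites Called site table.
#' @param truth Simulator truth (list with `edited_sites`).
#' @param min_level Recall restricted to true sites with level >= this.
#' @return List `n_called`, `n_true`, `precision`, `recall`,
#'   `level_mean_error` (mean of estimated minus true level over true
#'   positives) and `level_se` (its standard error).
#' @export
detection_performance <- function(sites, truth, min_level = 0.05) {
  s <- data.table::as.data.table(sites)[mismatch_type == "A>G"]
  tr <- data.table::as.data.table(truth$edited_sites)
  key_s <- paste(s$orf_id, s$pos)
  key_t <- paste(tr$orf_id, tr$pos)
  tp <- key_s %in% key_t
  detectable <- tr$level >= min_level
  rec <- if (any(detectable))
    mean(key_t[detectable] %in% key_s) else NA_real_
  err <- s$editing_level[tp] - tr$level[match(key_s[tp], key_t)]
  list(n_called = nrow(s), n_true = nrow(tr),
       precision = if (nrow(s) > 0) mean(tp) else NA_real_,
       recall = rec,
       level_mean_error = if (length(err)) mean(err) else NA_real_,
       level_se = if (length(err) > 1)
         stats::sd(err) / sqrt(length(err)) else NA_real_)
}
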