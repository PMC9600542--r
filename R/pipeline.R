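## End-to-end orchestration: simulate (or read) -> screen -> summarize ->
## treemap, with a YAML-configurable entry point mirrored by the
## `pvsignal` command-line script (inst/cli/pvsignal.R).

#' Read a pipeline configuration from YAML
#'
#' The configuration holds either a `simulate` block (keys `n_reports`,
#' `seed`, and `drugs` / `events` / `planted` which are lists of records
#' or the string `"default"` for the package catalogs) or an `input` block
#' (`icsr` path, optional `links` path and `dialect`, optional `meddra`
#' path), plus optional `screen` (`target_drugs`, `background`,
#' `comparator_drugs`, `criteria`) and `summarize` (`subset_soc`) blocks.
#'
#' @param file Path to a YAML file.
#' @return The configuration list, unvalidated (validation happens in
#'   [run_pipeline()]).
#' @export
read_pipeline_config <- function(file) {
  if (!file.exists(file)) {
    pv_stop("pv_io_error", "config file not found: '%s'", file)
  }
  yaml::read_yaml(file)
}

config_catalog <- function(spec, default, fields) {
  if (is.null(spec) || identical(spec, "default")) return(default())
  df <- do.call(rbind, lapply(spec, function(rec) {
    as.data.frame(rec[fields], stringsAsFactors = FALSE)
  }))
  df
}

# Build a synth_config from the `simulate` block of a pipeline config.
simulate_config <- function(block) {
  synth_config(
    n_reports = block$n_reports %||% 20000,
    drug_catalog = config_catalog(block$drugs, default_drug_catalog,
                                  c("drug", "prob")),
    event_catalog = config_catalog(block$events, default_event_catalog,
                                   c("event_pt", "baseline")),
    planted_rr = if (identical(block$planted, "none")) NULL else
      config_catalog(block$planted, default_planted_pairs,
                     c("drug", "event_pt", "rho")),
    demographics = demographic_defaults(),
    mean_events_per_report = block$mean_events_per_report,
    seed = block$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

criteria_from_config <- function(block) {
  cr <- block$criteria %||% list()
  signal_criteria(
    min_reports = cr$min_reports %||% 3,
    prr_min = cr$prr_min %||% 2,
    ror_min = cr$ror_min %||% 2,
    ic025_min = cr$ic025_min %||% 0,
    ic025_strict = cr$ic025_strict %||% TRUE
  )
}

stage <- function(log, quiet, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!quiet) message(msg)
  c(log, msg)
}

#' Run the full signal-detection pipeline
#'
#' Executes simulate (or read) -> screen -> summarize -> treemap and
#' writes the artifact bundle to `outdir`: `results.csv` (one row per
#' screened pair with PRR/ROR/IC/IC025 and the signal flag),
#' `soc_summary.csv`, `demographics.csv`, `subset_shares.csv` (signal
#' shares within the configured or top SOC), `treemap.svg`, `run.log`,
#' and `truth_eval.csv` (planted-pair sensitivity and null false-flag
#' rate) when the input was simulated. Runs are reproducible: the same
#' configuration, including its seed, produces identical outputs.
#'
#' @param config Configuration list (see [read_pipeline_config()]) or a
#'   path to a YAML file.
#' @param outdir Output directory, created if missing.
#' @param quiet Suppress stage messages (they are always written to
#'   `run.log`).
#' @return Invisibly, a list with the screen results, summaries, layout,
#'   truth evaluation (or `NULL`) and output file paths.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character()

  dictionary <- if (!is.null(config$input$meddra)) {
    read_meddra_dictionary(config$input$meddra)
  } else {
    toy_dictionary()
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    scfg <- simulate_config(config$simulate)
    sim <- generate_reports(scfg, dictionary = dictionary)
    dataset <- sim$dataset
    truth <- sim$truth
    log <- stage(log, quiet, "simulate: generated %d reports (seed %d)",
                 n_reports(dataset), scfg$seed)
  } else if (!is.null(config$input)) {
    dataset <- read_icsr_table(config$input$icsr,
                               dialect = config$input$dialect %||% "long",
                               links_file = config$input$links,
                               dictionary = dictionary,
                               lenient = isTRUE(config$input$lenient))
    log <- stage(log, quiet, "read: %d reports from '%s'",
                 n_reports(dataset), config$input$icsr)
  } else {
    pv_stop("pv_config_error",
            "config needs either a 'simulate' or an 'input' block")
  }

  screen_block <- config$screen %||% list()
  targets <- screen_block$target_drugs %||% unique(dataset$drugs$drug)
  criteria <- criteria_from_config(screen_block)
  results <- screen_signals(
    dataset, targets, criteria = criteria,
    background = screen_block$background %||% "all_reports",
    comparator_drugs = screen_block$comparator_drugs)
  log <- stage(log, quiet, "screen: %d pairs screened, %d signals found",
               nrow(results), sum(results$is_signal))

  soc_summary <- rollup_by_soc(results, dictionary)
  demo_summary <- demographics_summary(dataset)
  subset_soc <- config$summarize$subset_soc %||% soc_summary$soc[1]
  sig <- results[results$is_signal, , drop = FALSE]
  in_soc <- !is.na(pt_soc(dictionary, sig$event_pt)) &
    pt_soc(dictionary, sig$event_pt) == subset_soc
  shares <- if (any(in_soc)) subset_shares(sig[in_soc, , drop = FALSE]) else
    NULL
  log <- stage(log, quiet,
               "summarize: %d SOC(s) with signals; subset '%s' has %d signal(s)",
               nrow(soc_summary), subset_soc, sum(in_soc))

  layout <- if (nrow(soc_summary) > 0) treemap_layout(soc_summary) else NULL

  paths <- list(
    results = file.path(outdir, "results.csv"),
    soc_summary = file.path(outdir, "soc_summary.csv"),
    demographics = file.path(outdir, "demographics.csv"),
    subset_shares = file.path(outdir, "subset_shares.csv"),
    treemap = file.path(outdir, "treemap.svg"),
    log = file.path(outdir, "run.log")
  )
  res_out <- results
  for (col in c("prr", "ror", "ic", "ic025")) {
    res_out[[col]] <- ifelse(is.na(res_out[[col]]), "",
                             sprintf("%.6g", res_out[[col]]))
  }
  write_csv_plain(res_out, paths$results)
  write_csv_plain(soc_summary, paths$soc_summary)
  write_csv_plain(demo_summary, paths$demographics)
  if (!is.null(shares)) {
    keep <- intersect(c("event_pt", "n_reports", "share_pct",
                        "prr", "ror", "ic025"), names(shares))
    sh <- shares[, keep, drop = FALSE]
    for (col in c("prr", "ror", "ic025")) {
      if (col %in% names(sh)) sh[[col]] <- sprintf("%.6g", sh[[col]])
    }
    write_csv_plain(sh, paths$subset_shares)
  }
  if (!is.null(layout)) {
    treemap_svg(layout, paths$treemap)
  }

  truth_eval <- NULL
  if (!is.null(truth)) {
    truth_eval <- evaluate_truth(results, truth)
    paths$truth_eval <- file.path(outdir, "truth_eval.csv")
    te <- truth_eval
    te$value <- sprintf("%.6g", te$value)
    write_csv_plain(te, paths$truth_eval)
    log <- stage(log, quiet,
                 "truth: sensitivity %.1f%%, false-flag rate %.2f%%",
                 truth_eval$value[truth_eval$metric == "sensitivity_pct"],
                 truth_eval$value[truth_eval$metric == "false_flag_pct"])
  }
  writeLines(log, paths$log)

  invisible(list(results = results, soc_summary = soc_summary,
                 demographics = demo_summary, subset_shares = shares,
                 layout = layout, truth_eval = truth_eval, paths = paths))
}

#' Compare screen results against simulation ground truth
#'
#' Sensitivity is the percentage of planted pairs (`rho >= 2`) flagged as
#' signals; the false-flag rate is the percentage of null catalog pairs
#' with at least `min_reports` co-reports that were flagged.
#'
#' @param results A `disproportionality_result` data frame.
#' @param truth The `truth` element of [generate_reports()] output.
#' @param min_reports Report-count floor applied to the null denominator
#'   (default 3, matching the default signal criterion).
#' @return Data frame with columns `metric`, `value`, `numerator`,
#'   `denominator`; metrics `sensitivity_pct` and `false_flag_pct`.
#' @export
evaluate_truth <- function(results, truth, min_reports = 3) {
  key <- function(d, e) paste(d, e, sep = "\r")
  res_key <- key(results$drug, results$event_pt)
  flagged <- res_key[results$is_signal]

  planted <- key(truth$planted_pairs$drug, truth$planted_pairs$event_pt)
  sens_num <- sum(planted %in% flagged)
  sens_den <- length(planted)

  eligible <- res_key[results$a >= min_reports]
  null_eligible <- intersect(key(truth$null_pairs$drug,
                                 truth$null_pairs$event_pt), eligible)
  ff_num <- sum(null_eligible %in% flagged)
  ff_den <- length(null_eligible)

  data.frame(
    metric = c("sensitivity_pct", "false_flag_pct"),
    value = c(if (sens_den > 0) 100 * sens_num / sens_den else NA_real_,
              if (ff_den > 0) 100 * ff_num / ff_den else 0),
    numerator = c(sens_num, ff_num),
    denominator = c(sens_den, ff_den),
    stringsAsFactors = FALSE
  )
}
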