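## Hierarchy roll-ups and summary tables: signals per primary SOC, report
## shares within a SOC subset, the eosinophil preferred-term filter, and
## demographic breakdowns. All printed percentages use round-half-up to
## two decimals (see round_half_up()).

#' Roll signals up to primary system organ classes
#'
#' Counts, for each primary SOC, the number of signal PTs mapping to it and
#' the total reports behind those signals. Each signal is counted exactly
#' once (under its primary SOC; secondary multiaxial links are not
#' represented). PTs that do not resolve in the dictionary are excluded
#' from the summary and returned in the `unmapped` attribute, never
#' silently dropped.
#'
#' @param results A `disproportionality_result` data frame (or any data
#'   frame with `event_pt`, `n_reports` and logical `is_signal` columns);
#'   only rows with `is_signal = TRUE` are rolled up.
#' @param dictionary A [meddra_dictionary()].
#' @return Data frame with columns `soc`, `n_signals`, `n_reports`, ordered
#'   by descending `n_signals` (ties by SOC name); attribute `unmapped`
#'   lists unresolved signal PTs.
#' @export
rollup_by_soc <- function(results, dictionary) {
  stopifnot(is.data.frame(results),
            all(c("event_pt", "n_reports", "is_signal") %in% names(results)))
  sig <- results[results$is_signal %in% TRUE, , drop = FALSE]
  soc <- pt_soc(dictionary, sig$event_pt)
  unmapped <- sort(unique(sig$event_pt[is.na(soc)]))
  keep <- !is.na(soc)
  agg <- if (any(keep)) {
    stats::aggregate(
      cbind(n_signals = 1L, n_reports = sig$n_reports[keep]),
      by = list(soc = soc[keep]), FUN = sum)
  } else {
    data.frame(soc = character(), n_signals = integer(),
               n_reports = integer(), stringsAsFactors = FALSE)
  }
  agg <- agg[c_order(-agg$n_signals, agg$soc), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "unmapped") <- unmapped
  agg
}

#' Report shares of signals within one SOC subset
#'
#' Expresses each signal's report count as a percentage of the subset's
#' total signal reports, the layout used to tabulate e.g. ear-and-labyrinth
#' signals of one drug. Shares are rounded half-up to two decimals and sum
#' to 100 up to rounding slack.
#'
#' @param results A non-empty data frame of signal rows (columns `event_pt`
#'   and `n_reports`; any extra columns such as `prr`, `ror`, `ic025` are
#'   carried through), typically [screen_signals()] output restricted to
#'   the signals of one SOC.
#' @return The input rows with a `share_pct` column, ordered by descending
#'   `n_reports` then PT.
#' @export
subset_shares <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) {
    pv_stop("pv_empty_error", "subset_shares requires a non-empty subset")
  }
  out <- as.data.frame(results)
  out$share_pct <- round_half_up(out$n_reports / sum(out$n_reports) * 100, 2)
  out <- out[c_order(-out$n_reports, out$event_pt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter preferred terms to eosinophil-related ones
#'
#' Retains PT names containing the case-insensitive substring
#' `"eosinophil"`. The singular stem also matches terms such as
#' "Eosinophilia" and "Eosinophil count increase" that a plural-form match
#' would miss. Idempotent.
#'
#' @param pt_names Character vector of preferred terms.
#' @return The matching subset, in input order.
#' @examples
#' eosinophil_filter(c("Eosinophilia", "Ear pain", "Hypereosinophilic syndrome"))
#' @export
eosinophil_filter <- function(pt_names) {
  pt_names[grepl("eosinophil", pt_names, ignore.case = TRUE)]
}

#' Demographic breakdown of a report subset
#'
#' Tabulates, per demographic field, the report count and column percentage
#' of every category among the reports matched by `subset`.
#'
#' @param dataset An `icsr_dataset`.
#' @param subset Optional selector of reports: a predicate function taking
#'   the demographics data frame and returning a logical vector, a logical
#'   vector of length [n_reports()], or a character vector of report ids.
#'   Default: all reports.
#' @return Data frame with columns `field`, `category`, `count`, `pct`
#'   (percentage of the field's column total, rounded half-up to two
#'   decimals). Categories never observed in the subset are omitted.
#' @export
demographics_summary <- function(dataset, subset = NULL) {
  stopifnot(inherits(dataset, "icsr_dataset"))
  demo <- dataset$demographics
  keep <- if (is.null(subset)) {
    rep(TRUE, nrow(demo))
  } else if (is.function(subset)) {
    subset(demo)
  } else if (is.logical(subset)) {
    subset
  } else {
    demo$report_id %in% subset
  }
  demo <- demo[keep, , drop = FALSE]
  total <- nrow(demo)
  cats <- icsr_categories()
  rows <- lapply(names(cats), function(f) {
    tab <- table(factor(demo[[f]], levels = cats[[f]]))
    tab <- tab[tab > 0]
    if (length(tab) == 0) return(NULL)
    data.frame(field = f, category = names(tab),
               count = as.integer(tab),
               pct = round_half_up(as.integer(tab) / total * 100, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(field = character(), category = character(),
                      count = integer(), pct = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
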