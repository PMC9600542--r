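## Two-by-two contingency tables for drug-event pairs.
##
## The counting unit is the report (case): each report falls in exactly one
## cell for a given pair.
##   a: reports listing the target drug AND the event PT
##   b: reports listing the target drug without that PT
##   c: reports listing the PT without the target drug
##   d: reports listing neither
## so a + b + c + d equals the size of the background universe.

#' Construct a two-by-two contingency table
#'
#' @param a,b,c,d Non-negative integer cell counts (see module description
#'   for the cell semantics).
#' @return Object of class `contingency_table` with derived margins
#'   `n = a+b+c+d`, `n_drug = a+b`, `n_event = a+c` and the expected joint
#'   count under independence `expected = n_drug * n_event / n`.
#' @examples
#' contingency_table(10, 90, 10, 890)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4 || any(is.na(cells)) || any(cells < 0) ||
      any(cells != floor(cells))) {
    pv_stop("pv_schema_error",
            "contingency cells must be four non-negative integers")
  }
  # integer-valued doubles: margin products overflow 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  structure(
    list(a = a, b = b, c = c, d = d,
         n = n, n_drug = a + b, n_event = a + c,
         expected = if (n > 0) (a + b) * (a + c) / n else 0),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%.0f b=%.0f c=%.0f d=%.0f (n=%.0f, expected=%.3f)\n",
              x$a, x$b, x$c, x$d, x$n, x$expected))
  invisible(x)
}

# Resolve the background universe of report ids for a dataset.
background_ids <- function(dataset, background, comparator_drugs) {
  if (background == "all_reports") {
    return(dataset$demographics$report_id)
  }
  if (is.null(comparator_drugs) || length(comparator_drugs) == 0) {
    pv_stop("pv_config_error",
            "background 'listed_drugs_only' requires comparator_drugs")
  }
  keep <- dataset$drugs$drug %in% norm_label(comparator_drugs)
  unique(dataset$drugs$report_id[keep])
}

#' Build the 2x2 table for one drug-event pair
#'
#' Counts reports, not report-drug or report-event rows: a report listing
#' the drug twice and the event twice still contributes one to `a`. A drug
#' or event absent from the dataset yields a table with an empty margin
#' (`a + b = 0` or `a + c = 0`), not an error; downstream statistics flag
#' it as undefined.
#'
#' @param dataset An `icsr_dataset`.
#' @param drug Target drug name.
#' @param event_pt Target event preferred term.
#' @param background `"all_reports"` (default) compares against every report
#'   in the dataset; `"listed_drugs_only"` restricts the universe to reports
#'   listing at least one drug from `comparator_drugs` (e.g. the other
#'   members of a drug class).
#' @param comparator_drugs Character vector of comparator drug names,
#'   required when `background = "listed_drugs_only"`.
#' @return A `contingency_table`.
#' @export
build_table <- function(dataset, drug, event_pt,
                        background = c("all_reports", "listed_drugs_only"),
                        comparator_drugs = NULL) {
  stopifnot(inherits(dataset, "icsr_dataset"))
  background <- match.arg(background)
  if (n_reports(dataset) == 0) {
    pv_stop("pv_empty_error", "dataset contains no reports")
  }
  universe <- background_ids(dataset, background, comparator_drugs)
  drug <- norm_label(drug); event_pt <- norm_label(event_pt)

  with_drug <- unique(dataset$drugs$report_id[dataset$drugs$drug == drug])
  with_event <- unique(dataset$events$report_id[
    dataset$events$event_pt == event_pt])
  with_drug <- intersect(with_drug, universe)
  with_event <- intersect(with_event, universe)

  a <- length(intersect(with_drug, with_event))
  b <- length(with_drug) - a
  cc <- length(with_event) - a
  d <- length(universe) - a - b - cc
  contingency_table(a, b, cc, d)
}

#' All drug-event tables for a set of target drugs
#'
#' For each target drug, enumerates every event PT co-reported with that
#' drug at least once and returns the corresponding 2x2 cells. Pairs with
#' `a = 0` carry no reporting signal and are skipped.
#'
#' @inheritParams build_table
#' @param target_drugs Character vector of drugs to screen (non-empty).
#' @return Data frame with columns `drug`, `event_pt`, `a`, `b`, `c`, `d`,
#'   one row per (target drug, co-reported PT) pair, ordered by drug then
#'   PT (C collation).
#' @export
all_pair_tables <- function(dataset, target_drugs,
                            background = c("all_reports", "listed_drugs_only"),
                            comparator_drugs = NULL) {
  stopifnot(inherits(dataset, "icsr_dataset"))
  background <- match.arg(background)
  if (length(target_drugs) == 0) {
    pv_stop("pv_config_error", "target_drugs must be non-empty")
  }
  target_drugs <- unique(norm_label(target_drugs))
  universe <- background_ids(dataset, background, comparator_drugs)
  n <- length(universe)

  drugs <- data.table::as.data.table(dataset$drugs)
  events <- data.table::as.data.table(dataset$events)
  if (background != "all_reports") {
    drugs <- drugs[drugs$report_id %in% universe, ]
    events <- events[events$report_id %in% universe, ]
  }
  # total reports per event PT over the whole universe (the a + c margin)
  ev_margin <- events[, list(n_event = .N), by = "event_pt"]

  per_drug <- lapply(target_drugs, function(dg) {
    rid <- drugs$report_id[drugs$drug == dg]
    n_drug <- length(rid)
    if (n_drug == 0) return(NULL)
    co <- events[events$report_id %in% rid, ]
    if (nrow(co) == 0) return(NULL)
    a_tab <- co[, list(a = .N), by = "event_pt"]
    a_tab <- merge(a_tab, ev_margin, by = "event_pt", sort = FALSE)
    data.frame(
      drug = dg, event_pt = a_tab$event_pt,
      a = a_tab$a, b = n_drug - a_tab$a,
      c = a_tab$n_event - a_tab$a,
      d = n - n_drug - (a_tab$n_event - a_tab$a),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_drug)
  if (is.null(out)) {
    out <- data.frame(drug = character(), event_pt = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), stringsAsFactors = FALSE)
  }
  out <- out[c_order(out$drug, out$event_pt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
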