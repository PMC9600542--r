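## Domain model: individual case safety reports (ICSRs) and their tabular
## interchange formats.
##
## A dataset is stored in normalized form:
##   demographics: one row per report (report_id + the five categorical fields)
##   drugs:        one row per (report_id, drug)      -- a set, no duplicates
##   events:       one row per (report_id, event_pt)  -- a set, no duplicates
## plus an optional PT -> primary-SOC dictionary.

DEMOGRAPHIC_FIELDS <- c("continent", "age_group", "sex", "serious", "notifier")

#' Category sets for ICSR demographic fields
#'
#' The closed category sets used to validate report demographics. Age bands
#' follow the convention of large spontaneous-reporting extracts (neonatal
#' through elderly bands); the `45–65 years` / `65–74 years`
#' labels overlap textually at 65 and are treated as disjoint with age 65
#' assigned to the younger band.
#'
#' @return Named list of character vectors, one per demographic field.
#' @examples
#' icsr_categories()$sex
#' @export
icsr_categories <- function() {
  list(
    continent = c("Africa", "Americas", "Asia", "Europe", "Oceania", "Unknown"),
    age_group = c("0–27 days", "28 days to 23 months", "2–11 years",
                  "12–17 years", "18–44 years", "45–65 years",
                  "65–74 years", "≥75 years", "Unknown"),
    sex       = c("Male", "Female", "Unknown"),
    serious   = c("Yes", "No", "Unknown"),
    notifier  = c("Physician", "Pharmacist", "Other Health Professional",
                  "Consumer/Non-Health Professional", "Lawyer", "Unknown")
  )
}

check_enum <- function(values, field, lenient) {
  allowed <- icsr_categories()[[field]]
  bad <- !(values %in% allowed) & !is.na(values)
  if (any(bad)) {
    if (lenient) {
      values[bad] <- "Unknown"
    } else {
      pv_stop("pv_schema_error",
              "field '%s' contains value(s) outside its category set: %s",
              field, paste(unique(values[bad]), collapse = ", "))
    }
  }
  empty <- is.na(values) | values == ""
  if (any(empty)) {
    if (!lenient) {
      pv_stop("pv_schema_error", "field '%s' contains empty values", field)
    }
    values[empty] <- "Unknown"
  }
  values
}

#' Construct an ICSR dataset
#'
#' Assembles a validated spontaneous-report dataset from a per-report
#' demographics table and report--drug / report--event link tables. Drugs
#' and events are treated as sets per report: duplicates are collapsed and
#' every report must retain at least one drug and one event. Demographic
#' values are checked against [icsr_categories()]; with `lenient = TRUE`
#' out-of-set values become `"Unknown"` instead of failing.
#'
#' @param demographics Data frame with columns `report_id`, `continent`,
#'   `age_group`, `sex`, `serious`, `notifier`; one row per report.
#' @param drug_links Data frame with columns `report_id`, `drug`.
#' @param event_links Data frame with columns `report_id`, `event_pt`.
#' @param dictionary Optional [meddra_dictionary()]; when present, event
#'   terms that do not resolve are recorded in the dataset's `unmapped`
#'   diagnostic set (never dropped).
#' @param lenient Map unknown demographic strings to `"Unknown"` instead of
#'   raising a schema error.
#' @return An object of class `icsr_dataset`.
#' @seealso [read_icsr_table()], [generate_reports()]
#' @export
icsr_dataset <- function(demographics, drug_links, event_links,
                         dictionary = NULL, lenient = FALSE) {
  need <- c("report_id", DEMOGRAPHIC_FIELDS)
  miss <- setdiff(need, names(demographics))
  if (length(miss) > 0) {
    pv_stop("pv_schema_error", "demographics table lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  demographics <- as.data.frame(demographics)[, need]
  demographics$report_id <- norm_label(demographics$report_id)
  if (anyDuplicated(demographics$report_id)) {
    dup <- unique(demographics$report_id[duplicated(demographics$report_id)])
    pv_stop("pv_integrity_error", "duplicate report_id(s): %s",
            paste(utils::head(dup, 5), collapse = ", "))
  }
  for (f in DEMOGRAPHIC_FIELDS) {
    demographics[[f]] <- check_enum(norm_label(demographics[[f]]), f, lenient)
  }

  tidy_links <- function(links, col) {
    miss <- setdiff(c("report_id", col), names(links))
    if (length(miss) > 0) {
      pv_stop("pv_schema_error", "link table lacks column(s): %s",
              paste(miss, collapse = ", "))
    }
    links <- data.frame(report_id = norm_label(links$report_id),
                        value = norm_label(links[[col]]),
                        stringsAsFactors = FALSE)
    links <- links[links$value != "", , drop = FALSE]
    links <- unique(links)
    names(links)[2] <- col
    stray <- setdiff(links$report_id, demographics$report_id)
    if (length(stray) > 0) {
      pv_stop("pv_integrity_error",
              "%s links refer to unknown report_id(s): %s",
              col, paste(utils::head(stray, 5), collapse = ", "))
    }
    links[c_order(links$report_id, links[[col]]), , drop = FALSE]
  }
  drugs  <- tidy_links(drug_links, "drug")
  events <- tidy_links(event_links, "event_pt")

  no_drug  <- setdiff(demographics$report_id, drugs$report_id)
  no_event <- setdiff(demographics$report_id, events$report_id)
  if (length(no_drug) > 0) {
    pv_stop("pv_integrity_error", "report(s) without any drug: %s",
            paste(utils::head(no_drug, 5), collapse = ", "))
  }
  if (length(no_event) > 0) {
    pv_stop("pv_integrity_error", "report(s) without any event: %s",
            paste(utils::head(no_event, 5), collapse = ", "))
  }

  demographics <- demographics[c_order(demographics$report_id), , drop = FALSE]
  rownames(demographics) <- rownames(drugs) <- rownames(events) <- NULL

  unmapped <- character()
  if (!is.null(dictionary)) {
    stopifnot(inherits(dictionary, "meddra_dictionary"))
    pts <- unique(events$event_pt)
    unmapped <- sort(pts[is.na(pt_soc(dictionary, pts))])
  }

  structure(
    list(demographics = demographics, drugs = drugs, events = events,
         dictionary = dictionary, unmapped = unmapped),
    class = "icsr_dataset"
  )
}

#' Number of reports in a dataset
#' @param dataset An `icsr_dataset`.
#' @return Integer count of reports (cases).
#' @export
n_reports <- function(dataset) {
  stopifnot(inherits(dataset, "icsr_dataset"))
  nrow(dataset$demographics)
}

#' @export
print.icsr_dataset <- function(x, ...) {
  cat(sprintf("<icsr_dataset> %d reports, %d drugs, %d event terms\n",
              nrow(x$demographics), length(unique(x$drugs$drug)),
              length(unique(x$events$event_pt))))
  if (length(x$unmapped) > 0) {
    cat(sprintf("  %d event term(s) unmapped in the dictionary\n",
                length(x$unmapped)))
  }
  invisible(x)
}

#' Preferred terms not covered by the dataset's dictionary
#'
#' @param dataset An `icsr_dataset` built with a dictionary.
#' @return Sorted character vector of event PTs with no dictionary entry.
#' @export
unmapped_pts <- function(dataset) {
  stopifnot(inherits(dataset, "icsr_dataset"))
  dataset$unmapped
}

#' Order-insensitive dataset equality
#'
#' Two datasets are equal when they contain the same reports with the same
#' demographics and the same drug and event sets, regardless of row order.
#'
#' @param a,b `icsr_dataset` objects.
#' @return Logical scalar.
#' @export
datasets_equal <- function(a, b) {
  canon <- function(d) {
    lapply(d[c("demographics", "drugs", "events")], function(df) {
      df <- df[do.call(c_order, unname(as.list(df))), , drop = FALSE]
      rownames(df) <- NULL
      df
    })
  }
  isTRUE(all.equal(canon(a), canon(b)))
}

## --- tabular interchange -------------------------------------------------

LONG_COLUMNS <- c("report_id", "drug", "event_pt", DEMOGRAPHIC_FIELDS)

#' Read an ICSR table
#'
#' Reads the package's CSV interchange format into an [icsr_dataset()].
#' The `long` dialect is a single file with one row per report x drug x
#' event combination and the demographic columns repeated on every row;
#' the `paired` dialect splits the same content into a per-report
#' demographics file plus a report--drug--event link file. Demographic
#' values repeated across rows of one `report_id` must agree exactly.
#'
#' @param file Path to the long-dialect CSV, or to the demographics CSV for
#'   the paired dialect.
#' @param dialect `"long"` (default) or `"paired"`.
#' @param links_file Path to the link CSV (paired dialect only).
#' @param dictionary,lenient Passed to [icsr_dataset()].
#' @return An `icsr_dataset`.
#' @examples
#' f <- system.file("extdata", "icsr_demo.csv", package = "pvsignal")
#' read_icsr_table(f)
#' @export
read_icsr_table <- function(file, dialect = c("long", "paired"),
                            links_file = NULL, dictionary = NULL,
                            lenient = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    df <- read_csv_plain(file, required = LONG_COLUMNS)
    if (nrow(df) == 0) {
      pv_stop("pv_empty_error", "'%s' contains no report rows", file)
    }
    demo <- unique(df[, c("report_id", DEMOGRAPHIC_FIELDS)])
    if (anyDuplicated(demo$report_id)) {
      bad <- unique(demo$report_id[duplicated(demo$report_id)])
      pv_stop("pv_integrity_error",
              "conflicting demographics within report_id(s): %s",
              paste(utils::head(bad, 5), collapse = ", "))
    }
    icsr_dataset(demo, df[, c("report_id", "drug")],
                 df[, c("report_id", "event_pt")],
                 dictionary = dictionary, lenient = lenient)
  } else {
    if (is.null(links_file)) {
      pv_stop("pv_schema_error", "paired dialect requires links_file")
    }
    demo <- read_csv_plain(file, required = c("report_id", DEMOGRAPHIC_FIELDS))
    links <- read_csv_plain(links_file,
                            required = c("report_id", "drug", "event_pt"))
    if (nrow(demo) == 0) {
      pv_stop("pv_empty_error", "'%s' contains no report rows", file)
    }
    icsr_dataset(demo, links[, c("report_id", "drug")],
                 links[, c("report_id", "event_pt")],
                 dictionary = dictionary, lenient = lenient)
  }
}

#' Write an ICSR table
#'
#' Serializes a dataset to the CSV interchange format read by
#' [read_icsr_table()]. Rows are emitted in a canonical order
#' (report_id, drug, event_pt under C collation) so that equal datasets
#' produce byte-identical files; re-reading the output recovers a dataset
#' equal to the input ([datasets_equal()]).
#'
#' @param dataset An `icsr_dataset`.
#' @inheritParams read_icsr_table
#' @return The primary output path, invisibly.
#' @export
write_icsr_table <- function(dataset, file, dialect = c("long", "paired"),
                             links_file = NULL) {
  stopifnot(inherits(dataset, "icsr_dataset"))
  dialect <- match.arg(dialect)
  links <- merge(dataset$drugs, dataset$events, by = "report_id",
                 all = FALSE, sort = FALSE)
  links <- links[c_order(links$report_id, links$drug, links$event_pt), ,
                 drop = FALSE]
  if (dialect == "long") {
    long <- merge(links, dataset$demographics, by = "report_id", sort = FALSE)
    long <- long[, LONG_COLUMNS, drop = FALSE]
    long <- long[c_order(long$report_id, long$drug, long$event_pt), ,
                 drop = FALSE]
    write_csv_plain(long, file)
  } else {
    if (is.null(links_file)) {
      pv_stop("pv_schema_error", "paired dialect requires links_file")
    }
    write_csv_plain(dataset$demographics, file)
    write_csv_plain(links, links_file)
  }
  invisible(file)
}
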