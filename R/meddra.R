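## MedDRA-like terminology: preferred term (PT) -> primary system organ
## class (SOC), optionally with HLT/HLGT intermediate levels. MedDRA is
## multiaxial (a PT may link to several SOCs) but hierarchy summaries here
## use the primary SOC only, so each PT maps to exactly one SOC.

#' Construct a PT-to-SOC dictionary
#'
#' @param entries Data frame with columns `pt`, `primary_soc` and optional
#'   `hlt`, `hlgt`. Duplicate rows restating the same mapping are collapsed;
#'   a PT mapped to two different primary SOCs is an integrity error.
#' @return An object of class `meddra_dictionary`.
#' @seealso [read_meddra_dictionary()], [pt_soc()]
#' @export
meddra_dictionary <- function(entries) {
  miss <- setdiff(c("pt", "primary_soc"), names(entries))
  if (length(miss) > 0) {
    pv_stop("pv_schema_error", "dictionary lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  entries <- as.data.frame(entries)
  entries$pt <- norm_label(entries$pt)
  entries$primary_soc <- norm_label(entries$primary_soc)
  for (col in c("hlt", "hlgt")) {
    entries[[col]] <- if (col %in% names(entries))
      norm_label(entries[[col]]) else NA_character_
  }
  entries <- unique(entries[, c("pt", "primary_soc", "hlt", "hlgt")])
  if (any(entries$pt == "") || any(entries$primary_soc == "")) {
    pv_stop("pv_schema_error", "dictionary contains empty pt or primary_soc")
  }
  dup <- unique(entries$pt[duplicated(entries$pt)])
  if (length(dup) > 0) {
    pv_stop("pv_integrity_error",
            "PT(s) mapped to more than one primary SOC: %s",
            paste(utils::head(dup, 5), collapse = ", "))
  }
  entries <- entries[c_order(entries$pt), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "meddra_dictionary")
}

#' Read a PT-to-SOC dictionary from CSV
#'
#' Expects columns `pt`, `primary_soc` and optionally `hlt`, `hlgt`.
#'
#' @param file Path to the CSV file.
#' @return A `meddra_dictionary`.
#' @examples
#' f <- system.file("extdata", "meddra_toy.csv", package = "pvsignal")
#' d <- read_meddra_dictionary(f)
#' pt_soc(d, "Ear pain")
#' @export
read_meddra_dictionary <- function(file) {
  meddra_dictionary(read_csv_plain(file, required = c("pt", "primary_soc")))
}

#' Look up the primary SOC of preferred terms
#'
#' Lookup is case-preserving: the exact PT string is matched first; when it
#' misses, a case-insensitive fallback is tried and resolves only if it is
#' unambiguous. Terms that still miss return `NA`.
#'
#' @param dictionary A `meddra_dictionary`.
#' @param pt Character vector of preferred terms.
#' @return Character vector of primary SOC names, `NA` where unresolved.
#' @export
pt_soc <- function(dictionary, pt) {
  stopifnot(inherits(dictionary, "meddra_dictionary"))
  pt <- norm_label(pt)
  e <- dictionary$entries
  out <- e$primary_soc[match(pt, e$pt)]
  miss <- is.na(out)
  if (any(miss)) {
    lo <- tolower(e$pt)
    # case-insensitive fallback, only where the folded form is unambiguous
    ambiguous <- lo %in% lo[duplicated(lo)]
    idx <- match(tolower(pt[miss]), ifelse(ambiguous, NA_character_, lo))
    out[miss] <- e$primary_soc[idx]
  }
  out
}

#' @export
print.meddra_dictionary <- function(x, ...) {
  cat(sprintf("<meddra_dictionary> %d preferred terms across %d SOCs\n",
              nrow(x$entries), length(unique(x$entries$primary_soc))))
  invisible(x)
}
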