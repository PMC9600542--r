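## Internal helpers shared across modules.

# Classed conditions so callers can distinguish schema, integrity,
# configuration and empty-input failures programmatically.
pv_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "pv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Round half away from zero
#'
#' Decimal rounding where ties go up (`round_half_up(0.125, 2)` is `0.13`),
#' as used for all printed percentages in the package's summary tables.
#' Base [round()] uses round-half-to-even, which disagrees with the
#' convention of published pharmacovigilance report tables on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.125, 2.675, 50.865), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon guards ties stored just below .5 by binary floating point
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

## --- minimal RFC-4180 CSV I/O -------------------------------------------
## A dedicated writer keeps output byte-stable (fixed field order, "\n"
## line endings, quoting only where required) so identical datasets always
## serialize identically -- relied on for round-trip and determinism checks.

csv_field <- function(x) {
  x <- enc2utf8(as.character(x))
  x[is.na(x)] <- ""
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs], fixed = TRUE), '"')
  x
}

write_csv_plain <- function(df, file) {
  header <- paste(csv_field(names(df)), collapse = ",")
  if (nrow(df) > 0) {
    cols <- lapply(df, csv_field)
    body <- do.call(paste, c(cols, sep = ","))
    lines <- c(header, body)
  } else {
    lines <- header
  }
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(file)
}

read_csv_plain <- function(file, required = character()) {
  if (!file.exists(file)) {
    pv_stop("pv_io_error", "input file not found: '%s'", file)
  }
  df <- tryCatch(
    utils::read.csv(file, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8", strip.white = FALSE),
    error = function(e) {
      pv_stop("pv_empty_error", "could not parse '%s' as CSV: %s",
              file, conditionMessage(e))
    }
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    pv_stop("pv_schema_error", "missing required column(s) in '%s': %s",
            file, paste(missing, collapse = ", "))
  }
  df
}

# Exact-string matching is defined on NFC-normalized, whitespace-trimmed
# names; no fuzzy matching.
norm_label <- function(x) {
  trimws(stringi_nfc(enc2utf8(as.character(x))))
}

# NFC normalization without adding a dependency: R >= 4.1 exposes it
# through iconv on platforms with ICU; fall back to identity if absent.
stringi_nfc <- function(x) {
  out <- tryCatch(iconv(x, from = "UTF-8", to = "UTF-8-NFC"),
                  error = function(e) x)
  ifelse(is.na(out) & !is.na(x), x, out)
}

# Deterministic C-locale ordering, independent of the session collation.
c_order <- function(...) {
  order(..., method = "radix")
}
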