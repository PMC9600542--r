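## Disproportionality statistics on a 2x2 reporting table and the
## composite signal criterion.
##
##   PRR = [a/(a+b)] / [c/(c+d)]        proportional reporting ratio
##   ROR = (a/b) / (c/d) = ad/bc        reporting odds ratio
##   IC  = log2((a + 0.5) / (E + 0.5))  shrinkage information component,
##         E = (a+b)(a+c)/n the expected joint count under independence
##   IC025: lower bound of the IC's 95% credibility interval, either the
##         closed-form approximation
##             IC - 3.3 (a+0.5)^-1/2 - 2.4 (a+0.5)^-3/2
##         or the 2.5th percentile of log2(G/(E+0.5)) with
##         G ~ Gamma(shape = a + 0.5, rate = 1), by Monte Carlo.
##
## The +0.5 shrinkage pulls the IC of rare pairs toward 0; for large counts
## the IC converges to the plain log2 observed-over-expected reporting
## ratio. PRR and ROR use the raw cells with no continuity correction.
## Statistics whose denominators vanish are returned as NA ("undefined"),
## never clamped to 0 or infinity, and an undefined statistic fails the
## signal criterion.

# Vectorized kernels on raw cells; NA encodes "undefined". Cells are
# promoted to double up front: products like a*d overflow 32-bit integers
# at database scale.
calc_prr <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  out <- (a / (a + b)) / (c / (c + d))
  out[(a + b) == 0 | (c + d) == 0 | c == 0] <- NA_real_
  out
}

calc_ror <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  out <- (a * d) / (b * c)
  out[b == 0 | c == 0 | d == 0] <- NA_real_
  out
}

calc_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  out <- log2((a + 0.5) / (e + 0.5))
  out[n == 0] <- NA_real_
  out
}

calc_ic025_approx <- function(a, b, c, d) {
  s <- a + 0.5
  calc_ic(a, b, c, d) - 3.3 * s^(-0.5) - 2.4 * s^(-1.5)
}

as_cells <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  list(a = t$a, b = t$b, c = t$c, d = t$d)
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`: the proportion of the target drug's
#' reports mentioning the event, relative to the same proportion among all
#' other reports. Undefined (`NA`) when the drug margin, the comparator
#' margin or `c` is zero.
#'
#' @param t A [contingency_table()].
#' @return Non-negative numeric scalar, or `NA` if undefined.
#' @examples
#' prr(contingency_table(10, 90, 10, 890)) # 9
#' @export
prr <- function(t) {
  with(as_cells(t), calc_prr(a, b, c, d))
}

#' Reporting odds ratio
#'
#' `ROR = (a/b) / (c/d) = ad/bc`: the odds of the event among the target
#' drug's reports versus the odds among all other reports. Undefined (`NA`)
#' when `b`, `c` or `d` is zero.
#'
#' @inheritParams prr
#' @return Non-negative numeric scalar, or `NA` if undefined.
#' @export
ror <- function(t) {
  with(as_cells(t), calc_ror(a, b, c, d))
}

#' Shrinkage information component
#'
#' `IC = log2((a + 0.5) / (E + 0.5))` with `E = (a+b)(a+c)/n`: a Bayesian
#' log2 observed-to-expected reporting ratio. The +0.5 terms shrink rare
#' pairs toward independence (IC = 0); with `a = E = 0` (an empty margin)
#' the IC is exactly 0 by convention, and for large counts it approaches
#' the unshrunk `log2(a/E)`.
#'
#' @inheritParams prr
#' @return Numeric scalar, or `NA` when the table is empty (`n = 0`).
#' @export
ic <- function(t) {
  with(as_cells(t), calc_ic(a, b, c, d))
}

#' Lower 95% credibility bound of the information component
#'
#' The signal-defining lower end of the IC's 95% credibility interval.
#' `method = "approx"` uses the closed form
#' `IC - 3.3 (a+0.5)^(-1/2) - 2.4 (a+0.5)^(-3/2)`; `method = "mc"` draws
#' the observed-count posterior `G ~ Gamma(a + 0.5, rate = 1)` and takes
#' the 2.5th percentile of `log2(G / (E + 0.5))`. The two agree closely for
#' `a >= 3` (the report-count floor of the signal criterion).
#'
#' @inheritParams prr
#' @param method `"approx"` (closed form, default) or `"mc"` (Monte Carlo).
#' @param n_draws Number of posterior draws for `method = "mc"`.
#' @param seed Optional integer seed for the Monte Carlo draws; the global
#'   RNG state is restored afterwards.
#' @return Numeric scalar, always `<=` [ic()] for the approximation.
#' @examples
#' t <- contingency_table(10, 90, 90, 810)
#' ic025(t)               # about -1.089 at independence with a = 10
#' @export
ic025 <- function(t, method = c("approx", "mc"), n_draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  cl <- as_cells(t)
  if (method == "approx") {
    return(with(cl, calc_ic025_approx(a, b, c, d)))
  }
  n <- with(cl, a + b + c + d)
  if (n == 0) return(NA_real_)
  e <- with(cl, (a + b) * (a + c) / n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  g <- stats::rgamma(n_draws, shape = cl$a + 0.5, rate = 1)
  stats::quantile(log2(g / (e + 0.5)), probs = 0.025, names = FALSE)
}

#' Composite signal criterion thresholds
#'
#' A drug-event pair is a signal when it was reported at least
#' `min_reports` times and PRR, ROR and IC025 all clear their thresholds.
#' `ic025_strict` controls whether the IC025 comparison is strict
#' (`> ic025_min`, default) or weak (`>=`).
#'
#' @param min_reports Minimum report count `a` (default 3).
#' @param prr_min,ror_min PRR and ROR thresholds (default 2; compared as >=).
#' @param ic025_min IC025 threshold (default 0).
#' @param ic025_strict Use a strict inequality for IC025 (default `TRUE`).
#' @return Object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_reports = 3, prr_min = 2, ror_min = 2,
                            ic025_min = 0, ic025_strict = TRUE) {
  if (!is.finite(min_reports) || min_reports < 1 ||
      !all(is.finite(c(prr_min, ror_min, ic025_min)))) {
    pv_stop("pv_config_error", "signal criteria must be finite, min_reports >= 1")
  }
  structure(list(min_reports = as.integer(min_reports), prr_min = prr_min,
                 ror_min = ror_min, ic025_min = ic025_min,
                 ic025_strict = isTRUE(ic025_strict)),
            class = "signal_criteria")
}

apply_criteria <- function(a, prr, ror, ic025, criteria) {
  ic_ok <- if (criteria$ic025_strict) ic025 > criteria$ic025_min else
    ic025 >= criteria$ic025_min
  ok <- (a >= criteria$min_reports) &
    !is.na(prr) & prr >= criteria$prr_min &
    !is.na(ror) & ror >= criteria$ror_min &
    !is.na(ic025) & ic_ok
  ok & !is.na(ok)
}

#' Evaluate one drug-event table against the signal criterion
#'
#' @param t A [contingency_table()].
#' @param criteria A [signal_criteria()] object.
#' @param drug,event_pt Optional labels carried into the result row.
#' @return One-row data frame with columns `drug`, `event_pt`, `a`, `b`,
#'   `c`, `d`, `n_reports` (= `a`), `prr`, `ror`, `ic`, `ic025` and the
#'   logical `is_signal`.
#' @export
evaluate_signal <- function(t, criteria = signal_criteria(),
                            drug = NA_character_, event_pt = NA_character_) {
  stopifnot(inherits(criteria, "signal_criteria"))
  cl <- as_cells(t)
  res <- data.frame(
    drug = drug, event_pt = event_pt,
    a = cl$a, b = cl$b, c = cl$c, d = cl$d,
    n_reports = cl$a,
    prr = prr(t), ror = ror(t), ic = ic(t),
    ic025 = ic025(t, method = "approx"),
    stringsAsFactors = FALSE
  )
  res$is_signal <- apply_criteria(res$a, res$prr, res$ror, res$ic025, criteria)
  class(res) <- c("disproportionality_result", "data.frame")
  res
}

#' Screen every drug-event pair of a dataset
#'
#' Builds the 2x2 table for every (target drug, co-reported PT) pair via
#' [all_pair_tables()], computes PRR, ROR, IC and the closed-form IC025,
#' and applies the composite signal criterion. Ordering is deterministic:
#' drug, then descending report count, then PT.
#'
#' @inheritParams all_pair_tables
#' @param criteria A [signal_criteria()] object.
#' @return Data frame of class `disproportionality_result`, one row per
#'   pair, with the columns of [evaluate_signal()].
#' @export
screen_signals <- function(dataset, target_drugs,
                           criteria = signal_criteria(),
                           background = c("all_reports", "listed_drugs_only"),
                           comparator_drugs = NULL) {
  stopifnot(inherits(criteria, "signal_criteria"))
  if (length(target_drugs) == 0) {
    out <- evaluate_signal(contingency_table(0, 0, 0, 0), criteria)[0, ]
    return(out)
  }
  tabs <- all_pair_tables(dataset, target_drugs, background = background,
                          comparator_drugs = comparator_drugs)
  res <- data.frame(
    drug = tabs$drug, event_pt = tabs$event_pt,
    a = tabs$a, b = tabs$b, c = tabs$c, d = tabs$d,
    n_reports = tabs$a,
    prr = calc_prr(tabs$a, tabs$b, tabs$c, tabs$d),
    ror = calc_ror(tabs$a, tabs$b, tabs$c, tabs$d),
    ic = calc_ic(tabs$a, tabs$b, tabs$c, tabs$d),
    ic025 = calc_ic025_approx(tabs$a, tabs$b, tabs$c, tabs$d),
    stringsAsFactors = FALSE
  )
  res$is_signal <- apply_criteria(res$a, res$prr, res$ror, res$ic025, criteria)
  res <- res[c_order(res$drug, -res$n_reports, res$event_pt), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("disproportionality_result", "data.frame")
  res
}
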