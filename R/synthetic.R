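## Synthetic spontaneous-reporting-database generator.
##
## Generative model, per report:
##   * drugs:  independent Bernoulli per catalog drug with its marginal
##     probability, re-drawn until at least one drug is listed;
##   * events: independent Bernoulli per catalog PT with probability
##     baseline * rho, where rho is the largest planted relative reporting
##     ratio among the report's listed drugs for that PT (1 if none),
##     capped at 1, re-drawn until at least one event is listed;
##   * demographics: drawn independently of drugs and events from the
##     configured per-field marginals.
## Conditioning on non-empty drug/event sets mirrors the fact that a
## spontaneous report exists only as a drug-AE record; under no planted
## association it inflates all event rates by a common factor and leaves
## drug-event independence (hence PRR = ROR = 1, IC = 0 in expectation)
## intact.

#' Demographic marginal distributions of a large omalizumab reporting extract
#'
#' Per-field category proportions modelled on the demographic mix of
#' omalizumab adverse-event reports in a global pharmacovigilance database
#' (about 78% of reports from the Americas, 64.6% female reporters, 50.9%
#' serious, and age unknown for nearly half of reports). These are the
#' generator's default demographic marginals.
#'
#' @param renormalize Rescale each field to sum exactly to 1 (default
#'   `TRUE`); with `FALSE` the published proportions are returned as
#'   printed, which may sum to slightly off 1 from rounding.
#' @return Named list of named numeric vectors, one per demographic field;
#'   every category of [icsr_categories()] is present (possibly with
#'   probability 0).
#' @examples
#' demographic_defaults(renormalize = FALSE)$continent[["Americas"]] # 0.7823
#' @export
demographic_defaults <- function(renormalize = TRUE) {
  raw <- list(
    continent = c("Africa" = 0.0044, "Americas" = 0.7823, "Asia" = 0.0405,
                  "Europe" = 0.1655, "Oceania" = 0.0074, "Unknown" = 0),
    age_group = c("0–27 days" = 0.0011, "28 days to 23 months" = 0.0011,
                  "2–11 years" = 0.0130, "12–17 years" = 0.0327,
                  "18–44 years" = 0.1751, "45–65 years" = 0.2205,
                  "65–74 years" = 0.0602, "≥75 years" = 0.0257,
                  "Unknown" = 0.4705),
    sex       = c("Male" = 0.2722, "Female" = 0.6462, "Unknown" = 0.0816),
    serious   = c("Yes" = 0.5087, "No" = 0.4700, "Unknown" = 0.0213),
    notifier  = c("Physician" = 0.4334, "Pharmacist" = 0.0324,
                  "Other Health Professional" = 0.1957,
                  "Consumer/Non-Health Professional" = 0.2996,
                  "Lawyer" = 0.0002, "Unknown" = 0.0386)
  )
  cats <- icsr_categories()
  out <- lapply(names(raw), function(f) {
    v <- raw[[f]][cats[[f]]]
    names(v) <- cats[[f]]
    v[is.na(v)] <- 0
    if (renormalize) v / sum(v) else v
  })
  names(out) <- names(raw)
  out
}

#' Generator configuration
#'
#' @param n_reports Number of reports to generate (positive integer).
#' @param drug_catalog Data frame with columns `drug`, `prob`: the marginal
#'   probability that a report lists each drug.
#' @param event_catalog Data frame with columns `event_pt`, `baseline`: the
#'   baseline probability that a report lists each PT.
#' @param planted_rr Optional data frame with columns `drug`, `event_pt`,
#'   `rho`: planted relative reporting ratios (`rho >= 0`, multiplying the
#'   PT's baseline within reports listing the drug). Every key must
#'   resolve in the catalogs and `baseline * rho` is capped at 1.
#' @param demographics Per-field marginal probabilities as returned by
#'   [demographic_defaults()] (the default); each field must sum to 1
#'   within `1e-9` over the categories of [icsr_categories()].
#' @param mean_events_per_report Optional positive target for the expected
#'   number of events per report before conditioning; when given, baseline
#'   probabilities are rescaled proportionally (then capped at 1) to hit it.
#' @param seed Integer RNG seed; identical configurations generate
#'   identical datasets.
#' @return Object of class `synth_config`.
#' @seealso [generate_reports()]
#' @export
synth_config <- function(n_reports, drug_catalog, event_catalog,
                         planted_rr = NULL,
                         demographics = demographic_defaults(),
                         mean_events_per_report = NULL, seed = 1L) {
  if (!is.numeric(n_reports) || n_reports < 1) {
    pv_stop("pv_config_error", "n_reports must be a positive integer")
  }
  drug_catalog <- as.data.frame(drug_catalog)
  event_catalog <- as.data.frame(event_catalog)
  if (!all(c("drug", "prob") %in% names(drug_catalog)) ||
      !all(c("event_pt", "baseline") %in% names(event_catalog))) {
    pv_stop("pv_schema_error",
            "catalogs need columns drug/prob and event_pt/baseline")
  }
  drug_catalog$drug <- norm_label(drug_catalog$drug)
  event_catalog$event_pt <- norm_label(event_catalog$event_pt)
  if (anyDuplicated(drug_catalog$drug) || anyDuplicated(event_catalog$event_pt)) {
    pv_stop("pv_integrity_error", "catalog entries must be unique")
  }
  probs <- c(drug_catalog$prob, event_catalog$baseline)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    pv_stop("pv_config_error", "catalog probabilities must lie in [0, 1]")
  }
  if (all(drug_catalog$prob == 0) || all(event_catalog$baseline == 0)) {
    pv_stop("pv_config_error",
            "infeasible config: a non-empty report can never be drawn")
  }
  if (!is.null(mean_events_per_report)) {
    if (mean_events_per_report <= 0) {
      pv_stop("pv_config_error", "mean_events_per_report must be positive")
    }
    scale <- mean_events_per_report / sum(event_catalog$baseline)
    event_catalog$baseline <- pmin(1, event_catalog$baseline * scale)
  }
  if (!is.null(planted_rr)) {
    planted_rr <- as.data.frame(planted_rr)
    if (!all(c("drug", "event_pt", "rho") %in% names(planted_rr))) {
      pv_stop("pv_schema_error", "planted_rr needs columns drug, event_pt, rho")
    }
    planted_rr$drug <- norm_label(planted_rr$drug)
    planted_rr$event_pt <- norm_label(planted_rr$event_pt)
    if (any(!planted_rr$drug %in% drug_catalog$drug) ||
        any(!planted_rr$event_pt %in% event_catalog$event_pt)) {
      pv_stop("pv_config_error",
              "planted_rr keys must resolve in the drug/event catalogs")
    }
    if (any(!is.finite(planted_rr$rho)) || any(planted_rr$rho < 0)) {
      pv_stop("pv_config_error", "planted rho values must be finite and >= 0")
    }
    if (anyDuplicated(planted_rr[c("drug", "event_pt")])) {
      pv_stop("pv_integrity_error", "duplicate planted (drug, event_pt) pair")
    }
  } else {
    planted_rr <- data.frame(drug = character(), event_pt = character(),
                             rho = numeric(), stringsAsFactors = FALSE)
  }
  cats <- icsr_categories()
  for (f in names(cats)) {
    m <- demographics[[f]]
    if (is.null(m) || !all(names(m) %in% cats[[f]]) ||
        any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      pv_stop("pv_config_error",
              "demographic marginal for '%s' must sum to 1 over its categories",
              f)
    }
  }
  structure(
    list(n_reports = as.integer(n_reports), drug_catalog = drug_catalog,
         event_catalog = event_catalog, planted_rr = planted_rr,
         demographics = demographics, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Bernoulli inclusion matrix (n x k) with per-column probabilities,
# re-drawing all-zero rows so every report keeps >= 1 entry.
draw_inclusion <- function(n, prob_matrix) {
  k <- ncol(prob_matrix)
  inc <- matrix(stats::runif(n * k), nrow = n) < prob_matrix
  empty <- which(rowSums(inc) == 0)
  guard <- 0
  while (length(empty) > 0) {
    guard <- guard + 1
    if (guard > 10000) {
      pv_stop("pv_config_error",
              "cannot draw non-empty rows; probabilities too small")
    }
    redraw <- matrix(stats::runif(length(empty) * k),
                     nrow = length(empty)) < prob_matrix[empty, , drop = FALSE]
    keep <- rowSums(redraw) > 0
    inc[empty[keep], ] <- redraw[keep, , drop = FALSE]
    empty <- empty[!keep]
  }
  inc
}

#' Generate a synthetic reporting database with known ground truth
#'
#' Draws `config$n_reports` spontaneous reports under the generative model
#' described above. The returned ground truth labels every catalog pair:
#' pairs planted with `rho >= 2` are `planted_pairs` (true reporting
#' associations the screen should recover), all other drug-PT catalog
#' combinations are `null_pairs`.
#'
#' @param config A [synth_config()].
#' @param dictionary Optional [meddra_dictionary()] attached to the
#'   resulting dataset.
#' @return List with elements `dataset` (an `icsr_dataset`) and `truth`
#'   (list of data frames `planted_pairs` and `null_pairs`).
#' @examples
#' cfg <- synth_config(
#'   n_reports = 200,
#'   drug_catalog = data.frame(drug = c("alpha", "beta"), prob = c(0.4, 0.7)),
#'   event_catalog = data.frame(event_pt = c("Headache", "Rash", "Nausea"),
#'                              baseline = c(0.5, 0.3, 0.4)),
#'   planted_rr = data.frame(drug = "alpha", event_pt = "Rash", rho = 3),
#'   seed = 7)
#' sim <- generate_reports(cfg)
#' sim$dataset
#' @export
generate_reports <- function(config, dictionary = NULL) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_reports
  dcat <- config$drug_catalog
  ecat <- config$event_catalog
  ids <- sprintf("R%0*d", nchar(as.character(n)), seq_len(n))

  drug_inc <- draw_inclusion(
    n, matrix(dcat$prob, nrow = n, ncol = nrow(dcat), byrow = TRUE))

  # per-report, per-PT inclusion probability: baseline times the max
  # planted rho among the report's drugs (1 where none), capped at 1
  prob <- matrix(ecat$baseline, nrow = n, ncol = nrow(ecat), byrow = TRUE)
  if (nrow(config$planted_rr) > 0) {
    rho_eff <- matrix(1, nrow = n, ncol = nrow(ecat))
    for (i in seq_len(nrow(config$planted_rr))) {
      di <- match(config$planted_rr$drug[i], dcat$drug)
      ei <- match(config$planted_rr$event_pt[i], ecat$event_pt)
      rows <- drug_inc[, di]
      rho_eff[rows, ei] <- pmax(rho_eff[rows, ei], config$planted_rr$rho[i])
    }
    prob <- prob * rho_eff
    prob[prob > 1] <- 1
  }
  event_inc <- draw_inclusion(n, prob)

  demo <- data.frame(report_id = ids, stringsAsFactors = FALSE)
  for (f in names(config$demographics)) {
    m <- config$demographics[[f]]
    demo[[f]] <- sample(names(m), n, replace = TRUE, prob = m)
  }

  di <- which(drug_inc, arr.ind = TRUE)
  ei <- which(event_inc, arr.ind = TRUE)
  drug_links <- data.frame(report_id = ids[di[, 1]],
                           drug = dcat$drug[di[, 2]],
                           stringsAsFactors = FALSE)
  event_links <- data.frame(report_id = ids[ei[, 1]],
                            event_pt = ecat$event_pt[ei[, 2]],
                            stringsAsFactors = FALSE)
  dataset <- icsr_dataset(demo, drug_links, event_links,
                          dictionary = dictionary)

  planted <- config$planted_rr[config$planted_rr$rho >= 2, , drop = FALSE]
  all_pairs <- expand.grid(drug = dcat$drug, event_pt = ecat$event_pt,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d, e) paste(d, e, sep = "\r")
  null_pairs <- all_pairs[!key(all_pairs$drug, all_pairs$event_pt) %in%
                            key(planted$drug, planted$event_pt), , drop = FALSE]
  rownames(planted) <- rownames(null_pairs) <- NULL

  list(dataset = dataset,
       truth = list(planted_pairs = planted, null_pairs = null_pairs))
}
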