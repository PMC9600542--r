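## Default generator catalogs: a synthetic stand-in for a whole-database
## reporting universe containing the five biologics licensed for severe
## asthma. Biologic marginals keep their observed report-volume ratios but
## are scaled so the five drugs jointly cover about a tenth of reports, as
## they would against a full database comparator, with common asthma
## co-medications supplying the background; disproportionality statistics
## behave degenerately when one target drug dominates the universe (the
## shrinkage IC is bounded above by log2(1/drug share)). Planted relative
## reporting ratios reproduce the disproportionality pattern published
## for these biologics (ear-and-labyrinth and eosinophil-related signals
## concentrated on omalizumab, three ear and two eosinophil signals on
## mepolizumab, isolated eosinophil-count signals on benralizumab and
## dupilumab). Baseline event probabilities are chosen once as
## field-realistic values: common general/skin/respiratory complaints
## dominate (about two events per report before conditioning) while ear
## and eosinophil terms are rare, sized so planted pairs have expected
## co-report counts of roughly 8-50 at the default 60,000 reports.

# report totals per biologic in the emulated universe; the denominator
# scales them to a whole-database share of about 10% combined
BIOLOGIC_REPORT_TOTALS <- c(
  omalizumab = 32618, mepolizumab = 7344, benralizumab = 2387,
  reslizumab = 315, dupilumab = 20559
)
BIOLOGIC_UNIVERSE_SCALE <- 632230

#' Default drug catalog of the synthetic reporting universe
#'
#' Five monoclonal antibodies for severe asthma, with marginal listing
#' probabilities proportional to their observed report volumes (omalizumab
#' about 5% of reports), plus common background co-medications that make
#' up the rest of the database universe.
#'
#' @return Data frame with columns `drug`, `prob`.
#' @export
default_drug_catalog <- function() {
  rbind(
    data.frame(drug = names(BIOLOGIC_REPORT_TOTALS),
               prob = unname(BIOLOGIC_REPORT_TOTALS /
                               BIOLOGIC_UNIVERSE_SCALE),
               stringsAsFactors = FALSE),
    data.frame(drug = c("prednisolone", "salbutamol", "montelukast",
                        "fluticasone", "cetirizine"),
               prob = c(0.28, 0.25, 0.18, 0.20, 0.12),
               stringsAsFactors = FALSE)
  )
}

# (PT, baseline probability) triples of the default event catalog; ear and
# eosinophil terms carry small baselines, filler terms carry the bulk of
# per-report event mass.
default_event_rows <- function() {
  rbind(
    # ear and labyrinth terms
    data.frame(event_pt = c(
      "Ear pain", "Ear discomfort", "Otorrhoea", "Ear pruritus",
      "Ear congestion", "Ear swelling", "Ear disorder",
      "Tympanic membrane perforation", "Deafness unilateral",
      "Vertigo positional", "Middle ear effusion", "Meniere's disease",
      "Cerumen impaction", "Tympanic membrane disorder",
      "Tympanic membrane scarring", "Eustachian tube obstruction",
      "Eustachian tube disorder"),
      baseline = c(0.0020, 0.0010, 0.00020, 0.00040, 0.00030, 0.00030,
                   0.0010, 0.00040, 0.00120, 0.00060, 0.00070, 0.00070,
                   0.00060, 0.00025, 0.00006, 0.00015, 0.00020)),
    # eosinophil-related terms
    data.frame(event_pt = c(
      "Eosinophilic granulomatosis with polyangiitis", "Eosinophilia",
      "Eosinophil count increase", "Eosinophilic pneumonia",
      "Eosinophilic oesophagitis", "Hypereosinophilic syndrome",
      "Eosinophilic pneumonia chronic", "Eosinophil count abnormal",
      "Eosinophilic bronchitis"),
      baseline = c(0.00020, 0.0015, 0.00030, 0.00040, 0.00010, 0.00008,
                   0.00006, 0.00020, 0.00002)),
    # common filler terms
    data.frame(event_pt = c(
      "Drug ineffective", "Headache", "Dyspnoea", "Asthma", "Urticaria",
      "Fatigue", "Cough", "Nausea", "Dizziness", "Pruritus", "Rash",
      "Injection site reaction", "Injection site pain", "Arthralgia",
      "Pyrexia", "Anaphylactic reaction", "Alopecia", "Malaise", "Pain",
      "Vomiting", "Oedema peripheral", "Chest discomfort", "Wheezing",
      "Insomnia", "Hypersensitivity", "Myalgia", "Sinusitis", "Migraine",
      "Paraesthesia"),
      baseline = c(0.15, 0.12, 0.12, 0.10, 0.08, 0.10, 0.08, 0.09, 0.08,
                   0.07, 0.08, 0.10, 0.06, 0.06, 0.06, 0.02, 0.02, 0.05,
                   0.06, 0.04, 0.03, 0.04, 0.05, 0.03, 0.04, 0.04, 0.03,
                   0.02, 0.02))
  )
}

#' Default event catalog of the synthetic asthma-biologics universe
#'
#' @return Data frame with columns `event_pt`, `baseline`: 17
#'   ear-and-labyrinth terms, 9 eosinophil-related terms and 29 common
#'   filler terms with their baseline per-report listing probabilities.
#' @export
default_event_catalog <- function() {
  rows <- default_event_rows()
  rownames(rows) <- NULL
  rows
}

#' Default planted drug-event associations
#'
#' Relative reporting ratios planted on top of the baseline event
#' probabilities: the full set of ear-and-labyrinth and eosinophil
#' disproportionality strengths attributed to omalizumab, the three ear
#' signals and two eosinophil signals of mepolizumab, and the single
#' abnormal-eosinophil-count signal each of benralizumab and dupilumab.
#'
#' @return Data frame with columns `drug`, `event_pt`, `rho`.
#' @export
default_planted_pairs <- function() {
  oma_ear <- data.frame(
    drug = "omalizumab",
    event_pt = c("Ear pain", "Ear discomfort", "Otorrhoea", "Ear pruritus",
                 "Ear congestion", "Ear swelling", "Ear disorder",
                 "Tympanic membrane perforation", "Deafness unilateral",
                 "Vertigo positional", "Middle ear effusion",
                 "Meniere's disease", "Cerumen impaction",
                 "Tympanic membrane disorder", "Tympanic membrane scarring",
                 "Eustachian tube obstruction", "Eustachian tube disorder"),
    rho = c(6.27, 7.10, 17.17, 8.22, 8.55, 7.17, 2.30, 7.77, 2.19, 4.59,
            3.90, 4.01, 4.71, 10.72, 162.74, 17.75, 13.11))
  oma_eos <- data.frame(
    drug = "omalizumab",
    event_pt = c("Eosinophilic granulomatosis with polyangiitis",
                 "Eosinophilia", "Eosinophil count increase",
                 "Eosinophilic pneumonia", "Eosinophilic oesophagitis",
                 "Hypereosinophilic syndrome", "Eosinophilic pneumonia chronic",
                 "Eosinophil count abnormal"),
    rho = c(81.54, 2.35, 12.29, 6.00, 27.75, 41.66, 50.86, 14.47))
  mepo <- data.frame(
    drug = "mepolizumab",
    event_pt = c("Ear pain", "Ear disorder", "Ear discomfort",
                 "Eosinophilic bronchitis", "Eosinophilic oesophagitis"),
    rho = c(3.47, 5.13, 3.30, 726.14, 43.84))
  others <- data.frame(
    drug = c("benralizumab", "dupilumab"),
    event_pt = "Eosinophil count abnormal",
    rho = c(775.56, 38.68))
  out <- rbind(oma_ear, oma_eos, mepo, others)
  rownames(out) <- NULL
  out
}

#' Toy PT-to-SOC dictionary shipped with the package
#'
#' Loads `inst/extdata/meddra_toy.csv`: a small synthetic dictionary
#' covering every PT of the default event catalog (ear terms under
#' "Ear and labyrinth disorders", eosinophil terms under blood,
#' respiratory, gastrointestinal, vascular and investigation classes, and
#' the filler terms across further SOCs). It is not licensed MedDRA
#' content; SOC assignments are plausible but synthetic.
#'
#' @return A [meddra_dictionary()].
#' @export
toy_dictionary <- function() {
  read_meddra_dictionary(
    system.file("extdata", "meddra_toy.csv", package = "pvsignal",
                mustWork = TRUE))
}

#' Demonstration generator configuration
#'
#' Bundles the default catalogs, planted associations and demographic
#' marginals into a ready-to-run [synth_config()] emulating the
#' asthma-biologics reporting universe.
#'
#' @param n_reports Number of reports (default 60000).
#' @param seed RNG seed (default 42).
#' @return A `synth_config`.
#' @examples
#' sim <- generate_reports(demo_config(n_reports = 500), toy_dictionary())
#' sim$dataset
#' @export
demo_config <- function(n_reports = 60000, seed = 42) {
  synth_config(
    n_reports = n_reports,
    drug_catalog = default_drug_catalog(),
    event_catalog = default_event_catalog(),
    planted_rr = default_planted_pairs(),
    demographics = demographic_defaults(),
    seed = seed
  )
}
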