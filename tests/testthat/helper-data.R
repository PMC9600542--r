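# Shared fixture builders. All data are constructed in code.

demo_row <- function(report_id, continent = "Europe",
                     age_group = "18–44 years", sex = "Female",
                     serious = "No", notifier = "Physician") {
  data.frame(report_id = report_id, continent = continent,
             age_group = age_group, sex = sex, serious = serious,
             notifier = notifier, stringsAsFactors = FALSE)
}

# Build a dataset from a list of reports, each a list(drugs=, events=).
make_dataset <- function(reports, dictionary = NULL, lenient = FALSE) {
  ids <- sprintf("R%02d", seq_along(reports))
  demo <- do.call(rbind, lapply(ids, demo_row))
  drugs <- do.call(rbind, lapply(seq_along(reports), function(i) {
    data.frame(report_id = ids[i], drug = reports[[i]]$drugs,
               stringsAsFactors = FALSE)
  }))
  events <- do.call(rbind, lapply(seq_along(reports), function(i) {
    data.frame(report_id = ids[i], event_pt = reports[[i]]$events,
               stringsAsFactors = FALSE)
  }))
  icsr_dataset(demo, drugs, events, dictionary = dictionary,
               lenient = lenient)
}

# The canonical 4-report enumeration example: {D,E}, {D}, {E}, {X}.
tiny_dataset <- function() {
  make_dataset(list(
    list(drugs = "D", events = "E"),
    list(drugs = "D", events = "F"),
    list(drugs = "X", events = "E"),
    list(drugs = "X", events = "G")
  ))
}

# Random strictly-positive 2x2 cells for property tests.
random_cells <- function(n, seed, a_range = c(1, 1000)) {
  set.seed(seed)
  data.frame(
    a = sample(a_range[1]:a_range[2], n, replace = TRUE),
    b = sample(1:1000, n, replace = TRUE),
    c = sample(1:1000, n, replace = TRUE),
    d = sample(1:1000, n, replace = TRUE)
  )
}

# Brute-force contingency oracle: double loop over reports, set membership
# checked per report. Deliberately naive and independent of build_table().
bf_table <- function(dataset, drug, event_pt) {
  ids <- dataset$demographics$report_id
  a <- b <- cc <- d <- 0L
  for (id in ids) {
    has_d <- drug %in% dataset$drugs$drug[dataset$drugs$report_id == id]
    has_e <- event_pt %in%
      dataset$events$event_pt[dataset$events$report_id == id]
    if (has_d && has_e) a <- a + 1L
    else if (has_d) b <- b + 1L
    else if (has_e) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Small synthetic config used by several generator tests: one target drug
# at marginal 0.1 with one plantable event at baseline 0.002, plus dense
# filler drugs/events so conditioning on non-empty reports is negligible.
recovery_config <- function(n_reports, rho, seed) {
  synth_config(
    n_reports = n_reports,
    drug_catalog = data.frame(drug = c("target", "filler_drug"),
                              prob = c(0.1, 0.95)),
    event_catalog = data.frame(
      event_pt = c("Target event", paste0("Filler ", 1:5)),
      baseline = c(0.002, rep(0.6, 5))),
    planted_rr = if (!is.null(rho))
      data.frame(drug = "target", event_pt = "Target event", rho = rho),
    seed = seed
  )
}
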