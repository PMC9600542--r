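# SOC roll-ups, subset shares, eosinophil filter, demographics summary.

# The published ear-and-labyrinth signal pattern: 17 PTs, 394 reports.
ear_signal_counts <- function() {
  data.frame(
    event_pt = c("Ear pain", "Ear discomfort", "Otorrhoea", "Ear pruritus",
                 "Ear congestion", "Ear swelling", "Ear disorder",
                 "Tympanic membrane perforation", "Deafness unilateral",
                 "Vertigo positional", "Middle ear effusion",
                 "Meniere's disease", "Cerumen impaction",
                 "Tympanic membrane disorder", "Tympanic membrane scarring",
                 "Eustachian tube obstruction", "Eustachian tube disorder"),
    n_reports = c(152, 76, 25, 23, 21, 17, 16, 12, 11, 8, 8, 7, 5, 4, 3, 3, 3),
    is_signal = TRUE,
    stringsAsFactors = FALSE
  )
}

test_that("17 ear signals roll up to one SOC with 394 reports", {
  roll <- rollup_by_soc(ear_signal_counts(), toy_dictionary())
  expect_equal(nrow(roll), 1L)
  expect_equal(roll$soc, "Ear and labyrinth disorders")
  expect_equal(roll$n_signals, 17L)
  expect_equal(roll$n_reports, 394L)
})

test_that("rollup matches a brute-force tally and conserves totals", {
  set.seed(29)
  dict_df <- data.frame(pt = paste0("PT", 1:50),
                        primary_soc = sample(paste0("SOC", 1:5), 50,
                                             replace = TRUE))
  dict <- meddra_dictionary(dict_df)
  results <- data.frame(event_pt = paste0("PT", 1:50),
                        n_reports = sample(3:200, 50, replace = TRUE),
                        is_signal = sample(c(TRUE, FALSE), 50,
                                           replace = TRUE, prob = c(.7, .3)))
  roll <- rollup_by_soc(results, dict)
  sig <- results[results$is_signal, ]
  expect_equal(sum(roll$n_signals), nrow(sig))
  expect_equal(sum(roll$n_reports), sum(sig$n_reports))
  for (s in roll$soc) {
    pts <- dict_df$pt[dict_df$primary_soc == s]
    expect_equal(roll$n_signals[roll$soc == s],
                 sum(sig$event_pt %in% pts))
    expect_equal(roll$n_reports[roll$soc == s],
                 sum(sig$n_reports[sig$event_pt %in% pts]))
  }
  expect_true(all(diff(roll$n_signals) <= 0))
})

test_that("unmapped signal PTs are surfaced, not silently dropped", {
  dict <- meddra_dictionary(data.frame(pt = "Ear pain",
                                       primary_soc = "Ear and labyrinth disorders"))
  results <- data.frame(event_pt = c("Ear pain", "Mystery PT"),
                        n_reports = c(10, 5), is_signal = TRUE)
  roll <- rollup_by_soc(results, dict)
  expect_equal(sum(roll$n_signals), 1L)
  expect_equal(attr(roll, "unmapped"), "Mystery PT")
})

test_that("subset shares reproduce the published ear percentages", {
  shares <- subset_shares(ear_signal_counts())
  expect_equal(shares$share_pct[shares$event_pt == "Ear pain"], 38.58)
  expect_equal(shares$share_pct[shares$event_pt == "Ear discomfort"], 19.29)
  expect_equal(shares$share_pct[shares$event_pt == "Otorrhoea"], 6.35)
  expect_equal(shares$event_pt[1], "Ear pain") # descending n_reports
  expect_lt(abs(sum(shares$share_pct) - 100), 0.1)
})

test_that("single-row subsets get 100% and empty subsets error", {
  one <- subset_shares(data.frame(event_pt = "Ear pain", n_reports = 7))
  expect_equal(one$share_pct, 100)
  expect_error(subset_shares(data.frame(event_pt = character(),
                                        n_reports = integer())),
               class = "pv_empty_error")
})

test_that("share percentages are exactly round-half-up of count/total", {
  set.seed(37)
  counts <- sample(1:500, 20)
  shares <- subset_shares(data.frame(event_pt = paste0("PT", 1:20),
                                     n_reports = counts))
  manual <- round_half_up(shares$n_reports / sum(counts) * 100, 2)
  expect_identical(shares$share_pct, manual)
  expect_lt(abs(sum(shares$share_pct) - 100), 0.1)
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.135, 2), 0.14)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(50.865, 2), 50.87)
})

test_that("eosinophil filter keeps exactly the eosinophil PTs, idempotently", {
  expect_equal(
    eosinophil_filter(c("Eosinophilia", "Ear pain",
                        "Hypereosinophilic syndrome")),
    c("Eosinophilia", "Hypereosinophilic syndrome"))
  expect_equal(eosinophil_filter(character(0)), character(0))

  eos_pts <- c("Eosinophilic granulomatosis with polyangiitis",
               "Eosinophilia", "Eosinophil count increase",
               "Eosinophilic pneumonia", "Eosinophilic oesophagitis",
               "Hypereosinophilic syndrome", "Eosinophilic pneumonia chronic",
               "Eosinophil count abnormal")
  mixed <- c(ear_signal_counts()$event_pt, eos_pts)
  kept <- eosinophil_filter(mixed)
  expect_setequal(kept, eos_pts)
  expect_length(kept, 8L)
  expect_identical(eosinophil_filter(kept), kept)
})

test_that("demographics summary counts match brute-force tallies", {
  sim <- generate_reports(recovery_config(2000, rho = NULL, seed = 19))
  ds <- sim$dataset
  summ <- demographics_summary(ds)
  for (i in seq_len(nrow(summ))) {
    expect_equal(summ$count[i],
                 sum(ds$demographics[[summ$field[i]]] == summ$category[i]))
    expect_equal(summ$pct[i],
                 round_half_up(summ$count[i] / n_reports(ds) * 100, 2))
  }
  # counts conserve the column total per field
  totals <- tapply(summ$count, summ$field, sum)
  expect_true(all(totals == n_reports(ds)))
})

test_that("demographics summary respects subset predicates", {
  ds <- make_dataset(list(list(drugs = "a", events = "E"),
                          list(drugs = "b", events = "E"),
                          list(drugs = "a", events = "F")))
  sub <- demographics_summary(ds, subset = function(demo)
    demo$report_id %in% ds$drugs$report_id[ds$drugs$drug == "a"])
  expect_equal(sum(sub$count[sub$field == "sex"]), 2)
  expect_equal(sub$pct[sub$field == "sex"], 100)
})
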