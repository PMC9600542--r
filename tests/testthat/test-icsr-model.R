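# ICSR domain model and tabular interchange.

test_that("long-dialect rows are deduplicated into report-level sets", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- rbind(
    cbind(demo_row("R1"), drug = "omalizumab", event_pt = "Ear pain"),
    cbind(demo_row("R1"), drug = "omalizumab", event_pt = "Otorrhoea"),
    cbind(demo_row("R1"), drug = "omalizumab", event_pt = "Ear pain")
  )
  utils::write.csv(rows, f, row.names = FALSE)
  ds <- read_icsr_table(f)
  expect_equal(n_reports(ds), 1L)
  expect_setequal(ds$events$event_pt, c("Ear pain", "Otorrhoea"))
  expect_equal(ds$drugs$drug, "omalizumab")
})

test_that("conflicting demographics within one report_id are an integrity error", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- rbind(
    cbind(demo_row("R2", sex = "Male"), drug = "a", event_pt = "Rash"),
    cbind(demo_row("R2", sex = "Female"), drug = "a", event_pt = "Rash")
  )
  utils::write.csv(rows, f, row.names = FALSE)
  expect_error(read_icsr_table(f), class = "pv_integrity_error")
})

test_that("schema, empty-file and enum-closure errors are signaled", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- cbind(demo_row("R1"), drug = "a", event_pt = "Rash")
  utils::write.csv(rows[, setdiff(names(rows), "sex")], f, row.names = FALSE)
  expect_error(read_icsr_table(f), class = "pv_schema_error")
  expect_error(read_icsr_table(f), "sex")

  writeLines(paste(c("report_id,drug,event_pt,continent,age_group,sex,",
                     "serious,notifier"), collapse = ""), f)
  expect_error(read_icsr_table(f), class = "pv_empty_error")

  rows2 <- cbind(demo_row("R1", sex = "nonbinary?"), drug = "a",
                 event_pt = "Rash")
  utils::write.csv(rows2, f, row.names = FALSE)
  expect_error(read_icsr_table(f), class = "pv_schema_error")
  lenient <- read_icsr_table(f, lenient = TRUE)
  expect_equal(lenient$demographics$sex, "Unknown")
})

test_that("shipped fixture round-trips byte-identically and dataset-equal", {
  src <- system.file("extdata", "icsr_demo.csv", package = "pvsignal")
  ds <- read_icsr_table(src)
  expect_equal(n_reports(ds), 10L)
  out <- withr::local_tempfile(fileext = ".csv")
  write_icsr_table(ds, out)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(src, "raw", file.size(src)))
  expect_true(datasets_equal(ds, read_icsr_table(out)))
})

test_that("paired dialect round-trips to an equal dataset", {
  ds <- tiny_dataset()
  demo_f <- withr::local_tempfile(fileext = ".csv")
  links_f <- withr::local_tempfile(fileext = ".csv")
  write_icsr_table(ds, demo_f, dialect = "paired", links_file = links_f)
  back <- read_icsr_table(demo_f, dialect = "paired", links_file = links_f)
  expect_true(datasets_equal(ds, back))
})

test_that("empty dataset writes a header-only file", {
  empty_demo <- demo_row("R1")[0, ]
  empty <- icsr_dataset(empty_demo,
                        data.frame(report_id = character(),
                                   drug = character()),
                        data.frame(report_id = character(),
                                   event_pt = character()))
  f <- withr::local_tempfile(fileext = ".csv")
  write_icsr_table(empty, f)
  expect_equal(readLines(f),
               "report_id,drug,event_pt,continent,age_group,sex,serious,notifier")
})

test_that("fields containing commas and quotes survive the CSV round trip", {
  ds <- make_dataset(list(
    list(drugs = "drug, combination", events = c('PT with "quotes"',
                                                 "Poisoning, accidental"))
  ))
  f <- withr::local_tempfile(fileext = ".csv")
  write_icsr_table(ds, f)
  back <- read_icsr_table(f)
  expect_true(datasets_equal(ds, back))
  expect_setequal(back$events$event_pt,
                  c('PT with "quotes"', "Poisoning, accidental"))
})

test_that("reports need at least one drug and one event", {
  expect_error(
    icsr_dataset(demo_row("R1"),
                 data.frame(report_id = "R1", drug = "a"),
                 data.frame(report_id = character(),
                            event_pt = character())),
    class = "pv_integrity_error")
})

test_that("dictionary enforces one primary SOC per PT, case-insensitive fallback", {
  d <- meddra_dictionary(data.frame(
    pt = c("Ear pain", "Ear pain", "Rash"),
    primary_soc = c("Ear and labyrinth disorders",
                    "Ear and labyrinth disorders",
                    "Skin and subcutaneous tissue disorders")))
  expect_equal(pt_soc(d, "Ear pain"), "Ear and labyrinth disorders")
  expect_equal(pt_soc(d, "EAR PAIN"), "Ear and labyrinth disorders")
  expect_true(is.na(pt_soc(d, "Vertigo")))

  expect_error(
    meddra_dictionary(data.frame(
      pt = c("Ear pain", "Ear pain"),
      primary_soc = c("Ear and labyrinth disorders", "Nervous system disorders"))),
    class = "pv_integrity_error")
})

test_that("unmapped event terms are collected, never dropped", {
  dict <- meddra_dictionary(data.frame(pt = "Rash",
                                       primary_soc = "Skin disorders"))
  ds <- make_dataset(list(list(drugs = "a", events = c("Rash", "Mystery PT"))),
                     dictionary = dict)
  expect_equal(unmapped_pts(ds), "Mystery PT")
  expect_equal(nrow(ds$events), 2L)
})
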