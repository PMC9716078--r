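write_lines_tbl <- function(dir, name, header, rows) {
  writeLines(c(header, rows), file.path(dir, paste0(name, ".txt")))
}

minimal_quarter <- function(dir, demo_rows) {
  write_lines_tbl(dir, "DEMO",
                  "primaryid$caseid$caseversion$event_dt$rept_dt$age$age_cod$sex$wt$wt_cod$occp_cod$reporter_country",
                  demo_rows)
  write_lines_tbl(dir, "DRUG", "primaryid$drug_seq$role_cod$drugname$indi_pt",
                  "1001$1$PS$CANAGLIFLOZIN$Type 2 diabetes mellitus")
  write_lines_tbl(dir, "REAC", "primaryid$pt", "1001$Acute pancreatitis")
}

test_that("age unit codes convert into years", {
  dir <- withr::local_tempdir()
  minimal_quarter(dir, c(
    "1001$1$1$20150624$20150701$5.5$DEC$M$$$MD$US",
    "1002$2$1$201506$2015$660$MON$F$$$CN$CA",
    "1003$3$1$2015$20150701$500$YR$M$$$XX$GB"
  ))
  suppressMessages(r <- parse_quarter(dir))
  expect_equal(r$demo$age_years[1], 55)
  expect_equal(r$demo$age_years[2], 55)
  expect_true(is.na(r$demo$age_years[3])) # 500 years -> out of range
  expect_equal(r$demo$reporter, c("physician", "consumer", "unknown"))
})

test_that("partial dates carry their precision", {
  dir <- withr::local_tempdir()
  minimal_quarter(dir, c(
    "1001$1$1$20150624$20150701$55$YR$M$$$MD$US",
    "1002$2$1$201506$2015$55$YR$F$$$MD$US"
  ))
  suppressMessages(r <- parse_quarter(dir))
  expect_equal(r$demo$event_date, as.Date(c("2015-06-24", "2015-06-01")))
  expect_equal(r$demo$event_date_precision, c("day", "month"))
  expect_equal(r$demo$report_date_precision, c("day", "year"))
})

test_that("missing mandatory tables raise an I/O error", {
  dir <- withr::local_tempdir()
  write_lines_tbl(dir, "DEMO",
                  "primaryid$caseid$caseversion$event_dt$rept_dt$age$age_cod$sex$wt$wt_cod$occp_cod$reporter_country",
                  "1001$1$1$20150624$20150701$55$YR$M$$$MD$US")
  expect_error(suppressMessages(parse_quarter(dir)),
               class = "pvsignal_io_error")
  expect_error(parse_quarter(file.path(dir, "nope")),
               class = "pvsignal_io_error")
})

test_that("malformed rows are skipped and counted", {
  dir <- withr::local_tempdir()
  minimal_quarter(dir, c(
    "1001$1$1$20150624$20150701$55$YR$M$$$MD$US",
    "$$$$$$$$$$$"
  ))
  expect_message(r <- parse_quarter(dir), "skipped 1")
  expect_equal(n_reports(r), 1)
  expect_equal(attr(r, "n_skipped"), 1L)
})

test_that("deduplication keeps the highest case version with stated tie-breaks", {
  reports <- make_reports(list(
    list(id = "A1", case = "X", version = 1,
         drugs = list(c("CANAGLIFLOZIN", "PS")), pts = "Pancreatitis"),
    list(id = "A2", case = "X", version = 2,
         drugs = list(c("CANAGLIFLOZIN", "PS")), pts = "Pancreatitis"),
    # same version: later report date wins
    list(id = "B1", case = "Y", version = 1, rept_date = "2018-01-01",
         drugs = list(c("DAPAGLIFLOZIN", "PS")), pts = "Nausea"),
    list(id = "B2", case = "Y", version = 1, rept_date = "2019-01-01",
         drugs = list(c("DAPAGLIFLOZIN", "PS")), pts = "Nausea"),
    # same version and date: lexicographically largest primary id wins
    list(id = "C1", case = "Z", version = 1,
         drugs = list(c("EMPAGLIFLOZIN", "PS")), pts = "Nausea"),
    list(id = "C2", case = "Z", version = 1,
         drugs = list(c("EMPAGLIFLOZIN", "PS")), pts = "Nausea")
  ))
  d <- deduplicate(reports)
  expect_setequal(d$demo$primary_id, c("A2", "B2", "C2"))
  # idempotent
  expect_identical(deduplicate(d)$demo, d$demo)
  # already-unique set unchanged
  u <- filter_ok <- deduplicate(d)
  expect_equal(n_reports(u), 3)
})

test_that("many-versioned cases collapse to one record each", {
  specs <- purrr::flatten(purrr::map(1:10, function(i) {
    purrr::map(1:3, function(v) {
      list(id = sprintf("%02d-%d", i, v), case = sprintf("case%02d", i),
           version = v, drugs = list(c("CANAGLIFLOZIN", "PS")),
           pts = "Nausea")
    })
  }))
  d <- deduplicate(make_reports(specs))
  expect_equal(n_reports(d), 10)
  expect_true(all(d$demo$case_version == 3))
})

test_that("cohort extraction applies role, matching, and exclusion rules", {
  reports <- make_reports(list(
    list(id = "1", drugs = list(c("ACUTE MED CANAGLIFLOZIN", "PS")),
         pts = "ACUTE PANCREATITIS"),                  # cased PT variant
    list(id = "2", drugs = list(c("Invokana", "SS")), pts = "Nausea"),
    list(id = "3", drugs = list(c("canagliflozin", "C")),
         pts = "Pancreatitis"),                        # concomitant only
    list(id = "4", drugs = list(c("ASPIRIN", "PS")), pts = "Pancreatitis"),
    list(id = "5", sex = NA, drugs = list(c("JARDIANCE", "PS")),
         pts = "Nausea"),
    list(id = "6", age = NA, drugs = list(c("FARXIGA", "PS")),
         pts = "Nausea"),
    list(id = "7", drugs = list(c("CANAGLIFLOZIN", "PS"),
                                c("DAPAGLIFLOZIN", "SS")),
         pts = "Pancreatitis")                          # two distinct SGLT-2i
  ))
  cohort <- extract_cohort(reports)
  expect_setequal(cohort$primary_id, c("1", "2", "5", "6", "7"))
  expect_true(cohort$ap[cohort$primary_id == "1"])
  expect_false(cohort$ap[cohort$primary_id == "2"])

  strict <- extract_cohort(reports, require_demographics = TRUE,
                           drop_multi_sglt2i = TRUE)
  expect_setequal(strict$primary_id, c("1", "2"))
  att <- attr(strict, "attrition")
  expect_equal(unname(att["dropped_demographics"]), 2)
  expect_equal(unname(att["dropped_multi_sglt2i"]), 1)
  # relaxing the role restriction admits the concomitant-only report
  relaxed <- extract_cohort(reports, roles = c("PS", "SS", "C", "I"))
  expect_true("3" %in% relaxed$primary_id)
})

test_that("cohort extraction is order-independent", {
  sim <- simulate_reports(sim_config(n_reports = 2000,
                                     target_prevalence = 0.2, seed = 31))
  r <- sim$reports
  perm <- withr::with_seed(1, sample.int(nrow(r$demo)))
  shuffled <- faers_reports(r$demo[perm, ], r$drug, r$reac, r$outc, r$ther)
  c1 <- extract_cohort(r)
  c2 <- extract_cohort(shuffled)
  expect_equal(as.data.frame(c1), as.data.frame(c2), ignore_attr = TRUE)
})

test_that("co-medication and heart-failure flags come from drug rows", {
  reports <- make_reports(list(
    list(id = "1", drugs = list(c("CANAGLIFLOZIN", "PS", "Cardiac failure"),
                                c("ATORVASTATIN", "C"),
                                c("LIRAGLUTIDE", "C")),
         pts = "Acute pancreatitis"),
    list(id = "2", drugs = list(c("JARDIANCE", "PS",
                                  "Type 2 diabetes mellitus")),
         pts = "Nausea")
  ))
  cohort <- extract_cohort(reports)
  r1 <- cohort[cohort$primary_id == "1", ]
  expect_true(r1$statin & r1$glp1ra & r1$heart_failure)
  expect_false(r1$dpp4i)
  r2 <- cohort[cohort$primary_id == "2", ]
  expect_false(r2$statin | r2$heart_failure)
  expect_equal(r2$sglt2i, "empagliflozin")
})

test_that("cohort summary pools counts and means as count-weighted values", {
  specs <- purrr::flatten(purrr::map(1:8, function(i) {
    list(list(id = paste0("c", i), sex = if (i <= 5) "M" else "F",
              age = 40 + i,
              drugs = list(c("CANAGLIFLOZIN", "PS")), pts = "Pancreatitis"),
         list(id = paste0("d", i), sex = if (i <= 2) "M" else "F",
              age = 60 + i,
              drugs = list(c("FARXIGA", "PS")), pts = "Nausea"))
  }))
  cohort <- extract_cohort(make_reports(specs))
  s <- summarize_cohort(cohort)
  male <- s$counts[s$counts$characteristic == "sex" & s$counts$level == "M", ]
  expect_equal(male$n[male$drug == "pooled"], 7)
  expect_equal(male$pct[male$drug == "pooled"], round_half_up(700 / 16, 1))
  # percentages within one characteristic sum to 100 within rounding slack
  sums <- dplyr::summarise(
    dplyr::group_by(s$counts, .data$characteristic, .data$drug),
    s = sum(.data$pct), .groups = "drop"
  )
  expect_true(all(abs(sums$s - 100) <= 0.3))
  # pooled mean age is the count-weighted mean of per-drug means
  age <- s$age
  expect_equal(
    age$mean_age[age$drug == "pooled"],
    pooled_mean(age$mean_age[age$drug != "pooled"],
                age$n[age$drug != "pooled"])
  )
})

test_that("a single-stratum cohort pools to its own summary", {
  specs <- purrr::map(1:6, function(i) {
    list(id = paste0("x", i), sex = "F", age = 50 + i,
         drugs = list(c("CANAGLIFLOZIN", "PS")), pts = "Pancreatitis")
  })
  s <- summarize_cohort(extract_cohort(make_reports(specs)))
  fem <- s$counts[s$counts$characteristic == "sex", ]
  expect_equal(fem$pct[fem$drug == "pooled"],
               fem$pct[fem$drug == "canagliflozin"])
  expect_equal(s$age$mean_age[s$age$drug == "pooled"],
               s$age$mean_age[s$age$drug == "canagliflozin"])
})

test_that("rounding helpers use half-up convention", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(pooled_percent(c(1), c(3)), 33.3)
})
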