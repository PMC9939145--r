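drug_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    primaryid = vapply(rows, `[[`, "", 1), drug_seq = 1L,
    drugname = vapply(rows, `[[`, "", 2),
    prod_ai = NA_character_,
    role_cod = vapply(rows, `[[`, "", 3)
  )
}

test_that("primary-suspect brand and free-text names match; other roles never do", {
  dt <- drug_tbl(c("1", "LYNPARZA.", "PS"),
                 c("2", "NIRAPARIB", "C"),
                 c("3", "olaparib 150 mg tablets", "PS"),
                 c("4", "ZEJULA", "SS"))
  m <- match_target_drug(dt)
  expect_equal(m$drug[m$primaryid == "1"], "olaparib")
  expect_equal(m$drug[m$primaryid == "3"], "olaparib")
  expect_false("2" %in% m$primaryid)
  expect_false("4" %in% m$primaryid)
})

test_that("reports naming two target drugs as primary suspect are excluded and counted", {
  dt <- drug_tbl(c("1", "LYNPARZA", "PS"), c("1", "ZEJULA", "PS"),
                 c("2", "RUBRACA", "PS"))
  m <- match_target_drug(dt)
  expect_equal(m$primaryid, "2")
  expect_equal(attr(m, "n_ambiguous"), 1)
})

test_that("dictionary invariants reject shared or empty tokens", {
  expect_error(drug_dictionary(list(a = "X", b = c("Y", "X"))), "shared")
  expect_error(drug_dictionary(list(a = "")), "non-empty")
  d <- drug_dictionary(list(a = "lynparza  extra"))
  expect_equal(d$token, "LYNPARZA EXTRA")
})

test_that("PT/SOC mapping flags target-SOC membership via primary SOC only", {
  map <- example_pt_soc_map()
  reac <- tibble::tibble(primaryid = c("1", "1", "2", "3", "3"),
                         pt = c("Anaemia", "Nausea", "Nausea",
                                "Anaemia", "Thrombocytopenia"))
  ev <- attach_events(reac, map)
  expect_true(ev$in_target_soc[ev$primaryid == "1"])
  expect_equal(ev$soc_pts[[which(ev$primaryid == "1")]], "ANAEMIA")
  expect_false(ev$in_target_soc[ev$primaryid == "2"])
  # two haematology PTs: one report at SOC level, two entries at PT level
  expect_true(ev$in_target_soc[ev$primaryid == "3"])
  expect_length(ev$soc_pts[[which(ev$primaryid == "3")]], 2)
})

test_that("a secondary SOC link never recruits a report", {
  map <- pt_soc_map(tibble::tibble(
    pt_name = c("Weird term", "Weird term"),
    soc_name = c("Other", "Blood and lymphatic system disorders"),
    soc_code = c("99999999", SOC_BLOOD_LYMPHATIC),
    is_primary_soc = c(TRUE, FALSE)))
  ev <- attach_events(tibble::tibble(primaryid = "1", pt = "Weird term"), map)
  expect_false(ev$in_target_soc)
})

test_that("PT/SOC map invariants are enforced", {
  df <- tibble::tibble(pt_name = c("A", "A"), soc_name = c("x", "x"),
                       soc_code = c("1", "1"), is_primary_soc = c(TRUE, FALSE))
  expect_error(pt_soc_map(df), "duplicated")
  df$soc_code <- c("1", "2"); df$is_primary_soc <- c(TRUE, TRUE)
  expect_error(pt_soc_map(df), "exactly one primary")
})

test_that("indication terms group into the study categories", {
  indi <- tibble::tibble(primaryid = c("1", "2", "3"),
                         indi_pt = c("Ovarian cancer", "Prostate cancer",
                                     "BREAST CANCER STAGE II"))
  g <- classify_indication(indi, primaryids = c("1", "2", "3", "4"))
  expect_equal(g$indication_group, c("ovarian cancer", "others",
                                     "breast cancer", "missing"))
})

test_that("onset days are computed only from day-precision, ordered dates", {
  res <- compute_onset_days(c("20210101", "20210201", "202101", "20210101", ""),
                            c("20210129", "20210101", "20210301", "20210101", "20210301"))
  expect_equal(res$onset_days, c(28L, NA, NA, 0L, NA))
  expect_equal(res$onset_status, c("valid", "date_error", "inaccurate",
                                   "valid", "missing"))
})

test_that("the earliest day-precision therapy start of the target drug is used", {
  dir <- withr::local_tempdir()
  write_tiny_quarter(dir)
  # give report 101 a second olaparib therapy episode starting earlier
  ther <- file.path(dir, "THER21Q1.txt")
  writeLines(c(readLines(ther), "101$3$20201201$20210301"), ther)
  drug <- file.path(dir, "DRUG21Q1.txt")
  writeLines(c(readLines(drug), "101$3$LYNPARZA$OLAPARIB$PS"), drug)
  q <- read_faers_quarter(dir, "21Q1")
  cohort <- build_cohort(q)
  row <- cohort[cohort$primaryid == "101", ]
  expect_equal(row$start_raw, "20201201")
  expect_equal(row$onset_days, as.integer(as.Date("2021-01-10") - as.Date("2020-12-01")))
})

test_that("a built cohort carries demographics, events, outcomes and year", {
  dir <- withr::local_tempdir()
  write_tiny_quarter(dir)
  q <- read_faers_quarter(dir, "21Q1")
  cohort <- build_cohort(q)
  expect_setequal(cohort$primaryid, c("101", "201"))  # 301 has no PS target drug
  r101 <- cohort[cohort$primaryid == "101", ]
  expect_equal(r101$drug, "olaparib")
  expect_true(r101$in_target_soc)
  expect_true(r101$death)
  expect_equal(r101$indication_group, "ovarian cancer")
  expect_equal(r101$reporting_year, 2021L)
  expect_equal(r101$onset_days, 9L)
  # onset exclusions + valid onsets partition the cohort
  expect_equal(sum(cohort$onset_status == "valid") +
                 sum(cohort$onset_status != "valid"), nrow(cohort))
})
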