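mini_cohort <- function(drug, onset_days = NA_integer_, onset_status = "missing",
                        death = FALSE, outcomes = NULL) {
  n <- length(drug)
  if (is.null(outcomes)) {
    outcomes <- lapply(death, function(d) if (d) "DE" else character())
  }
  tibble::tibble(
    primaryid = as.character(seq_len(n)), drug = drug,
    onset_days = rep_len(onset_days, n), onset_status = rep_len(onset_status, n),
    death = rep_len(death, n), outcomes = outcomes,
    sex = "F", age_years = 60, indication_group = "others",
    occr_country = "US", occp_cod = "MD", reporting_year = 2021L
  )
}

test_that("onset quantiles are order statistics with linear interpolation", {
  co <- mini_cohort(rep("olaparib", 3), onset_days = c(10L, 28L, 101L),
                    onset_status = "valid")
  os <- onset_summary(co)
  row <- os$summary[os$summary$drug == "olaparib", ]
  expect_equal(row$median, 28)
  expect_equal(row$q1, (10 + 28) / 2)   # type-7 interpolation at n = 3
  expect_equal(row$q3, (28 + 101) / 2)
  expect_equal(row$n_valid, 3)
})

test_that("onset bins close at 30 and partition the non-negative days", {
  co <- mini_cohort(rep("x", 8), onset_days = c(0L, 30L, 31L, 60L, 361L, 360L, 91L, 180L),
                    onset_status = "valid")
  os <- onset_summary(co)
  b <- os$bins[os$bins$drug == "x", ]
  got <- stats::setNames(b$n, as.character(b$bin))
  expect_equal(got[["0-30"]], 2)
  expect_equal(got[["31-60"]], 2)
  expect_equal(got[["181-360"]], 1)
  expect_equal(got[[">=361"]], 1)
  expect_equal(got[["91-180"]], 2)
  expect_equal(sum(b$n), 8)  # no gaps, no overlaps
})

test_that("exclusions and valid onsets account for every report", {
  co <- mini_cohort(rep("x", 5), onset_days = c(5L, NA, NA, NA, NA),
                    onset_status = c("valid", "missing", "inaccurate",
                                     "date_error", "missing"))
  os <- onset_summary(co)
  excl <- os$exclusions[os$exclusions$drug == "x", ]
  expect_equal(sum(excl$n) + os$summary$n_valid[os$summary$drug == "x"], 5)
})

test_that("onset medians recover the generating log-normal at scale", {
  cfg <- clean_config(20000, seed = 77)
  g <- synth_generate(cfg)
  corpus <- dedup_corpus(g$quarter)
  cohort <- build_cohort(corpus, synth_dictionary(cfg), synth_pt_soc_map(cfg))
  os <- onset_summary(cohort)
  med <- os$summary$median[os$summary$drug == "niraparib"]
  target <- exp(cfg$onset_meanlog_by_drug[["niraparib"]])  # 21 days
  n_valid <- os$summary$n_valid[os$summary$drug == "niraparib"]
  expect_gt(n_valid, 50)
  # three large-sample standard errors of a log-normal sample median
  tol <- target * (exp(3 * 1.2533 * cfg$onset_sdlog / sqrt(n_valid)) - 1)
  expect_lt(abs(med - target), tol + 1)  # +1 day for the floor() discretisation
})

test_that("the rank test matches a hand computation and its degenerate contract", {
  kw <- kruskal_wallis_onset(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  # untied ranks 1..9: H = 12/(9*10) * 3*((2-5)^2 + 0 + (8-5)^2) = 7.2
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))
  # identical groups: H = 0; all values identical: contract H = 0, p = 1
  expect_equal(kruskal_wallis_onset(list(a = 1:4, b = 1:4))$statistic, 0)
  kw0 <- kruskal_wallis_onset(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  expect_error(kruskal_wallis_onset(list(a = 1:3)), "two")
})

test_that("rank-test type-I error sits near its nominal level", {
  set.seed(101)
  p <- replicate(1000, {
    g <- list(rnorm(30), rnorm(30), rnorm(30))
    stats::kruskal.test(g)$p.value
  })
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.075)
})

test_that("fatality proportions and the omnibus test reproduce hand values", {
  co <- reference_cohort()
  fa <- fatality_analysis(co)
  by <- fa$by_drug
  expect_equal(round(100 * by$proportion[by$drug == "olaparib"], 2), 16.30)
  expect_equal(round(100 * by$proportion[by$drug == "niraparib"], 2), 4.67)
  expect_equal(round(100 * by$proportion[by$drug == "rucaparib"], 2), 3.79)
  expect_equal(round(100 * by$proportion[by$drug == "talazoparib"], 2), 15.89)
  expect_equal(fa$method, "chi-squared")
  expect_lt(fa$p_value, 0.001)
  # chi-squared equals the observed-minus-expected oracle on the 4x2 table
  tab <- cbind(by$n_deaths, by$n_reports - by$n_deaths)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(fa$statistic, sum((tab - e)^2 / e))
})

test_that("small tables fall back to Fisher and match hypergeometric enumeration", {
  co <- mini_cohort(rep(c("a", "b"), each = 10),
                    death = c(rep(TRUE, 3), rep(FALSE, 7), TRUE, rep(FALSE, 9)))
  fa <- fatality_analysis(co)
  expect_equal(fa$method, "fisher")
  # full enumeration: sum the probabilities of all tables no more likely
  # than the observed one, margins fixed (deaths = 4, groups 10/10)
  probs <- stats::dhyper(0:4, 10, 10, 4)
  obs <- stats::dhyper(3, 10, 10, 4)
  p_oracle <- sum(probs[probs <= obs * (1 + 1e-7)])
  expect_equal(fa$p_value, p_oracle)
})

test_that("degenerate fatality inputs are flagged, not tested", {
  co <- mini_cohort(rep(c("a", "b"), each = 5), death = FALSE)
  fa <- fatality_analysis(co)
  expect_equal(fa$method, "degenerate")
  expect_true(all(fa$by_drug$proportion == 0))
})

test_that("the descriptive table reproduces published-style marginals", {
  co <- reference_cohort()
  dt <- descriptive_table(co)
  g <- function(section, category) dt[dt$section == section & dt$category == category, ]
  expect_equal(g("gender", "Female")$n, 3367)
  expect_equal(g("gender", "Female")$pct, 82.36)
  expect_equal(g("indication", "Ovarian cancer")$pct, 67.98)
  expect_equal(g("serious_outcome", "Hospitalization")$pct, 28.82)
  expect_equal(g("country", "US")$n, 2647)
  expect_equal(g("reporter", "Consumer")$n, 1664)
  expect_equal(g("year", "2020")$n, 1013)
  expect_equal(g("onset", "0-30")$n, 934)
})

test_that("multi-select outcomes count a report once per category", {
  co <- mini_cohort("x", death = TRUE, outcomes = list(c("DE", "HO")))
  dt <- descriptive_table(co)
  expect_equal(dt$n[dt$section == "serious_outcome" & dt$category == "Death"], 1L)
  expect_equal(dt$n[dt$section == "serious_outcome" & dt$category == "Hospitalization"], 1L)
})

test_that("an empty cohort yields an all-zero descriptive table", {
  co <- mini_cohort(character())
  dt <- descriptive_table(co)
  expect_true(all(dt$n == 0))
})
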