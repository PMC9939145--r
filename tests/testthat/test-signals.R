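random_tables <- function(n, seed, max_cell = 50) {
  set.seed(seed)
  tibble::tibble(a = sample.int(max_cell, n, TRUE), b = sample.int(max_cell, n, TRUE),
                 c = sample.int(max_cell, n, TRUE), d = sample.int(max_cell, n, TRUE))
}

test_that("contingency cells follow from the marginal report counts", {
  tb <- contingency_table(2, 5, 3, 10)
  expect_equal(unlist(tb), c(a = 2, b = 3, c = 1, d = 4))
  expect_error(contingency_table(5, 4, 6, 100), "negative")
})

test_that("the reporting odds ratio and its Woolf interval match closed forms", {
  s <- disproportionality(10, 10, 10, 10)
  expect_equal(s$ror, 1)
  expect_equal(s$ror_lo95, exp(-1.96 * sqrt(0.4)))
  expect_equal(s$ror_hi95, exp(1.96 * sqrt(0.4)))
  expect_equal(round(s$ror_lo95, 2), 0.29)
  expect_equal(round(s$ror_hi95, 2), 3.45)
  # independence: ad = bc gives exactly 1 everywhere, IC exactly 0
  s <- disproportionality(2, 4, 3, 6)
  expect_equal(s$ror, 1); expect_equal(s$prr, 1)
  expect_equal(s$ebgm, 1); expect_equal(s$ic, 0)
})

test_that("PRR and chi-squared behave on proportional and flat tables", {
  s <- disproportionality(1, 9, 10, 90)
  expect_equal(s$prr, 1); expect_equal(s$chi2, 0)
  expect_equal(disproportionality(10, 10, 10, 10)$chi2, 0)
})

test_that("chi-squared equals the observed-minus-expected oracle and chisq.test", {
  tb <- random_tables(300, seed = 21)
  s <- disproportionality(tb$a, tb$b, tb$c, tb$d)
  oracle <- vapply(seq_len(nrow(tb)), function(i) {
    m <- matrix(c(tb$a[i], tb$b[i], tb$c[i], tb$d[i]), 2, byrow = TRUE)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }, numeric(1))
  expect_equal(s$chi2, oracle, tolerance = 1e-9)
  i <- 17
  m <- matrix(c(tb$a[i], tb$b[i], tb$c[i], tb$d[i]), 2, byrow = TRUE)
  expect_equal(s$chi2[i],
               unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic))
})

test_that("IC is identically log2(EBGM) and bounds share the log-normal error", {
  tb <- random_tables(500, seed = 8)
  s <- disproportionality(tb$a, tb$b, tb$c, tb$d)
  expect_equal(s$ic, log2(s$ebgm))
  expect_equal(s$ic025, log2(s$ebgm05))
})

test_that("any zero cell flags the pair undefined and it fails every rule", {
  s <- disproportionality(0, 10, 5, 100)
  expect_false(s$defined)
  expect_true(is.na(s$ror))
  cl <- classify_signal(s)
  expect_false(cl$signal)
  expect_false(cl$ror_rule | cl$ic_rule | cl$ebgm_rule)
  # a drug with no reports at all: zero margin, chi2 also undefined
  s0 <- disproportionality(0, 0, 5, 100)
  expect_true(is.na(s0$chi2))
})

test_that("ordering law: ad > bc if and only if ROR > PRR > EBGM > 1", {
  tb <- random_tables(2000, seed = 33)
  s <- disproportionality(tb$a, tb$b, tb$c, tb$d)
  over <- tb$a * tb$d > tb$b * tb$c
  under <- tb$a * tb$d < tb$b * tb$c
  expect_true(all((s$ror > s$prr & s$prr > s$ebgm & s$ebgm > 1)[over]))
  expect_true(all((s$ror < s$prr & s$prr < s$ebgm & s$ebgm < 1)[under]))
  eq <- !over & !under
  expect_equal(s$ror[eq], rep(1, sum(eq)))
  expect_equal(s$ebgm[eq], rep(1, sum(eq)))
})

test_that("ROR and PRR rules are monotone in the co-report count", {
  tb <- random_tables(300, seed = 55, max_cell = 30)
  s1 <- classify_signal(disproportionality(tb$a, tb$b, tb$c, tb$d))
  s2 <- classify_signal(disproportionality(tb$a + 5, tb$b, tb$c, tb$d))
  expect_false(any(s1$ror_rule & !s2$ror_rule))
  expect_false(any(s1$prr_rule & !s2$prr_rule))
  # the shrinkage-style observed/expected measure is NOT monotone: its
  # expectation grows with a, so EBGM tends to 1 as a dominates the margins
  eb <- function(a) disproportionality(a, 1, 1, 100)$ebgm
  expect_gt(eb(3), 2)
  expect_lt(eb(1000), 2)
})

test_that("published-style statistics classify under the default thresholds", {
  stats <- reference_signal_stats()
  cl <- classify_signal(stats)
  expect_true(all(cl$signal))
  # a failing IC bound alone vetoes the joint rule
  one <- stats[1, ]
  one$ic025 <- -0.1
  expect_false(classify_signal(one)$signal)
})

test_that("an implanted pair dominates its drug's PT ranking in a scan", {
  cfg <- clean_config(20000, seed = 19,
                      association = tibble::tibble(drug = "olaparib",
                                                   pt = "ANAEMIA", rr = 10))
  g <- synth_generate(cfg)
  corpus <- dedup_corpus(g$quarter)
  cohort <- build_cohort(corpus, synth_dictionary(cfg), synth_pt_soc_map(cfg))
  scan <- signal_scan(corpus, cohort, synth_pt_soc_map(cfg))
  ola <- scan[scan$drug == "olaparib" & scan$level == "pt", ]
  expect_equal(ola$event[which.max(ola$ror)], "ANAEMIA")
  expect_true(ola$signal[ola$event == "ANAEMIA"])
  # scan tables agree exactly with the generator's bookkeeping
  tr <- g$truth$drug_pt
  for (i in seq_len(nrow(ola))) {
    t1 <- tr[tr$drug == "olaparib" & tr$pt == ola$event[i], ]
    expect_equal(unname(unlist(ola[i, c("a", "b", "c", "d")])),
                 unname(unlist(t1[, c("a", "b", "c", "d")])))
  }
})

test_that("an empty PT universe yields an empty PT-level scan", {
  cfg <- clean_config(500, seed = 4)
  g <- synth_generate(cfg)
  corpus <- dedup_corpus(g$quarter)
  # a map whose SOC codes never match the target SOC
  ec <- cfg$event_catalog
  map <- pt_soc_map(tibble::tibble(pt_name = ec$pt, soc_name = "Other",
                                   soc_code = "00000000", is_primary_soc = TRUE))
  cohort <- build_cohort(corpus, synth_dictionary(cfg), map)
  scan <- signal_scan(corpus, cohort, map, level = "pt")
  expect_equal(nrow(scan), 0)
})
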