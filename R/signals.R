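#' Build a 2x2 contingency table from marginal report counts
#'
#' The counting unit is the distinct report: `a` reports carry both the
#' target drug (as primary suspect) and the target event, `b` the drug
#' without the event, `c` the event under any other drug, `d` the
#' remainder of the corpus.
#'
#' @param n_drug_event distinct reports with drug and event (`a`).
#' @param n_drug total distinct reports with the drug (`a + b`).
#' @param n_event total distinct reports with the event (`a + c`).
#' @param n_total total distinct reports in the corpus (`N`).
#' @return tibble with integer columns `a`, `b`, `c`, `d` (vectorised).
#' @examples
#' contingency_table(2, 5, 3, 10)  # a=2 b=3 c=1 d=4
#' @export
contingency_table <- function(n_drug_event, n_drug, n_event, n_total) {
  a <- n_drug_event
  b <- n_drug - a
  cc <- n_event - a
  d <- n_total - a - b - cc
  if (any(c(a, b, cc, d) < 0, na.rm = TRUE)) {
    stop("inconsistent marginals: negative contingency cell")
  }
  tibble(a = a, b = b, c = cc, d = d)
}

#' Disproportionality statistics for 2x2 report tables
#'
#' Computes, per table, the reporting odds ratio with Woolf 95% confidence
#' interval, the proportional reporting ratio with the Pearson chi-squared
#' statistic of the 2x2 table, and observed/expected measures in their
#' widely used simplified closed forms: `EBGM = aN / ((a+b)(a+c))` and
#' `IC = log2(EBGM)`. Lower bounds for EBGM and IC use the same log-normal
#' error as the ROR interval, `exp(ln EBGM - z * se)` with
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`, so `ic025 = log2(ebgm05)` holds
#' identically. Under independence (`ad = bc`) all three ratios are 1 and
#' IC is 0.
#'
#' Any zero cell leaves the ratio statistics undefined (`NA`, flagged in
#' `defined`); no continuity correction is applied. The chi-squared
#' statistic is computed without Yates correction unless `yates = TRUE`.
#'
#' @param a,b,c,d vectors of cell counts (recycled to a common length).
#' @param z normal quantile for all lower/upper bounds (default 1.96).
#' @param yates apply the Yates continuity correction to chi-squared.
#' @return tibble with columns `n` (= `a`), `ror`, `ror_lo95`, `ror_hi95`,
#'   `prr`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05`, `defined`.
#' @examples
#' disproportionality(10, 10, 10, 10)          # all ratios 1
#' disproportionality(606, 744, 48648, 884002) # a strong signal
#' @export
disproportionality <- function(a, b, c, d, z = 1.96, yates = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- as.numeric(rep_len(a, n)); b <- as.numeric(rep_len(b, n))
  cc <- as.numeric(rep_len(c, n)); d <- as.numeric(rep_len(d, n))
  N <- a + b + cc + d
  defined <- a > 0 & b > 0 & cc > 0 & d > 0

  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ror <- (a * d) / (b * cc)
  prr <- (a / (a + b)) / (cc / (cc + d))
  ebgm <- a * N / ((a + b) * (a + cc))
  ebgm05 <- exp(log(ebgm) - z * se)

  dev <- abs(a * d - b * cc)
  if (yates) dev <- pmax(dev - N / 2, 0)
  chi2 <- N * dev^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))

  out <- tibble(
    n = a,
    ror = ror,
    ror_lo95 = exp(log(ror) - z * se),
    ror_hi95 = exp(log(ror) + z * se),
    prr = prr,
    chi2 = chi2,
    ic = log2(ebgm),
    ic025 = log2(ebgm05),
    ebgm = ebgm,
    ebgm05 = ebgm05,
    defined = defined
  )
  ratio_cols <- c("ror", "ror_lo95", "ror_hi95", "prr", "ic", "ic025", "ebgm", "ebgm05")
  out[!defined, ratio_cols] <- NA_real_
  # chi2 is well defined whenever all margins are positive
  chi_ok <- (a + b) > 0 & (cc + d) > 0 & (a + cc) > 0 & (b + d) > 0
  out$chi2[!chi_ok] <- NA_real_
  out
}

#' Threshold set for the joint four-criteria signal rule
#'
#' Defaults are the field-standard criteria: ROR 95% lower bound > 1 with
#' at least `min_a` co-reports; PRR >= 2 with chi-squared >= 4 and at least
#' `min_a` co-reports; IC lower bound > 0; EBGM lower bound > 2. A pair is
#' a signal only when all four hold simultaneously.
#'
#' @param min_a minimum co-report count for the ROR and PRR rules.
#' @param ror_lo_min,prr_min,chi2_min,ic025_min,ebgm05_min rule cut-offs.
#' @param z normal quantile used for interval bounds.
#' @return a named list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(min_a = 3, ror_lo_min = 1, prr_min = 2,
                              chi2_min = 4, ic025_min = 0, ebgm05_min = 2,
                              z = 1.96) {
  structure(list(min_a = min_a, ror_lo_min = ror_lo_min, prr_min = prr_min,
                 chi2_min = chi2_min, ic025_min = ic025_min,
                 ebgm05_min = ebgm05_min, z = z),
            class = "signal_thresholds")
}

#' Classify drug-event statistics against the joint signal rule
#'
#' Evaluates the four per-algorithm rules and their conjunction. Undefined
#' statistics (`NA`) fail their rule. Works on any data frame carrying the
#' statistic columns of [disproportionality()] (`n`, `ror_lo95`, `prr`,
#' `chi2`, `ic025`, `ebgm05`), e.g. a table of published statistics.
#'
#' @param stats data frame of statistics.
#' @param thresholds a [signal_thresholds()].
#' @return `stats` with added logical columns `ror_rule`, `prr_rule`,
#'   `ic_rule`, `ebgm_rule`, `signal`.
#' @export
classify_signal <- function(stats, thresholds = signal_thresholds()) {
  f <- function(x) !is.na(x) & x
  stats$ror_rule <- f(stats$ror_lo95 > thresholds$ror_lo_min & stats$n >= thresholds$min_a)
  stats$prr_rule <- f(stats$prr >= thresholds$prr_min & stats$chi2 >= thresholds$chi2_min &
                        stats$n >= thresholds$min_a)
  stats$ic_rule <- f(stats$ic025 > thresholds$ic025_min)
  stats$ebgm_rule <- f(stats$ebgm05 > thresholds$ebgm05_min)
  stats$signal <- stats$ror_rule & stats$prr_rule & stats$ic_rule & stats$ebgm_rule
  stats
}

# distinct-report event counts over the whole corpus
.corpus_event_counts <- function(reac) {
  reac2 <- tibble(primaryid = reac$primaryid, pt = normalize_term(reac$pt))
  reac2 <- reac2[nzchar(reac2$pt), , drop = FALSE] |> dplyr::distinct()
  list(
    pt_counts = reac2 |> dplyr::count(.data$pt, name = "n_event"),
    report_pts = reac2
  )
}

#' Scan a corpus for drug-event signals at PT and SOC level
#'
#' Builds one 2x2 table per (target drug, preferred term) pair — restricted
#' to PTs whose primary SOC is the target SOC and which co-occur with the
#' drug at least once — and per (target drug, target SOC), plus combined
#' rows pooling all target drugs. Background counts (`c`, `d`) come from
#' the full deduplicated corpus, so other target drugs sit in the
#' comparator of each per-drug row. Rows are ordered by drug, then
#' descending co-report count, then descending ROR, then PT name.
#'
#' @param quarter a deduplicated `faers_quarter` (the whole corpus).
#' @param cohort output of [build_cohort()] on the same corpus.
#' @param map a [pt_soc_map()].
#' @param target_soc_code SOC defining the event universe.
#' @param thresholds a [signal_thresholds()].
#' @param level `"pt"`, `"soc"`, or both.
#' @param include_combined add pooled all-target-drugs rows.
#' @return tibble: `drug`, `level`, `event`, the four cells, all statistics
#'   of [disproportionality()], the per-rule verdicts and `signal`.
#' @export
signal_scan <- function(quarter, cohort, map = example_pt_soc_map(),
                        target_soc_code = SOC_BLOOD_LYMPHATIC,
                        thresholds = signal_thresholds(),
                        level = c("pt", "soc"), include_combined = TRUE) {
  level <- match.arg(level, several.ok = TRUE)
  n_total <- nrow(quarter$demo)
  ev <- .corpus_event_counts(quarter$reac)
  primary <- map[map$is_primary_soc, , drop = FALSE]
  target_pts <- primary$pt_name[primary$soc_code == as.character(target_soc_code)]

  drug_totals <- cohort |> dplyr::count(.data$drug, name = "n_drug")
  drugs <- sort(unique(cohort$drug))
  rows <- list()

  if ("pt" %in% level) {
    drug_pt <- cohort |>
      dplyr::select("primaryid", "drug", "soc_pts") |>
      tidyr::unnest_longer("soc_pts", values_to = "pt") |>
      dplyr::distinct(.data$primaryid, .data$drug, .data$pt) |>
      dplyr::count(.data$drug, .data$pt, name = "n_drug_event")
    if (nrow(drug_pt) > 0) {
      drug_pt <- drug_pt |>
        dplyr::left_join(drug_totals, by = "drug") |>
        dplyr::left_join(ev$pt_counts, by = "pt")
      tb <- contingency_table(drug_pt$n_drug_event, drug_pt$n_drug,
                              drug_pt$n_event, n_total)
      rows$pt <- dplyr::bind_cols(
        tibble(drug = drug_pt$drug, level = "pt", event = drug_pt$pt), tb,
        disproportionality(tb$a, tb$b, tb$c, tb$d, z = thresholds$z))
    }
    if (include_combined && nrow(drug_pt) > 0) {
      all_pt <- cohort |>
        dplyr::select("primaryid", "soc_pts") |>
        tidyr::unnest_longer("soc_pts", values_to = "pt") |>
        dplyr::distinct(.data$primaryid, .data$pt) |>
        dplyr::count(.data$pt, name = "n_drug_event") |>
        dplyr::left_join(ev$pt_counts, by = "pt")
      tb <- contingency_table(all_pt$n_drug_event, nrow(cohort), all_pt$n_event, n_total)
      rows$pt_all <- dplyr::bind_cols(
        tibble(drug = "all", level = "pt", event = all_pt$pt), tb,
        disproportionality(tb$a, tb$b, tb$c, tb$d, z = thresholds$z))
    }
  }

  if ("soc" %in% level) {
    soc_reports <- unique(ev$report_pts$primaryid[ev$report_pts$pt %in% target_pts])
    n_event_soc <- length(soc_reports)
    per_drug <- cohort |>
      dplyr::group_by(.data$drug) |>
      dplyr::summarise(n_drug_event = sum(.data$in_target_soc),
                       n_drug = dplyr::n(), .groups = "drop")
    if (include_combined) {
      per_drug <- dplyr::bind_rows(
        per_drug,
        tibble(drug = "all", n_drug_event = sum(cohort$in_target_soc),
               n_drug = nrow(cohort)))
    }
    tb <- contingency_table(per_drug$n_drug_event, per_drug$n_drug, n_event_soc, n_total)
    rows$soc <- dplyr::bind_cols(
      tibble(drug = per_drug$drug, level = "soc",
             event = as.character(target_soc_code)), tb,
      disproportionality(tb$a, tb$b, tb$c, tb$d, z = thresholds$z))
  }

  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(classify_signal(
      dplyr::bind_cols(tibble(drug = character(), level = character(), event = character()),
                       contingency_table(integer(), integer(), integer(), integer())[0, ],
                       disproportionality(numeric(), numeric(), numeric(), numeric())[0, ]),
      thresholds))
  }
  out <- classify_signal(out, thresholds)
  out$drug <- factor(out$drug, levels = c(drugs, "all"))
  out <- out |>
    dplyr::arrange(.data$drug, .data$level,
                   dplyr::desc(.data$n), dplyr::desc(.data$ror), .data$event) |>
    dplyr::mutate(drug = as.character(.data$drug))
  out
}
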