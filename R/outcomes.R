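ONSET_BIN_BREAKS <- c(0, 30, 60, 90, 180, 360, Inf)
ONSET_BIN_LABELS <- c("0-30", "31-60", "61-90", "91-180", "181-360", ">=361")

.onset_bin <- function(days) {
  cut(days, breaks = c(-0.5, 30.5, 60.5, 90.5, 180.5, 360.5, Inf),
      labels = ONSET_BIN_LABELS)
}

#' Summarise time-to-onset per drug
#'
#' Medians and quartiles (linear interpolation, the default sample
#' quantile) of valid onset intervals, the standard day bins
#' 0-30 / 31-60 / 61-90 / 91-180 / 181-360 / >=361 (the last bin is closed
#' below at 361 so the bins partition the non-negative integers), and the
#' exclusion tally by reason. An `"all"` row pools every drug.
#'
#' @param cohort a [build_cohort()] table (or any tibble with `drug`,
#'   `onset_days`, `onset_status`).
#' @return list with tibbles `summary` (`drug`, `n_valid`, `median`, `q1`,
#'   `q3`), `bins` (`drug`, `bin`, `n`), and `exclusions` (`drug`,
#'   `onset_status`, `n`).
#' @export
onset_summary <- function(cohort) {
  groups <- dplyr::bind_rows(cohort, dplyr::mutate(cohort, drug = "all"))
  valid <- groups[groups$onset_status == "valid", , drop = FALSE]
  summary <- groups |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      n_valid = sum(.data$onset_status == "valid"),
      median = if (n_valid > 0) stats::median(.data$onset_days[.data$onset_status == "valid"]) else NA_real_,
      q1 = if (n_valid > 0) unname(stats::quantile(.data$onset_days[.data$onset_status == "valid"], 0.25)) else NA_real_,
      q3 = if (n_valid > 0) unname(stats::quantile(.data$onset_days[.data$onset_status == "valid"], 0.75)) else NA_real_,
      .groups = "drop"
    )
  bins <- valid |>
    dplyr::mutate(bin = .onset_bin(.data$onset_days)) |>
    dplyr::count(.data$drug, .data$bin, .drop = FALSE, name = "n") |>
    dplyr::filter(!is.na(.data$bin))
  exclusions <- groups |>
    dplyr::filter(.data$onset_status != "valid") |>
    dplyr::count(.data$drug, .data$onset_status, name = "n")
  list(summary = summary, bins = bins, exclusions = exclusions)
}

#' Kruskal-Wallis comparison of onset across drugs
#'
#' Rank test (tie-corrected H, chi-squared reference with k-1 degrees of
#' freedom) on valid onset intervals grouped by drug, via
#' [stats::kruskal.test()]. When every observation is identical the test is
#' degenerate and the contract `H = 0`, `p = 1` applies.
#'
#' @param onsets_by_drug named list of numeric vectors, or a cohort tibble
#'   (valid onsets grouped by `drug`).
#' @return list with `statistic` (H), `df`, `p_value`, `n` per group.
#' @export
kruskal_wallis_onset <- function(onsets_by_drug) {
  if (is.data.frame(onsets_by_drug)) {
    valid <- onsets_by_drug[onsets_by_drug$onset_status == "valid", , drop = FALSE]
    onsets_by_drug <- split(valid$onset_days, valid$drug)
  }
  onsets_by_drug <- onsets_by_drug[lengths(onsets_by_drug) > 0]
  if (length(onsets_by_drug) < 2) {
    stop("kruskal_wallis_onset needs at least two non-empty groups")
  }
  x <- unlist(onsets_by_drug, use.names = FALSE)
  if (length(unique(x)) == 1) {
    return(list(statistic = 0, df = length(onsets_by_drug) - 1L, p_value = 1,
                n = lengths(onsets_by_drug)))
  }
  kt <- stats::kruskal.test(onsets_by_drug)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = lengths(onsets_by_drug))
}

#' Fatality proportions per drug with an omnibus test
#'
#' Death means outcome code `DE` on the report. Per-drug proportions are
#' deaths over all reports for that drug; the omnibus comparison across
#' drugs uses Pearson's chi-squared on the drugs x (death, non-death)
#' table, switching to Fisher's exact test when any expected cell is below
#' 5 (with a simulated p-value, fixed seed, if exact enumeration is
#' infeasible).
#'
#' @param cohort a [build_cohort()] table (needs `drug` and `death`).
#' @param seed seed for a simulated Fisher p-value, if needed.
#' @return list with `by_drug` (tibble `drug`, `n_reports`, `n_deaths`,
#'   `proportion`), `overall` (the pooled row), `method`, `statistic`
#'   (chi-squared only), `p_value`.
#' @export
fatality_analysis <- function(cohort, seed = 1L) {
  by_drug <- cohort |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(n_reports = dplyr::n(), n_deaths = sum(.data$death),
                     .groups = "drop") |>
    dplyr::mutate(proportion = .data$n_deaths / .data$n_reports)
  overall <- tibble(drug = "all", n_reports = nrow(cohort),
                    n_deaths = sum(cohort$death),
                    proportion = sum(cohort$death) / max(nrow(cohort), 1))
  if (nrow(by_drug) < 2 || sum(by_drug$n_deaths) == 0 ||
      all(by_drug$n_deaths == by_drug$n_reports)) {
    return(list(by_drug = by_drug, overall = overall,
                method = "degenerate", statistic = NA_real_, p_value = NA_real_))
  }
  tab <- cbind(deaths = by_drug$n_deaths,
               survived = by_drug$n_reports - by_drug$n_deaths)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- tryCatch(stats::fisher.test(tab)$p.value, error = function(e) {
      withr_seed <- seed
      set.seed(withr_seed)
      stats::fisher.test(tab, simulate.p.value = TRUE, B = 10000)$p.value
    })
    return(list(by_drug = by_drug, overall = overall, method = "fisher",
                statistic = NA_real_, p_value = p))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(by_drug = by_drug, overall = overall, method = "chi-squared",
       statistic = unname(ct$statistic), p_value = ct$p.value)
}

.OUTCOME_LABELS <- c(DE = "Death", LT = "Life-threatening", HO = "Hospitalization",
                     DS = "Disability", CA = "Others", RI = "Others", OT = "Others")

.REPORTER_LABELS <- c(MD = "Physician", PH = "Pharmacist",
                      OT = "Other health-professional",
                      HP = "Other health-professional", CN = "Consumer")

#' Clinical-characteristics summary of a cohort
#'
#' Counts and percentages (denominator = total reports in the cohort) for
#' gender, age bands (<18, 18-65, >65, missing), drug, onset bins,
#' indication groups, serious outcomes (multi-select: a report with both a
#' death and a hospitalization outcome counts under both, so outcome
#' percentages can exceed 100 in total), the five most-reported countries,
#' reporter category, and reporting year.
#'
#' @param cohort a [build_cohort()] table.
#' @return tibble with columns `section`, `category`, `n`, `pct`.
#' @export
descriptive_table <- function(cohort) {
  n_total <- nrow(cohort)
  pct <- function(n) if (n_total > 0) round(100 * n / n_total, 2) else 0
  row <- function(section, category, n) tibble(section = section,
                                               category = category,
                                               n = as.integer(n), pct = pct(n))
  out <- list()

  sex <- ifelse(is.na(cohort$sex) | cohort$sex == "UNK", "Unknown or missing",
                ifelse(cohort$sex == "F", "Female", "Male"))
  out$sex <- dplyr::bind_rows(lapply(c("Female", "Male", "Unknown or missing"),
                                     function(k) row("gender", k, sum(sex == k))))

  age <- cohort$age_years
  band <- ifelse(is.na(age), "Unknown or missing",
                 ifelse(age < 18, "<18", ifelse(age <= 65, "18-65", ">65")))
  out$age <- dplyr::bind_rows(lapply(c("<18", "18-65", ">65", "Unknown or missing"),
                                     function(k) row("age", k, sum(band == k))))

  drug_counts <- cohort |> dplyr::count(.data$drug)
  out$drug <- dplyr::bind_rows(lapply(seq_len(nrow(drug_counts)), function(i)
    row("drug", drug_counts$drug[i], drug_counts$n[i])))

  onset_bin <- as.character(.onset_bin(cohort$onset_days))
  onset_bin[cohort$onset_status != "valid"] <- "Unknown or missing"
  out$onset <- dplyr::bind_rows(lapply(c(ONSET_BIN_LABELS, "Unknown or missing"),
                                       function(k) row("onset", k, sum(onset_bin == k))))

  ind_levels <- c("ovarian cancer" = "Ovarian cancer", "breast cancer" = "Breast cancer",
                  "others" = "Others", "missing" = "Unknown or missing")
  out$indication <- dplyr::bind_rows(lapply(names(ind_levels), function(k)
    row("indication", ind_levels[[k]], sum(cohort$indication_group == k))))

  oc <- lapply(cohort$outcomes, function(x) unique(unname(.OUTCOME_LABELS[x])))
  for (lab in c("Death", "Life-threatening", "Hospitalization", "Disability", "Others")) {
    out[[paste0("outc_", lab)]] <- row("serious_outcome", lab,
                                       sum(vapply(oc, function(x) lab %in% x, logical(1))))
  }

  country <- ifelse(is.na(cohort$occr_country), "Unknown", cohort$occr_country)
  top5 <- cohort |>
    dplyr::filter(!is.na(.data$occr_country)) |>
    dplyr::count(.data$occr_country, sort = TRUE) |>
    utils::head(5)
  out$country <- dplyr::bind_rows(lapply(seq_len(nrow(top5)), function(i)
    row("country", top5$occr_country[i], top5$n[i])))

  rep_cat <- ifelse(is.na(cohort$occp_cod), "Unknown",
                    unname(.REPORTER_LABELS[cohort$occp_cod]))
  rep_cat[is.na(rep_cat)] <- "Unknown"
  for (lab in c("Physician", "Pharmacist", "Other health-professional",
                "Consumer", "Unknown")) {
    out[[paste0("rep_", lab)]] <- row("reporter", lab, sum(rep_cat == lab))
  }

  yr <- cohort |>
    dplyr::filter(!is.na(.data$reporting_year)) |>
    dplyr::count(.data$reporting_year) |>
    dplyr::arrange(dplyr::desc(.data$reporting_year))
  out$year <- dplyr::bind_rows(lapply(seq_len(nrow(yr)), function(i)
    row("year", as.character(yr$reporting_year[i]), yr$n[i])))

  dplyr::bind_rows(out)
}
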