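#' Published PT-level statistics for the PARP-inhibitor haematotoxicity study
#'
#' The 56 drug-PT rows (report count, ROR with 95% CI, PRR with chi-squared,
#' IC with IC025, EBGM with EBGM05) reported for the four PARP inhibitors
#' at the preferred-term level, shipped as a plain TSV. Useful as a golden
#' input for the classify-only entry point.
#'
#' @return tibble with the statistic columns used by [classify_signal()].
#' @export
reference_signal_stats <- function() {
  as_tibble(utils::read.delim(
    system.file("extdata", "parpi_pt_signals.tsv", package = "faersignal",
                mustWork = TRUE),
    sep = "\t", check.names = FALSE))
}

#' Published marginal counts of the PARP-inhibitor haematotoxicity cohort
#'
#' Report counts by gender, age band, drug, onset bin, indication, serious
#' outcome, country, reporter and year, plus the study totals (24,045
#' target-drug reports, 4088 haematotoxicity reports, 9,264,231 reports in
#' the deduplicated corpus) and per-drug death counts.
#'
#' @return tibble `section`, `category`, `n`.
#' @export
reference_characteristics <- function() {
  as_tibble(utils::read.delim(
    system.file("extdata", "parpi_table1_counts.tsv", package = "faersignal",
                mustWork = TRUE),
    sep = "\t", colClasses = c("character", "character", "integer")))
}

.ref_n <- function(counts, section, category) {
  counts$n[counts$section == section & counts$category == category]
}

#' Synthetic report-level reconstruction of the published cohort
#'
#' Builds a 4088-row report-level table whose marginal distributions equal
#' the published counts exactly: drug, gender, age band, onset bin (bin
#' members placed at a representative mid-bin day), indication group,
#' serious outcomes (multi-select, with per-drug death counts honoured),
#' top-five countries, reporter category, and reporting year. Attributes
#' are assigned positionally and independently, so only the marginals —
#' not joint distributions beyond drug x death — are meaningful. This is a
#' synthetic reconstruction from published summary counts, not patient
#' data; it exists so that the descriptive, onset and fatality operations
#' can be exercised against the published ratios.
#'
#' @return a cohort-shaped tibble accepted by [descriptive_table()],
#'   [onset_summary()] and [fatality_analysis()].
#' @export
reference_cohort <- function() {
  ct <- reference_characteristics()
  n <- .ref_n(ct, "totals", "hematotoxicity_reports")
  rep_counts <- function(section, values) {
    counts <- vapply(values, function(v) .ref_n(ct, section, v), integer(1))
    rep(values, counts)
  }

  drugs <- c("olaparib", "niraparib", "rucaparib", "talazoparib")
  drug <- rep_counts("drug", drugs)
  death <- unlist(lapply(drugs, function(d) {
    k <- .ref_n(ct, "deaths_by_drug", d)
    m <- .ref_n(ct, "drug", d)
    c(rep(TRUE, k), rep(FALSE, m - k))
  }))

  sex_lab <- rep_counts("gender", c("Female", "Male", "Unknown or missing"))
  sex <- c(Female = "F", Male = "M", `Unknown or missing` = NA_character_)[sex_lab]

  age_lab <- rep_counts("age", c("<18", "18-65", ">65", "Unknown or missing"))
  age <- c(`<18` = 10, `18-65` = 40, `>65` = 70, `Unknown or missing` = NA_real_)[age_lab]

  onset_lab <- rep_counts("onset", c(ONSET_BIN_LABELS, "Unknown or missing"))
  onset_day <- c(`0-30` = 15, `31-60` = 45, `61-90` = 75, `91-180` = 135,
                 `181-360` = 270, `>=361` = 400,
                 `Unknown or missing` = NA_real_)[onset_lab]
  onset_status <- ifelse(is.na(onset_day), "missing", "valid")

  ind_lab <- rep_counts("indication", c("Ovarian cancer", "Breast cancer",
                                        "Others", "Unknown or missing"))
  indication <- c(`Ovarian cancer` = "ovarian cancer", `Breast cancer` = "breast cancer",
                  Others = "others", `Unknown or missing` = "missing")[ind_lab]

  flag <- function(k) c(rep(TRUE, k), rep(FALSE, n - k))
  lt <- flag(.ref_n(ct, "serious_outcome", "Life-threatening"))
  ho <- flag(.ref_n(ct, "serious_outcome", "Hospitalization"))
  ds <- flag(.ref_n(ct, "serious_outcome", "Disability"))
  ot <- flag(.ref_n(ct, "serious_outcome", "Others"))
  outcomes <- lapply(seq_len(n), function(i) {
    c(if (death[i]) "DE", if (lt[i]) "LT", if (ho[i]) "HO",
      if (ds[i]) "DS", if (ot[i]) "OT")
  })

  top5 <- c("US", "JP", "FR", "IT", "DE")
  country_named <- rep_counts("country", top5)
  n_rest <- n - length(country_named)
  # remainder spread over further codes, each kept below the 5th-place count
  rest_codes <- c("GB", "CA", "AU", "ES", "NL", "SE", "BE", "CH")
  per <- ceiling(n_rest / length(rest_codes))
  stopifnot(per < min(.ref_n(ct, "country", "DE")))
  country <- c(country_named, rep(rest_codes, length.out = n_rest))

  rep_lab <- rep_counts("reporter", c("Physician", "Pharmacist",
                                      "Other health-professional", "Consumer", "Unknown"))
  occp <- c(Physician = "MD", Pharmacist = "PH",
            `Other health-professional` = "OT", Consumer = "CN",
            Unknown = NA_character_)[rep_lab]

  year <- as.integer(rep_counts("year", as.character(2021:2015)))

  tibble(
    primaryid = sprintf("R%07d", seq_len(n)),
    drug = drug, death = death, sex = unname(sex), age_years = unname(age),
    onset_days = unname(onset_day), onset_status = onset_status,
    indication_group = unname(indication), outcomes = outcomes,
    occr_country = country, occp_cod = unname(occp), reporting_year = year
  )
}
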