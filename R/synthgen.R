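.default_drug_catalog <- function() {
  tibble(
    drug = c("olaparib", "niraparib", "rucaparib", "talazoparib",
             "METFORMIN", "ATORVASTATIN", "LISINOPRIL", "ADALIMUMAB",
             "IBUPROFEN", "OMEPRAZOLE", "LEVOTHYROXINE", "PEMBROLIZUMAB"),
    drugname = c("LYNPARZA", "ZEJULA", "RUBRACA", "TALZENNA",
                 "METFORMIN", "ATORVASTATIN", "LISINOPRIL", "HUMIRA",
                 "IBUPROFEN", "OMEPRAZOLE", "LEVOTHYROXINE", "KEYTRUDA"),
    prod_ai = c("OLAPARIB", "NIRAPARIB", "RUCAPARIB", "TALAZOPARIB",
                "METFORMIN", "ATORVASTATIN", "LISINOPRIL", "ADALIMUMAB",
                "IBUPROFEN", "OMEPRAZOLE", "LEVOTHYROXINE", "PEMBROLIZUMAB"),
    prob = c(0.008, 0.010, 0.005, 0.002,
             0.18, 0.15, 0.13, 0.10, 0.12, 0.11, 0.10, 0.075),
    is_target = c(rep(TRUE, 4), rep(FALSE, 8))
  )
}

.default_event_catalog <- function() {
  hema <- c("ANAEMIA" = 0.030, "THROMBOCYTOPENIA" = 0.015, "NEUTROPENIA" = 0.010,
            "PANCYTOPENIA" = 0.005, "MYELODYSPLASTIC SYNDROME" = 0.003,
            "BONE MARROW FAILURE" = 0.003, "LEUKOPENIA" = 0.004,
            "FEBRILE NEUTROPENIA" = 0.004)
  other <- c("NAUSEA" = 0.12, "FATIGUE" = 0.10, "DIARRHOEA" = 0.08,
             "HEADACHE" = 0.07, "VOMITING" = 0.06, "DIZZINESS" = 0.05,
             "RASH" = 0.05, "DYSPNOEA" = 0.04, "PYREXIA" = 0.04,
             "ARTHRALGIA" = 0.03)
  tibble(
    pt = c(names(hema), names(other)),
    prob = unname(c(hema, other)),
    soc_code = c(rep(SOC_BLOOD_LYMPHATIC, length(hema)), rep("10017947", length(other)))
  )
}

.default_association <- function() {
  targets <- c("olaparib", "niraparib", "rucaparib", "talazoparib")
  pts <- c("ANAEMIA", "THROMBOCYTOPENIA", "PANCYTOPENIA",
           "MYELODYSPLASTIC SYNDROME", "BONE MARROW FAILURE")
  tibble(
    drug = rep(targets, each = length(pts)),
    pt = rep(pts, times = length(targets)),
    rr = rep(c(8, 5, 5, 6, 5), times = length(targets))
  )
}

#' Configuration for the synthetic report generator
#'
#' Defines the statistical structure the generator emulates: categorical
#' drug and event marginals, implanted drug-event reporting-rate
#' multipliers, case-version duplication, missing/partial/reversed dates,
#' per-drug death rates and log-normal onset distributions. Defaults mimic
#' a PARP-inhibitor safety corpus: four target drugs at sub-percent
#' marginal frequency against a background of common drugs, haematological
#' events implanted at reporting-rate multipliers of 5-8, and per-drug
#' death rates and onset scales on the order reported for these drugs
#' (e.g. a median onset near 28 days overall).
#'
#' @param n_cases number of distinct cases to generate.
#' @param drug_catalog tibble `drug`, `drugname`, `prod_ai`, `prob`,
#'   `is_target`; probabilities are normalised internally.
#' @param event_catalog tibble `pt`, `prob`, `soc_code`; `prob` is the
#'   per-case occurrence probability of the event on a neutral drug.
#' @param association tibble `drug`, `pt`, `rr`: the occurrence probability
#'   of `pt` on a case of `drug` is `min(prob * rr, 0.95)`.
#' @param duplicate_rate fraction of cases emitted with a second version
#'   (same caseid, higher primaryid, later-or-equal fda_dt).
#' @param deleted_rate fraction of cases listed in the deleted-case file.
#' @param missing_date_rate,partial_date_rate,date_error_rate probabilities
#'   that a case's onset dates are blanked, truncated to month precision,
#'   or swapped (therapy start after event).
#' @param death_rate baseline probability of a death outcome; named
#'   per-drug entries in `death_rate_by_drug` override it.
#' @param death_rate_by_drug named numeric vector of per-drug death rates.
#' @param onset_meanlog,onset_sdlog log-normal onset parameters (days);
#'   named per-drug vectors `onset_meanlog_by_drug` override the mean.
#' @param onset_meanlog_by_drug named numeric vector.
#' @param seed mandatory integer seed; generation is fully deterministic.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_cases = 10000,
                         drug_catalog = .default_drug_catalog(),
                         event_catalog = .default_event_catalog(),
                         association = .default_association(),
                         duplicate_rate = 0.10,
                         deleted_rate = 0.0,
                         missing_date_rate = 0.35,
                         partial_date_rate = 0.05,
                         date_error_rate = 0.02,
                         death_rate = 0.05,
                         death_rate_by_drug = c(olaparib = 0.16, niraparib = 0.047,
                                                rucaparib = 0.038, talazoparib = 0.16),
                         onset_meanlog = log(28), onset_sdlog = 1.1,
                         onset_meanlog_by_drug = c(olaparib = log(63), niraparib = log(21),
                                                   rucaparib = log(22.5), talazoparib = log(35.5)),
                         seed) {
  if (missing(seed) || is.null(seed)) stop("synth_config: seed is mandatory")
  stopifnot(n_cases >= 1, all(drug_catalog$prob >= 0), all(event_catalog$prob >= 0),
            all(event_catalog$prob <= 1), all(association$rr > 0))
  rates <- c(duplicate_rate, deleted_rate, missing_date_rate,
             partial_date_rate, date_error_rate)
  stopifnot(all(rates >= 0), all(rates < 1))
  if (sum(drug_catalog$prob) <= 0) stop("drug probabilities are not normalizable")
  drug_catalog$prob <- drug_catalog$prob / sum(drug_catalog$prob)
  if (!all(association$drug %in% drug_catalog$drug) ||
      !all(association$pt %in% event_catalog$pt)) {
    stop("association refers to a drug or PT absent from the catalogs")
  }
  structure(list(
    n_cases = as.integer(n_cases), drug_catalog = drug_catalog,
    event_catalog = event_catalog, association = association,
    duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
    missing_date_rate = missing_date_rate, partial_date_rate = partial_date_rate,
    date_error_rate = date_error_rate, death_rate = death_rate,
    death_rate_by_drug = death_rate_by_drug,
    onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
    onset_meanlog_by_drug = onset_meanlog_by_drug,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# per-drug x per-event occurrence probability matrix (drugs in catalog order)
.event_prob_matrix <- function(config, cap = 0.95) {
  dc <- config$drug_catalog; ec <- config$event_catalog
  P <- matrix(rep(ec$prob, each = nrow(dc)), nrow = nrow(dc),
              dimnames = list(dc$drug, ec$pt))
  if (nrow(config$association) > 0) {
    idx <- cbind(match(config$association$drug, dc$drug),
                 match(config$association$pt, ec$pt))
    P[idx] <- P[idx] * config$association$rr
  }
  pmin(P, cap)
}

#' Exact large-sample reporting odds ratio implied by a generator config
#'
#' Computes, from the generator's own occurrence model (independent
#' per-event Bernoulli draws plus one weighted draw for cases that would
#' otherwise carry no event), the probability that a report of each drug
#' carries the event, and from those the population ROR of `drug` versus
#' all other drugs. This is the target an estimate from generated data
#' converges to.
#'
#' @param config a [synth_config()].
#' @param drug,pt the pair of interest.
#' @return the population reporting odds ratio (a number).
#' @export
synth_expected_ror <- function(config, drug, pt) {
  dc <- config$drug_catalog; ec <- config$event_catalog
  P <- .event_prob_matrix(config)
  W <- matrix(rep(ec$prob, each = nrow(dc)), nrow = nrow(dc))
  if (nrow(config$association) > 0) {
    idx <- cbind(match(config$association$drug, dc$drug),
                 match(config$association$pt, ec$pt))
    W[idx] <- W[idx] * config$association$rr
  }
  p0 <- apply(1 - P, 1, prod)                  # P(no event at all | drug)
  fill <- W / rowSums(W)                       # single weighted draw
  Pe <- P + p0 * fill                          # P(event on report | drug)
  j <- match(pt, ec$pt); i <- match(drug, dc$drug)
  if (is.na(i) || is.na(j)) stop("unknown drug or pt")
  p1 <- Pe[i, j]
  w <- dc$prob; w[i] <- 0; w <- w / sum(w)
  p_other <- sum(w * Pe[, j])
  (p1 / (1 - p1)) / (p_other / (1 - p_other))
}

.fmt_date <- function(d) format(d, "%Y%m%d")

#' Generate a synthetic corpus with known ground truth
#'
#' Each case receives one primary-suspect drug from the catalog marginals
#' and at least one preferred term; the occurrence probability of PT `e` on
#' a case of drug `D` is `min(marginal(e) * RR(D, e), 0.95)`. Onset days
#' are log-normal per drug; therapy start, event and FDA receipt dates are
#' consistent unless a configured date pathology (missing, month-precision,
#' start-after-event) is applied. A configured fraction of cases is emitted
#' twice — same caseid, caseversion 2, strictly higher primaryid,
#' later-or-equal fda_dt, identical children — so deduplication recovers
#' exactly the distinct cases; the ground truth records the intended
#' post-dedup state.
#'
#' @param config a [synth_config()].
#' @return list with `quarter` (a `faers_quarter`) and `truth`: `n_cases`,
#'   `case` (tibble `caseid`, `primaryid`, `drug`, `events` list-column,
#'   `death`, `onset_days`), `drug_pt` (tibble `drug`, `pt`, `a`, `b`,
#'   `c`, `d` over distinct cases), `deaths_by_drug`, `deleted_caseids`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cases
  dc <- config$drug_catalog; ec <- config$event_catalog
  n_ev <- nrow(ec)

  caseid <- sprintf("%d", 1000000 + seq_len(n))
  pid1 <- sprintf("%s01", caseid)

  drug_idx <- sample.int(nrow(dc), n, replace = TRUE, prob = dc$prob)
  drug <- dc$drug[drug_idx]

  P <- .event_prob_matrix(config)
  occ <- matrix(stats::runif(n * n_ev), n, n_ev) < P[drug_idx, , drop = FALSE]
  none <- which(rowSums(occ) == 0)
  if (length(none) > 0) {
    W <- .event_prob_matrix(config, cap = Inf)   # un-capped weights
    for (di in unique(drug_idx[none])) {
      cases <- none[drug_idx[none] == di]
      picked <- sample.int(n_ev, length(cases), replace = TRUE, prob = W[di, ])
      occ[cbind(cases, picked)] <- TRUE
    }
  }

  meanlog <- rep(config$onset_meanlog, n)
  hit <- drug %in% names(config$onset_meanlog_by_drug)
  meanlog[hit] <- config$onset_meanlog_by_drug[drug[hit]]
  onset_days <- pmax(0L, as.integer(floor(stats::rlnorm(n, meanlog, config$onset_sdlog))))

  start_date <- as.Date("2015-01-01") + sample.int(2300, n, replace = TRUE) - 1L
  event_date <- start_date + onset_days
  fda_date <- event_date + stats::rpois(n, 20)
  end_date <- start_date + sample.int(365, n, replace = TRUE)

  start_raw <- .fmt_date(start_date)
  event_raw <- .fmt_date(event_date)

  u <- stats::runif(n)
  p_err <- config$date_error_rate
  p_part <- config$partial_date_rate
  p_miss <- config$missing_date_rate
  is_err <- u < p_err & onset_days > 0
  is_part <- u >= p_err & u < p_err + p_part
  is_miss <- u >= p_err + p_part & u < p_err + p_part + p_miss
  tmp <- start_raw[is_err]
  start_raw[is_err] <- event_raw[is_err]
  event_raw[is_err] <- tmp
  start_raw[is_part] <- substr(start_raw[is_part], 1, 6)
  blank_start <- is_miss & stats::runif(n) < 0.5
  start_raw[blank_start] <- NA_character_
  event_raw[is_miss & !blank_start] <- NA_character_

  death_p <- rep(config$death_rate, n)
  hit <- drug %in% names(config$death_rate_by_drug)
  death_p[hit] <- config$death_rate_by_drug[drug[hit]]
  death <- stats::runif(n) < death_p

  sex <- sample(c("F", "M", NA_character_), n, replace = TRUE, prob = c(0.82, 0.04, 0.14))
  age <- round(stats::rnorm(n, 62, 12), 1)
  age[age < 18] <- 18 + abs(age[age < 18] - 18) %% 60
  age[stats::runif(n) < 0.45] <- NA_real_
  country <- sample(c("US", "JP", "FR", "IT", "DE", "GB", "CA", "AU"), n,
                    replace = TRUE, prob = c(0.60, 0.10, 0.05, 0.03, 0.02, 0.08, 0.07, 0.05))
  occp <- sample(c("MD", "PH", "OT", "CN", NA_character_), n,
                 replace = TRUE, prob = c(0.29, 0.03, 0.18, 0.40, 0.10))

  is_target <- dc$is_target[drug_idx]
  ind_grp <- character(n)
  ind_grp[is_target] <- sample(c("OVARIAN CANCER", "BREAST CANCER", "PROSTATE CANCER", ""),
                               sum(is_target), replace = TRUE,
                               prob = c(0.68, 0.05, 0.19, 0.08))
  ind_grp[!is_target] <- sample(c("HYPERTENSION", "DIABETES MELLITUS", ""),
                                sum(!is_target), replace = TRUE, prob = c(0.4, 0.3, 0.3))

  demo <- tibble(
    primaryid = pid1, caseid = caseid, caseversion = "1",
    fda_dt = .fmt_date(fda_date), event_dt = event_raw,
    age = ifelse(is.na(age), NA_character_, sprintf("%.1f", age)),
    age_cod = ifelse(is.na(age), NA_character_, "YR"),
    sex = sex, occr_country = country, occp_cod = occp
  )

  # PS row per case; ~30% carry a dose-qualified free-text name, plus 0-2
  # concomitant mentions which must never recruit a report
  dose_suffix <- stats::runif(n) < 0.3
  ps_name <- ifelse(dose_suffix, paste0(dc$drugname[drug_idx], " 100 MG TABLETS"),
                    dc$drugname[drug_idx])
  n_con <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  con_case <- rep(seq_len(n), n_con)
  con_drug_idx <- sample.int(nrow(dc), length(con_case), replace = TRUE, prob = dc$prob)
  drug_tbl <- dplyr::bind_rows(
    tibble(primaryid = pid1, drug_seq = "1", drugname = ps_name,
           prod_ai = dc$prod_ai[drug_idx], role_cod = "PS"),
    tibble(primaryid = pid1[con_case],
           drug_seq = as.character(1L + stats::ave(con_case, con_case, FUN = seq_along)),
           drugname = dc$drugname[con_drug_idx],
           prod_ai = dc$prod_ai[con_drug_idx], role_cod = "C")
  ) |> dplyr::arrange(.data$primaryid, .data$drug_seq)

  hits <- which(occ, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  reac <- tibble(primaryid = pid1[hits[, 1]], pt = ec$pt[hits[, 2]])

  outc_list <- list(tibble(primaryid = pid1[death], outc_cod = "DE"))
  for (spec in list(c("HO", 0.29), c("LT", 0.10), c("DS", 0.01), c("OT", 0.55))) {
    sel <- stats::runif(n) < as.numeric(spec[2])
    outc_list[[length(outc_list) + 1]] <- tibble(primaryid = pid1[sel], outc_cod = spec[1])
  }
  outc <- dplyr::bind_rows(outc_list) |> dplyr::arrange(.data$primaryid, .data$outc_cod)

  ther <- tibble(primaryid = pid1, drug_seq = "1",
                 start_dt = start_raw, end_dt = .fmt_date(end_date))
  has_indi <- nzchar(ind_grp)
  indi <- tibble(primaryid = pid1[has_indi], drug_seq = "1", indi_pt = ind_grp[has_indi])

  # case-version duplicates: re-emit demo and children under a higher
  # primaryid with a later-or-equal fda_dt
  dup <- stats::runif(n) < config$duplicate_rate
  final_pid <- pid1
  if (any(dup)) {
    pid2 <- sprintf("%s02", caseid[dup])
    final_pid[dup] <- pid2
    remap <- function(df, sel_pid, new_pid) {
      sub <- df[df$primaryid %in% sel_pid, , drop = FALSE]
      sub$primaryid <- new_pid[match(sub$primaryid, sel_pid)]
      sub
    }
    demo2 <- demo[dup, , drop = FALSE]
    demo2$primaryid <- pid2
    demo2$caseversion <- "2"
    demo2$fda_dt <- .fmt_date(fda_date[dup] + sample(0:60, sum(dup), replace = TRUE))
    demo <- dplyr::bind_rows(demo, demo2)
    drug_tbl <- dplyr::bind_rows(drug_tbl, remap(drug_tbl, pid1[dup], pid2))
    reac <- dplyr::bind_rows(reac, remap(reac, pid1[dup], pid2))
    outc <- dplyr::bind_rows(outc, remap(outc, pid1[dup], pid2))
    ther <- dplyr::bind_rows(ther, remap(ther, pid1[dup], pid2))
    indi <- dplyr::bind_rows(indi, remap(indi, pid1[dup], pid2))
  }
  deleted <- character()
  if (config$deleted_rate > 0) {
    deleted <- caseid[stats::runif(n) < config$deleted_rate]
  }

  quarter <- structure(list(
    demo = demo, drug = drug_tbl, reac = reac, outc = outc, ther = ther,
    indi = indi, deleted_caseids = deleted, log = list()
  ), class = "faers_quarter")
  quarter$demo$age_years <- normalize_age_years(quarter$demo$age, quarter$demo$age_cod)
  quarter$drug$drug_seq <- as.integer(quarter$drug$drug_seq)
  quarter$ther$drug_seq <- as.integer(quarter$ther$drug_seq)
  quarter$indi$drug_seq <- as.integer(quarter$indi$drug_seq)

  keep <- !caseid %in% deleted
  n_de <- rowsum(occ[keep, , drop = FALSE] + 0L, group = drug[keep])
  n_drug <- as.vector(table(factor(drug[keep], levels = rownames(n_de))))
  n_event <- unname(colSums(occ[keep, , drop = FALSE]))
  n_tot <- sum(keep)
  drug_pt <- tibble(
    drug = rep(rownames(n_de), times = ncol(n_de)),
    pt = rep(colnames(n_de), each = nrow(n_de)),
    a = as.vector(n_de),
    b = rep(n_drug, times = ncol(n_de)) - as.vector(n_de),
    c = rep(n_event, each = nrow(n_de)) - as.vector(n_de)
  )
  drug_pt$d <- n_tot - drug_pt$a - drug_pt$b - drug_pt$c

  truth <- list(
    n_cases = n_tot,
    case = tibble(caseid = caseid, primaryid = final_pid, drug = drug,
                  events = apply(occ, 1, function(r) ec$pt[r], simplify = FALSE),
                  death = death, onset_days = onset_days)[keep, , drop = FALSE],
    drug_pt = drug_pt,
    deaths_by_drug = tapply(death[keep], drug[keep], sum),
    deleted_caseids = deleted
  )
  list(quarter = quarter, truth = truth)
}

#' PT to SOC map matching the default synthetic event catalog
#'
#' @param config a [synth_config()].
#' @return a [pt_soc_map()] with one primary SOC row per catalog PT.
#' @export
synth_pt_soc_map <- function(config) {
  ec <- config$event_catalog
  pt_soc_map(tibble(
    pt_name = ec$pt,
    soc_name = ifelse(ec$soc_code == SOC_BLOOD_LYMPHATIC,
                      "Blood and lymphatic system disorders", "Other disorders"),
    soc_code = ec$soc_code,
    is_primary_soc = TRUE
  ))
}

#' Drug dictionary covering the synthetic target drugs
#'
#' @param config a [synth_config()].
#' @return a [drug_dictionary()] with one entry per target catalog drug.
#' @export
synth_dictionary <- function(config) {
  dc <- config$drug_catalog[config$drug_catalog$is_target, , drop = FALSE]
  if (nrow(dc) == 0) stop("no target drugs in the catalog")
  drug_dictionary(stats::setNames(
    lapply(seq_len(nrow(dc)), function(i) unique(c(dc$drugname[i], dc$prod_ai[i]))),
    dc$drug))
}
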