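#' Normalise free-text drug or term strings for matching
#'
#' Uppercases, collapses runs of whitespace, and trims. FAERS `drugname` is
#' free text ("olaparib 150 mg tablets", "LYNPARZA."), so all matching works
#' on normalised substrings.
#'
#' @param x character vector.
#' @return normalised character vector.
#' @export
normalize_term <- function(x) {
  x <- toupper(ifelse(is.na(x), "", x))
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Build a validated drug dictionary
#'
#' A dictionary maps each target drug to the normalised name tokens
#' (generic and brand names) that identify it in free-text drug fields.
#' Tokens must be non-empty and no token may be claimed by two drugs.
#'
#' @param drugs named list: element names are drug labels, values are
#'   character vectors of name tokens.
#' @return a tibble with columns `drug`, `token`, class `drug_dictionary`.
#' @export
drug_dictionary <- function(drugs) {
  stopifnot(is.list(drugs), length(drugs) > 0, !is.null(names(drugs)))
  df <- tibble(
    drug = rep(names(drugs), lengths(drugs)),
    token = normalize_term(unlist(drugs, use.names = FALSE))
  )
  if (any(!nzchar(df$token))) stop("drug dictionary tokens must be non-empty")
  dup <- df$token[duplicated(df$token)]
  if (length(dup) > 0) {
    stop(sprintf("drug dictionary token(s) shared by two drugs: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  class(df) <- c("drug_dictionary", class(df))
  df
}

#' The four marketed PARP inhibitors, by generic and US brand name
#'
#' Olaparib (LYNPARZA), niraparib (ZEJULA), rucaparib (RUBRACA) and
#' talazoparib (TALZENNA) — the default target-drug dictionary.
#'
#' @return a `drug_dictionary`.
#' @export
parpi_dictionary <- function() {
  drug_dictionary(list(
    olaparib    = c("OLAPARIB", "LYNPARZA"),
    niraparib   = c("NIRAPARIB", "ZEJULA"),
    rucaparib   = c("RUCAPARIB", "RUBRACA"),
    talazoparib = c("TALAZOPARIB", "TALZENNA")
  ))
}

#' Map reports to target drugs via primary-suspect rows
#'
#' A report maps to drug D iff it has at least one DRUG row with role code
#' `PS` whose normalised `drugname` or `prod_ai` contains one of D's
#' dictionary tokens. Reports matching two different target drugs as PS are
#' ambiguous: they are excluded and counted (attribute `n_ambiguous`).
#' Suspect role codes other than PS never match, so a concomitant mention of
#' a target drug does not recruit the report.
#'
#' @param drug_rows tibble of DRUG rows (`primaryid`, `drugname`, `prod_ai`,
#'   `role_cod`, `drug_seq`).
#' @param dictionary a [drug_dictionary()].
#' @return tibble (`primaryid`, `drug`), one row per matched report, with
#'   attribute `n_ambiguous`.
#' @export
match_target_drug <- function(drug_rows, dictionary = parpi_dictionary()) {
  ps <- drug_rows[drug_rows$role_cod %in% "PS", , drop = FALSE]
  if (nrow(ps) == 0) {
    out <- tibble(primaryid = character(), drug = character())
    attr(out, "n_ambiguous") <- 0L
    return(out)
  }
  text <- paste(normalize_term(ps$drugname), normalize_term(ps$prod_ai))
  hits <- lapply(unique(dictionary$drug), function(d) {
    tokens <- dictionary$token[dictionary$drug == d]
    hit <- Reduce(`|`, lapply(tokens, function(tk) grepl(tk, text, fixed = TRUE)))
    if (any(hit)) tibble(primaryid = ps$primaryid[hit], drug = d) else NULL
  })
  matched <- dplyr::bind_rows(hits) |> dplyr::distinct()
  if (nrow(matched) == 0) {
    attr(matched, "n_ambiguous") <- 0L
    return(matched)
  }
  per_report <- matched |>
    dplyr::count(.data$primaryid, name = "n_drugs")
  ambiguous <- per_report$primaryid[per_report$n_drugs > 1]
  out <- matched[!matched$primaryid %in% ambiguous, , drop = FALSE]
  attr(out, "n_ambiguous") <- length(ambiguous)
  out
}

#' Build a validated PT to SOC mapping table
#'
#' Stands in for the (licensed) MedDRA hierarchy: rows of
#' (`pt_name`, `soc_name`, `soc_code`, `is_primary_soc`). A PT may map to
#' several SOCs but must have exactly one primary SOC; (pt, soc) pairs must
#' be unique. Event attachment uses the primary SOC only, so a report cannot
#' enter a SOC cohort through a secondary link.
#'
#' @param df data frame with the four columns above.
#' @return a tibble of class `pt_soc_map` with normalised `pt_name`.
#' @export
pt_soc_map <- function(df) {
  req <- c("pt_name", "soc_name", "soc_code", "is_primary_soc")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("pt_soc_map requires column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  df$pt_name <- normalize_term(df$pt_name)
  df$soc_code <- as.character(df$soc_code)
  df$is_primary_soc <- as.logical(df$is_primary_soc)
  if (anyDuplicated(df[, c("pt_name", "soc_code")])) {
    stop("pt_soc_map: duplicated (pt, soc) pair")
  }
  n_primary <- tapply(df$is_primary_soc, df$pt_name, sum)
  if (any(n_primary != 1)) {
    stop(sprintf("pt_soc_map: every PT needs exactly one primary SOC; offending PT(s): %s",
                 paste(names(n_primary)[n_primary != 1], collapse = ", ")))
  }
  class(df) <- c("pt_soc_map", class(df))
  df
}

#' Read a PT to SOC mapping from a tab-separated file
#'
#' @param path TSV file with header columns `pt_name`, `soc_name`,
#'   `soc_code`, `is_primary_soc`.
#' @return a [pt_soc_map()].
#' @export
read_pt_soc_map <- function(path) {
  pt_soc_map(utils::read.delim(path, sep = "\t", colClasses = "character"))
}

#' Illustrative PT to SOC mapping for haematological terms
#'
#' A small mapping table covering the haematological preferred terms used in
#' the worked examples plus common non-haematological terms, with the SOC
#' "Blood and lymphatic system disorders" coded `10005329`. It is a
#' synthetic stand-in for a MedDRA extract, not MedDRA content.
#'
#' @return a [pt_soc_map()].
#' @export
example_pt_soc_map <- function() {
  read_pt_soc_map(system.file("extdata", "pt_soc_example.tsv",
                              package = "faersignal", mustWork = TRUE))
}

#' SOC code for blood and lymphatic system disorders
#' @export
SOC_BLOOD_LYMPHATIC <- "10005329"

#' Attach PT-level events and a SOC membership flag to reports
#'
#' For each report, collects its distinct preferred terms and flags whether
#' at least one maps — through its primary SOC — to the target SOC. PTs
#' absent from the map are counted (attribute `n_unmapped_pts`) but kept in
#' the PT list. A report with several target-SOC PTs counts once at SOC
#' level while each PT still counts at PT level.
#'
#' @param reac_rows tibble of REAC rows (`primaryid`, `pt`).
#' @param map a [pt_soc_map()].
#' @param target_soc_code SOC code defining the cohort of interest.
#' @return tibble (`primaryid`, `pts` list-column, `soc_pts` list-column,
#'   `in_target_soc`), attribute `n_unmapped_pts`.
#' @export
attach_events <- function(reac_rows, map, target_soc_code = SOC_BLOOD_LYMPHATIC) {
  reac <- tibble(primaryid = reac_rows$primaryid, pt = normalize_term(reac_rows$pt))
  reac <- reac[nzchar(reac$pt), , drop = FALSE] |> dplyr::distinct()
  primary <- map[map$is_primary_soc, , drop = FALSE]
  n_unmapped <- length(setdiff(unique(reac$pt), primary$pt_name))
  target_pts <- primary$pt_name[primary$soc_code == as.character(target_soc_code)]
  out <- reac |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      pts = list(.data$pt),
      soc_pts = list(intersect(.data$pt, target_pts)),
      in_target_soc = length(intersect(.data$pt, target_pts)) > 0,
      .groups = "drop"
    )
  attr(out, "n_unmapped_pts") <- n_unmapped
  out
}

#' Group indication terms into study categories
#'
#' One category per report: `"ovarian cancer"` if any indication term
#' contains that phrase (normalised), else `"breast cancer"` analogously,
#' else `"others"` when any indication term is present, else `"missing"`.
#'
#' @param indi_rows tibble of INDI rows (`primaryid`, `indi_pt`).
#' @param primaryids report ids to classify (reports without INDI rows get
#'   `"missing"`).
#' @return tibble (`primaryid`, `indication_group`).
#' @export
classify_indication <- function(indi_rows, primaryids) {
  term <- normalize_term(indi_rows$indi_pt)
  present <- nzchar(term)
  grp <- indi_rows[present, , drop = FALSE] |>
    dplyr::mutate(term = term[present]) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      indication_group = if (any(grepl("OVARIAN CANCER", .data$term, fixed = TRUE))) {
        "ovarian cancer"
      } else if (any(grepl("BREAST CANCER", .data$term, fixed = TRUE))) {
        "breast cancer"
      } else "others",
      .groups = "drop"
    )
  tibble(primaryid = primaryids) |>
    dplyr::left_join(grp, by = "primaryid") |>
    dplyr::mutate(indication_group = ifelse(is.na(.data$indication_group),
                                            "missing", .data$indication_group))
}

#' Time to onset between therapy start and event date
#'
#' Onset is the whole-day interval from therapy start (`START_DT`) to the
#' adverse-event date (`EVENT_DT`). Only pairs where both dates have day
#' precision yield a value; otherwise an exclusion reason is returned:
#' `"missing"` (either date absent), `"inaccurate"` (either date partial or
#' calendar-invalid), or `"date_error"` (start later than event). Day-0
#' onsets are valid.
#'
#' @param start_raw,event_raw character vectors of raw date strings.
#' @return tibble (`onset_days` integer or `NA`, `onset_status` one of
#'   `"valid"`, `"missing"`, `"inaccurate"`, `"date_error"`).
#' @examples
#' compute_onset_days("20210101", "20210129")  # 28 days
#' @export
compute_onset_days <- function(start_raw, event_raw) {
  n <- max(length(start_raw), length(event_raw))
  start <- parse_partial_date(rep_len(start_raw, n))
  event <- parse_partial_date(rep_len(event_raw, n))
  status <- rep("valid", n)
  status[start$precision %in% c("month", "year", "invalid") |
           event$precision %in% c("month", "year", "invalid")] <- "inaccurate"
  status[start$precision == "missing" | event$precision == "missing"] <- "missing"
  days <- as.integer(event$date - start$date)
  bad_order <- status == "valid" & days < 0
  status[bad_order] <- "date_error"
  days[status != "valid"] <- NA_integer_
  tibble(onset_days = days, onset_status = status)
}

# earliest day-precision therapy start per (primaryid, target drug),
# restricted to drug_seq rows on which the target drug itself appears
.first_target_start <- function(ther_rows, drug_rows, drug_map, dictionary) {
  if (nrow(drug_map) == 0) {
    return(tibble(primaryid = character(), start_raw = character()))
  }
  dr <- drug_rows[drug_rows$primaryid %in% drug_map$primaryid &
                    drug_rows$role_cod %in% "PS", , drop = FALSE]
  dr <- dr |> dplyr::inner_join(drug_map, by = "primaryid")
  text <- paste(normalize_term(dr$drugname), normalize_term(dr$prod_ai))
  is_target_row <- vapply(seq_len(nrow(dr)), function(i) {
    tokens <- dictionary$token[dictionary$drug == dr$drug[i]]
    any(vapply(tokens, function(tk) grepl(tk, text[i], fixed = TRUE), logical(1)))
  }, logical(1))
  dr <- dr[is_target_row, c("primaryid", "drug_seq"), drop = FALSE]
  th <- ther_rows |>
    dplyr::inner_join(dr, by = c("primaryid", "drug_seq"))
  if (nrow(th) == 0) {
    return(tibble(primaryid = character(), start_raw = character()))
  }
  pd <- parse_partial_date(th$start_dt)
  th$.date <- pd$date
  th$.day <- pd$precision == "day"
  th |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      start_raw = if (any(.data$.day)) {
        .data$start_dt[.data$.day][which.min(.data$.date[.data$.day])]
      } else if (all(is.na(.data$start_dt))) NA_character_ else .data$start_dt[1],
      .groups = "drop"
    )
}

#' Assemble the analysis cohort for a set of target drugs
#'
#' Joins the deduplicated corpus into one report-level table for the
#' target-drug reports: matched drug, PT list and target-SOC flag,
#' demographics, indication category, outcome codes, death flag, onset days
#' with exclusion status (using the earliest day-precision therapy start of
#' the target drug itself), and reporting year from `fda_dt`.
#'
#' @param quarter a deduplicated `faers_quarter`.
#' @param dictionary a [drug_dictionary()].
#' @param map a [pt_soc_map()].
#' @param target_soc_code SOC code defining the event cohort flag.
#' @return tibble with one row per target-drug report; attribute
#'   `n_ambiguous` carries the count of multi-target PS reports excluded.
#' @export
build_cohort <- function(quarter, dictionary = parpi_dictionary(),
                         map = example_pt_soc_map(),
                         target_soc_code = SOC_BLOOD_LYMPHATIC) {
  drug_map <- match_target_drug(quarter$drug, dictionary)
  events <- attach_events(quarter$reac, map, target_soc_code)
  indi <- classify_indication(quarter$indi, drug_map$primaryid)
  outc <- quarter$outc |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(outcomes = list(unique(.data$outc_cod)), .groups = "drop")
  starts <- .first_target_start(quarter$ther, quarter$drug, drug_map, dictionary)

  demo <- quarter$demo[, c("primaryid", "caseid", "fda_dt", "event_dt",
                           "age_years", "sex", "occr_country", "occp_cod")]
  cohort <- drug_map |>
    dplyr::inner_join(demo, by = "primaryid") |>
    dplyr::left_join(events, by = "primaryid") |>
    dplyr::left_join(indi, by = "primaryid") |>
    dplyr::left_join(outc, by = "primaryid") |>
    dplyr::left_join(starts, by = "primaryid")
  cohort$pts <- lapply(cohort$pts, function(x) if (is.null(x)) character() else x)
  cohort$soc_pts <- lapply(cohort$soc_pts, function(x) if (is.null(x)) character() else x)
  cohort$in_target_soc[is.na(cohort$in_target_soc)] <- FALSE
  cohort$outcomes <- lapply(cohort$outcomes, function(x) if (is.null(x)) character() else x)
  cohort$death <- vapply(cohort$outcomes, function(x) "DE" %in% x, logical(1))
  onset <- compute_onset_days(cohort$start_raw, cohort$event_dt)
  cohort$onset_days <- onset$onset_days
  cohort$onset_status <- onset$onset_status
  cohort$reporting_year <- suppressWarnings(as.integer(substr(cohort$fda_dt, 1, 4)))
  attr(cohort, "n_ambiguous") <- attr(drug_map, "n_ambiguous")
  cohort
}
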