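.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.list(df[[j]])) {
    df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}

#' Run the full signal-detection pipeline on a report corpus
#'
#' Orchestrates ingest, deduplication, cohort extraction, disproportionality
#' scanning, and onset/fatality summaries, writing the study-style result
#' tables and a machine-checkable audit of every filtering edge:
#' `table1.tsv` (clinical characteristics of the target-SOC cohort),
#' `table2.tsv` (SOC-level statistics per drug plus a pooled row),
#' `table3.tsv` (PT-level statistics, signals flagged), `onset.tsv`,
#' `fatality.tsv`, and `audit.json`.
#'
#' @param input either a `faers_quarter` (or list of them), or a directory
#'   path containing quarter files.
#' @param quarter_labels labels of the quarters to read when `input` is a
#'   directory.
#' @param dictionary a [drug_dictionary()].
#' @param map a [pt_soc_map()] or path to a TSV readable by
#'   [read_pt_soc_map()].
#' @param target_soc_code SOC defining the event cohort.
#' @param thresholds a [signal_thresholds()].
#' @param out_dir output directory (created); `NULL` skips file output.
#' @param seed seed for any resampled p-values.
#' @return invisibly, a list with `cohort`, `scan`, `table1`, `onset`,
#'   `fatality`, and `audit`.
#' @export
run_pipeline <- function(input, quarter_labels = NULL,
                         dictionary = parpi_dictionary(),
                         map = example_pt_soc_map(),
                         target_soc_code = SOC_BLOOD_LYMPHATIC,
                         thresholds = signal_thresholds(),
                         out_dir = NULL, seed = 1L) {
  stage <- "ingest"
  audit <- list()
  result <- tryCatch({
    if (is.character(input)) {
      stopifnot(!is.null(quarter_labels))
      quarters <- lapply(quarter_labels, function(q) read_faers_quarter(input, q))
      corpus <- bind_faers_quarters(quarters)
    } else if (inherits(input, "faers_quarter")) {
      corpus <- input
    } else {
      corpus <- bind_faers_quarters(input)
    }
    if (is.character(map)) map <- read_pt_soc_map(map)
    audit$n_raw_demo_rows <- nrow(corpus$demo)

    stage <- "dedup"
    corpus <- dedup_corpus(corpus)
    audit$dedup <- corpus$dedup_audit
    audit$n_reports <- nrow(corpus$demo)

    stage <- "cohort"
    cohort <- build_cohort(corpus, dictionary, map, target_soc_code)
    audit$n_target_drug_reports <- nrow(cohort)
    audit$n_ambiguous_excluded <- attr(cohort, "n_ambiguous")
    soc_cohort <- cohort[cohort$in_target_soc, , drop = FALSE]
    audit$n_target_soc_reports <- nrow(soc_cohort)
    audit$n_onset_valid <- sum(soc_cohort$onset_status == "valid")

    stage <- "signals"
    scan <- signal_scan(corpus, cohort, map, target_soc_code, thresholds)
    audit$n_pt_pairs <- sum(scan$level == "pt" & scan$drug != "all")
    audit$n_signals <- sum(scan$signal & scan$level == "pt" & scan$drug != "all")

    stage <- "outcomes"
    onset <- onset_summary(soc_cohort)
    fatality <- fatality_analysis(soc_cohort, seed = seed)
    table1 <- descriptive_table(soc_cohort)

    list(cohort = cohort, scan = scan, table1 = table1,
         onset = onset, fatality = fatality, audit = audit)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s [audit: %s]",
                 stage, conditionMessage(e),
                 jsonlite::toJSON(audit, auto_unbox = TRUE)), call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(result$table1, file.path(out_dir, "table1.tsv"))
    .write_tsv(result$scan[result$scan$level == "soc", ], file.path(out_dir, "table2.tsv"))
    .write_tsv(result$scan[result$scan$level == "pt" & result$scan$drug != "all", ],
               file.path(out_dir, "table3.tsv"))
    .write_tsv(result$onset$summary, file.path(out_dir, "onset.tsv"))
    .write_tsv(result$fatality$by_drug, file.path(out_dir, "fatality.tsv"))
    jsonlite::write_json(result$audit, file.path(out_dir, "audit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}

#' Classify a table of precomputed statistics
#'
#' The classify-only entry point: applies the joint signal rule to a TSV
#' (or data frame) of already-computed statistics — for example a table of
#' published values — without touching raw report data.
#'
#' @param stats a data frame, or path to a TSV, with columns `n`,
#'   `ror_lo95`, `prr`, `chi2`, `ic025`, `ebgm05` (extra columns pass
#'   through).
#' @param thresholds a [signal_thresholds()].
#' @return the table with per-rule verdicts and `signal` appended.
#' @export
classify_signal_table <- function(stats, thresholds = signal_thresholds()) {
  if (is.character(stats)) {
    stats <- utils::read.delim(stats, sep = "\t", check.names = FALSE)
  }
  classify_signal(as_tibble(stats), thresholds)
}
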