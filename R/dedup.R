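#' Reduce case versions to one report per case
#'
#' Applies the FDA-recommended deduplication for spontaneous report extracts:
#' cases on the deleted list are removed first; then, within each `caseid`,
#' only rows carrying the latest `fda_dt` survive; among those, the single
#' row with the numerically highest `primaryid` is kept. The composition
#' yields exactly one report per surviving case.
#'
#' @param demo tibble of DEMO rows with at least `primaryid`, `caseid`,
#'   `fda_dt` (8-digit day precision).
#' @param deleted_caseids character vector of case ids to expunge.
#' @return A list with `demo` (the surviving rows), `kept_primaryids`,
#'   and an `audit` list: `n_input`, `n_after_deleted_removal`, `n_output`,
#'   `n_removed_deleted`, `n_removed_version`.
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c("100", "101", "200"), caseid = c("7", "7", "8"),
#'   fda_dt = c("20200101", "20200101", "20200301"))
#' dedup_reports(demo)$kept_primaryids
#' @export
dedup_reports <- function(demo, deleted_caseids = character()) {
  n_input <- nrow(demo)
  demo <- demo[!(demo$caseid %in% deleted_caseids), , drop = FALSE]
  n_after <- nrow(demo)

  pid <- suppressWarnings(as.numeric(demo$primaryid))
  if (anyNA(pid)) {
    bad <- demo$primaryid[is.na(pid)]
    stop(sprintf("non-numeric primaryid in DEMO (corrupt input): %s",
                 paste(utils::head(bad, 3), collapse = ", ")))
  }
  fda <- suppressWarnings(as.numeric(demo$fda_dt))
  if (anyNA(fda)) {
    stop("DEMO fda_dt must be an 8-digit date for every row used in deduplication")
  }

  if (nrow(demo) == 0) {
    return(list(demo = demo, kept_primaryids = character(),
                audit = list(n_input = n_input, n_after_deleted_removal = 0L,
                             n_output = 0L, n_removed_deleted = n_input,
                             n_removed_version = 0L)))
  }

  kept <- demo |>
    dplyr::mutate(.pid = pid, .fda = fda) |>
    dplyr::group_by(.data$caseid) |>
    dplyr::filter(.data$.fda == max(.data$.fda)) |>
    dplyr::filter(.data$.pid == max(.data$.pid)) |>
    dplyr::ungroup() |>
    dplyr::select(-".pid", -".fda")

  list(
    demo = kept,
    kept_primaryids = kept$primaryid,
    audit = list(
      n_input = n_input,
      n_after_deleted_removal = n_after,
      n_output = nrow(kept),
      n_removed_deleted = n_input - n_after,
      n_removed_version = n_after - nrow(kept)
    )
  )
}

#' Restrict a corpus to a set of surviving reports
#'
#' Subsets the DEMO table and every child table of a quarter to the reports
#' kept by [dedup_reports()], logging how many rows each table lost.
#'
#' @param quarter a `faers_quarter`.
#' @param kept_primaryids character vector of surviving report ids.
#' @return the filtered `faers_quarter`, with a `filter_log` element of
#'   per-table removed-row counts.
#' @export
filter_children <- function(quarter, kept_primaryids) {
  filter_log <- list()
  for (tab in names(.faers_required_cols)) {
    before <- nrow(quarter[[tab]])
    quarter[[tab]] <- quarter[[tab]][quarter[[tab]]$primaryid %in% kept_primaryids, , drop = FALSE]
    filter_log[[tab]] <- list(n_before = before, n_removed = before - nrow(quarter[[tab]]))
  }
  quarter$filter_log <- filter_log
  quarter
}

#' Deduplicate a whole corpus in one step
#'
#' Convenience wrapper: runs [dedup_reports()] on the DEMO table (using the
#' quarter's own deleted-case list) and [filter_children()] on the result.
#'
#' @param quarter a `faers_quarter` (possibly several quarters bound).
#' @return the deduplicated quarter with `dedup_audit` attached.
#' @export
dedup_corpus <- function(quarter) {
  res <- dedup_reports(quarter$demo, quarter$deleted_caseids)
  out <- filter_children(quarter, res$kept_primaryids)
  out$demo <- res$demo
  out$dedup_audit <- res$audit
  out
}
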