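#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @import dplyr
NULL

# Required columns per table in the quarterly ASCII dialect. Extra columns are
# ignored; a missing required column is fatal. Matching is case-insensitive.
.faers_required_cols <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
           "age", "age_cod", "sex", "occr_country", "occp_cod"),
  drug = c("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "drug_seq", "indi_pt")
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

.days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  d[month == 2 & leap] <- 29L
  d
}

#' Classify raw date strings into partial dates
#'
#' FAERS date fields are digit strings of varying completeness: 8 digits
#' (`YYYYMMDD`, full day), 6 digits (`YYYYMM`, month known), or 4 digits
#' (`YYYY`, year only). Anything else, including calendar-impossible dates
#' such as `"20210230"`, is classified `invalid`; empty or `NA` input is
#' `missing`. Only day-precision dates ever take part in date arithmetic.
#'
#' @param raw character vector of raw date strings.
#' @return A tibble with one row per input: `raw`, `precision` (one of
#'   `"day"`, `"month"`, `"year"`, `"invalid"`, `"missing"`), and `date`
#'   (a `Date`, non-`NA` only for day precision).
#' @examples
#' parse_partial_date(c("20150101", "202101", "2021", "20210230", ""))
#' @export
parse_partial_date <- function(raw) {
  raw <- as.character(raw)
  raw[is.na(raw)] <- ""
  raw <- trimws(raw)
  n <- length(raw)
  precision <- rep("invalid", n)
  precision[raw == ""] <- "missing"

  is8 <- grepl("^[0-9]{8}$", raw)
  y <- suppressWarnings(as.integer(substr(raw, 1, 4)))
  m <- suppressWarnings(as.integer(substr(raw, 5, 6)))
  d <- suppressWarnings(as.integer(substr(raw, 7, 8)))
  ok_day <- is8 & !is.na(m) & m >= 1 & m <= 12
  ok_day[ok_day] <- d[ok_day] >= 1 & d[ok_day] <= .days_in_month(y[ok_day], m[ok_day])
  precision[ok_day] <- "day"

  is6 <- grepl("^[0-9]{6}$", raw)
  m6 <- suppressWarnings(as.integer(substr(raw, 5, 6)))
  precision[is6 & !is.na(m6) & m6 >= 1 & m6 <= 12] <- "month"
  precision[grepl("^[0-9]{4}$", raw)] <- "year"

  date <- rep(as.Date(NA), n)
  if (any(ok_day)) {
    date[ok_day] <- as.Date(sprintf("%04d-%02d-%02d", y[ok_day], m[ok_day], d[ok_day]))
  }
  tibble(raw = raw, precision = precision, date = date)
}

#' Normalise reported age to years
#'
#' Applies the unit code conversions `YR` x1, `DEC` x10, `MON` /12, `WK`
#' /52.143, `DY` /365.25, `HR` /8766. A missing unit code with a numeric age
#' is taken as years (the dominant convention in the data). Results outside
#' \[0, 120\] years are set missing as a sanity guard.
#'
#' @param age numeric or character vector of reported ages.
#' @param age_cod character vector of unit codes.
#' @return numeric vector of ages in years (`NA` where unusable).
#' @export
normalize_age_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(age_cod), "", age_cod)))
  factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.143,
              DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor[cod])
  f[cod == ""] <- 1
  out <- age * f
  out[!is.finite(out) | out < 0 | out > 120] <- NA_real_
  out
}

# Parse one '$'-delimited table file. The dialect has no quoting or escaping,
# so a plain split is exact; rows whose field count disagrees with the header
# are skipped and counted, never fatal. Encoding latin1 tolerates stray bytes.
.read_faers_table <- function(path, table) {
  required <- .faers_required_cols[[table]]
  lines <- readLines(path, encoding = "latin1", warn = FALSE)
  if (length(lines) == 0) {
    stop(sprintf("FAERS %s file '%s' is empty (no header)", toupper(table), path))
  }
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop(sprintf("FAERS %s file is missing required column(s): %s",
                 toupper(table), paste(missing_cols, collapse = ", ")))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  n_fields <- length(header)
  # sentinel keeps trailing empty fields from being dropped by strsplit
  parts <- strsplit(paste0(body, "$\r"), "$", fixed = TRUE)
  lens <- lengths(parts)
  good <- lens == n_fields + 1L
  n_skipped <- sum(!good)
  rows <- parts[good]
  if (length(rows) > 0) {
    mat <- matrix(unlist(rows, use.names = FALSE), ncol = n_fields + 1L, byrow = TRUE)
    mat <- mat[, seq_len(n_fields), drop = FALSE]
  } else {
    mat <- matrix(character(), ncol = n_fields, nrow = 0)
  }
  colnames(mat) <- header
  df <- as_tibble(mat[, required, drop = FALSE])
  df[df == ""] <- NA_character_
  list(rows = df, n_read = length(body), n_skipped = n_skipped)
}

.typed_quarter_table <- function(df, table) {
  log <- list(n_invalid_code = 0L)
  if (table == "demo") {
    df$caseversion <- suppressWarnings(as.integer(df$caseversion))
    df$age_years <- normalize_age_years(df$age, df$age_cod)
    df$sex <- toupper(trimws(df$sex))
    df$sex[!df$sex %in% c("F", "M", "UNK")] <- NA_character_
  } else if (table == "drug") {
    df$drug_seq <- suppressWarnings(as.integer(df$drug_seq))
    ok <- toupper(trimws(ifelse(is.na(df$role_cod), "", df$role_cod))) %in% .role_codes
    log$n_invalid_code <- sum(!ok)
    df <- df[ok, , drop = FALSE]
    df$role_cod <- toupper(trimws(df$role_cod))
  } else if (table == "outc") {
    ok <- toupper(trimws(ifelse(is.na(df$outc_cod), "", df$outc_cod))) %in% .outcome_codes
    log$n_invalid_code <- sum(!ok)
    df <- df[ok, , drop = FALSE]
    df$outc_cod <- toupper(trimws(df$outc_cod))
  } else if (table %in% c("ther", "indi")) {
    df$drug_seq <- suppressWarnings(as.integer(df$drug_seq))
  }
  list(rows = df, log = log)
}

#' Read one quarterly extract directory into typed tables
#'
#' Expects the six table files `DEMO<label>.txt`, `DRUG<label>.txt`,
#' `REAC<label>.txt`, `OUTC<label>.txt`, `THER<label>.txt`,
#' `INDI<label>.txt` plus an optional `DELETED<label>.txt` (one case id per
#' line) in the `$`-delimited dialect with a header row. Column order is
#' irrelevant; names match case-insensitively; extra columns are ignored.
#' Rows with a wrong field count or an unknown role/outcome code are skipped
#' and counted, never fatal. Child rows whose `primaryid` has no DEMO row
#' are kept but counted as orphans.
#'
#' @param directory path to the quarter directory.
#' @param quarter_label label embedded in the file names, e.g. `"21Q3"`.
#' @return A `faers_quarter`: a list with tibbles `demo`, `drug`, `reac`,
#'   `outc`, `ther`, `indi`, a character vector `deleted_caseids`, and a
#'   `log` of per-table row/skip/orphan counts.
#' @export
read_faers_quarter <- function(directory, quarter_label) {
  tables <- list()
  log <- list()
  for (tab in names(.faers_required_cols)) {
    path <- file.path(directory, paste0(toupper(tab), quarter_label, ".txt"))
    if (!file.exists(path)) {
      stop(sprintf("mandatory FAERS file not found: %s", path))
    }
    parsed <- .read_faers_table(path, tab)
    typed <- .typed_quarter_table(parsed$rows, tab)
    tables[[tab]] <- typed$rows
    log[[tab]] <- list(n_read = parsed$n_read,
                       n_skipped_malformed = parsed$n_skipped,
                       n_skipped_invalid_code = typed$log$n_invalid_code)
  }
  del_path <- file.path(directory, paste0("DELETED", quarter_label, ".txt"))
  deleted <- character()
  if (file.exists(del_path)) {
    deleted <- trimws(readLines(del_path, encoding = "latin1", warn = FALSE))
    deleted <- deleted[nzchar(deleted)]
  }
  demo_ids <- tables$demo$primaryid
  for (tab in c("drug", "reac", "outc", "ther", "indi")) {
    log[[tab]]$n_orphan <- sum(!tables[[tab]]$primaryid %in% demo_ids)
  }
  structure(c(tables, list(deleted_caseids = deleted, log = log)),
            class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter>\n")
  for (tab in names(.faers_required_cols)) {
    cat(sprintf("  %s: %d rows\n", toupper(tab), nrow(x[[tab]])))
  }
  cat(sprintf("  deleted case ids: %d\n", length(x$deleted_caseids)))
  invisible(x)
}

.write_faers_table <- function(df, cols, path) {
  df <- df[, cols, drop = FALSE]
  mat <- as.matrix(df)
  mat[is.na(mat)] <- ""
  lines <- c(paste(cols, collapse = "$"),
             apply(mat, 1L, paste, collapse = "$"))
  if (nrow(df) == 0) lines <- lines[1]
  writeLines(lines, path)
}

#' Write a quarter back to the `$`-delimited dialect
#'
#' Inverse of [read_faers_quarter()]: emits the six table files (and a
#' DELETED file when the quarter carries deleted case ids) so that a
#' read/write cycle is record-identical on valid rows. Output is byte-stable
#' for identical input.
#'
#' @param quarter a `faers_quarter` (or a compatible list of tibbles).
#' @param directory output directory, created if needed.
#' @param quarter_label label embedded in the file names.
#' @return the directory path, invisibly.
#' @export
write_faers_quarter <- function(quarter, directory, quarter_label) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(.faers_required_cols)) {
    .write_faers_table(quarter[[tab]], .faers_required_cols[[tab]],
                       file.path(directory, paste0(toupper(tab), quarter_label, ".txt")))
  }
  if (length(quarter$deleted_caseids) > 0) {
    writeLines(quarter$deleted_caseids,
               file.path(directory, paste0("DELETED", quarter_label, ".txt")))
  }
  invisible(directory)
}

#' Concatenate several quarters into one corpus
#'
#' Row-binds each table across quarters and unions the deleted case lists.
#' `primaryid` need not be unique afterwards; deduplication handles the
#' versioning.
#'
#' @param quarters list of `faers_quarter` objects.
#' @return a single `faers_quarter`.
#' @export
bind_faers_quarters <- function(quarters) {
  stopifnot(length(quarters) >= 1)
  out <- list()
  for (tab in names(.faers_required_cols)) {
    out[[tab]] <- dplyr::bind_rows(lapply(quarters, `[[`, tab))
  }
  out$deleted_caseids <- unique(unlist(lapply(quarters, `[[`, "deleted_caseids")))
  out$log <- lapply(quarters, `[[`, "log")
  structure(out, class = "faers_quarter")
}
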