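# Small hand-built fixtures used across test files.

demo_row <- function(primaryid, caseid, fda_dt = "20200101", event_dt = "20200101",
                     age = "60", age_cod = "YR", sex = "F", country = "US",
                     occp = "MD", caseversion = "1") {
  tibble::tibble(primaryid = primaryid, caseid = caseid, caseversion = caseversion,
                 fda_dt = fda_dt, event_dt = event_dt, age = age, age_cod = age_cod,
                 sex = sex, occr_country = country, occp_cod = occp,
                 age_years = faersignal::normalize_age_years(age, age_cod))
}

# a three-report quarter written as raw '$'-delimited text files
write_tiny_quarter <- function(dir, label = "21Q1", extra_drug_line = NULL,
                               shuffle_columns = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(name, lines) writeLines(lines, file.path(dir, paste0(name, label, ".txt")))
  demo_hdr <- "primaryid$caseid$caseversion$fda_dt$event_dt$age$age_cod$sex$occr_country$occp_cod"
  if (shuffle_columns) {
    w("DEMO", c("caseid$primaryid$caseversion$event_dt$fda_dt$age$age_cod$sex$occr_country$occp_cod",
                "1$101$1$20210110$20210201$64$YR$F$US$MD",
                "2$201$1$20210215$20210301$70$YR$M$JP$CN",
                "3$301$1$$20210401$$$F$FR$OT"))
  } else {
    w("DEMO", c(demo_hdr,
                "101$1$1$20210201$20210110$64$YR$F$US$MD",
                "201$2$1$20210301$20210215$70$YR$M$JP$CN",
                "301$3$1$20210401$$$$F$FR$OT"))
  }
  drug_lines <- c("primaryid$drug_seq$drugname$prod_ai$role_cod",
                  "101$1$LYNPARZA.$OLAPARIB$PS",
                  "101$2$ASPIRIN$ASPIRIN$C",
                  "201$1$ZEJULA$NIRAPARIB$PS",
                  "301$1$NIRAPARIB$NIRAPARIB$C")
  if (!is.null(extra_drug_line)) drug_lines <- c(drug_lines, extra_drug_line)
  w("DRUG", drug_lines)
  w("REAC", c("primaryid$pt", "101$Anaemia", "101$Nausea", "201$Thrombocytopenia",
              "301$Nausea"))
  w("OUTC", c("primaryid$outc_cod", "101$DE", "101$HO", "201$HO"))
  w("THER", c("primaryid$drug_seq$start_dt$end_dt",
              "101$1$20210101$20210301", "201$1$20210201$20210401"))
  w("INDI", c("primaryid$drug_seq$indi_pt", "101$1$Ovarian cancer",
              "201$1$Breast cancer", "301$1$Prostate cancer"))
  invisible(dir)
}

# random DEMO tables for deduplication fuzzing
random_demo <- function(n_cases, seed) {
  set.seed(seed)
  n_rows <- n_cases + rpois(1, n_cases / 2)
  caseid <- as.character(sample.int(n_cases, n_rows, replace = TRUE))
  tibble::tibble(
    primaryid = as.character(sample.int(10 * n_rows, n_rows)),
    caseid = caseid,
    fda_dt = format(as.Date("2020-01-01") + sample.int(400, n_rows, replace = TRUE),
                    "%Y%m%d")
  )
}

# config used where tests need a clean corpus with no pathologies
clean_config <- function(n_cases, seed, ...) {
  synth_config(n_cases = n_cases, seed = seed, duplicate_rate = 0,
               deleted_rate = 0, missing_date_rate = 0, partial_date_rate = 0,
               date_error_rate = 0, ...)
}

no_association <- tibble::tibble(drug = character(), pt = character(), rr = numeric())
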