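# Cohort schema, CSV input/output, validation, and study exclusions.
#
# One row = one child admitted to the PICU with septic shock. Day-1 values
# are taken from the first 24 h after meeting shock criteria; Day-3 serum
# creatinine defines the primary outcome; vital status is tracked to day 28.

#' Cohort column schema
#'
#' The documented CSV schema for a patient cohort. Booleans are serialized
#' as 0/1 and the empty string encodes a missing value.
#'
#' @return A data frame with columns `column`, `type`
#'   (`"character"`/`"numeric"`/`"integer"`/`"logical"`) and `optional`.
#' @export
cohort_schema <- function() {
  s <- rbind(
    c("patient_id",           "character", FALSE),
    c("age",                  "numeric",   FALSE),
    c("male",                 "logical",   FALSE),
    c("transplant_history",   "logical",   FALSE),
    c("height_cm",            "numeric",   TRUE),
    c("weight_kg",            "numeric",   FALSE),
    c("baseline_scr_known",   "numeric",   TRUE),
    c("d1_scr",               "numeric",   TRUE),
    c("d3_scr",               "numeric",   TRUE),
    c("d1_platelets",         "numeric",   FALSE),
    c("d1_fluid_in_L",        "numeric",   FALSE),
    c("d1_fluid_out_L",       "numeric",   FALSE),
    c("d1_mech_vent",         "logical",   FALSE),
    c("d1_vasoactive",        "logical",   FALSE),
    c("d1_vis",               "numeric",   FALSE),
    c("prism_iii",            "integer",   FALSE),
    c("persevere_ii",         "numeric",   FALSE),
    c("krt_day1",             "logical",   FALSE),
    c("krt_day1_7",           "logical",   FALSE),
    c("d3_krt",               "logical",   FALSE),
    c("picu_los_days",        "numeric",   FALSE),
    c("died_by_day28",        "logical",   FALSE),
    c("esrd_or_unknown_ckd",  "logical",   FALSE)
  )
  data.frame(column = s[, 1], type = s[, 2], optional = as.logical(s[, 3]),
             stringsAsFactors = FALSE)
}

# Per-row invariant messages; empty string when the row is clean.
# A value that is optional and missing is never a violation.
check_record_values <- function(df) {
  probs <- function(bad, msg) ifelse(!is.na(bad) & bad, msg, "")
  bad <- cbind(
    probs(df$age <= 0,                           "age must be > 0"),
    probs(df$weight_kg <= 0,                     "weight_kg must be > 0"),
    probs(df$height_cm <= 0,                     "height_cm must be > 0"),
    probs(df$baseline_scr_known <= 0,            "baseline_scr_known must be > 0"),
    probs(df$d1_scr <= 0,                        "d1_scr must be > 0"),
    probs(df$d3_scr <= 0,                        "d3_scr must be > 0"),
    probs(df$d1_platelets < 0,                   "d1_platelets must be >= 0"),
    probs(df$d1_fluid_in_L < 0,                  "d1_fluid_in_L must be >= 0"),
    probs(df$d1_fluid_out_L < 0,                 "d1_fluid_out_L must be >= 0"),
    probs(df$d1_vis < 0,                         "d1_vis must be >= 0"),
    probs(df$prism_iii < 0,                      "prism_iii must be >= 0"),
    probs(df$persevere_ii < 0 | df$persevere_ii > 1,
          "persevere_ii must be in [0,1]"),
    probs(df$picu_los_days < 0,                  "picu_los_days must be >= 0")
  )
  apply(bad, 1, function(r) paste(r[nzchar(r)], collapse = "; "))
}

parse_cohort_columns <- function(raw, schema) {
  out <- list()
  parse_errs <- character(nrow(raw))
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    v <- raw[[col]]
    v[!nzchar(trimws(v))] <- NA_character_
    v <- trimws(v)
    if (schema$type[i] == "character") {
      out[[col]] <- v
    } else if (schema$type[i] == "logical") {
      lg <- rep(NA, length(v))
      lg[v %in% c("1", "TRUE", "true", "T")] <- TRUE
      lg[v %in% c("0", "FALSE", "false", "F")] <- FALSE
      bad <- !is.na(v) & is.na(lg)
      parse_errs[bad] <- paste0(parse_errs[bad], col, " not a 0/1 boolean; ")
      out[[col]] <- lg
    } else {
      num <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & is.na(num)
      parse_errs[bad] <- paste0(parse_errs[bad], col, " not numeric; ")
      if (schema$type[i] == "integer") {
        frac <- !is.na(num) & num != floor(num)
        parse_errs[frac] <- paste0(parse_errs[frac], col, " not an integer; ")
      }
      out[[col]] <- num
    }
  }
  list(df = as.data.frame(out, stringsAsFactors = FALSE), parse_errs = parse_errs)
}

#' Validate an in-memory cohort table
#'
#' Applies the same schema and invariant checks as [read_cohort()].
#'
#' @param df A data frame with the columns of [cohort_schema()].
#' @param strict Error on the first violation (`TRUE`) or drop offending
#'   rows with a warning (`FALSE`).
#' @return The validated cohort (invisibly identical to `df` when clean).
#' @export
validate_cohort <- function(df, strict = TRUE) {
  schema <- cohort_schema()
  missing_cols <- setdiff(schema$column, names(df))
  if (length(missing_cols))
    abort("cohort is missing mandatory column(s): ",
          paste(missing_cols, collapse = ", "))
  df <- df[, schema$column]
  req <- schema$column[!schema$optional]
  miss <- vapply(req, function(col) is.na(df[[col]]), logical(nrow(df)))
  miss <- if (nrow(df) == 1L) matrix(miss, nrow = 1) else miss
  miss_msg <- apply(miss, 1, function(r)
    if (any(r)) paste0("missing required value(s): ",
                       paste(req[r], collapse = ", ")) else "")
  inv_msg <- check_record_values(df)
  msg <- trimws(paste(miss_msg, inv_msg, sep = "; "))
  msg <- sub("^;\\s*", "", sub(";\\s*$", "", msg))
  bad <- nzchar(msg)
  if (any(bad)) {
    lines <- paste0("row ", which(bad), " (patient_id=",
                    df$patient_id[bad], "): ", msg[bad])
    if (strict)
      abort("invalid cohort rows:\n", paste(lines, collapse = "\n"))
    warning(sum(bad), " invalid row(s) dropped:\n",
            paste(lines, collapse = "\n"), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a patient cohort from CSV
#'
#' Comma-separated, UTF-8, mandatory header; booleans as 0/1; empty string
#' means missing. Row order is preserved.
#'
#' @param path Path to the cohort CSV.
#' @param strict If `TRUE` (default) any invalid row aborts the read with a
#'   message naming the row, patient and field; if `FALSE` offending rows
#'   are dropped with a warning.
#' @return A validated cohort data frame (one row per patient).
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  schema <- cohort_schema()
  missing_cols <- setdiff(schema$column, names(raw))
  if (length(missing_cols))
    abort("cohort file is missing mandatory column(s): ",
          paste(missing_cols, collapse = ", "))
  parsed <- parse_cohort_columns(raw, schema)
  df <- parsed$df
  bad_parse <- nzchar(parsed$parse_errs)
  if (any(bad_parse)) {
    lines <- paste0("row ", which(bad_parse), " (patient_id=",
                    df$patient_id[bad_parse], "): ",
                    sub(";\\s*$", "", parsed$parse_errs[bad_parse]))
    if (strict)
      abort("unparseable cohort rows:\n", paste(lines, collapse = "\n"))
    warning(sum(bad_parse), " unparseable row(s) dropped:\n",
            paste(lines, collapse = "\n"), call. = FALSE)
    df <- df[!bad_parse, , drop = FALSE]
    rownames(df) <- NULL
  }
  validate_cohort(df, strict = strict)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: booleans become 0/1, missing values become
#' empty strings, numerics are written with 15 significant digits so a
#' round trip reproduces every field.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  schema <- cohort_schema()
  out <- cohort[, schema$column]
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    v <- out[[col]]
    chr <- if (schema$type[i] == "logical") {
      ifelse(is.na(v), "", ifelse(v, "1", "0"))
    } else if (schema$type[i] == "character") {
      ifelse(is.na(v), "", v)
    } else {
      ifelse(is.na(v), "", vapply(v, function(x)
        format(x, digits = 15, scientific = FALSE, trim = TRUE), character(1)))
    }
    out[[col]] <- chr
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the study exclusion criteria
#'
#' Removes patients with end-stage kidney disease or pre-existing kidney
#' disease without a known baseline creatinine, and patients missing Day-1
#' or Day-3 serum creatinine. A missing Day-3 creatinine excludes the
#' patient even when kidney replacement therapy was received, because the
#' creatinine-based Day-3 outcome is undefined for that row (the KRT-based
#' alternative is noted in the returned reason).
#'
#' @param cohort A validated cohort data frame.
#' @return A list with `included` (cohort rows retained), `excluded` (rows
#'   removed, with a `reason` column), and `counts` (n in, out, and per
#'   reason).
#' @export
apply_exclusions <- function(cohort) {
  reason <- rep(NA_character_, nrow(cohort))
  renal <- !is.na(cohort$esrd_or_unknown_ckd) & cohort$esrd_or_unknown_ckd
  reason[renal] <- "esrd_or_preexisting_kidney_disease_without_baseline"
  miss <- is.na(reason) & (is.na(cohort$d1_scr) | is.na(cohort$d3_scr))
  reason[miss] <- ifelse(cohort$krt_day1_7[miss],
                         "missing_d1_or_d3_scr (KRT received; SCr outcome undefined)",
                         "missing_d1_or_d3_scr")
  keep <- is.na(reason)
  excluded <- cohort[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  rownames(excluded) <- NULL
  included <- cohort[keep, , drop = FALSE]
  rownames(included) <- NULL
  list(
    included = included,
    excluded = excluded,
    counts = list(n_input = nrow(cohort),
                  n_included = nrow(included),
                  n_renal_history = sum(renal),
                  n_missing_scr = sum(miss))
  )
}

#' Load the published contingency counts
#'
#' The transcribed marginal counts of the validation study's published
#' tables: cohort size, Day-3 severe AKI cases, positives and true
#' positives for each Day-1 classifier, and secondary-outcome counts by
#' sRAI group and by AKI group. These margins are sufficient to rebuild
#' every 2x2 table behind the published diagnostic metrics and relative
#' risks.
#'
#' @return A list with elements `n_total`, `n_d3_aki`, `classifiers`
#'   (`srai`, `rai`, `d1scr`, each with `n_positive`, `n_true_positive`)
#'   and `outcomes` (event counts by group).
#' @export
load_printed_fixture <- function() {
  path <- system.file("extdata", "printed_counts.json", package = "srai",
                      mustWork = TRUE)
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (cl in names(fx$classifiers)) {
    c0 <- fx$classifiers[[cl]]
    stopifnot(c0$n_true_positive <= min(c0$n_positive, fx$n_d3_aki),
              c0$n_positive <= fx$n_total)
  }
  stopifnot(fx$n_d3_aki <= fx$n_total)
  fx
}
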