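# Readers, writers and validators for the three tabular inputs.
#
# All files are comma-separated UTF-8 with a header row and "." as the decimal
# mark; no locale handling. A patient table is an ordinary data frame with
# columns patient_id, sex, age_at_index, label, bmi and one 0/1 column per
# dictionary feature.

SEX_LEVELS <- c("F", "M")
LABEL_LEVELS <- c("case", "control")
VOCAB_LEVELS <- c("ICD9CM", "ICD10CM")

#' Read and validate a patient table
#'
#' Reads the cohort CSV (one row per subject) and enforces the domain
#' invariants: required columns present, ages at least 18 years, unique
#' patient ids, sex in `{F, M}`, label in `{case, control}`. Missing BMI is
#' preserved as `NA`; missing feature cells default to 0 (absence-of-code
#' semantics) with a logged count.
#'
#' @param path Path to a CSV with columns `patient_id`, `sex`, `age_at_index`,
#'   `label`, optionally `bmi`, and the feature columns named in `dict`.
#' @param dict A [feature_dictionary()]; feature columns absent from the file
#'   are created as all-zero (logged).
#' @return A data frame with one row per subject, `sex` and `label` as
#'   factors, and a 0/1 integer column per dictionary feature.
#' @export
read_patient_table <- function(path, dict = feature_dictionary()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "sex", "age_at_index", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_strokeage("patient table schema error: missing column(s) %s",
                   paste(missing_cols, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    dups <- unique(df$patient_id[duplicated(df$patient_id)])
    stop_strokeage("duplicate patient_id(s): %s",
                   paste(utils::head(dups, 5), collapse = ", "))
  }
  bad_sex <- setdiff(unique(df$sex), SEX_LEVELS)
  if (length(bad_sex)) {
    stop_strokeage("sex must be one of {F, M}; found: %s",
                   paste(bad_sex, collapse = ", "))
  }
  bad_label <- setdiff(unique(df$label), LABEL_LEVELS)
  if (length(bad_label)) {
    stop_strokeage("label must be one of {case, control}; found: %s",
                   paste(bad_label, collapse = ", "))
  }
  if (!is.numeric(df$age_at_index)) {
    df$age_at_index <- suppressWarnings(as.numeric(df$age_at_index))
  }
  young <- !is.na(df$age_at_index) & df$age_at_index < 18
  if (any(young) || anyNA(df$age_at_index)) {
    off <- df$patient_id[young | is.na(df$age_at_index)]
    stop_strokeage("age_at_index must be >= 18 and non-missing; offending id(s): %s",
                   paste(utils::head(off, 10), collapse = ", "))
  }
  if (!"bmi" %in% names(df)) df$bmi <- NA_real_
  df$bmi <- suppressWarnings(as.numeric(df$bmi))
  df$sex <- factor(df$sex, levels = SEX_LEVELS)
  df$label <- factor(df$label, levels = LABEL_LEVELS)

  n_defaulted <- 0L
  for (f in dict$name) {
    if (!f %in% names(df)) {
      df[[f]] <- 0L
      n_defaulted <- n_defaulted + nrow(df)
    } else {
      v <- suppressWarnings(as.integer(df[[f]]))
      n_defaulted <- n_defaulted + sum(is.na(v))
      v[is.na(v)] <- 0L
      if (!all(v %in% c(0L, 1L))) {
        stop_strokeage("feature column '%s' must be 0/1", f)
      }
      df[[f]] <- v
    }
  }
  if (n_defaulted > 0) {
    log_msg("patient table: %d missing feature cell(s) defaulted to 0", n_defaulted)
  }
  df <- df[c("patient_id", "sex", "age_at_index", "label", "bmi", dict$name)]
  log_msg("read %d patient record(s) from %s", nrow(df), path)
  df
}

#' Write a patient table
#'
#' Inverse of [read_patient_table()]: missing BMI is written as an empty cell
#' so a round-trip preserves missingness.
#'
#' @param patients Patient data frame.
#' @param path Output CSV path.
#' @export
write_patient_table <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a long-format diagnosis table
#'
#' Reads one row per (patient, diagnosis code) event. Events dated after the
#' index encounter (`days_before_index < 0`) are dropped with a logged count;
#' same-day events (`days_before_index == 0`) are retained, since index-day
#' diagnoses encode the presenting comorbidity profile.
#'
#' @param path CSV with columns `patient_id`, `vocabulary`, `code`,
#'   `days_before_index`.
#' @return Data frame of retained events; attribute `n_dropped` records the
#'   post-index exclusions.
#' @export
read_diagnosis_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "vocabulary", "code", "days_before_index")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_strokeage("diagnosis table schema error: missing column(s) %s",
                   paste(missing_cols, collapse = ", "))
  }
  bad_vocab <- setdiff(unique(df$vocabulary), VOCAB_LEVELS)
  if (length(bad_vocab)) {
    stop_strokeage("unknown vocabulary value(s): %s (expected ICD9CM/ICD10CM)",
                   paste(bad_vocab, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  df$code <- as.character(df$code)
  df$days_before_index <- as.integer(df$days_before_index)
  post <- df$days_before_index < 0
  n_dropped <- sum(post)
  if (n_dropped > 0) {
    log_msg("diagnosis table: dropped %d post-index event(s)", n_dropped)
  }
  df <- df[!post, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  log_msg("read %d pre-index diagnosis event(s) from %s", nrow(df), path)
  df
}

#' @rdname read_diagnosis_table
#' @param events Diagnosis event data frame.
#' @export
write_diagnosis_table <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ICD-to-Phecode mapping table
#'
#' One row per (vocabulary, code, phecode) triple; many-to-many mappings are
#' supported and duplicate rows deduplicated. Codes absent from the map simply
#' map to the empty set at lookup time.
#'
#' @param path CSV with columns `vocabulary`, `code`, `phecode`.
#' @return A data frame of class `phecode_map`.
#' @export
read_phecode_map <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop_strokeage("cannot read phecode map %s: %s",
                                       path, conditionMessage(e))
  )
  required <- c("vocabulary", "code", "phecode")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_strokeage("phecode map schema error: missing column(s) %s",
                   paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop_strokeage("phecode map %s is empty", path)
  malformed <- which(!nzchar(df$code) | !nzchar(df$phecode) |
                       !df$vocabulary %in% VOCAB_LEVELS)
  if (length(malformed)) {
    stop_strokeage("phecode map: malformed row(s) at line(s) %s",
                   paste(utils::head(malformed + 1L, 5), collapse = ", "))
  }
  df <- unique(df[required])
  rownames(df) <- NULL
  class(df) <- c("phecode_map", "data.frame")
  log_msg("read phecode map: %d mapping row(s), %d distinct phecode(s)",
          nrow(df), length(unique(df$phecode)))
  df
}

#' @rdname read_phecode_map
#' @param map A `phecode_map` data frame.
#' @export
write_phecode_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up the phecodes for a diagnosis code
#'
#' @param map A `phecode_map`.
#' @param vocabulary `"ICD9CM"` or `"ICD10CM"`.
#' @param code Diagnosis code string.
#' @return Character vector of phecodes (possibly empty), sorted.
#' @export
phecode_lookup <- function(map, vocabulary, code) {
  hit <- map$vocabulary == vocabulary & map$code == code
  sort(unique(map$phecode[hit]))
}
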