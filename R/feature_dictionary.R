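#' Clinical feature dictionary
#'
#' The default dictionary of 23 binary clinical variables used by the
#' age-bracketed classifier grid and the prevalence tables. The set mixes
#' traditional vascular risk factors (hypertension, dyslipidemia, diabetes,
#' atrial fibrillation, ...) with rarer etiologies that predominantly afflict
#' younger stroke patients (patent foramen ovale, migraine, cervicocephalic
#' dissection, hypercoagulable state). Each entry carries a display name and a
#' capture-window tag describing when the variable is ascertained relative to
#' the index encounter: `"at-index"`, `"three-month-buffer"` (conditions whose
#' definitive diagnosis may follow discharge), or `"any-time"` (lifelong
#' conditions such as fibromuscular dysplasia).
#'
#' Window tags are metadata only: upstream extraction is expected to have
#' applied them, so they are configurable rather than enforced here.
#'
#' @param features Optional data frame overriding the default dictionary; must
#'   have columns `name`, `display`, `window` with unique names.
#' @return A data frame of class `feature_dictionary` with columns `name`,
#'   `display`, `window`.
#' @examples
#' dict <- feature_dictionary()
#' nrow(dict) # 23
#' @export
feature_dictionary <- function(features = NULL) {
  if (is.null(features)) {
    features <- data.frame(
      name = c(
        "hypertension", "dyslipidemia", "diabetes", "atrial_fibrillation",
        "myocardial_infarction", "heart_failure", "chronic_kidney_disease",
        "neoplasm", "rheumatic_disease", "mood_disorder", "smoking_current",
        "alcohol_abuse", "drug_abuse", "giant_cell_arteritis", "vasculitis",
        "sickle_cell_disease", "arteriopathy", "fibromuscular_dysplasia",
        "pfo", "migraine", "cervicocephalic_dissection",
        "hypercoagulable_state", "bmi_overweight"
      ),
      display = c(
        "Hypertension", "Dyslipidemia", "Diabetes mellitus",
        "Atrial fibrillation", "Myocardial infarction", "Heart failure",
        "Chronic kidney disease", "Neoplasm", "Rheumatic disease",
        "Mood disorder", "Current smoking", "Alcohol abuse or dependence",
        "Drug abuse or dependence", "Giant cell arteritis", "Vasculitis",
        "Sickle cell disease", "Arteriopathy", "Fibromuscular dysplasia",
        "Patent foramen ovale", "Migraine", "Cervicocephalic dissection",
        "Hypercoagulable state", "Overweight (BMI > 25)"
      ),
      window = c(
        "at-index", "at-index", "at-index", "at-index",
        "at-index", "at-index", "at-index",
        "any-time", "any-time", "any-time", "at-index",
        "any-time", "any-time", "three-month-buffer", "three-month-buffer",
        "any-time", "three-month-buffer", "any-time",
        "three-month-buffer", "any-time", "three-month-buffer",
        "three-month-buffer", "at-index"
      ),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(features),
            all(c("name", "display", "window") %in% names(features)))
  if (anyDuplicated(features$name)) {
    stop_strokeage("feature dictionary names must be unique")
  }
  bad <- setdiff(unique(features$window),
                 c("at-index", "three-month-buffer", "any-time"))
  if (length(bad)) {
    stop_strokeage("unknown capture-window tag(s): %s",
                   paste(bad, collapse = ", "))
  }
  class(features) <- c("feature_dictionary", "data.frame")
  features
}

#' @export
print.feature_dictionary <- function(x, ...) {
  cat(sprintf("Clinical feature dictionary: %d variables\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
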