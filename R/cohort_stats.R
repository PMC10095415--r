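# Descriptive layer: case/control prevalence comparisons per bracket, BMI
# dichotomization, and single-variable PMM imputation of missing BMI.

#' Compare case/control prevalence in a 2x2 table
#'
#' Pearson's chi-squared test (no continuity correction by default) when
#' every expected cell count is at least `expected_min` (default 5),
#' otherwise Fisher's exact test (two-sided). A table with a zero row or
#' column margin is degenerate: the comparison carries no information and
#' `p = 1` is returned with a warning. Significance at 0.05 is recorded
#' downstream but never filters output.
#'
#' The uncorrected statistic approximates Fisher's mid-p; set
#' `correct = TRUE` for the Yates-corrected version, which tracks the
#' ordinary two-sided Fisher p closely on balanced tables.
#'
#' @param a,b Case counts: exposed, unexposed.
#' @param c,d Control counts: exposed, unexposed.
#' @param expected_min Expected-count threshold for the Fisher fallback.
#' @param correct Apply the continuity correction (default `FALSE`).
#' @return List: `test_used` (`"chi2"` or `"fisher"`), `statistic`
#'   (chi-squared only, else `NA`), `p_value`.
#' @examples
#' compare_prevalence(10, 20, 20, 10) # chi2, X^2 ~ 6.667, p ~ 0.0098
#' @export
compare_prevalence <- function(a, b, c, d, expected_min = 5,
                               correct = FALSE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1", call. = FALSE)
    return(list(test_used = "chi2", statistic = 0, p_value = 1))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= expected_min)) {
    ht <- stats::chisq.test(tab, correct = correct)
    list(test_used = "chi2", statistic = unname(ht$statistic),
         p_value = unname(ht$p.value))
  } else {
    ht <- stats::fisher.test(tab)
    list(test_used = "fisher", statistic = NA_real_,
         p_value = unname(ht$p.value))
  }
}

#' Dichotomize BMI
#'
#' `"normal"` if BMI is at most 25 kg/m^2, `"overweight"` above. Missing
#' values must be imputed first ([impute_bmi()]).
#'
#' @param bmi Numeric BMI values (kg/m^2), positive, non-missing.
#' @return Character vector `"normal"`/`"overweight"`.
#' @export
dichotomize_bmi <- function(bmi) {
  if (anyNA(bmi)) stop_strokeage("missing BMI: impute before dichotomizing")
  if (any(bmi <= 0)) stop_strokeage("BMI must be positive")
  ifelse(bmi <= 25, "normal", "overweight")
}

#' Impute missing BMI by predictive mean matching
#'
#' Single-variable chained-equation imputation: BMI is regressed on sex, age
#' at index and the clinical features over the complete records; for each
#' missing value, `m` donor draws are taken from the `k` complete records
#' whose predicted BMI is nearest the recipient's prediction, and the final
#' imputed value is the median of the draws. Observed values are never
#' altered; every imputed id is logged. The `bmi_overweight` feature column,
#' if present, is refreshed from the completed BMI.
#'
#' @param patients Patient data frame.
#' @param m Number of donor draws per missing value (default 5).
#' @param k Donor pool size per draw (default 5 nearest by predicted BMI).
#' @param seed Integer seed.
#' @param dict Feature dictionary (predictors for the matching model).
#' @return Completed patient data frame; attribute `imputed_ids` lists the
#'   patients whose BMI was filled in.
#' @export
impute_bmi <- function(patients, m = 5L, k = 5L, seed = 1L,
                       dict = feature_dictionary()) {
  miss <- is.na(patients$bmi)
  if (!any(miss)) return(patients)
  if (all(miss)) stop_strokeage("all BMI values are missing; cannot impute")
  if (mean(miss) >= 0.20) {
    stop_strokeage("BMI missingness %.1f%% >= 20%%: imputation unsupported",
                   100 * mean(miss))
  }
  if (sum(!miss) < 50) {
    stop_strokeage("need >= 50 complete BMI records, have %d", sum(!miss))
  }
  preds <- setdiff(dict$name, "bmi_overweight")
  preds <- intersect(preds, names(patients))
  form <- stats::reformulate(c("sex", "age_at_index", preds), response = "bmi")
  fit <- stats::lm(form, data = patients[!miss, , drop = FALSE])
  yhat_obs <- stats::predict(fit, newdata = patients[!miss, , drop = FALSE])
  yhat_mis <- stats::predict(fit, newdata = patients[miss, , drop = FALSE])
  donors <- patients$bmi[!miss]

  with_seed(seed, {
    imputed <- vapply(yhat_mis, function(yh) {
      nearest <- order(abs(yhat_obs - yh))[seq_len(min(k, length(donors)))]
      stats::median(donors[sample(nearest, m, replace = TRUE)])
    }, numeric(1))
    patients$bmi[miss] <- imputed
  })
  if ("bmi_overweight" %in% names(patients)) {
    patients$bmi_overweight <-
      as.integer(dichotomize_bmi(patients$bmi) == "overweight")
  }
  ids <- patients$patient_id[miss]
  log_msg("imputed BMI for %d patient(s)", length(ids))
  attr(patients, "imputed_ids") <- ids
  patients
}

#' Per-bracket prevalence table
#'
#' For every feature x sex x bracket cell, counts and percentages of exposed
#' cases and controls with the chi-squared/Fisher comparison of
#' [compare_prevalence()]. A Benjamini-Hochberg adjusted p-value column is
#' emitted alongside the raw one for reference; nothing is filtered on it.
#'
#' @param patients Patient data frame.
#' @param brackets Numeric upper ages; `Inf` rows are labeled `"all"`.
#' @param sexes Subset of `c("F", "M")`.
#' @param dict Feature dictionary.
#' @param filter_controls Passed to [make_bracket()].
#' @return Data frame: `feature`, `sex`, `bracket`, `case_count`,
#'   `case_pct`, `control_count`, `control_pct`, `test_used`, `p_value`,
#'   `p_adjusted`.
#' @export
prevalence_table <- function(patients, brackets = c(default_brackets(), Inf),
                             sexes = SEX_LEVELS, dict = feature_dictionary(),
                             filter_controls = TRUE) {
  rows <- list()
  for (sex in sexes) {
    for (upper in brackets) {
      d <- make_bracket(patients, upper, sex,
                        filter_controls = filter_controls)
      n_case <- sum(d$label == "case")
      n_control <- sum(d$label == "control")
      for (f in dict$name) {
        a <- sum(d[[f]][d$label == "case"])
        c_ <- sum(d[[f]][d$label == "control"])
        cmp <- suppressWarnings(
          compare_prevalence(a, n_case - a, c_, n_control - c_)
        )
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, sex = sex,
          bracket = if (is.finite(upper)) paste0("<", upper) else "all",
          case_count = a, case_pct = 100 * a / n_case,
          control_count = c_, control_pct = 100 * c_ / n_control,
          test_used = cmp$test_used, p_value = cmp$p_value,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
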