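# Seeded synthetic EHR cohort with a planted change-point age.
#
# The generator emulates the structure the estimators consume: case ages
# skewed old (Beta-shaped) and control ages near-uniform over 18-95; binary
# comorbidities drawn Bernoulli with a log-odds-linear age trend plus a case
# effect; a subset of "young-profile" features (PFO-like, migraine-like,
# dissection-like, hypercoagulable-like) whose case prevalence carries an
# extra log-odds bump below the planted cut-point age tau; continuous BMI
# with MCAR missingness; and per-phenotype ICD-like code emission through a
# toy phecode map. The change-point enters only through case feature
# prevalence, so controls carry no step.

#' Default per-feature generative model
#'
#' One row per dictionary feature: control prevalence at age 50
#' (`baseline`), case odds multiplier (`case_or`), log-odds age slope per
#' year (`age_slope`), and the `young_profile` flag marking the four
#' rare-etiology features that receive the extra below-tau case bump.
#' Baselines sit at the levels common in emergency-department cohorts
#' (hypertension-like near 35%, rare arteriopathies below 3%); slopes are
#' deliberately gentle (at most 0.004 log-odds per year) so that the planted
#' change-point remains the single dominant age effect — the generator's
#' purpose is a recoverable discontinuity, not a faithful reproduction of
#' real comorbidity gradients (see the methods vignette for the trade-off).
#' `bmi_overweight` is derived from the continuous BMI draw rather than this
#' logistic model.
#'
#' @return Data frame: `name`, `baseline`, `case_or`, `age_slope`,
#'   `young_profile`.
#' @export
default_feature_model <- function() {
  data.frame(
    name = feature_dictionary()$name,
    baseline = c(0.35, 0.30, 0.18, 0.08, 0.06, 0.07, 0.08, 0.06, 0.05,
                 0.28, 0.22, 0.08, 0.06, 0.012, 0.018, 0.006, 0.025, 0.010,
                 0.20, 0.25, 0.10, 0.15, NA),
    case_or = c(2.2, 1.8, 1.6, 2.0, 1.6, 1.6, 1.4, 1.3, 1.0,
                1.0, 1.2, 1.0, 1.2, 1.0, 1.3, 1.2, 1.5, 1.5,
                1.5, 1.2, 2.0, 1.8, NA),
    age_slope = c(0.004, 0.003, 0.002, 0.004, 0.003, 0.003, 0.003, 0.002,
                  0.001, 0.000, -0.001, -0.001, -0.002, 0.001, 0.000,
                  -0.001, 0.000, -0.001, -0.002, -0.002, -0.002, -0.001, NA),
    young_profile = feature_dictionary()$name %in%
      c("pfo", "migraine", "cervicocephalic_dissection",
        "hypercoagulable_state"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Validated bundle of every generator parameter. Defaults plant the
#' change-point at 53 years (female) and 52 years (male) with a +2.0
#' log-odds young-profile bump, 3000 cases and 3000 controls per sex, and
#' 2.3% MCAR missingness on BMI.
#'
#' @param n_cases,n_controls Total subjects per class (split by `sex_ratio`).
#' @param sex_ratio Fraction female, in (0, 1).
#' @param age_range Years, default `c(18, 95)`.
#' @param tau_f,tau_m Planted cut-point ages, inside `age_range`.
#' @param young_shift Extra case log-odds for young-profile features below
#'   tau.
#' @param features Feature model data frame ([default_feature_model()]).
#' @param n_noise_phenotypes Extra label-independent phenotypes emitted into
#'   the diagnosis stream (they widen the phecode space the way incidental
#'   comorbidities do).
#' @param noise_slope_range Range of the noise phenotypes' log-odds age
#'   slopes (drawn uniformly; symmetric about zero by default so the noise
#'   stream adds no net age gradient). Set to `c(0, 0)` for an
#'   age-exchangeable noise stream.
#' @param codes_per_phenotype ICD-like codes per phenotype in the toy map.
#' @param code_emit_prob Per-code emission probability for an active
#'   phenotype (at least one code is always emitted).
#' @param case_age_shape,control_age_shape Beta shape pairs for the age
#'   densities over `age_range`: cases skewed old, controls near-uniform.
#' @param bmi_mean,bmi_sd,bmi_case_shift,bmi_missing Continuous BMI model:
#'   Gaussian mean/sd (kg/m^2), additive case shift, MCAR missing fraction.
#' @param seed Master seed; every component draws from a derived substream.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 6000L, n_controls = 6000L,
                          sex_ratio = 0.5, age_range = c(18, 95),
                          tau_f = 53, tau_m = 52, young_shift = 2.0,
                          features = default_feature_model(),
                          case_age_shape = c(3.2, 1.6),
                          control_age_shape = c(1.2, 1.2),
                          n_noise_phenotypes = 30L,
                          noise_slope_range = c(-0.015, 0.015),
                          codes_per_phenotype = 3L, code_emit_prob = 0.7,
                          bmi_mean = 27.5, bmi_sd = 5, bmi_case_shift = 0.8,
                          bmi_missing = 0.023, seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              sex_ratio = sex_ratio, age_range = as.numeric(age_range),
              tau_f = tau_f, tau_m = tau_m, young_shift = young_shift,
              features = features,
              case_age_shape = as.numeric(case_age_shape),
              control_age_shape = as.numeric(control_age_shape),
              n_noise_phenotypes = as.integer(n_noise_phenotypes),
              noise_slope_range = as.numeric(noise_slope_range),
              codes_per_phenotype = as.integer(codes_per_phenotype),
              code_emit_prob = code_emit_prob,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              bmi_case_shift = bmi_case_shift, bmi_missing = bmi_missing,
              seed = as.integer(seed))
  problems <- character(0)
  if (cfg$n_cases < 2 || cfg$n_controls < 0) {
    problems <- c(problems, "n_cases must be >= 2 and n_controls >= 0")
  }
  if (!(cfg$sex_ratio > 0 && cfg$sex_ratio < 1)) {
    problems <- c(problems, "sex_ratio must lie in (0, 1)")
  }
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0 ||
      cfg$age_range[1] < 18) {
    problems <- c(problems, "age_range must be increasing with minimum >= 18")
  }
  for (tau in c(cfg$tau_f, cfg$tau_m)) {
    if (tau <= cfg$age_range[1] || tau >= cfg$age_range[2]) {
      problems <- c(problems, "tau must lie strictly inside age_range")
    }
  }
  pv <- cfg$features$baseline[!is.na(cfg$features$baseline)]
  if (any(pv <= 0 | pv >= 1)) {
    problems <- c(problems, "feature baselines must lie in (0, 1)")
  }
  if (length(cfg$case_age_shape) != 2 || any(cfg$case_age_shape <= 0) ||
      length(cfg$control_age_shape) != 2 || any(cfg$control_age_shape <= 0)) {
    problems <- c(problems, "age shape parameters must be positive pairs")
  }
  if (!(cfg$code_emit_prob > 0 && cfg$code_emit_prob <= 1)) {
    problems <- c(problems, "code_emit_prob must lie in (0, 1]")
  }
  if (cfg$bmi_missing < 0 || cfg$bmi_missing >= 1) {
    problems <- c(problems, "bmi_missing must lie in [0, 1)")
  }
  if (length(problems)) {
    stop_strokeage("invalid cohort configuration:\n  - %s",
                   paste(problems, collapse = "\n  - "))
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d cases / %d controls, tau F/M = %g/%g, young_shift = %g, seed = %d\n",
    x$n_cases, x$n_controls, x$tau_f, x$tau_m, x$young_shift, x$seed))
  invisible(x)
}

#' Toy ICD-to-phecode map
#'
#' Synthetic ICD-like codes (alternating ICD9CM/ICD10CM vocabularies), each
#' mapping to exactly one phecode, with disjoint code sets per phecode.
#'
#' @param n_phenotypes Number of phecodes (or a character vector of phecode
#'   names).
#' @param codes_per_phenotype Codes mapped to each phecode.
#' @param seed Integer seed (the map itself is deterministic in its inputs;
#'   the seed is reserved for future stochastic variants).
#' @return A `phecode_map` data frame.
#' @export
make_toy_phecode_map <- function(n_phenotypes, codes_per_phenotype = 3L,
                                 seed = 1L) {
  phecodes <- if (is.character(n_phenotypes)) {
    n_phenotypes
  } else {
    sprintf("PH%03d", seq_len(n_phenotypes))
  }
  stopifnot(length(phecodes) >= 1, codes_per_phenotype >= 1)
  rows <- expand.grid(j = seq_len(codes_per_phenotype),
                      i = seq_along(phecodes))
  df <- data.frame(
    vocabulary = ifelse(rows$j %% 2 == 1, "ICD10CM", "ICD9CM"),
    code = sprintf("S%03d.%d", rows$i, rows$j),
    phecode = phecodes[rows$i],
    stringsAsFactors = FALSE
  )
  class(df) <- c("phecode_map", "data.frame")
  df
}

#' Simulate a synthetic cohort
#'
#' Draws patients, clinical features, continuous BMI and a pre-index
#' diagnosis stream from a [cohort_config()]. Case ages follow a Beta-shaped
#' density over the age range (default Beta(3.2, 1.6): strongly skewed old,
#' as stroke onset is); controls are near-uniform (Beta(1.2, 1.2)). Each
#' binary feature is Bernoulli with
#' `logit(p) = logit(baseline) + case * log(case_or) + age_slope * (age - 50)
#'  + [young_profile & case & age < tau_sex] * young_shift`.
#' Every active phenotype (the 22 modeled features plus the noise
#' phenotypes) emits a subset of its toy-map codes as pre-index diagnosis
#' events. Fully deterministic given the config seed: each component draws
#' from its own derived substream.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `patients`, `diagnoses`,
#'   `phecode_map`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  fm <- config$features
  modeled <- fm[!is.na(fm$baseline), , drop = FALSE]
  lo <- config$age_range[1]; hi <- config$age_range[2]

  n <- config$n_cases + config$n_controls
  label <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  sex <- c(
    rep(c("F", "M"), c(round(config$n_cases * config$sex_ratio),
                       config$n_cases - round(config$n_cases * config$sex_ratio))),
    rep(c("F", "M"), c(round(config$n_controls * config$sex_ratio),
                       config$n_controls - round(config$n_controls * config$sex_ratio)))
  )
  age <- with_seed(sub_seed(config$seed, 1L), {
    ca <- config$case_age_shape; co <- config$control_age_shape
    u <- ifelse(label == "case",
                stats::rbeta(n, ca[1], ca[2]),
                stats::rbeta(n, co[1], co[2]))
    lo + (hi - lo) * u
  })
  tau <- ifelse(sex == "F", config$tau_f, config$tau_m)
  is_case <- label == "case"

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = factor(sex, levels = SEX_LEVELS),
    age_at_index = age,
    label = factor(label, levels = LABEL_LEVELS),
    bmi = NA_real_,
    stringsAsFactors = FALSE
  )

  feat_mat <- with_seed(sub_seed(config$seed, 2L), {
    vapply(seq_len(nrow(modeled)), function(j) {
      row <- modeled[j, ]
      eta <- stats::qlogis(row$baseline) +
        is_case * log(row$case_or) +
        row$age_slope * (age - 50) +
        (row$young_profile & is_case & age < tau) * config$young_shift
      stats::rbinom(n, 1L, stats::plogis(eta))
    }, integer(n))
  })
  colnames(feat_mat) <- modeled$name
  for (f in modeled$name) patients[[f]] <- feat_mat[, f]

  with_seed(sub_seed(config$seed, 3L), {
    bmi_true <- stats::rnorm(n, config$bmi_mean + is_case * config$bmi_case_shift,
                             config$bmi_sd)
    bmi_true <- pmax(bmi_true, 14)
    patients$bmi_overweight <- as.integer(bmi_true > 25)
    drop_mask <- stats::runif(n) < config$bmi_missing
    patients$bmi <- ifelse(drop_mask, NA_real_, round(bmi_true, 1))
  })
  patients <- patients[c("patient_id", "sex", "age_at_index", "label", "bmi",
                         fm$name)]

  # phenotype space: modeled features + label-independent noise phenotypes
  noise_names <- if (config$n_noise_phenotypes > 0) {
    sprintf("NOISE%03d", seq_len(config$n_noise_phenotypes))
  } else {
    character(0)
  }
  phecode_names <- c(paste0("PH_", modeled$name), noise_names)
  map <- make_toy_phecode_map(phecode_names, config$codes_per_phenotype)

  diagnoses <- with_seed(sub_seed(config$seed, 4L), {
    noise_mat <- if (length(noise_names)) {
      # label-independent incidental phenotypes; the default slope range is
      # symmetric about zero so the stream adds no net age gradient
      base <- stats::runif(length(noise_names), 0.02, 0.25)
      slope <- stats::runif(length(noise_names), config$noise_slope_range[1],
                            config$noise_slope_range[2])
      vapply(seq_along(noise_names), function(j) {
        stats::rbinom(n, 1L,
                      stats::plogis(stats::qlogis(base[j]) + slope[j] * (age - 50)))
      }, integer(n))
    } else {
      matrix(0L, n, 0)
    }
    active <- cbind(feat_mat, noise_mat)
    colnames(active) <- phecode_names
    hits <- which(active == 1L, arr.ind = TRUE)
    # each active phenotype emits each of its codes with code_emit_prob,
    # always at least one
    k <- config$codes_per_phenotype
    emit <- matrix(stats::runif(nrow(hits) * k) < config$code_emit_prob,
                   nrow(hits), k)
    none <- rowSums(emit) == 0
    if (any(none)) {
      emit[cbind(which(none), sample.int(k, sum(none), replace = TRUE))] <- TRUE
    }
    sel <- which(emit, arr.ind = TRUE)
    # map rows are laid out code-within-phecode, so row = (i - 1) * k + j
    map_row <- (hits[sel[, 1], "col"] - 1L) * k + sel[, 2]
    data.frame(
      patient_id = patients$patient_id[hits[sel[, 1], "row"]],
      vocabulary = map$vocabulary[map_row],
      code = map$code[map_row],
      days_before_index = sample(0:3650, nrow(sel), replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$code), ]
  rownames(diagnoses) <- NULL

  structure(list(patients = patients, diagnoses = diagnoses,
                 phecode_map = map, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patients (%d cases), %d diagnosis events, %d phecodes\n",
    nrow(x$patients), sum(x$patients$label == "case"),
    nrow(x$diagnoses), length(unique(x$phecode_map$phecode))))
  invisible(x)
}
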