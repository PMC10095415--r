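# High-level pipeline stages. Each run_* function chains the module
# operations, optionally writes the stage's output files into out_dir, and
# drops a JSON run manifest (config snapshot, seed, input digests, package
# version, per-stage row counts and timings) for auditability.

write_manifest <- function(out_dir, stage, config, seed, inputs, counts,
                           started, partial = FALSE) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("strokeage")),
    seed = seed,
    config = config,
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(unlist(inputs)))
    } else {
      list()
    },
    row_counts = counts,
    elapsed_seconds = round(as.numeric(Sys.time()) - started, 3),
    partial = partial,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a cohort and write its three input files
#'
#' @param config A [cohort_config()], or a path to a YAML/JSON file whose
#'   fields override the defaults.
#' @param out_dir Output directory (created if needed); receives
#'   `patients.csv`, `diagnoses.csv`, `phecode_map.csv` and `manifest.json`.
#' @return The `synthetic_cohort`, invisibly.
#' @export
run_simulate <- function(config = cohort_config(), out_dir) {
  started <- as.numeric(Sys.time())
  if (is.character(config)) config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  write_patient_table(cohort$patients, file.path(out_dir, "patients.csv"))
  write_diagnosis_table(cohort$diagnoses, file.path(out_dir, "diagnoses.csv"))
  write_phecode_map(cohort$phecode_map, file.path(out_dir, "phecode_map.csv"))
  write_manifest(out_dir, "simulate", unclass(config), config$seed,
                 inputs = list(),
                 counts = list(patients = nrow(cohort$patients),
                               diagnoses = nrow(cohort$diagnoses),
                               map_rows = nrow(cohort$phecode_map)),
                 started = started)
  invisible(cohort)
}

# Config file loader: YAML or JSON; fields override cohort_config() defaults.
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$features)) raw$features <- as.data.frame(raw$features)
  do.call(cohort_config, raw)
}

#' Run Approach 1: phenotype-similarity cut-point
#'
#' Chains the stages: diagnosis events -> per-patient phecode sets ->
#' sex-stratified phenotype matrix (stroke cases only) -> per-patient
#' median cosine-similarity profile -> loess trend (reporting) and the
#' maximally selected standardized Wilcoxon cut-point (estimation).
#'
#' @param patients Patient data frame or path to `patients.csv`.
#' @param diagnoses Diagnosis data frame or path to `diagnoses.csv`.
#' @param map A `phecode_map` or path to `phecode_map.csv` (e.g. a
#'   user-supplied real ICD-to-phecode map).
#' @param sex `"F"` or `"M"`.
#' @param epsilon Proportion constraint for [estimate_cutpoint()].
#' @param span Loess span for the reported trend.
#' @param block_size Row block size for the similarity computation.
#' @param out_dir Optional; receives `similarity_profile.tsv`, `trend.tsv`,
#'   `cutpoint.json`, `manifest.json`.
#' @return List of class `approach1_result`: `profile`, `trend`, `cutpoint`
#'   (a `cutpoint` object), `sex`.
#' @export
run_approach1 <- function(patients, diagnoses, map, sex, epsilon = 0.1,
                          span = 0.75, block_size = 512L, out_dir = NULL) {
  started <- as.numeric(Sys.time())
  inputs <- list()
  if (is.character(patients)) {
    inputs$patients <- patients
    patients <- read_patient_table(patients)
  }
  if (is.character(diagnoses)) {
    inputs$diagnoses <- diagnoses
    diagnoses <- read_diagnosis_table(diagnoses)
  }
  if (is.character(map)) {
    inputs$map <- map
    map <- read_phecode_map(map)
  }
  if (nrow(diagnoses) == 0) stop_strokeage("approach1: empty diagnosis table")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_strokeage("approach1 stage '%s': %s", name, conditionMessage(e))
    })
  }
  sets <- stage("map_to_phecodes", map_to_phecodes(diagnoses, map))
  pm <- stage("build_phenotype_matrix",
              build_phenotype_matrix(sets, patients, sex))
  profile <- stage("median_similarity_profile",
                   median_similarity_profile(pm, block_size = block_size))
  fit <- stage("estimate_cutpoint",
               estimate_cutpoint(median_similarity ~ age_at_index,
                                 data = profile, epsilon = epsilon))
  trend <- stage("loess_smooth",
                 loess_smooth(profile$age_at_index, profile$median_similarity,
                              span = span))
  res <- structure(list(profile = profile, trend = trend, cutpoint = fit,
                        sex = sex),
                   class = "approach1_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(profile, file.path(out_dir, "similarity_profile.tsv"))
    write_tsv(trend, file.path(out_dir, "trend.tsv"))
    jsonlite::write_json(
      list(sex = sex, cutpoint = fit$cutpoint,
           max_statistic = fit$max_statistic, epsilon = fit$epsilon,
           n = fit$n, degenerate = fit$degenerate,
           candidates = fit$candidates),
      file.path(out_dir, "cutpoint.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, "approach1",
                   list(sex = sex, epsilon = epsilon, span = span,
                        block_size = block_size),
                   seed = NA, inputs = inputs,
                   counts = list(patients = nrow(patients),
                                 diagnoses = nrow(diagnoses),
                                 profile = nrow(profile)),
                   started = started)
  }
  res
}

#' @export
print.approach1_result <- function(x, ...) {
  cat(sprintf("Approach 1 (phenotype similarity), sex %s: %d profiled patients\n",
              x$sex, nrow(x$profile)))
  print(x$cutpoint)
  invisible(x)
}

#' Run Approach 2: bracketed classifier importance-trend cut-point
#'
#' Chains [run_model_grid()] -> [importance_similarity_trend()] ->
#' [estimate_bracket_cutpoint()]. BMI is imputed first when missing.
#'
#' @param patients Patient data frame or path to `patients.csv`.
#' @param epsilon Proportion constraint for the bracket cut-point.
#' @param seed Master seed for the model grid (and BMI imputation).
#' @param out_dir Optional; receives `model_grid.tsv`, `importance.tsv`,
#'   `importance_trend.tsv`, `bracket_cutpoints.json`, `tuning.json`,
#'   `manifest.json`.
#' @inheritParams run_model_grid
#' @return List of class `approach2_result`: `grid`, `trend`, `cutpoints`.
#' @export
run_approach2 <- function(patients, epsilon = 0.1, seed = 1L,
                          algorithms = ALGORITHMS,
                          brackets = default_brackets(), sexes = SEX_LEVELS,
                          dict = feature_dictionary(),
                          cv = list(folds = 5L, repeats = 5L),
                          grid_size = 5L, filter_controls = TRUE,
                          out_dir = NULL) {
  started <- as.numeric(Sys.time())
  inputs <- list()
  if (is.character(patients)) {
    inputs$patients <- patients
    patients <- read_patient_table(patients, dict = dict)
  }
  if (anyNA(patients$bmi)) {
    patients <- impute_bmi(patients, seed = sub_seed(seed, 999L), dict = dict)
  }
  grid <- run_model_grid(patients, algorithms = algorithms,
                         brackets = brackets, sexes = sexes, dict = dict,
                         cv = cv, grid_size = grid_size, seed = seed,
                         filter_controls = filter_controls)
  trend <- importance_similarity_trend(grid)
  cutpoints <- estimate_bracket_cutpoint(trend, epsilon = epsilon)
  res <- structure(list(grid = grid, trend = trend, cutpoints = cutpoints),
                   class = "approach2_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(as.data.frame(grid), file.path(out_dir, "model_grid.tsv"))
    write_tsv(importance_table(grid), file.path(out_dir, "importance.tsv"))
    write_tsv(as.data.frame(trend),
              file.path(out_dir, "importance_trend.tsv"))
    jsonlite::write_json(
      list(epsilon = epsilon, cutpoints = as.data.frame(cutpoints)),
      file.path(out_dir, "bracket_cutpoints.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      lapply(grid$models, function(m) {
        list(grid = m$tuning$grid, cv_auroc = m$tuning$cv_auroc,
             selected = m$tuning$selected)
      }),
      file.path(out_dir, "tuning.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, "approach2",
                   list(epsilon = epsilon, algorithms = algorithms,
                        brackets = brackets, sexes = sexes,
                        cv = cv, grid_size = grid_size,
                        filter_controls = filter_controls),
                   seed = seed, inputs = inputs,
                   counts = list(patients = nrow(patients),
                                 models = length(grid$models),
                                 failures = length(grid$errors)),
                   started = started,
                   partial = length(grid$errors) > 0)
  }
  res
}

#' @export
print.approach2_result <- function(x, ...) {
  print(x$grid)
  print(x$cutpoints)
  invisible(x)
}

#' Run the descriptive prevalence stage
#'
#' @inheritParams prevalence_table
#' @param patients Patient data frame or path to `patients.csv`.
#' @param out_dir Optional; receives `prevalence.tsv` and `manifest.json`.
#' @return The prevalence data frame.
#' @export
run_prevalence <- function(patients, brackets = c(default_brackets(), Inf),
                           sexes = SEX_LEVELS, dict = feature_dictionary(),
                           out_dir = NULL) {
  started <- as.numeric(Sys.time())
  inputs <- list()
  if (is.character(patients)) {
    inputs$patients <- patients
    patients <- read_patient_table(patients, dict = dict)
  }
  tab <- prevalence_table(patients, brackets = brackets, sexes = sexes,
                          dict = dict)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(tab, file.path(out_dir, "prevalence.tsv"))
    write_manifest(out_dir, "prevalence",
                   list(brackets = brackets, sexes = sexes), seed = NA,
                   inputs = inputs,
                   counts = list(patients = nrow(patients), rows = nrow(tab)),
                   started = started)
  }
  tab
}
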