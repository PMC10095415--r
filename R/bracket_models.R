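# Approach 2 stage 1: the (algorithm x age-bracket x sex) classifier grid.
#
# Each model is trained on cases vs controls restricted to one sex and one
# cumulative age bracket (age_at_index strictly below the bracket's upper
# age; "all" applies no age filter). Training follows a fixed protocol:
# stratified 80/20 split, hyperparameters picked by mean cross-validated
# AUROC over a seeded random grid of 5 candidate configurations, final refit
# on the full training portion, AUROC and accuracy measured on the held-out
# 20% only, and a feature-importance vector rescaled to max 100.

ALGORITHMS <- c("GLM", "RF", "XGB")

#' Default age-bracket grid
#'
#' The 17 cumulative upper ages used by the bracketed classifier grid:
#' below 40, 45, 46, ..., 55, 60, 65, 70, 75 and 80 years, with extra
#' resolution over 45-55 where most historical "young stroke" definitions
#' fall. The all-ages reference bracket is handled separately.
#'
#' @return Integer vector of 17 upper ages.
#' @export
default_brackets <- function() {
  c(40L, 45L, 46L, 47L, 48L, 49L, 50L, 51L, 52L, 53L, 54L, 55L,
    60L, 65L, 70L, 75L, 80L)
}

#' Subset a cohort to one sex and age bracket
#'
#' The bracket is cumulative: membership is `age_at_index < upper_age`
#' (strict), so a 54.9-year-old belongs to the `<55` bracket and a
#' 55.0-year-old does not. `upper_age = Inf` (the "all" bracket) applies no
#' age filter. By default controls are filtered by the same rule as cases so
#' that bracket-to-bracket comparisons are not confounded by the control age
#' distribution; set `filter_controls = FALSE` to keep the full control pool.
#'
#' @param patients Patient data frame.
#' @param upper_age Numeric upper age, or `Inf` for all ages.
#' @param sex `"F"` or `"M"`.
#' @param filter_controls Apply the age filter to controls too (default).
#' @return Data frame with both classes; errors if either class is empty.
#' @export
make_bracket <- function(patients, upper_age, sex, filter_controls = TRUE) {
  sex <- match.arg(sex, SEX_LEVELS)
  keep_sex <- patients$sex == sex
  in_age <- patients$age_at_index < upper_age
  keep <- keep_sex & (in_age |
                        (!filter_controls & patients$label == "control"))
  out <- patients[keep, , drop = FALSE]
  n_case <- sum(out$label == "case")
  n_control <- sum(out$label == "control")
  if (n_case == 0 || n_control == 0) {
    stop_strokeage("bracket <%s (%s): empty class (cases %d, controls %d)",
                   format(upper_age), sex, n_case, n_control)
  }
  rownames(out) <- NULL
  out
}

# ---- hyperparameter spaces --------------------------------------------------
# Random grid: `grid_size` candidate configurations drawn from fixed,
# documented ranges. GLM = ridge-penalized logistic regression (glmnet,
# alpha 0), lambda log-uniform on [1e-4, 1]. RF = ranger probability forest:
# trees {100..400}, mtry {2..8}, min node size {1..20}. XGB = xgboost
# binary:logistic: eta log-uniform [0.03, 0.3], depth {2..6},
# rounds {50..300}.
draw_param_grid <- function(algorithm, grid_size, p) {
  switch(algorithm,
    GLM = data.frame(
      lambda = sort(10^stats::runif(grid_size, -4, 0), decreasing = TRUE)
    ),
    RF = data.frame(
      num_trees = sample(seq(100L, 300L, by = 50L), grid_size, replace = TRUE),
      mtry = sample(2:min(8L, p), grid_size, replace = TRUE),
      min_node_size = sample(c(5L, 10L, 20L, 40L, 80L), grid_size,
                             replace = TRUE)
    ),
    XGB = data.frame(
      eta = 10^stats::runif(grid_size, log10(0.03), log10(0.3)),
      max_depth = sample(2:6, grid_size, replace = TRUE),
      nrounds = sample(seq(50L, 250L, by = 50L), grid_size, replace = TRUE)
    ),
    stop_strokeage("unknown algorithm '%s'", algorithm)
  )
}

# Optional inverse-prevalence weights (class_weights flag); NULL = unweighted.
prevalence_weights <- function(y) {
  tab <- table(y)
  w <- as.numeric(length(y) / (length(tab) * tab[as.character(y)]))
  w
}

# `final` enables the impurity-importance accounting needed only on the
# refit that reports importance.
fit_one <- function(algorithm, X, y, params, weights = NULL, final = FALSE) {
  switch(algorithm,
    GLM = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         lambda = params$lambda, standardize = TRUE,
                         weights = weights %||% rep(1, length(y))),
    RF = ranger::ranger(
      x = X, y = y, probability = TRUE,
      num.trees = params$num_trees, mtry = params$mtry,
      min.node.size = params$min_node_size,
      importance = if (final) "impurity" else "none",
      case.weights = weights,
      num.threads = 1L, seed = sample.int(.Machine$integer.max, 1L)
    ),
    XGB = {
      dm <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "case"),
                                 weight = weights)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = params$eta,
                      max_depth = params$max_depth, nthread = 1L,
                      verbosity = 0),
        data = dm, nrounds = params$nrounds
      )
    }
  )
}

predict_prob <- function(algorithm, fit, X, params) {
  switch(algorithm,
    GLM = as.numeric(stats::predict(fit, newx = X, s = params$lambda,
                                    type = "response")),
    RF = stats::predict(fit, data = X, num.threads = 1L)$predictions[, "case"],
    XGB = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X)))
  )
}

auroc <- function(labels, prob) {
  as.numeric(pROC::auc(labels, prob, levels = c("control", "case"),
                       direction = "<", quiet = TRUE))
}

# Rank-form AUROC (midranks under ties) for the CV inner loop, where only
# the ordering of candidate configurations matters; equals the
# Mann-Whitney/pROC value, without per-call ROC-object overhead.
auroc_fast <- function(labels, prob) {
  pos <- labels == "case"
  n1 <- sum(pos)
  n0 <- length(labels) - n1
  (sum(rank(prob)[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, fold labels are shuffled.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train one bracket classifier
#'
#' Implements the fixed training protocol for a single (algorithm, sex,
#' bracket) cell: stratified 80/20 train/test split; a seeded random grid of
#' `grid_size` hyperparameter configurations scored by mean AUROC over
#' `cv$folds`-fold cross-validation repeated `cv$repeats` times on the
#' training portion; final refit of the winning configuration on the full
#' training portion; AUROC and accuracy (0.5 threshold) computed on the
#' held-out 20% only; feature importance extracted from the final refit and
#' rescaled to max 100.
#'
#' @param data Bracket data frame from [make_bracket()]; features must be
#'   complete (impute BMI first, see [impute_bmi()]).
#' @param algorithm `"GLM"`, `"RF"` or `"XGB"`.
#' @param dict Feature dictionary naming the model's predictor columns.
#' @param cv List `list(folds = 5, repeats = 5)`.
#' @param grid_size Number of random hyperparameter configurations (5).
#' @param test_fraction Held-out fraction (0.2).
#' @param seed Integer seed; the whole fit is deterministic given it.
#' @param class_weights If `TRUE`, apply inverse-prevalence case weights
#'   (off by default: imbalance is left unadjusted).
#' @return List of class `bracket_model`: `algorithm`, `sex`, `upper_age`,
#'   `n_case`, `n_control`, `auroc`, `accuracy`, `importance` (named,
#'   max 100), `tuning` (grid tried, CV score per row, selected index).
#' @export
train_bracket_model <- function(data, algorithm, dict = feature_dictionary(),
                                cv = list(folds = 5L, repeats = 5L),
                                grid_size = 5L, test_fraction = 0.2,
                                seed = 1L, class_weights = FALSE) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  y <- factor(as.character(data$label), levels = c("control", "case"))
  if (nlevels(droplevels(y)) < 2) {
    stop_strokeage("single-class input: cannot train a classifier")
  }
  if (min(table(y)) < 20) {
    stop_strokeage("need >= 20 subjects per class (have %s)",
                   paste(table(y), collapse = "/"))
  }
  X <- as.matrix(data[dict$name])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop_strokeage("features must be complete; impute BMI first")
  if (all(apply(X, 2, function(v) length(unique(v))) == 1L)) {
    stop_strokeage("degenerate input: every feature is constant")
  }

  weights_of <- if (class_weights) prevalence_weights else function(y) NULL

  with_seed(seed, {
    # stratified 80/20 split
    test_idx <- unlist(lapply(levels(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, round(test_fraction * length(idx)))
    }), use.names = FALSE)
    tr_X <- X[-test_idx, , drop = FALSE]; tr_y <- y[-test_idx]
    te_X <- X[test_idx, , drop = FALSE]; te_y <- y[test_idx]

    grid <- draw_param_grid(algorithm, grid_size, ncol(X))
    cv_score <- matrix(NA_real_, nrow(grid), cv$folds * cv$repeats)
    col <- 0L
    for (rep_i in seq_len(cv$repeats)) {
      fold <- stratified_folds(tr_y, cv$folds)
      for (k in seq_len(cv$folds)) {
        col <- col + 1L
        in_X <- tr_X[fold != k, , drop = FALSE]
        in_y <- tr_y[fold != k]
        out_X <- tr_X[fold == k, , drop = FALSE]
        out_y <- tr_y[fold == k]
        if (algorithm == "GLM") {
          # one path fit scores every lambda candidate at once
          fit <- glmnet::glmnet(in_X, in_y, family = "binomial", alpha = 0,
                                lambda = grid$lambda, standardize = TRUE,
                                weights = weights_of(in_y) %||%
                                  rep(1, length(in_y)))
          pr <- stats::predict(fit, newx = out_X, s = grid$lambda,
                               type = "response")
          for (g in seq_len(nrow(grid))) {
            cv_score[g, col] <- auroc_fast(out_y, pr[, g])
          }
        } else {
          for (g in seq_len(nrow(grid))) {
            fit <- fit_one(algorithm, in_X, in_y, grid[g, , drop = FALSE],
                           weights = weights_of(in_y))
            pr <- predict_prob(algorithm, fit, out_X, grid[g, , drop = FALSE])
            cv_score[g, col] <- auroc_fast(out_y, pr)
          }
        }
      }
    }
    mean_cv <- rowMeans(cv_score)
    best <- which.max(mean_cv)
    params <- grid[best, , drop = FALSE]

    final <- fit_one(algorithm, tr_X, tr_y, params,
                     weights = weights_of(tr_y), final = TRUE)
    pr_te <- predict_prob(algorithm, final, te_X, params)
    imp <- extract_importance(final, algorithm, tr_X, params)

    structure(
      list(
        algorithm = algorithm,
        sex = as.character(data$sex[1]),
        upper_age = attr(data, "upper_age") %||% NA_real_,
        n_case = sum(y == "case"),
        n_control = sum(y == "control"),
        auroc = auroc(te_y, pr_te),
        accuracy = mean((pr_te >= 0.5) == (te_y == "case")),
        importance = imp,
        tuning = list(grid = grid, cv_auroc = mean_cv, selected = best,
                      folds = cv$folds, repeats = cv$repeats),
        seed = seed
      ),
      class = "bracket_model"
    )
  })
}

#' Extract a normalized feature-importance vector
#'
#' Per algorithm: GLM uses the absolute standardized coefficient
#' (|beta_j| x sd(x_j), scale-free); RF the impurity (mean Gini decrease)
#' importance; XGB the total split gain, with features never used in a split
#' scored 0. The vector is rescaled so its maximum is 100.
#'
#' @param fit Fitted model object.
#' @param algorithm `"GLM"`, `"RF"` or `"XGB"`.
#' @param X Training matrix (column names define the feature order; GLM
#'   needs the column standard deviations).
#' @param params Selected hyperparameter row (GLM needs `lambda`).
#' @return Named numeric vector over the feature columns, max 100.
#' @export
extract_importance <- function(fit, algorithm, X, params = NULL) {
  features <- colnames(X)
  raw <- switch(algorithm,
    GLM = {
      beta <- as.numeric(stats::coef(fit, s = params$lambda))[-1L]
      abs(beta) * apply(X, 2, stats::sd)
    },
    RF = {
      imp <- fit$variable.importance
      imp[match(features, names(imp))]
    },
    XGB = {
      tab <- xgboost::xgb.importance(model = fit)
      gain <- tab$Gain[match(features, tab$Feature)]
      gain[is.na(gain)] <- 0
      gain
    }
  )
  raw <- as.numeric(raw)
  raw[is.na(raw)] <- 0
  names(raw) <- features
  if (max(raw) <= 0) stop_strokeage("all raw feature importances are zero")
  raw / max(raw) * 100
}

#' @export
print.bracket_model <- function(x, ...) {
  cat(sprintf("%s | sex %s | bracket %s | n = %d/%d | AUROC %.3f | accuracy %.3f\n",
              x$algorithm, x$sex,
              if (is.finite(x$upper_age)) paste0("<", x$upper_age) else "all",
              x$n_case, x$n_control, x$auroc, x$accuracy))
  invisible(x)
}

#' Run the full (algorithm x bracket x sex) model grid
#'
#' Trains one classifier per combination of algorithm, age-limited bracket
#' and sex (3 x 17 x 2 = 102 with the defaults) plus one all-ages reference
#' model per (algorithm, sex) — the anchor the importance-trend stage
#' compares every bracket against. Per-bracket failures (e.g. a sparse young
#' bracket) are collected and reported; a failed reference model aborts the
#' grid. Deterministic given `seed`.
#'
#' @inheritParams train_bracket_model
#' @param patients Patient data frame (both classes, both sexes).
#' @param algorithms Subset of `c("GLM", "RF", "XGB")`.
#' @param brackets Numeric upper ages (default [default_brackets()]).
#' @param sexes Subset of `c("F", "M")`.
#' @param filter_controls Passed to [make_bracket()].
#' @return Object of class `model_grid`: list with `models` (list of
#'   `bracket_model`, including the `upper_age = Inf` references), `errors`
#'   (per-bracket failures), `seed`.
#' @export
run_model_grid <- function(patients, algorithms = ALGORITHMS,
                           brackets = default_brackets(),
                           sexes = SEX_LEVELS,
                           dict = feature_dictionary(),
                           cv = list(folds = 5L, repeats = 5L),
                           grid_size = 5L, test_fraction = 0.2,
                           seed = 1L, filter_controls = TRUE,
                           class_weights = FALSE) {
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  sexes <- match.arg(sexes, SEX_LEVELS, several.ok = TRUE)
  models <- list()
  errors <- list()
  cell <- 0L
  for (sex in sexes) {
    for (alg in algorithms) {
      for (upper in c(Inf, as.numeric(brackets))) {
        cell <- cell + 1L
        cell_seed <- sub_seed(seed, cell)
        tag <- sprintf("%s_%s_%s", alg, sex,
                       if (is.finite(upper)) paste0("lt", upper) else "all")
        res <- tryCatch({
          d <- make_bracket(patients, upper, sex,
                            filter_controls = filter_controls)
          attr(d, "upper_age") <- upper
          train_bracket_model(d, alg, dict = dict, cv = cv,
                              grid_size = grid_size,
                              test_fraction = test_fraction,
                              seed = cell_seed,
                              class_weights = class_weights)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          if (!is.finite(upper)) {
            stop_strokeage("all-ages reference model failed (%s, %s): %s",
                           alg, sex, conditionMessage(res))
          }
          errors[[tag]] <- conditionMessage(res)
          log_msg("model grid: %s failed: %s", tag, conditionMessage(res))
        } else {
          models[[tag]] <- res
        }
      }
    }
  }
  structure(list(models = models, errors = errors, seed = seed),
            class = "model_grid")
}

#' @export
print.model_grid <- function(x, ...) {
  df <- as.data.frame(x)
  n_ref <- sum(!is.finite(df$upper_age))
  cat(sprintf("Bracket model grid: %d age-limited model(s), %d reference model(s), %d failure(s)\n",
              nrow(df) - n_ref, n_ref, length(x$errors)))
  cat(sprintf("  AUROC range: %.3f - %.3f\n", min(df$auroc), max(df$auroc)))
  invisible(x)
}

#' @export
as.data.frame.model_grid <- function(x, ...) {
  do.call(rbind, lapply(unname(x$models), function(m) {
    data.frame(algorithm = m$algorithm, sex = m$sex, upper_age = m$upper_age,
               n_case = m$n_case, n_control = m$n_control,
               auroc = m$auroc, accuracy = m$accuracy,
               stringsAsFactors = FALSE)
  }))
}

#' Long-format importance table from a model grid
#'
#' One row per (algorithm, sex, bracket, feature) with the max-100
#' importance; `mean_across_algorithms = TRUE` instead averages the three
#' algorithms' vectors per (sex, bracket) — the heatmap-table variant.
#'
#' @param grid A `model_grid`.
#' @param mean_across_algorithms Average over algorithms (default `FALSE`).
#' @return Data frame `algorithm`, `sex`, `upper_age`, `feature`,
#'   `importance`.
#' @export
importance_table <- function(grid, mean_across_algorithms = FALSE) {
  out <- do.call(rbind, lapply(unname(grid$models), function(m) {
    data.frame(algorithm = m$algorithm, sex = m$sex, upper_age = m$upper_age,
               feature = names(m$importance),
               importance = as.numeric(m$importance),
               stringsAsFactors = FALSE)
  }))
  if (mean_across_algorithms) {
    agg <- stats::aggregate(importance ~ sex + upper_age + feature, out, mean)
    agg$algorithm <- "mean"
    out <- agg[c("algorithm", "sex", "upper_age", "feature", "importance")]
  }
  out
}
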