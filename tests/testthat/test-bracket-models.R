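# Bracket construction, the training protocol, importance extraction and
# the grid runner. Model fits use small cohorts and a light CV profile so
# each block stays quick.

# The separable-cohort fixture make_separable() lives in helper-oracles.R.

test_that("bracket membership uses the strict upper-age rule", {
  pats <- tiny_patient_df()
  pats$age_at_index <- c(54.9, 40, 55.0, 40, 30, 55.0, 60, 70)
  got <- make_bracket(pats, 55, "F")
  expect_true(all(got$age_at_index < 55))
  expect_true("T01" %in% got$patient_id)    # 54.9 included
  expect_false("T03" %in% got$patient_id)   # 55.0 excluded

  all_ages <- make_bracket(pats, Inf, "F")
  expect_equal(nrow(all_ages), sum(pats$sex == "F"))

  expect_error(make_bracket(pats[pats$label == "case", ], 55, "F"),
               "empty class")
})

test_that("the default grid is 17 brackets with fine 45-55 resolution", {
  b <- default_brackets()
  expect_length(b, 17)
  expect_equal(b, c(40L, 45:55, seq(60L, 80L, by = 5L)))
})

test_that("all three algorithms separate a strongly informative feature", {
  df <- make_separable(1000)
  for (alg in c("GLM", "RF", "XGB")) {
    fit <- train_bracket_model(df, alg, cv = list(folds = 3L, repeats = 1L),
                               seed = 7)
    expect_gte(fit$auroc, 0.95)
    # a planted feature dominates the importance vector
    expect_true(names(which.max(fit$importance)) %in%
                  c("pfo", "migraine", "hypercoagulable_state"))
    expect_equal(max(fit$importance), 100)
    expect_true(all(fit$importance >= 0))
  }
})

test_that("label permutation drops AUROC to chance", {
  df <- make_separable(1000)
  set.seed(15)
  df$label <- sample(df$label)
  for (alg in c("GLM", "RF", "XGB")) {
    fit <- train_bracket_model(df, alg, cv = list(folds = 3L, repeats = 1L),
                               seed = 7)
    expect_gte(fit$auroc, 0.40)
    expect_lte(fit$auroc, 0.60)
  }
})

test_that("training rejects degenerate inputs", {
  df <- make_separable(200)
  all_case <- df
  all_case$label <- factor("case", levels = c("case", "control"))
  expect_error(train_bracket_model(all_case, "GLM"), "single-class")

  few <- df[c(1:10, 101:110), ]
  expect_error(train_bracket_model(few, "GLM",
                                   cv = list(folds = 2L, repeats = 1L)),
               ">= 20")

  flat <- df
  for (f in feature_dictionary()$name) flat[[f]] <- 1L
  expect_error(train_bracket_model(flat, "GLM",
                                   cv = list(folds = 2L, repeats = 1L)),
               "constant")
})

test_that("importance rescaling and zero handling follow the max-100 rule", {
  X <- matrix(rbinom(300, 1, 0.5), 100, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  fake <- list(variable.importance = c(f1 = 2, f2 = 1, f3 = 0))
  got <- extract_importance(fake, "RF", X)
  expect_equal(unname(got), c(100, 50, 0))

  fake0 <- list(variable.importance = c(f1 = 0, f2 = 0, f3 = 0))
  expect_error(extract_importance(fake0, "RF", X), "zero")
})

test_that("importance is invariant to feature-column order", {
  df <- make_separable(600)
  dict <- feature_dictionary()
  perm_dict <- dict[rev(seq_len(nrow(dict))), ]
  a <- train_bracket_model(df, "GLM", dict = dict,
                           cv = list(folds = 3L, repeats = 1L), seed = 5)
  b <- train_bracket_model(df, "GLM", dict = perm_dict,
                           cv = list(folds = 3L, repeats = 1L), seed = 5)
  # coordinate descent leaves order-dependent differences at convergence
  # precision; the vectors agree to ~0.1% of the 0-100 scale
  expect_equal(a$importance[dict$name], b$importance[dict$name],
               tolerance = 1e-3)
})

test_that("the grid runner is deterministic and counts models correctly", {
  co <- simulate_cohort(cohort_config(n_cases = 700, n_controls = 700,
                                      seed = 19))
  pats <- impute_bmi(co$patients, seed = 19)
  g1 <- run_model_grid(pats, algorithms = "GLM", brackets = c(50, 60),
                       sexes = "F", cv = list(folds = 3L, repeats = 1L),
                       seed = 23)
  expect_length(g1$models, 3)                  # 2 brackets + "all" reference
  df1 <- as.data.frame(g1)
  expect_equal(sum(is.finite(df1$upper_age)), 2)

  g2 <- run_model_grid(pats, algorithms = "GLM", brackets = c(50, 60),
                       sexes = "F", cv = list(folds = 3L, repeats = 1L),
                       seed = 23)
  expect_identical(as.data.frame(g1)$auroc, as.data.frame(g2)$auroc)
  expect_identical(g1$models[[1]]$importance, g2$models[[1]]$importance)

  # per-bracket failures are collected, not fatal
  g3 <- run_model_grid(pats, algorithms = "GLM", brackets = c(19, 60),
                       sexes = "F", cv = list(folds = 3L, repeats = 1L),
                       seed = 23)
  expect_length(g3$errors, 1)
  expect_match(names(g3$errors), "lt19")
})

test_that("training AUROC beats a label-permuted control fit", {
  df <- make_separable(600, p_case = 0.7, p_ctrl = 0.3)
  real <- train_bracket_model(df, "XGB", cv = list(folds = 3L, repeats = 1L),
                              seed = 3)
  set.seed(77)
  null_df <- df
  null_df$label <- sample(df$label)
  nul <- train_bracket_model(null_df, "XGB",
                             cv = list(folds = 3L, repeats = 1L), seed = 3)
  expect_gt(real$auroc, nul$auroc)
})
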