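# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (double loops, exhaustive
# enumeration) so it cannot share a defect with the package's optimized
# paths.

options(strokeage.verbose = 0)

# Naive pairwise cosine on a plain binary matrix, self-pair excluded.
naive_median_similarity <- function(X) {
  n <- nrow(X)
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) S[i, j] <- cosine_similarity(X[i, ], X[j, ])
    }
  }
  apply(S, 1, stats::median, na.rm = TRUE)
}

# Exhaustive permutation moments of the left-group rank sum: assign the
# observed midranks to groups in every possible way (via all n!
# permutations of positions) and return mean and variance of S.
perm_rank_sum_moments <- function(scores, m) {
  n <- length(scores)
  r <- rank(scores)
  perms <- all_permutations(n)
  s_vals <- apply(perms, 1, function(p) sum(r[p[seq_len(m)]]))
  list(mean = mean(s_vals), var = stats::var(s_vals) * (length(s_vals) - 1) /
         length(s_vals))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      row <- row + 1L
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

# Brute-force cut-point: evaluate standardized_wilcoxon() at every distinct
# age satisfying the proportion constraint; first maximum wins.
brute_force_cutpoint <- function(ages, scores, epsilon) {
  n <- length(ages)
  cands <- sort(unique(ages))
  best <- NULL
  for (mu in cands) {
    m <- sum(ages <= mu)
    if (m / n < epsilon || m / n > 1 - epsilon) next
    stat <- standardized_wilcoxon(scores, ages <= mu)
    if (is.null(best) || stat > best$stat + 1e-12) {
      best <- list(mu = mu, stat = stat)
    }
  }
  best
}

# Small deterministic patient table for IO and stats tests.
tiny_patient_df <- function(n = 8) {
  dict <- feature_dictionary()
  df <- data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    sex = rep(c("F", "M"), length.out = n),
    age_at_index = seq(30, 30 + 5 * (n - 1), by = 5),
    label = rep(c("case", "control"), each = ceiling(n / 2))[seq_len(n)],
    bmi = round(seq(22, 32, length.out = n), 1),
    stringsAsFactors = FALSE
  )
  for (f in dict$name) df[[f]] <- rep_len(c(0L, 1L), n)
  df
}

# Strongly separable fixture: three informative features at case/control
# prevalence p_case/p_ctrl (a single binary feature caps AUROC at
# p_case (1 - p_ctrl) + ties/2 = 0.90, below the 0.95 sanity bar), rest noise.
make_separable <- function(n = 1000, p_case = 0.9, p_ctrl = 0.1, seed = 41) {
  dict <- feature_dictionary()
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("s%04d", seq_len(n)),
    sex = factor("F", levels = c("F", "M")),
    age_at_index = runif(n, 20, 90),
    label = factor(rep(c("case", "control"), each = n / 2),
                   levels = c("case", "control")),
    bmi = rnorm(n, 27, 4), stringsAsFactors = FALSE
  )
  for (f in dict$name) df[[f]] <- rbinom(n, 1, 0.3)
  for (f in c("pfo", "migraine", "hypercoagulable_state")) {
    df[[f]] <- ifelse(df$label == "case", rbinom(n, 1, p_case),
                      rbinom(n, 1, p_ctrl))
  }
  df
}

write_tiny_cohort <- function(dir) {
  df <- tiny_patient_df()
  utils::write.csv(df, file.path(dir, "patients.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  file.path(dir, "patients.csv")
}
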