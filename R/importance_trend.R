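# Approach 2 stage 2: cosine similarity between each bracket's
# feature-importance vector and the all-ages reference, then the shared
# cut-point estimator on the resulting (upper age, similarity) trend.

#' Importance-similarity trend
#'
#' For every (algorithm, sex), compares each age-limited bracket's
#' feature-importance vector against the same algorithm's and sex's
#' all-ages reference vector by cosine similarity. Importances are used raw
#' (max-100 scale, no re-centering), so nonnegativity bounds the similarity
#' to `[0, 1]`: a young bracket whose classifier leans on a different
#' comorbidity profile than the full cohort scores low.
#'
#' @param grid A `model_grid` from [run_model_grid()]; must contain the
#'   `upper_age = Inf` reference for every (algorithm, sex) present.
#' @return Data frame of class `importance_trend`: `algorithm`, `sex`,
#'   `upper_age`, `similarity`, ordered by upper age within group.
#' @export
importance_similarity_trend <- function(grid) {
  models <- grid$models
  meta <- data.frame(
    algorithm = vapply(models, `[[`, "", "algorithm"),
    sex = vapply(models, `[[`, "", "sex"),
    upper_age = vapply(models, `[[`, 0, "upper_age"),
    stringsAsFactors = FALSE
  )
  groups <- unique(meta[meta$algorithm != "" , c("algorithm", "sex")])
  out <- NULL
  for (g in seq_len(nrow(groups))) {
    alg <- groups$algorithm[g]; sex <- groups$sex[g]
    sel <- meta$algorithm == alg & meta$sex == sex
    ref_i <- which(sel & !is.finite(meta$upper_age))
    if (length(ref_i) != 1L) {
      stop_strokeage("missing all-ages reference model for (%s, %s)", alg, sex)
    }
    ref <- models[[ref_i]]$importance
    brk_i <- which(sel & is.finite(meta$upper_age))
    if (!length(brk_i)) next
    sims <- vapply(brk_i, function(i) {
      v <- models[[i]]$importance
      cosine_similarity(v[names(ref)], ref)
    }, numeric(1))
    df <- data.frame(algorithm = alg, sex = sex,
                     upper_age = meta$upper_age[brk_i],
                     similarity = sims, stringsAsFactors = FALSE)
    out <- rbind(out, df[order(df$upper_age), ])
  }
  rownames(out) <- NULL
  class(out) <- c("importance_trend", "data.frame")
  out
}

#' Bracket cut-point per (algorithm, sex)
#'
#' Applies [estimate_cutpoint()] to each (algorithm, sex) group's
#' (bracket upper age, similarity) series. The trend's abscissa is the
#' bracket's upper age, so a cut-point of 52 reads "importance profiles of
#' brackets up to <52 differ from the full cohort". With the default
#' 17-bracket grid, `epsilon = 0.1` admits thresholds leaving at least 2
#' brackets per side.
#'
#' @param trend An `importance_trend`.
#' @param epsilon Proportion constraint for [estimate_cutpoint()].
#' @return Data frame of class `bracket_cutpoints`: `algorithm`, `sex`,
#'   `cutpoint`, `max_statistic`, `degenerate`; attribute `fits` holds the
#'   full `cutpoint` objects keyed `algorithm_sex`.
#' @export
estimate_bracket_cutpoint <- function(trend, epsilon = 0.1) {
  groups <- unique(as.data.frame(trend)[c("algorithm", "sex")])
  rows <- NULL
  fits <- list()
  for (g in seq_len(nrow(groups))) {
    alg <- groups$algorithm[g]; sex <- groups$sex[g]
    sub <- trend[trend$algorithm == alg & trend$sex == sex, , drop = FALSE]
    if (nrow(sub) < 4) {
      stop_strokeage("(%s, %s): need >= 4 brackets in the trend, have %d",
                     alg, sex, nrow(sub))
    }
    fit <- estimate_cutpoint(sub$upper_age, scores = sub$similarity,
                             epsilon = epsilon)
    fits[[paste(alg, sex, sep = "_")]] <- fit
    rows <- rbind(rows, data.frame(
      algorithm = alg, sex = sex, cutpoint = fit$cutpoint,
      max_statistic = fit$max_statistic, degenerate = fit$degenerate,
      stringsAsFactors = FALSE
    ))
  }
  rownames(rows) <- NULL
  attr(rows, "fits") <- fits
  class(rows) <- c("bracket_cutpoints", "data.frame")
  rows
}

#' @export
print.bracket_cutpoints <- function(x, ...) {
  cat("Bracket cut-points (importance-similarity trend):\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
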