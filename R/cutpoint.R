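# Maximally selected standardized Wilcoxon cut-point estimation.
#
# For a candidate age threshold mu, the subjects split into a "young" group
# {age <= mu} and an "old" group {age > mu}. The rank sum S of the scores in
# the young group, standardized by its permutation mean and variance, gives a
# two-sample statistic; the cut-point estimate is the threshold maximizing
# |S - E[S]| / sqrt(Var[S]) over all thresholds leaving at least a fraction
# epsilon of subjects on each side. Ties get midranks; the tie correction
# enters only through the sum of squared midranks.

#' Standardized Wilcoxon rank-sum statistic
#'
#' Computes `|S - E[S]| / sqrt(Var[S])` where `S` is the rank sum of the
#' "left" group (midranks for ties), `E[S] = m(n+1)/2`, and
#' `Var[S] = m(n-m)/(n(n-1)) * (sum r_k^2 - n(n+1)^2/4)` — the exact mean and
#' variance of `S` under random assignment of the observed (mid)ranks to
#' groups. Returns 0 when all scores are tied (`Var[S] = 0`).
#'
#' @param scores Numeric scores.
#' @param left Logical vector: `TRUE` for the left (young) group. Both groups
#'   must be nonempty.
#' @return Nonnegative statistic.
#' @examples
#' standardized_wilcoxon(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)) # ~1.549
#' @export
standardized_wilcoxon <- function(scores, left) {
  stopifnot(is.logical(left), length(scores) == length(left),
            !anyNA(scores), !anyNA(left))
  n <- length(scores)
  m <- sum(left)
  if (m == 0L || m == n) stop_strokeage("both groups must be nonempty")
  r <- rank(scores)  # midranks
  s <- sum(r[left])
  e <- m * (n + 1) / 2
  v <- m * (n - m) / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  if (v <= 0) return(0)
  abs(s - e) / sqrt(v)
}

#' Estimate the age cut-point by a maximally selected rank statistic
#'
#' Fits the change-point model: every distinct observed age `mu` whose split
#' `{age <= mu}` vs `{age > mu}` leaves each side with a proportion of
#' subjects in `[epsilon, 1 - epsilon]` is a candidate threshold; the
#' standardized Wilcoxon statistic of the scores is evaluated at each, and
#' the returned cut-point maximizes it (ties broken toward the smaller
#' threshold, for determinism). The estimate reads as "young" means age at
#' or below the cut-point.
#'
#' The default interface is a formula `score ~ age` with a data frame, in the
#' style of R modelling functions; numeric vectors are accepted via the
#' default method.
#'
#' An optional permutation p-value (off by default, as the procedure reports
#' the argmax unconditionally) permutes scores against ages and recomputes
#' the maximal statistic.
#'
#' @param x A formula `score ~ age`, or a numeric vector of ages.
#' @param data Data frame for the formula method.
#' @param scores Numeric scores (default method).
#' @param epsilon Minimum proportion of subjects required on each side of any
#'   candidate threshold, in (0, 0.5). Default 0.1, the usual proportion
#'   bound for maximally selected statistics.
#' @param n_perm Number of label permutations for the optional p-value;
#'   `0` (default) skips it.
#' @param seed Seed for the permutation p-value.
#' @param ... Passed between methods.
#' @return Object of class `cutpoint`: `cutpoint`, `max_statistic`,
#'   `epsilon`, `n`, `candidates` (data frame `threshold`, `statistic`,
#'   `n_left`, `n_right`), `degenerate` flag, optional `p_value`, plus the
#'   input `series`.
#' @examples
#' fit <- estimate_cutpoint(c(40, 50, 60, 70), scores = c(10, 9, 1, 2),
#'                          epsilon = 0.25)
#' coef(fit) # 50
#' @export
estimate_cutpoint <- function(x, ...) UseMethod("estimate_cutpoint")

#' @rdname estimate_cutpoint
#' @export
estimate_cutpoint.formula <- function(x, data, epsilon = 0.1, n_perm = 0L,
                                      seed = 1L, ...) {
  mf <- stats::model.frame(x, data)
  fit <- estimate_cutpoint.default(mf[[2L]], scores = mf[[1L]],
                                   epsilon = epsilon, n_perm = n_perm,
                                   seed = seed)
  fit$call <- match.call()
  fit
}

#' @rdname estimate_cutpoint
#' @export
estimate_cutpoint.default <- function(x, scores, epsilon = 0.1, n_perm = 0L,
                                      seed = 1L, ...) {
  ages <- as.numeric(x)
  scores <- as.numeric(scores)
  stopifnot(length(ages) == length(scores), !anyNA(ages), !anyNA(scores),
            all(is.finite(ages)), all(is.finite(scores)))
  if (length(ages) < 4) stop_strokeage("need at least 4 (age, score) pairs")
  if (epsilon <= 0 || epsilon >= 0.5) {
    stop_strokeage("epsilon must lie in (0, 0.5)")
  }
  n <- length(ages)
  ord <- order(ages)
  a <- ages[ord]
  r <- rank(scores)[ord]            # midranks, in age order
  sum_r2 <- sum(r^2)
  cum_s <- cumsum(r)

  # distinct ages: a threshold at the *last* occurrence of each age value
  last_of_age <- which(c(a[-n] != a[-1], TRUE))
  m <- last_of_age                  # n_left for threshold at a[last_of_age]
  prop <- m / n
  admissible <- prop >= epsilon & prop <= 1 - epsilon
  if (!any(admissible)) {
    stop_strokeage(
      "no admissible candidate threshold: epsilon = %g leaves no split of n = %d with both sides >= %g",
      epsilon, n, epsilon * n)
  }
  m <- m[admissible]
  thr <- a[last_of_age][admissible]
  s <- cum_s[last_of_age][admissible]
  e <- m * (n + 1) / 2
  v <- m * (n - m) / (n * (n - 1)) * (sum_r2 - n * (n + 1)^2 / 4)
  stat <- ifelse(v > 0, abs(s - e) / sqrt(pmax(v, 0)), 0)

  degenerate <- all(stat == 0)
  if (degenerate) {
    warning("all candidate statistics are 0 (scores tied); returning the smallest admissible threshold",
            call. = FALSE)
  }
  best <- which.max(stat)  # first maximum = smallest threshold on ties
  res <- structure(
    list(
      cutpoint = thr[best],
      max_statistic = stat[best],
      epsilon = epsilon,
      n = n,
      candidates = data.frame(threshold = thr, statistic = stat,
                              n_left = m, n_right = n - m),
      degenerate = degenerate,
      series = data.frame(age = ages, score = scores),
      call = match.call()
    ),
    class = "cutpoint"
  )
  if (n_perm > 0) {
    res$p_value <- perm_pvalue_cutpoint(a, r, last_of_age[admissible],
                                        sum_r2, res$max_statistic,
                                        n_perm, seed)
    res$n_perm <- as.integer(n_perm)
  }
  res
}

# Permutation null of the *maximal* statistic: permute scores (equivalently,
# midranks) against ages and re-maximize over the same admissible thresholds.
perm_pvalue_cutpoint <- function(a, r, idx, sum_r2, observed, n_perm, seed) {
  n <- length(r)
  m <- idx
  e <- m * (n + 1) / 2
  v <- m * (n - m) / (n * (n - 1)) * (sum_r2 - n * (n + 1)^2 / 4)
  sdv <- sqrt(pmax(v, 0))
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      rp <- r[sample.int(n)]
      stat <- abs(cumsum(rp)[idx] - e)
      stat <- ifelse(sdv > 0, stat / sdv, 0)
      if (max(stat) >= observed) exceed <- exceed + 1L
    }
    (exceed + 1) / (n_perm + 1)
  })
}

#' Null quantile of the maximal statistic under label permutation
#'
#' Helper for calibration checks: the `prob` quantile of the maximally
#' selected statistic when scores are randomly permuted against ages.
#'
#' @inheritParams estimate_cutpoint.default
#' @param prob Quantile level (default 0.95).
#' @return The permutation-null quantile of the maximal statistic.
#' @export
cutpoint_null_quantile <- function(x, scores, epsilon = 0.1, n_perm = 199L,
                                   prob = 0.95, seed = 1L) {
  ages <- as.numeric(x)
  n <- length(ages)
  ord <- order(ages)
  a <- ages[ord]
  r <- rank(scores)[ord]
  sum_r2 <- sum(r^2)
  last_of_age <- which(c(a[-n] != a[-1], TRUE))
  prop <- last_of_age / n
  idx <- last_of_age[prop >= epsilon & prop <= 1 - epsilon]
  m <- idx
  e <- m * (n + 1) / 2
  v <- m * (n - m) / (n * (n - 1)) * (sum_r2 - n * (n + 1)^2 / 4)
  sdv <- sqrt(pmax(v, 0))
  with_seed(seed, {
    maxima <- vapply(seq_len(n_perm), function(b) {
      rp <- r[sample.int(n)]
      stat <- abs(cumsum(rp)[idx] - e)
      max(ifelse(sdv > 0, stat / sdv, 0))
    }, numeric(1))
    stats::quantile(maxima, prob, names = FALSE)
  })
}

#' @export
print.cutpoint <- function(x, ...) {
  cat("Maximally selected standardized Wilcoxon cut-point\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  n = %d, epsilon = %g, %d candidate threshold(s)\n",
              x$n, x$epsilon, nrow(x$candidates)))
  cat(sprintf("  cut-point: %.4g (max statistic %.4g)\n",
              x$cutpoint, x$max_statistic))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p-value: %.4g (%d permutations)\n",
                x$p_value, x$n_perm))
  }
  if (isTRUE(x$degenerate)) cat("  note: degenerate trend (all scores tied)\n")
  invisible(x)
}

#' @export
summary.cutpoint <- function(object, ...) {
  top <- object$candidates[order(-object$candidates$statistic), ]
  structure(list(fit = object, top = utils::head(top, 5)),
            class = "summary.cutpoint")
}

#' @export
print.summary.cutpoint <- function(x, ...) {
  print(x$fit)
  cat("Top candidate thresholds:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cutpoint <- function(object, ...) c(cutpoint = object$cutpoint)

#' Plot a cut-point fit
#'
#' Two stacked base-graphics panels: the score-versus-age scatter with an
#' optional loess trend, and the standardized-statistic profile over the
#' candidate thresholds; the selected cut-point is marked in both.
#'
#' @param x A `cutpoint` object.
#' @param smooth Add a loess trend line to the scatter (default `TRUE` when
#'   at least 10 points).
#' @param span Loess span for the trend line.
#' @param ... Further arguments passed to [plot()].
#' @export
plot.cutpoint <- function(x, smooth = nrow(x$series) >= 10, span = 0.75, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  with(x$series, graphics::plot(age, score, pch = 16, cex = 0.5,
                                col = "grey40", xlab = "age at index (years)",
                                ylab = "score", ...))
  if (isTRUE(smooth)) {
    tc <- loess_smooth(x$series$age, x$series$score, span = span)
    graphics::lines(tc$age, tc$fitted, col = "steelblue", lwd = 2)
  }
  graphics::abline(v = x$cutpoint, col = "firebrick", lty = 2)
  graphics::mtext(sprintf("cut-point = %.3g", x$cutpoint), side = 3,
                  adj = 1, cex = 0.8)
  with(x$candidates, graphics::plot(threshold, statistic, type = "b",
                                    pch = 16, cex = 0.6,
                                    xlab = "candidate threshold (years)",
                                    ylab = "standardized statistic"))
  graphics::abline(v = x$cutpoint, col = "firebrick", lty = 2)
  invisible(x)
}

#' Loess trend smoother for reporting
#'
#' Local linear regression with tricube weights (the [stats::loess()]
#' fit, degree 1, no robustness iterations), evaluated on a grid. Used only
#' to visualise the similarity-versus-age trend; the cut-point estimator
#' never consumes the smoothed values, so smoothing choices cannot move the
#' estimate.
#'
#' @param age,score Numeric vectors (at least 5 points).
#' @param span Neighborhood fraction in (0, 1]; must cover at least 3 points.
#' @param grid Evaluation ages; default 100 points over the observed range.
#' @return Data frame `age`, `fitted`; attribute `span`.
#' @export
loess_smooth <- function(age, score, span = 0.75, grid = NULL) {
  stopifnot(length(age) == length(score))
  if (length(age) < 5) stop_strokeage("loess smoothing needs >= 5 points")
  if (span <= 0 || span > 1) stop_strokeage("span must lie in (0, 1]")
  if (floor(span * length(age)) < 3) {
    stop_strokeage("span %g covers fewer than 3 of %d points", span, length(age))
  }
  if (is.null(grid)) grid <- seq(min(age), max(age), length.out = 100L)
  fit <- stats::loess(score ~ age, data = data.frame(age = age, score = score),
                      span = span, degree = 1, family = "gaussian",
                      surface = "direct",
                      control = stats::loess.control(iterations = 1))
  out <- data.frame(age = grid,
                    fitted = stats::predict(fit, newdata = data.frame(age = grid)))
  attr(out, "span") <- span
  out
}
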