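#' F test for equality of two sample variances
#'
#' Two-sided variance-ratio test used to pick the t-statistic branch of the
#' variance-adaptive permutation test. The statistic is `var(x)/var(y)` and
#' the p-value is `2 * min(P(F <= f), P(F >= f))` under F(n1-1, n2-1),
#' capped at 1.
#'
#' @param x,y Numeric vectors, each of length >= 2 with nonzero variance.
#' @return A list with `statistic` (F) and `p.value`.
#' @examples
#' f_variance_test(c(30.02, 29.99, 30.11, 29.97, 30.01, 29.99),
#'                 c(29.89, 29.93, 29.72, 29.98, 30.02, 29.98))
#' @export
f_variance_test <- function(x, y) {
  check_two_samples(x, y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 || v2 == 0) {
    stop("degenerate input: zero variance in one of the samples", call. = FALSE)
  }
  f <- v1 / v2
  df1 <- length(x) - 1; df2 <- length(y) - 1
  p <- 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
  list(statistic = f, p.value = min(p, 1), df1 = df1, df2 = df2)
}

#' Two-sample t tests of the adaptive permutation procedure
#'
#' `student_t()` is the pooled-variance two-sample t test (df = n1 + n2 - 2);
#' `welch_t()` is Welch's unequal-variance t test with Welch-Satterthwaite
#' degrees of freedom; `adaptive_t()` runs the variance F test first and
#' dispatches to the pooled branch when the F-test p-value is at least
#' `f_alpha`, otherwise to the Welch branch.
#'
#' @param x,y Numeric vectors of length >= 2.
#' @param f_alpha Significance level of the branch-deciding F test.
#' @return A list of class `"ttest_outcome"` with `statistic`, `df`,
#'   `p.value`, `branch` (`"pooled"` or `"welch"`) and the component
#'   statistics (means, variances, sample sizes, pooled SD).
#' @examples
#' x <- c(30.02, 29.99, 30.11, 29.97, 30.01, 29.99)
#' y <- c(29.89, 29.93, 29.72, 29.98, 30.02, 29.98)
#' student_t(x, y)$p.value   # 0.0786
#' welch_t(x, y)$p.value     # 0.0908
#' adaptive_t(x, y)$branch   # "pooled": F-test p = 0.114 >= 0.05
#' @export
student_t <- function(x, y) {
  check_two_samples(x, y)
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("degenerate input: zero pooled variance", call. = FALSE)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  ttest_outcome(tt, df, branch = "pooled", x, y, pooled_sd = sqrt(sp2))
}

#' @rdname student_t
#' @export
welch_t <- function(x, y) {
  check_two_samples(x, y)
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) stop("degenerate input: both variances zero", call. = FALSE)
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  ttest_outcome(tt, df, branch = "welch", x, y, pooled_sd = NA_real_)
}

#' @rdname student_t
#' @export
adaptive_t <- function(x, y, f_alpha = 0.05) {
  ft <- f_variance_test(x, y)
  if (ft$p.value >= f_alpha) student_t(x, y) else welch_t(x, y)
}

ttest_outcome <- function(statistic, df, branch, x, y, pooled_sd) {
  out <- list(
    statistic = statistic, df = df,
    p.value = 2 * stats::pt(-abs(statistic), df),
    branch = branch,
    mean1 = mean(x), mean2 = mean(y),
    var1 = stats::var(x), var2 = stats::var(y),
    n1 = length(x), n2 = length(y), pooled_sd = pooled_sd
  )
  class(out) <- "ttest_outcome"
  out
}

check_two_samples <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("samples must be finite and non-missing", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.ttest_outcome <- function(x, ...) {
  cat(sprintf("%s two-sample t: t = %.4g, df = %.4g, p = %.4g\n",
              x$branch, x$statistic, x$df, x$p.value))
  invisible(x)
}

# Vectorized adaptive t across rows of a matrix. m1/v1 etc. are per-row
# means/variances. Returns list of vectors; degenerate rows (both variances
# zero) get p = 1 with branch "degenerate".
adaptive_t_vec <- function(m1, v1, m2, v2, n1, n2, f_alpha) {
  fstat <- v1 / v2
  pF <- 2 * pmin(stats::pf(fstat, n1 - 1, n2 - 1),
                 stats::pf(fstat, n1 - 1, n2 - 1, lower.tail = FALSE))
  pF <- pmin(pF, 1)
  # one zero variance: F p-value is 0 (maximal inequality) -> welch branch
  one_zero <- xor(v1 == 0, v2 == 0)
  pF[one_zero] <- 0
  welch <- pF < f_alpha

  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t_pool <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df_pool <- n1 + n2 - 2

  se2 <- v1 / n1 + v2 / n2
  t_welch <- (m1 - m2) / sqrt(se2)
  df_welch <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))

  tt <- ifelse(welch, t_welch, t_pool)
  df <- ifelse(welch, df_welch, df_pool)
  p <- 2 * stats::pt(-abs(tt), df)

  degenerate <- (v1 == 0 & v2 == 0) | !is.finite(p)
  p[degenerate] <- 1
  tt[degenerate & !is.finite(tt)] <- 0
  branch <- ifelse(degenerate, "degenerate", ifelse(welch, "welch", "pooled"))
  list(statistic = tt, df = df, p = p, branch = branch, f_p = pF)
}

row_stats <- function(Y, Y2, idx) {
  n <- length(idx)
  m <- rowMeans(Y[, idx, drop = FALSE])
  q <- rowMeans(Y2[, idx, drop = FALSE])
  v <- (q - m^2) * n / (n - 1)
  v[v < 0] <- 0  # guard against negative round-off
  list(m = m, v = v, n = n)
}

#' Variance-adaptive permutation test
#'
#' Permutation test whose statistic adapts to variance inequality: at the
#' observed labelling and at every resample, an F test compares the two group
#' variances and the pooled-variance or Welch t statistic is chosen
#' accordingly. The permutation p-value is the proportion of resamples whose
#' t-test p-value does not exceed the observed t-test p-value.
#'
#' Group labels are shuffled with group sizes preserved. When the number of
#' distinct group assignments `choose(n1+n2, n1)` is at most `B` (and
#' `exhaustive = "auto"`), all assignments are enumerated instead of sampled.
#' A resample in which both groups happen to have zero variance contributes a
#' permuted p-value of 1.
#'
#' @param x,y Numeric vectors (the two groups); combined length >= 4.
#' @param B Number of permutations.
#' @param seed Integer seed for the label shuffles (ignored when exhaustive).
#' @param f_alpha Significance level of the branch-deciding F test.
#' @param estimator `"plain"` counts `#\{p_perm <= p_obs\} / B`;
#'   `"plus-one"` uses the positively biased but never-zero
#'   `(1 + count) / (1 + B)`.
#' @param exhaustive `"auto"`, `"never"` or `"always"` (errors if
#'   enumeration is infeasible at `B` permutations).
#' @return A list with `p.value` (permutation p), `observed` (the
#'   `ttest_outcome` at the true labels), `B` (resamples used), `exhaustive`,
#'   and `branch_counts` over the resamples.
#' @examples
#' permutation_test(rnorm(10), rnorm(10), B = 200, seed = 1)
#' @export
permutation_test <- function(x, y, B = 1000, seed = NULL, f_alpha = 0.05,
                             estimator = c("plain", "plus-one"),
                             exhaustive = c("auto", "never", "always")) {
  check_two_samples(x, y)
  X <- matrix(c(x, y), nrow = 1)
  res <- permutation_test_matrix(X, n1 = length(x), B = B, seed = seed,
                                 f_alpha = f_alpha,
                                 estimator = match.arg(estimator),
                                 exhaustive = match.arg(exhaustive))
  obs <- adaptive_t(x, y, f_alpha = f_alpha)
  list(p.value = res$p_perm, observed = obs, B = attr(res, "B"),
       exhaustive = attr(res, "exhaustive"),
       branch_counts = attr(res, "branch_counts"))
}

#' Row-wise variance-adaptive permutation test on an intensity matrix
#'
#' Applies the adaptive permutation test of [permutation_test()] to every row
#' of a matrix whose first `n1` columns form group 1 and the remaining
#' columns group 2. All rows share the same label shuffles, which is what
#' makes the per-protein test affordable at cohort scale.
#'
#' @param X Numeric matrix (features x observations), group-1 columns first.
#' @param n1 Number of group-1 columns.
#' @inheritParams permutation_test
#' @return A tibble with one row per feature: `statistic`, `df`, `branch`,
#'   `p_obs`, `p_perm`, plus attributes `B`, `exhaustive`, `branch_counts`.
#' @export
permutation_test_matrix <- function(X, n1, B = 1000, seed = NULL,
                                    f_alpha = 0.05,
                                    estimator = c("plain", "plus-one"),
                                    exhaustive = c("auto", "never", "always")) {
  estimator <- match.arg(estimator)
  exhaustive <- match.arg(exhaustive)
  stopifnot(is.matrix(X), n1 >= 2, ncol(X) - n1 >= 2)
  n <- ncol(X)
  n2 <- n - n1
  if (n < 4) stop("need a combined sample size of at least 4", call. = FALSE)

  Y <- X
  Y2 <- Y * Y
  g1 <- seq_len(n1)
  obs1 <- row_stats(Y, Y2, g1)
  obs2 <- row_stats(Y, Y2, (n1 + 1):n)
  obs <- adaptive_t_vec(obs1$m, obs1$v, obs2$m, obs2$v, n1, n2, f_alpha)

  n_total <- choose(n, n1)
  do_exhaustive <- switch(exhaustive,
    auto = n_total <= B,
    always = TRUE,
    never = FALSE
  )
  if (exhaustive == "always" && n_total > B) {
    stop("exhaustive enumeration needs choose(n, n1) <= B permutations",
         call. = FALSE)
  }
  if (do_exhaustive) {
    perms <- utils::combn(n, n1)
  } else {
    draw <- function() replicate(B, sample.int(n, n1))
    perms <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    perms <- matrix(perms, nrow = n1)
  }
  B_eff <- ncol(perms)

  counts <- numeric(nrow(Y))
  branch_counts <- c(pooled = 0, welch = 0, degenerate = 0)
  for (b in seq_len(B_eff)) {
    idx1 <- perms[, b]
    s1 <- row_stats(Y, Y2, idx1)
    s2 <- row_stats(Y, Y2, seq_len(n)[-idx1])
    pb <- adaptive_t_vec(s1$m, s1$v, s2$m, s2$v, n1, n2, f_alpha)
    # tolerance absorbs last-ulp noise so exact permutation ties count
    counts <- counts + (pb$p <= obs$p * (1 + 1e-9) + 1e-12)
    tb <- table(factor(pb$branch, levels = names(branch_counts)))
    branch_counts <- branch_counts + as.numeric(tb)
  }
  p_perm <- if (estimator == "plain") counts / B_eff else (1 + counts) / (1 + B_eff)

  out <- tibble::tibble(
    statistic = obs$statistic, df = obs$df, branch = obs$branch,
    p_obs = obs$p, p_perm = p_perm
  )
  attr(out, "B") <- B_eff
  attr(out, "exhaustive") <- do_exhaustive
  attr(out, "branch_counts") <- branch_counts
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")`: step-up
#' false-discovery-rate adjustment, monotone and capped at 1, input order
#' preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on a lambda grid by
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, smooths the curve
#' with a cubic smoothing spline and evaluates it at the largest lambda,
#' then computes `q_(i) = pi0 * m * p_(i) / i` with cumulative-minimum
#' monotonization, mapped back to input order. With fewer than `min_m`
#' p-values the pi0 estimate is unstable and is fixed at 1 (q-values then
#' equal BH-adjusted p-values).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda Grid for pi0 estimation.
#' @param pi0 Optional fixed pi0 (bypasses estimation).
#' @param min_m Minimum number of p-values for pi0 estimation.
#' @return A list with `qvalue` (same order as `p`) and `pi0`.
#' @export
storey_qvalue <- function(p, lambda = seq(0, 0.90, by = 0.05), pi0 = NULL,
                          min_m = 100) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(list(qvalue = numeric(0), pi0 = 1))
  if (is.null(pi0)) {
    if (m < min_m) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(pi0, 1)
      if (pi0 <= 0) {
        warning("pi0 estimate <= 0; clamped to a small positive value")
        pi0 <- 1 / m
      }
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / (m:1)
  q <- pmin(cummin(q), 1)[ro]
  list(qvalue = q, pi0 = pi0)
}

#' Per-protein differential test between healthy samples and one subtype
#'
#' Runs the three-step significance procedure for every protein: (1) the
#' variance-adaptive permutation test of healthy vs subtype per-individual
#' intensities, (2) Benjamini-Hochberg adjustment of the permutation
#' p-values, (3) Storey-Tibshirani q-values. Replicate injections of an
#' individual are averaged first, so label shuffles move all replicates of
#' an individual together.
#'
#' @param mat Proteins x sample-replicate log2 intensity matrix with column
#'   names matching `annotation$sample_id`.
#' @param annotation Sample annotation tibble with `sample_id`,
#'   `individual_id`, `group` and `subtype` columns (see [add_subtype()]).
#' @param subtype Subtype to contrast against the healthy group.
#' @param B,seed,f_alpha,estimator Passed to [permutation_test_matrix()].
#' @return A tibble: `protein_id`, `statistic`, `df`, `branch`, `p_obs`,
#'   `p_perm`, `p_bh`, `q`, `direction` (`"up"` if the subtype mean exceeds
#'   the healthy mean). Attributes carry `pi0`, `B`, `subtype` and `seed`.
#' @export
diff_test <- function(mat, annotation, subtype, B = 1000, seed = NULL,
                      f_alpha = 0.05, estimator = c("plain", "plus-one")) {
  estimator <- match.arg(estimator)
  subtype <- match.arg(subtype, subtype_levels())
  ind <- collapse_replicates(mat, annotation)
  ann <- attr(ind, "individuals")
  healthy <- ann$individual_id[ann$group == "healthy"]
  cases <- ann$individual_id[!is.na(ann$subtype) & ann$subtype == subtype]
  if (length(healthy) < 2 || length(cases) < 2) {
    stop("need at least 2 healthy and 2 '", subtype, "' individuals",
         call. = FALSE)
  }
  X <- cbind(ind[, healthy, drop = FALSE], ind[, cases, drop = FALSE])
  res <- permutation_test_matrix(X, n1 = length(healthy), B = B, seed = seed,
                                 f_alpha = f_alpha, estimator = estimator)
  stor <- storey_qvalue(res$p_perm)
  out <- tibble::tibble(
    protein_id = rownames(mat),
    statistic = res$statistic, df = res$df, branch = res$branch,
    p_obs = res$p_obs, p_perm = res$p_perm,
    p_bh = bh_adjust(res$p_perm),
    q = stor$qvalue,
    direction = ifelse(
      rowMeans(ind[, cases, drop = FALSE]) >=
        rowMeans(ind[, healthy, drop = FALSE]), "up", "down")
  )
  attr(out, "pi0") <- stor$pi0
  attr(out, "B") <- attr(res, "B")
  attr(out, "subtype") <- subtype
  attr(out, "seed") <- seed
  out
}

#' Significance screening at the three q-value cutoffs
#'
#' Declares per-cutoff significant protein sets at the three nested q-value
#' thresholds and reports the expected number of false positives per set
#' (threshold times set size).
#'
#' @param results A [diff_test()] result tibble (needs `protein_id` and `q`).
#' @param cutoffs Strictly decreasing q thresholds; exactly three.
#' @return A tibble with one row per cutoff: `cutoff` (1..3), `threshold`,
#'   `proteins` (list column), `n`, `expected_fp`.
#' @export
declare_significant <- function(results, cutoffs = c(0.2, 0.1, 0.05)) {
  if (length(cutoffs) != 3 || any(diff(cutoffs) >= 0)) {
    stop("cutoffs must be exactly three strictly decreasing thresholds",
         call. = FALSE)
  }
  sets <- lapply(cutoffs, function(th) results$protein_id[results$q < th])
  tibble::tibble(
    cutoff = seq_along(cutoffs),
    threshold = cutoffs,
    proteins = sets,
    n = lengths(sets),
    expected_fp = cutoffs * lengths(sets)
  )
}
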