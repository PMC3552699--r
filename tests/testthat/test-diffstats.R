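# The two printed six-sample vectors used as a worked example of the
# F / pooled-t / Welch-t branch decision.
wx <- c(30.02, 29.99, 30.11, 29.97, 30.01, 29.99)
wy <- c(29.89, 29.93, 29.72, 29.98, 30.02, 29.98)

test_that("F variance test matches the worked example and var.test oracle", {
  ft <- f_variance_test(wx, wy)
  expect_equal(ft$statistic, 0.2122, tolerance = 1e-4)
  expect_equal(ft$p.value, 0.1141, tolerance = 1e-3)
  oracle <- stats::var.test(wx, wy)
  expect_equal(ft$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(ft$p.value, oracle$p.value, tolerance = 1e-12)

  expect_equal(f_variance_test(wx, wx)$statistic, 1)
  expect_equal(f_variance_test(wx, wx)$p.value, 1)

  ft2 <- f_variance_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(ft2$statistic, 0.25)
  expect_equal(ft2$p.value, stats::var.test(c(1, 2, 3), c(2, 4, 6))$p.value,
               tolerance = 1e-12)
  expect_error(f_variance_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("pooled and Welch t match the worked example and t.test oracle", {
  st <- student_t(wx, wy)
  expect_equal(st$statistic, 1.959, tolerance = 1e-3)
  expect_equal(st$p.value, 0.078, tolerance = 1e-2)
  expect_equal(st$df, 10)
  o1 <- stats::t.test(wx, wy, var.equal = TRUE)
  expect_equal(st$statistic, unname(o1$statistic), tolerance = 1e-12)
  expect_equal(st$p.value, o1$p.value, tolerance = 1e-12)

  wt <- welch_t(wx, wy)
  expect_equal(wt$statistic, 1.959, tolerance = 1e-3)
  expect_equal(wt$p.value, 0.091, tolerance = 1e-2)
  expect_equal(wt$df, 7.03, tolerance = 1e-2)
  o2 <- stats::t.test(wx, wy)
  expect_equal(wt$df, unname(o2$parameter), tolerance = 1e-12)
  expect_equal(wt$p.value, o2$p.value, tolerance = 1e-12)

  # same values in both groups: zero mean difference
  st0 <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(st0$statistic, 0)
  expect_equal(st0$p.value, 1)

  # hand-derived: pooled s^2 = 1, SE = sqrt(2/3)
  st3 <- student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(st3$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st3$df, 4)

  # equal sample sizes: Welch and pooled statistics coincide
  set.seed(5)
  a <- rnorm(7); b <- rnorm(7, sd = 3)
  expect_equal(welch_t(a, b)$statistic, student_t(a, b)$statistic,
               tolerance = 1e-12)
})

test_that("adaptive_t picks the branch from the F test", {
  at <- adaptive_t(wx, wy, f_alpha = 0.05)
  expect_equal(at$branch, "pooled")   # F p = 0.114 >= 0.05
  expect_equal(at$p.value, 0.078, tolerance = 1e-2)

  set.seed(7)
  a <- rnorm(10, sd = 1); b <- rnorm(10, sd = 10)
  expect_lt(f_variance_test(a, b)$p.value, 0.05)
  expect_equal(adaptive_t(a, b)$branch, "welch")

  expect_equal(adaptive_t(c(1, 2, 3), c(1, 2, 3))$branch, "pooled")
  expect_equal(adaptive_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
})

# brute-force enumeration oracle perm_oracle() lives in helper-oracles.R

test_that("exhaustive permutation p equals brute-force enumeration", {
  cases <- list(
    list(x = c(0, 1), y = c(10, 11)),
    list(x = c(1.2, 0.3, 2.2), y = c(4.1, 3.3, 5.0)),
    list(x = c(0.1, 0.5, 0.9, 0.2), y = c(0.4, 0.6, 0.8))
  )
  for (cs in cases) {
    res <- permutation_test(cs$x, cs$y, B = 1000, exhaustive = "auto")
    expect_true(res$exhaustive)
    expect_equal(res$p.value, perm_oracle(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("weakest possible observed statistic gives permutation p = 1", {
  res <- permutation_test(c(1, 2, 3), c(3, 1, 2), B = 100, exhaustive = "auto")
  expect_equal(res$p.value, 1)
})

test_that("permutation p is deterministic for a fixed seed", {
  set.seed(99); x <- rnorm(12); y <- rnorm(12, 0.5)
  a <- permutation_test(x, y, B = 200, seed = 3, exhaustive = "never")
  b <- permutation_test(x, y, B = 200, seed = 3, exhaustive = "never")
  expect_identical(a$p.value, b$p.value)
  expect_identical(a$branch_counts, b$branch_counts)
})

test_that("plus-one estimator shifts the plain estimator as (1+c)/(1+B)", {
  set.seed(1); x <- rnorm(8); y <- rnorm(8, 1)
  a <- permutation_test(x, y, B = 99, seed = 2, exhaustive = "never")
  b <- permutation_test(x, y, B = 99, seed = 2, exhaustive = "never",
                        estimator = "plus-one")
  count <- a$p.value * 99
  expect_equal(b$p.value, (1 + count) / 100, tolerance = 1e-12)
})

test_that("matrix permutation test agrees with the scalar interface", {
  set.seed(21)
  X <- matrix(rnorm(5 * 14), 5)
  res <- permutation_test_matrix(X, n1 = 7, B = 150, seed = 8)
  for (i in c(1, 3, 5)) {
    single <- permutation_test(X[i, 1:7], X[i, 8:14], B = 150, seed = 8,
                               exhaustive = "never")
    expect_equal(res$p_perm[i], single$p.value, tolerance = 1e-12)
    expect_equal(res$p_obs[i], single$observed$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand example and p.adjust", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2); p <- runif(50)
  expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Storey q-values reduce to BH when pi0 = 1 and are monotone in p", {
  set.seed(3); p <- runif(200)
  q1 <- storey_qvalue(p, pi0 = 1)
  expect_equal(q1$qvalue, bh_adjust(p), tolerance = 1e-12)
  q <- storey_qvalue(p)
  expect_true(q$pi0 > 0 && q$pi0 <= 1)
  o <- order(p)
  expect_true(all(diff(q$qvalue[o]) >= -1e-12))
})

test_that("pi0 estimate approaches 1 on uniform null p-values", {
  set.seed(4)
  p <- runif(1000)
  q <- storey_qvalue(p)
  expect_gte(q$pi0, 0.85)
  expect_lte(q$pi0, 1.0)
})

test_that("small input sets fall back to pi0 = 1", {
  p <- runif(20)
  expect_equal(storey_qvalue(p)$pi0, 1)
})

test_that("declare_significant yields nested sets and the FPR formula", {
  res <- tibble::tibble(
    protein_id = paste0("P", 1:6),
    q = c(0.01, 0.04, 0.08, 0.15, 0.19, 0.5)
  )
  d <- declare_significant(res)
  expect_equal(d$n, c(5, 3, 2))
  expect_true(all(d$proteins[[3]] %in% d$proteins[[2]]))
  expect_true(all(d$proteins[[2]] %in% d$proteins[[1]]))
  expect_equal(d$expected_fp, c(0.2 * 5, 0.1 * 3, 0.05 * 2))

  empty <- declare_significant(res[0, ])
  expect_equal(empty$n, c(0, 0, 0))
  expect_equal(empty$expected_fp, c(0, 0, 0))

  expect_error(declare_significant(res, cutoffs = c(0.05, 0.1, 0.2)),
               "decreasing")
})

test_that("diff_test recovers planted signal with sensible direction", {
  des <- small_design(seed = 31, n_proteins = 120)
  planted <- protein_ids <- sprintf("P%06d", 1:25)
  plan <- flat_plan(planted, subtype = "LuminalA", effect = 2,
                    sigma_individual = 0.2, sigma_replicate = 0.1,
                    sigma_residual = 0.2)
  cohort <- generate_cohort(des, plan)
  mat <- quantile_normalize(cohort$intensities)
  res <- diff_test(mat, cohort$annotation, "LuminalA", B = 300, seed = 5)
  expect_equal(nrow(res), 120)
  expect_true(all(res$p_bh >= res$p_perm))
  expect_true(all(res$q <= res$p_bh + 1e-12))
  planted_q <- res$q[res$protein_id %in% planted]
  other_q <- res$q[!res$protein_id %in% planted]
  expect_lt(stats::median(planted_q), stats::median(other_q))
  expect_true(all(res$direction[res$protein_id %in% planted] == "up"))
})
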