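test_that("quantile normalization matches hand-evaluated rank means", {
  m <- matrix(c(1, 3, 2, 6), 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(1.5, 4.5))
  expect_equal(unname(out[, "b"]), c(1.5, 4.5))
  expect_equal(attr(out, "scale"), "log2qn")
})

test_that("quantile normalization is idempotent and equalizes column sums", {
  set.seed(10)
  m <- matrix(rnorm(200, 20, 2), 20, 10,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  q1 <- quantile_normalize(m)
  q2 <- quantile_normalize(q1)
  expect_equal(unclass(q1), unclass(q2), tolerance = 1e-12)
  expect_equal(diff(range(colSums(q1))), 0, tolerance = 1e-9)
  # identical columns pass through unchanged
  same <- matrix(rep(sort(rnorm(8)), 3), 8, 3,
                 dimnames = list(paste0("p", 1:8), paste0("s", 1:3)))
  expect_equal(unclass(quantile_normalize(same)), unclass(same),
               ignore_attr = TRUE)
})

test_that("quantile normalization rejects an all-missing column", {
  m <- matrix(c(1, 2, NA, NA), 2, dimnames = list(NULL, c("ok", "gone")))
  expect_error(quantile_normalize(m), "gone")
  expect_error(quantile_normalize(matrix(1:4, 4, 1)), "2 columns")
})

test_that("peptide aggregation averages rows per protein", {
  pep <- matrix(c(2, 4, 4, 6, 1, 1), 3, byrow = TRUE,
                dimnames = list(c("pepA", "pepB", "pepC"), c("s1", "s2")))
  map <- c(pepA = "prot1", pepB = "prot1", pepC = "prot2")
  out <- aggregate_to_protein(pep, map)
  expect_equal(unname(out["prot1", ]), c(3, 5))
  expect_equal(unname(out["prot2", ]), c(1, 1))
  # one peptide per protein is the identity
  solo <- aggregate_to_protein(pep, c(pepA = "x", pepB = "y", pepC = "z"))
  expect_equal(unname(solo), unname(pep))
  expect_error(aggregate_to_protein(pep, c(pepA = "prot1")), "unmapped")
  expect_error(aggregate_to_protein(pep, character(0)), "empty")
})

make_balanced_cohort <- function(effects = c(LuminalA = 0, LuminalB = 1,
                                             HER2Plus = 2, BasalLike = -1),
                                 sigma = 0, n_per = 6, r = 2, seed = 3,
                                 n_proteins = 10) {
  plan_eff <- lapply(effects, function(e) {
    stats::setNames(rep(e, n_proteins), sprintf("P%06d", seq_len(n_proteins)))
  })
  des <- cohort_design(n_healthy = 4,
                       subtype_counts = stats::setNames(rep(n_per,
                                                            length(effects)),
                                                        names(effects)),
                       n_proteins = n_proteins, n_replicates = r, seed = seed)
  plan <- effect_plan(plan_eff, sigma_individual = sigma / 2,
                      sigma_replicate = 0, sigma_residual = sigma)
  generate_cohort(des, plan)
}

test_that("noise-free planted effect contrasts are recovered exactly", {
  cohort <- make_balanced_cohort(sigma = 0)
  eff <- fit_subtype_effects(cohort$intensities, cohort$annotation)
  S <- effect_matrix(eff)
  # sum-to-zero estimates recover contrasts of the planted effects
  planted <- c(LuminalA = 0, LuminalB = 1, HER2Plus = 2, BasalLike = -1)
  for (p in rownames(S)) {
    est_contrast <- S[p, "LuminalB"] - S[p, "LuminalA"]
    expect_equal(est_contrast, 1, tolerance = 1e-6)
    expect_equal(S[p, "HER2Plus"] - S[p, "BasalLike"], 3, tolerance = 1e-6)
    expect_equal(sum(S[p, ]), 0, tolerance = 1e-9)
  }
})

test_that("closed-form REML matches the lme4 oracle on balanced data", {
  cohort <- make_balanced_cohort(sigma = 0.4, n_proteins = 6, seed = 8)
  closed <- fit_subtype_effects(cohort$intensities, cohort$annotation,
                                method = "closed")
  lmm <- fit_subtype_effects(cohort$intensities, cohort$annotation,
                             method = "lmer")
  expect_equal(effect_matrix(closed), effect_matrix(lmm), tolerance = 1e-6)
  expect_equal(closed$mu, lmm$mu, tolerance = 1e-6)
  ok <- lmm$converged & lmm$sigma_I > 1e-4  # away from the boundary
  expect_gt(sum(ok), 0)
  expect_equal(closed$sigma_I[ok], lmm$sigma_I[ok], tolerance = 1e-4)
  expect_equal(closed$sigma_e[ok], lmm$sigma_e[ok], tolerance = 1e-4)
})

test_that("REML fixed-effect contrasts equal subtype mean contrasts when balanced", {
  cohort <- make_balanced_cohort(sigma = 0.3, seed = 12)
  eff <- fit_subtype_effects(cohort$intensities, cohort$annotation)
  S <- effect_matrix(eff)
  ind <- collapse_replicates(cohort$intensities, cohort$annotation)
  ann <- attr(ind, "individuals")
  for (s in c("LuminalA", "HER2Plus")) {
    m_s <- rowMeans(ind[, ann$individual_id[!is.na(ann$subtype) &
                                              ann$subtype == s]])
    m_t <- rowMeans(ind[, ann$individual_id[!is.na(ann$subtype) &
                                              ann$subtype == "BasalLike"]])
    expect_equal(unname(S[, s] - S[, "BasalLike"]), unname(m_s - m_t),
                 tolerance = 1e-8)
  }
})

test_that("noisy balanced recovery stays within sampling error of the oracle", {
  cohort <- make_balanced_cohort(sigma = 0.2, n_per = 20, r = 1,
                                 n_proteins = 40, seed = 30)
  eff <- fit_subtype_effects(cohort$intensities, cohort$annotation)
  S <- effect_matrix(eff)
  contrast <- S[, "HER2Plus"] - S[, "LuminalA"]
  rmse <- sqrt(mean((contrast - 2)^2))
  expect_lt(rmse, 3 * 0.2 / sqrt(20))
})

test_that("a single subtype is rejected", {
  cohort <- make_balanced_cohort(effects = c(LuminalA = 0))
  expect_error(fit_subtype_effects(cohort$intensities, cohort$annotation),
               "at least 2 subtypes")
})

test_that("intensity and annotation TSVs round-trip", {
  cohort <- make_balanced_cohort(sigma = 0.1, n_proteins = 5)
  d <- tempfile(); dir.create(d)
  paths <- write_cohort(cohort, d)
  m2 <- read_intensity_tsv(paths[["intensities"]])
  expect_equal(unclass(m2), unclass(cohort$intensities),
               ignore_attr = TRUE, tolerance = 1e-12)
  a2 <- read_annotation_tsv(paths[["annotation"]])
  expect_equal(a2$sample_id, cohort$annotation$sample_id)
  expect_equal(a2$ER, cohort$annotation$ER)
})
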