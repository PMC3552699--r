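test_that("pathway generation is deterministic and honors overlap = 0", {
  db0 <- generate_pathway_db(10, c(4, 8), overlap_fraction = 0,
                             n_proteins = 200, seed = 3)
  sims <- utils::combn(length(db0), 2, function(ij) {
    jaccard_similarity(db0[[ij[1]]], db0[[ij[2]]])
  })
  expect_true(all(sims == 0))

  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(generate_pathway_db(12, c(5, 20), 0.3, 300, seed = 9), f1)
  write_gmt(generate_pathway_db(12, c(5, 20), 0.3, 300, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(generate_pathway_db(5, c(0, 10), 0.1, 100, seed = 1),
               "size_range")
  expect_error(generate_pathway_db(1, c(5, 10), 0.1, 100, seed = 1),
               "at least 2")
})

test_that("realized mean Jaccard matches a brute-force set-overlap oracle", {
  db <- generate_pathway_db(50, c(5, 40), overlap_fraction = 0.2,
                            n_proteins = 616, seed = 7)
  pairs <- utils::combn(50, 2)
  oracle <- mean(apply(pairs, 2, function(ij) {
    a <- db[[ij[1]]]; b <- db[[ij[2]]]
    length(intersect(a, b)) / length(union(a, b))
  }))
  pkg <- mean(apply(pairs, 2, function(ij) {
    jaccard_similarity(db[[ij[1]]], db[[ij[2]]])
  }))
  expect_equal(pkg, oracle, tolerance = 1e-12)
  expect_lt(abs(pkg - oracle), 0.05)
})

test_that("cohort dimensions and labels follow the design", {
  des <- cohort_design(seed = 2)  # study defaults
  plan <- effect_plan(list(), sigma_individual = 0.1)
  cohort <- generate_cohort(des, plan)
  ann <- cohort$annotation
  inds <- ann[!duplicated(ann$individual_id), ]
  expect_equal(sum(inds$group == "cancer"), 80)
  expect_equal(sum(inds$group == "healthy"), 80)
  expect_equal(unname(table(factor(cohort$truth$label,
                                   levels = subtype_levels()))),
               unname(c(LuminalA = 24, LuminalB = 15, HER2Plus = 10,
                        BasalLike = 19, Unknown = 12)),
               ignore_attr = TRUE)
  expect_equal(dim(cohort$intensities), c(616, 160 * 2))
  # receptor round trip recovers the true label for every patient
  expect_equal(as.character(inds$subtype[inds$group == "cancer"]),
               unname(cohort$truth$label))
})

test_that("zero effects and zero variances reproduce the baseline exactly", {
  des <- small_design(seed = 5, n_proteins = 30)
  plan <- effect_plan(list(), sigma_individual = 0, sigma_replicate = 0,
                      sigma_residual = 0)
  cohort <- generate_cohort(des, plan)
  expect_true(all(apply(cohort$intensities, 1, function(r) {
    diff(range(r)) == 0
  })))
})

test_that("planted effect size is recovered by a direct group-mean oracle", {
  des <- small_design(seed = 17, n_proteins = 100, n_replicates = 3,
                      counts = c(LuminalA = 20, BasalLike = 8),
                      n_healthy = 20)
  planted <- sprintf("P%06d", 1:50)
  plan <- flat_plan(planted, subtype = "LuminalA", effect = 2,
                    sigma_individual = 0, sigma_replicate = 0,
                    sigma_residual = 0.1)
  cohort <- generate_cohort(des, plan)
  diffs <- group_mean_diff(cohort$intensities, cohort$annotation, "LuminalA")
  # per-protein SE of the mean difference: residual sd over both groups
  se <- 0.1 * sqrt(1 / (20 * 3) + 1 / (20 * 3))
  expect_true(all(abs(diffs[planted] - 2) < 3 * se + 1e-9))
  expect_true(all(abs(diffs[setdiff(names(diffs), planted)]) < 3 * se + 1e-9))
})

test_that("cohort generation is bit-identical for a fixed seed", {
  des <- small_design(seed = 23)
  plan <- flat_plan(sprintf("P%06d", 1:5))
  a <- generate_cohort(des, plan)
  b <- generate_cohort(des, plan)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$annotation, b$annotation)
})

test_that("invalid plans are rejected", {
  des <- small_design()
  expect_error(
    generate_cohort(des, flat_plan("P000001", subtype = "HER2Plus")),
    "absent from design")
  expect_error(
    generate_cohort(des, flat_plan("P999999")),
    "outside the universe")
  expect_error(effect_plan(list(), sigma_individual = -1), ">= 0")
  expect_error(effect_plan(list(A = c(P000001 = Inf))), "finite")
})

test_that("null cohorts give approximately uniform permutation p-values", {
  des <- cohort_design(n_healthy = 10,
                       subtype_counts = c(LuminalA = 10),
                       n_proteins = 500, n_replicates = 1, seed = 41)
  plan <- effect_plan(list(), sigma_individual = 0.3, sigma_replicate = 0,
                      sigma_residual = 0.3)
  cohort <- generate_cohort(des, plan)
  mat <- quantile_normalize(cohort$intensities)
  res <- diff_test(mat, cohort$annotation, "LuminalA", B = 1000, seed = 6)
  ks <- suppressWarnings(stats::ks.test(res$p_perm, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("block-structured plans share effects within pairs, not across", {
  des <- cohort_design(seed = 13, n_proteins = 616)
  db <- generate_pathway_db(40, c(8, 25), 0.2, 616, seed = 13)
  plan <- effect_plan_blocks(des, db)
  eff <- plan$effects
  jac <- function(a, b) {
    length(intersect(names(a), names(b))) /
      length(union(names(a), names(b)))
  }
  expect_gt(jac(eff$LuminalA, eff$LuminalB), 0.6)
  expect_gt(jac(eff$HER2Plus, eff$BasalLike), 0.6)
  expect_lt(jac(eff$LuminalA, eff$HER2Plus), 0.3)
  expect_lt(jac(eff$LuminalB, eff$BasalLike), 0.3)
  # planted proteins belong to the generated pathway database
  members <- unique(unlist(db, use.names = FALSE))
  expect_true(all(unlist(lapply(eff, names)) %in% members))
})
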