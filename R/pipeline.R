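#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. All random stages derive
#' their seeds from the single `seed`, so identical configurations produce
#' identical outputs.
#'
#' @param seed Integer master seed (required).
#' @param design A [cohort_design()] for simulated input, or `NULL` when
#'   `intensities`/`annotation` paths are given.
#' @param plan An [effect_plan()] (simulated input only; defaults to
#'   [effect_plan_blocks()] on a generated pathway database).
#' @param intensities,annotation,gmt Optional input file paths (TSV, TSV,
#'   GMT) for user data.
#' @param B Permutations per test.
#' @param f_alpha Branch-deciding F-test level.
#' @param estimator Permutation p estimator (`"plain"` or `"plus-one"`).
#' @param cutoffs The three q-value thresholds.
#' @param score_mode Distance-score normalization (`"mean"` or `"sum"`).
#' @param linkage Clustering linkage.
#' @param profile_cutoff Cutoff index for pathway profiles.
#' @param prediction `"resubstitution"`, `"loo"` or `"none"`.
#' @param prediction_metric Metric used for patient prediction.
#' @param min_avg_count Network top-pathway threshold.
#' @param out_dir Output directory.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed, design = NULL, plan = NULL,
                            intensities = NULL, annotation = NULL, gmt = NULL,
                            B = 1000, f_alpha = 0.05,
                            estimator = "plain",
                            cutoffs = c(0.2, 0.1, 0.05),
                            score_mode = "mean", linkage = "average",
                            profile_cutoff = 2,
                            prediction = "resubstitution",
                            prediction_metric = "distance_score",
                            min_avg_count = 5, out_dir = tempfile("pathclust")) {
  if (missing(seed) || is.null(seed)) {
    stop("pipeline_config() requires an explicit seed", call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), design = design, plan = plan,
              intensities = intensities, annotation = annotation, gmt = gmt,
              B = B, f_alpha = f_alpha, estimator = estimator,
              cutoffs = cutoffs, score_mode = score_mode, linkage = linkage,
              profile_cutoff = profile_cutoff, prediction = prediction,
              prediction_metric = prediction_metric,
              min_avg_count = min_avg_count, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pathway-assisted clustering analysis in memory
#'
#' Sequences the stages: normalize, subtype, per-subtype differential tests,
#' significance screening, pathway-protein matrices, the four distance
#' matrices, hierarchical clustering, optional nearest-neighbor prediction,
#' and the pathway association network.
#'
#' @param mat Proteins x sample-replicate log2 intensity matrix.
#' @param annotation Sample annotation tibble (receptor columns required).
#' @param db A `"pathway_db"`.
#' @param config A [pipeline_config()].
#' @return A list with `effects`, `results` (per-subtype [diff_test()]
#'   tibbles), `declared`, `matrices` (per-subtype merged pathway-protein
#'   matrices), `profiles`, `distances` (named list of `subtype_dist`),
#'   `trees` (named list of `merge_tree`), `network`, and optionally
#'   `prediction`.
#' @export
analyze_cohort <- function(mat, annotation, db, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!identical(attr(mat, "scale"), "log2qn")) {
    mat <- quantile_normalize(mat)
  }
  annotation <- add_subtype(annotation)
  present <- intersect(subtype_levels(),
                       unique(as.character(stats::na.omit(annotation$subtype))))
  if (length(present) < 2) stop("need >= 2 subtypes in the cohort", call. = FALSE)

  effects <- fit_subtype_effects(mat, annotation)
  results <- lapply(present, function(s) {
    diff_test(mat, annotation, s, B = config$B,
              seed = config$seed + match(s, subtype_levels()),
              f_alpha = config$f_alpha, estimator = config$estimator)
  })
  names(results) <- present
  declared <- lapply(results, declare_significant, cutoffs = config$cutoffs)
  prot_index <- sort(unique(unlist(lapply(declared, function(d) {
    unlist(d$proteins)
  }))))
  matrices <- lapply(present, function(s) {
    pathway_protein_matrix(declared[[s]], db, results = results[[s]],
                           proteins = prot_index)
  })
  names(matrices) <- present
  profiles <- lapply(matrices, pathway_profile, cutoff = config$profile_cutoff)

  S <- effect_matrix(effects)
  distances <- list(
    protein_intensity = build_distance_matrix(
      stats::setNames(lapply(present, function(s) S[, s]), present),
      metric = "protein_intensity"),
    q_value = build_distance_matrix(
      lapply(results, function(r) r$q), metric = "q_value"),
    pathway_profile = build_distance_matrix(
      profiles, metric = "pathway_profile"),
    distance_score = build_distance_matrix(
      matrices, metric = "distance_score", mode = config$score_mode)
  )
  trees <- lapply(distances, hierarchical_cluster, linkage = config$linkage)

  changed <- vapply(matrices, function(Q) rowSums(Q > 0), numeric(nrow(matrices[[1]])))
  changed <- matrix(changed, nrow = nrow(matrices[[1]]),
                    dimnames = list(rownames(matrices[[1]]), present))
  top <- select_top_pathways(changed, min_avg_count = config$min_avg_count)
  network <- lapply(present, function(s) {
    sel <- if (length(top) >= 2) top else names(db)
    build_pathway_network(db, sel, changed_counts = changed[, s],
                          subtype = s)
  })
  names(network) <- present

  out <- list(effects = effects, results = results, declared = declared,
              matrices = matrices, profiles = profiles, distances = distances,
              trees = trees, changed_counts = changed,
              top_pathways = top, network = network)

  if (!identical(config$prediction, "none")) {
    out$prediction <- predict_cohort(
      mat, annotation, db = db, metric = config$prediction_metric,
      results = results, effects = effects, B = config$B,
      seed = config$seed, f_alpha = config$f_alpha,
      cutoffs = config$cutoffs, profile_cutoff = config$profile_cutoff,
      mode = config$score_mode,
      loo = identical(config$prediction, "loo"))
  }
  out
}

#' Run the pipeline end to end with file outputs and a manifest
#'
#' Resolves inputs (simulating a cohort and pathway database when paths are
#' not given), calls [analyze_cohort()], writes every stage output under
#' `config$out_dir` and returns a manifest with md5 checksums. Identical
#' configurations yield identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param db Optional pre-built `"pathway_db"` (otherwise read from
#'   `config$gmt` or generated).
#' @return A list with `manifest` (tibble: file, stage, md5), `analysis`
#'   (the [analyze_cohort()] result) and `paths`.
#' @export
run_pipeline <- function(config, db = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0); stages <- character(0)
  put <- function(path, stage) {
    files <<- c(files, path); stages <<- c(stages, stage)
    path
  }

  if (!is.null(config$intensities)) {
    mat <- read_intensity_tsv(config$intensities)
    annotation <- read_annotation_tsv(config$annotation)
    if (is.null(db)) db <- read_gmt(config$gmt)
  } else {
    design <- config$design %||% cohort_design(seed = config$seed)
    if (is.null(db)) {
      db <- generate_pathway_db(n_pathways = 40, size_range = c(8, 25),
                                n_proteins = design$n_proteins,
                                seed = config$seed)
    }
    plan <- config$plan %||% effect_plan_blocks(design, db)
    cohort <- generate_cohort(design, plan)
    mat <- cohort$intensities
    annotation <- cohort$annotation
    paths <- write_cohort(cohort, file.path(config$out_dir, "input"))
    for (p in paths) put(p, "simulate")
    put(write_gmt(db, file.path(config$out_dir, "input", "pathways.gmt")),
        "simulate")
  }

  res <- analyze_cohort(mat, annotation, db, config)

  put(write_intensity_tsv(quantile_normalize(mat),
                          file.path(config$out_dir, "normalized.tsv")),
      "normalize")
  readr::write_tsv(res$effects, put(file.path(config$out_dir, "effects.tsv"),
                                    "effects"))
  for (s in names(res$results)) {
    readr::write_tsv(res$results[[s]],
                     put(file.path(config$out_dir,
                                   paste0("difftest_", s, ".tsv")), "test"))
    write_pathway_matrix_tsv(res$matrices[[s]],
                             put(file.path(config$out_dir,
                                           paste0("matrix_", s, ".tsv")),
                                 "pathways"))
  }
  for (m in names(res$distances)) {
    write_distance_tsv(res$distances[[m]],
                       put(file.path(config$out_dir,
                                     paste0("dist_", m, ".tsv")), "distances"))
    writeLines(to_newick(res$trees[[m]]),
               put(file.path(config$out_dir, paste0("tree_", m, ".nwk")),
                   "cluster"))
  }
  for (s in names(res$network)) {
    write_network_graphml(res$network[[s]],
                          put(file.path(config$out_dir,
                                        paste0("network_", s, ".graphml")),
                              "network"))
  }
  if (!is.null(res$prediction)) {
    readr::write_tsv(res$prediction$predictions,
                     put(file.path(config$out_dir, "predictions.tsv"),
                         "predict"))
    readr::write_tsv(res$prediction$summary,
                     put(file.path(config$out_dir, "prediction_summary.tsv"),
                         "predict"))
  }

  manifest <- tibble::tibble(
    file = basename(files), stage = stages,
    md5 = unname(tools::md5sum(files))
  )
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  list(manifest = manifest, analysis = res, paths = files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
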