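#' Cohort design for synthetic plasma proteomics studies
#'
#' Defaults emulate the study conditions of a plasma proteomics breast cancer
#' cohort: 80 healthy controls, 80 patients split over the IHC subtypes as
#' 24 LuminalA / 15 LuminalB / 10 HER2Plus / 19 BasalLike / 12 Unknown,
#' 616 quantified proteins, and 2 replicate injections per plasma sample.
#'
#' @param n_healthy Number of healthy individuals.
#' @param subtype_counts Named integer vector of patients per subtype; names
#'   must be a subset of [subtype_levels()].
#' @param n_proteins Size of the protein universe (accessions
#'   `"P000001"`...).
#' @param n_replicates Replicate injections per individual.
#' @param seed Integer seed driving all cohort randomness.
#' @return A list of class `"cohort_design"`.
#' @export
cohort_design <- function(n_healthy = 80,
                          subtype_counts = c(LuminalA = 24, LuminalB = 15,
                                             HER2Plus = 10, BasalLike = 19,
                                             Unknown = 12),
                          n_proteins = 616, n_replicates = 2, seed = 1L) {
  if (n_healthy < 1 || n_proteins < 1 || n_replicates < 1 ||
      any(subtype_counts < 1)) {
    stop("all design counts must be positive", call. = FALSE)
  }
  bad <- setdiff(names(subtype_counts), subtype_levels())
  if (length(bad)) stop("unknown subtype(s): ", toString(bad), call. = FALSE)
  structure(list(n_healthy = as.integer(n_healthy),
                 subtype_counts = subtype_counts,
                 n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

protein_universe <- function(n) sprintf("P%06d", seq_len(n))

#' Generate a synthetic pathway database
#'
#' Draws `n_pathways` protein sets from a universe of synthetic accessions.
#' With `overlap_fraction = 0` the pathways are disjoint (sizes permitting);
#' otherwise each pathway draws roughly that fraction of its members from a
#' shared pool, so the expected pairwise overlap rises with
#' `overlap_fraction`.
#'
#' @param n_pathways Number of pathways (>= 2).
#' @param size_range Integer length-2 vector: min/max pathway size.
#' @param overlap_fraction Fraction in \[0, 1) of each pathway drawn from a
#'   common shared pool.
#' @param n_proteins Universe size.
#' @param seed Integer seed.
#' @return A named list of character vectors (class `"pathway_db"`), pathway
#'   name to protein accessions, with a `description` attribute.
#' @export
generate_pathway_db <- function(n_pathways = 215, size_range = c(5, 40),
                                overlap_fraction = 0.2, n_proteins = 616,
                                seed = 1L) {
  if (n_pathways < 2) stop("need at least 2 pathways", call. = FALSE)
  if (size_range[1] < 1) stop("invalid size_range: lower bound < 1", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)", call. = FALSE)
  }
  universe <- protein_universe(n_proteins)
  db <- withr::with_seed(seed, {
    sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
    if (overlap_fraction == 0) {
      # disjoint construction: partition the universe, recycling forbidden
      if (sum(sizes) > n_proteins) {
        sizes <- pmax(size_range[1], floor(sizes * n_proteins / sum(sizes)))
        if (sum(sizes) > n_proteins) {
          stop("universe too small for disjoint pathways of this size",
               call. = FALSE)
        }
      }
      pool <- sample(universe)
      ends <- cumsum(sizes)
      starts <- c(1, utils::head(ends, -1) + 1)
      lapply(seq_len(n_pathways), function(i) sort(pool[starts[i]:ends[i]]))
    } else {
      shared <- sample(universe, max(2, round(n_proteins * overlap_fraction)))
      lapply(seq_len(n_pathways), function(i) {
        k_shared <- round(sizes[i] * overlap_fraction)
        members <- c(sample(shared, min(k_shared, length(shared))),
                     sample(setdiff(universe, shared),
                            sizes[i] - min(k_shared, length(shared))))
        sort(unique(members))
      })
    }
  })
  names(db) <- sprintf("pathway_%03d", seq_len(n_pathways))
  attr(db, "description") <- sprintf("synthetic pathway %03d",
                                     seq_len(n_pathways))
  class(db) <- "pathway_db"
  db
}

#' Plan of planted differential effects for a synthetic cohort
#'
#' Low-level constructor. `effects` is a named list (one element per
#' subtype) of named numeric vectors: protein accession to signed log2
#' effect. `active_pathways` names the pathways the effects were drawn from.
#'
#' @param effects Named list of named numeric vectors (subtype -> protein ->
#'   log2 effect), all finite.
#' @param active_pathways Named list of character vectors (subtype ->
#'   pathway names).
#' @param sigma_individual,sigma_replicate,sigma_residual Nonnegative
#'   standard deviations (log2 units) of the individual biological effect,
#'   the per-injection global shift, and the residual.
#' @param baseline_mean,baseline_sd Distribution of per-protein baseline
#'   log2 abundance.
#' @return A list of class `"effect_plan"`.
#' @export
effect_plan <- function(effects, active_pathways = list(),
                        sigma_individual = 0.4, sigma_replicate = 0.15,
                        sigma_residual = 0.3,
                        baseline_mean = 22, baseline_sd = 1.5) {
  if (any(c(sigma_individual, sigma_replicate, sigma_residual) < 0)) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  if (!all(vapply(effects, function(e) all(is.finite(e)), logical(1)))) {
    stop("effect sizes must be finite", call. = FALSE)
  }
  structure(list(effects = effects, active_pathways = active_pathways,
                 sigma_individual = sigma_individual,
                 sigma_replicate = sigma_replicate,
                 sigma_residual = sigma_residual,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "effect_plan")
}

#' Block-structured effect plan: a luminal pair and a basal pair
#'
#' Builds the default planted structure used throughout validation: the two
#' luminal subtypes share a pool of differential proteins drawn from a set
#' of luminal-active pathways, the HER2Plus/BasalLike pair shares another
#' pool, and the Unknown subtype gets its own. Within a pair, the second
#' member keeps `overlap_within` of the pool and swaps the rest for proteins
#' from the other pair's pool (`overlap_between`), so within-pair effect
#' vectors are strongly correlated and cross-pair vectors weakly.
#'
#' @param design A [cohort_design()].
#' @param db A pathway database ([generate_pathway_db()]).
#' @param n_pathways_per_block Active pathways per block.
#' @param pool_size Differential proteins per block pool.
#' @param effect_size Log2 effect magnitude; signs alternate per protein.
#' @param overlap_within,overlap_between Fractions shared within a pair /
#'   leaked across pairs.
#' @param ... Passed on to [effect_plan()] (variance components etc.).
#' @return An `"effect_plan"`.
#' @export
effect_plan_blocks <- function(design, db, n_pathways_per_block = 4,
                               pool_size = 40, effect_size = 1.5,
                               overlap_within = 0.9, overlap_between = 0.1,
                               ...) {
  stopifnot(inherits(design, "cohort_design"), inherits(db, "pathway_db"))
  blocks <- list(luminal = c("LuminalA", "LuminalB"),
                 basal = c("HER2Plus", "BasalLike"),
                 unknown = "Unknown")
  blocks <- lapply(blocks, intersect, x = names(design$subtype_counts))
  blocks <- blocks[lengths(blocks) > 0]
  if (3 * n_pathways_per_block > length(db)) {
    stop("pathway database too small for the requested blocks", call. = FALSE)
  }
  withr::with_seed(design$seed + 1L, {
    pw_names <- names(db)
    pw_assign <- split(pw_names[seq_len(length(blocks) * n_pathways_per_block)],
                       rep(names(blocks), each = n_pathways_per_block))
    pools <- lapply(pw_assign, function(pws) {
      members <- unique(unlist(db[pws], use.names = FALSE))
      sample(members, min(pool_size, length(members)))
    })
    signs <- lapply(pools, function(p) {
      stats::setNames(effect_size * rep_len(c(1, -1), length(p)), p)
    })
    effects <- list()
    pathways <- list()
    other <- c(luminal = "basal", basal = "luminal", unknown = "luminal")
    for (bl in names(blocks)) {
      pool_eff <- signs[[bl]]
      for (k in seq_along(blocks[[bl]])) {
        s <- blocks[[bl]][k]
        if (k == 1) {
          effects[[s]] <- pool_eff
        } else {
          keep <- sample(names(pool_eff), round(overlap_within * length(pool_eff)))
          leak_pool <- signs[[other[[bl]]]]
          leak <- sample(names(leak_pool),
                         min(round(overlap_between * length(pool_eff)),
                             length(leak_pool)))
          effects[[s]] <- c(pool_eff[keep], leak_pool[leak])
        }
        pathways[[s]] <- pw_assign[[bl]]
      }
    }
    effect_plan(effects, active_pathways = pathways, ...)
  })
}

#' Generate a synthetic plasma proteomics cohort
#'
#' Simulates log2 intensities under the additive model: per-protein baseline
#' + planted subtype effect (cancer samples only) + Gaussian per-individual
#' biological effect (per protein) + Gaussian per-injection shift (shared
#' across proteins within a column, what quantile normalization removes) +
#' Gaussian residual. Receptor statuses are set from each patient's true
#' subtype (so [assign_subtype()] recovers the label); Unknown patients get
#' all-missing status.
#'
#' @param design A [cohort_design()].
#' @param plan An [effect_plan()]; all planted proteins must be inside the
#'   design's protein universe, and every subtype in the plan must appear in
#'   the design.
#' @param dropout Completely-at-random missingness fraction (default 0).
#' @return A list with `intensities` (proteins x sample-replicates, log2),
#'   `annotation` (tibble: sample_id, individual_id, group, replicate, ER,
#'   PR, HER2, subtype), and `truth` (per-subtype differential protein and
#'   active pathway sets, true label per patient, and the plan).
#' @export
generate_cohort <- function(design, plan, dropout = 0) {
  stopifnot(inherits(design, "cohort_design"), inherits(plan, "effect_plan"))
  universe <- protein_universe(design$n_proteins)
  bad_sub <- setdiff(names(plan$effects), names(design$subtype_counts))
  if (length(bad_sub)) {
    stop("plan subtype(s) absent from design: ", toString(bad_sub),
         call. = FALSE)
  }
  bad_prot <- setdiff(unlist(lapply(plan$effects, names)), universe)
  if (length(bad_prot)) {
    stop("planted protein(s) outside the universe: ",
         toString(utils::head(bad_prot, 5)), call. = FALSE)
  }

  subtypes <- rep(names(design$subtype_counts), design$subtype_counts)
  n_cancer <- length(subtypes)
  n_ind <- design$n_healthy + n_cancer
  r <- design$n_replicates
  ind_id <- sprintf("I%03d", seq_len(n_ind))
  group <- c(rep("cancer", n_cancer), rep("healthy", design$n_healthy))
  true_sub <- c(subtypes, rep(NA_character_, design$n_healthy))

  P <- design$n_proteins
  withr::with_seed(design$seed, {
    baseline <- stats::rnorm(P, plan$baseline_mean, plan$baseline_sd)
    eff <- matrix(0, P, n_ind, dimnames = list(universe, ind_id))
    for (s in names(plan$effects)) {
      e <- plan$effects[[s]]
      cols <- which(!is.na(true_sub) & true_sub == s)
      eff[names(e), cols] <- e
    }
    ind_eff <- matrix(stats::rnorm(P * n_ind, 0, plan$sigma_individual),
                      P, n_ind)
    n_col <- n_ind * r
    inj_shift <- stats::rnorm(n_col, 0, plan$sigma_replicate)
    resid <- matrix(stats::rnorm(P * n_col, 0, plan$sigma_residual), P, n_col)

    per_ind <- baseline + eff + ind_eff
    mat <- per_ind[, rep(seq_len(n_ind), each = r), drop = FALSE] +
      rep(inj_shift, each = P) + resid
    sample_id <- paste0(rep(ind_id, each = r), "_r", rep(seq_len(r), n_ind))
    dimnames(mat) <- list(universe, sample_id)
    if (dropout > 0) {
      mat[stats::runif(length(mat)) < dropout] <- NA_real_
    }

    status <- receptor_status(ifelse(is.na(true_sub), "Unknown", true_sub))
    status[is.na(true_sub), ] <- NA_character_
    annotation <- tibble::tibble(
      sample_id = sample_id,
      individual_id = rep(ind_id, each = r),
      group = rep(group, each = r),
      replicate = rep(seq_len(r), n_ind),
      ER = rep(status$ER, each = r),
      PR = rep(status$PR, each = r),
      HER2 = rep(status$HER2, each = r)
    )
    annotation <- add_subtype(annotation)
    attr(mat, "scale") <- "log2"
    list(
      intensities = mat,
      annotation = annotation,
      truth = list(
        differential = lapply(plan$effects, names),
        active_pathways = plan$active_pathways,
        label = stats::setNames(true_sub[seq_len(n_cancer)],
                                ind_id[seq_len(n_cancer)]),
        plan = plan
      )
    )
  })
}

#' Write a cohort's artifacts to disk
#'
#' Writes the intensity matrix TSV, annotation TSV and ground-truth JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    intensities = file.path(dir, "intensities.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_intensity_tsv(cohort$intensities, paths[["intensities"]])
  write_annotation_tsv(cohort$annotation, paths[["annotation"]])
  truth <- cohort$truth
  truth$plan <- NULL
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = FALSE)
  invisible(paths)
}
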