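# Shared fixture builders (all generated in code at test time).

# small two-subtype cohort for fast unit tests
small_design <- function(seed = 11L, n_proteins = 60, n_replicates = 2,
                         counts = c(LuminalA = 8, BasalLike = 8),
                         n_healthy = 10) {
  cohort_design(n_healthy = n_healthy, subtype_counts = counts,
                n_proteins = n_proteins, n_replicates = n_replicates,
                seed = seed)
}

# plan planting a fixed effect on chosen proteins of one subtype
flat_plan <- function(proteins, subtype = "LuminalA", effect = 2,
                      sigma_individual = 0, sigma_replicate = 0,
                      sigma_residual = 0.1, ...) {
  eff <- stats::setNames(rep(effect, length(proteins)), proteins)
  effect_plan(stats::setNames(list(eff), subtype),
              sigma_individual = sigma_individual,
              sigma_replicate = sigma_replicate,
              sigma_residual = sigma_residual, ...)
}

# direct (non-pipeline) group-mean oracle on an intensity matrix
group_mean_diff <- function(mat, annotation, subtype) {
  cases <- annotation$sample_id[!is.na(annotation$subtype) &
                                  annotation$subtype == subtype]
  healthy <- annotation$sample_id[annotation$group == "healthy"]
  rowMeans(mat[, cases, drop = FALSE]) - rowMeans(mat[, healthy, drop = FALSE])
}

# tiny pathway db as a plain list
toy_db <- function(sets) {
  structure(sets, class = "pathway_db")
}
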