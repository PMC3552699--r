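#' Hierarchical clustering of a subtype distance matrix
#'
#' Agglomerative clustering via `stats::hclust` with average (UPGMA), single
#' or complete linkage. Ties are broken deterministically by label order.
#'
#' @param D A `"subtype_dist"` or plain symmetric labelled matrix.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return A `"merge_tree"`: list with the underlying `hclust`, the leaf
#'   `labels`, the `linkage`, and `merges`, a tibble with one row per merge
#'   (`step`, `height`, `members_a`, `members_b` as list columns).
#' @export
hierarchical_cluster <- function(D, linkage = c("average", "single",
                                                "complete")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(D)
  if (anyNA(m)) stop("distance matrix contains NA", call. = FALSE)
  if (nrow(m) < 2) stop("need at least 2 labels", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  members <- function(k) {
    if (k < 0) hc$labels[-k] else unlist(Recall(hc$merge[k, 1]),
                                         use.names = FALSE)
  }
  # expand each merge row into its two member sets
  expand <- function(idx) {
    if (idx < 0) return(hc$labels[-idx])
    c(expand(hc$merge[idx, 1]), expand(hc$merge[idx, 2]))
  }
  merges <- tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    height = hc$height,
    members_a = lapply(hc$merge[, 1], expand),
    members_b = lapply(hc$merge[, 2], expand)
  )
  structure(list(hclust = hc, labels = hc$labels, linkage = linkage,
                 merges = merges),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("Agglomerative tree (", x$linkage, " linkage), ",
      length(x$labels), " leaves\n", sep = "")
  for (i in seq_len(nrow(x$merges))) {
    cat(sprintf("  %d: {%s} + {%s} at %.4g\n", i,
                paste(x$merges$members_a[[i]], collapse = ","),
                paste(x$merges$members_b[[i]], collapse = ","),
                x$merges$height[i]))
  }
  invisible(x)
}

#' Serialize a merge tree as Newick text
#'
#' Branch lengths derive from merge heights (each leaf sits at half the
#' height of its first merge, ultrametric).
#'
#' @param tree A `"merge_tree"`.
#' @return A Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy)
}

#' Test whether a set of labels forms a clade of the tree
#'
#' @param tree A `"merge_tree"`.
#' @param labels Character vector of leaf labels.
#' @return TRUE when some merge step joins exactly these labels.
#' @export
is_clade <- function(tree, labels) {
  labels <- sort(labels)
  any(vapply(seq_len(nrow(tree$merges)), function(i) {
    identical(sort(c(tree$merges$members_a[[i]],
                     tree$merges$members_b[[i]])), labels)
  }, logical(1)))
}

#' Nearest-neighbor subtype prediction
#'
#' Finds the exemplar closest to the patient profile under the chosen metric
#' and predicts that exemplar's subtype. Ties are broken by the canonical
#' subtype order ([subtype_levels()]) and flagged.
#'
#' @param profile Patient profile: numeric vector (correlation metrics) or
#'   merged pathway-protein matrix (`distance_score`).
#' @param exemplars Named list of subtype exemplars of the same shape.
#' @param metric,mode As in [build_distance_matrix()].
#' @param ... Passed to [corr_distance()].
#' @return A list: `label` (predicted subtype), `distances` (named vector),
#'   `tie` (logical).
#' @export
nn_predict <- function(profile, exemplars,
                       metric = c("protein_intensity", "q_value",
                                  "pathway_profile", "distance_score"),
                       mode = c("mean", "sum"), ...) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (length(exemplars) < 2) stop("need >= 2 exemplars", call. = FALSE)
  pairfun <- if (metric == "distance_score") {
    function(a, b) dist_score(a, b, mode = mode)
  } else {
    function(a, b) corr_distance(a, b, ...)
  }
  d <- vapply(exemplars, function(e) {
    tryCatch(pairfun(profile, e), error = function(err) NA_real_)
  }, numeric(1))
  if (all(is.na(d))) {
    stop("distance undefined for every exemplar", call. = FALSE)
  }
  ord <- intersect(subtype_levels(), names(d))
  ord <- c(ord, setdiff(names(d), ord))  # canonical order first
  d <- d[ord]
  best <- min(d, na.rm = TRUE)
  hits <- names(d)[!is.na(d) & d == best]
  list(label = hits[1], distances = d, tie = length(hits) > 1)
}

#' Evaluate subtype predictions against the truth
#'
#' Reports true positives and accuracy twice: over all evaluated patients
#' (five-subtype scope, Unknown included) and over patients whose true label
#' is one of the four known subtypes.
#'
#' @param predictions Tibble/data frame with columns `individual_id`,
#'   `predicted`, `truth` (plus any extras, kept).
#' @return A `"prediction_eval"`: the per-patient tibble plus a `summary`
#'   tibble with `scope`, `n`, `true_positives`, `accuracy`.
#' @export
evaluate_predictions <- function(predictions) {
  predictions <- tibble::as_tibble(predictions)
  need <- c("predicted", "truth")
  if (!all(need %in% names(predictions))) {
    stop("predictions need 'predicted' and 'truth' columns", call. = FALSE)
  }
  bad <- setdiff(unique(c(predictions$predicted, predictions$truth)),
                 subtype_levels())
  if (length(bad)) stop("unknown label(s): ", toString(bad), call. = FALSE)
  correct <- predictions$predicted == predictions$truth
  known <- predictions$truth != "Unknown"
  summary <- tibble::tibble(
    scope = c("all_five_subtypes", "four_known_subtypes"),
    n = c(length(correct), sum(known)),
    true_positives = c(sum(correct), sum(correct & known)),
    accuracy = c(mean(correct),
                 if (any(known)) mean(correct[known]) else NA_real_)
  )
  structure(list(predictions = predictions, summary = summary),
            class = "prediction_eval")
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat("Nearest-neighbor subtype prediction\n")
  print(x$summary)
  invisible(x)
}

#' Predict every patient's subtype by nearest-neighbor matching
#'
#' Cohort-level wrapper: builds subtype exemplars and per-patient profiles
#' for the chosen metric and runs [nn_predict()] for every patient.
#' Exemplars are built from all patients of the subtype (resubstitution,
#' the default) or excluding the test patient (`loo = TRUE`; only the
#' `protein_intensity` metric supports leave-one-out cheaply and other
#' metrics refuse it).
#'
#' Profiles per metric: `protein_intensity` matches the patient's mean
#' replicate intensities against the fitted subtype fixed-effect vectors;
#' `q_value` matches per-patient q vectors ([patient_qvalue_profile()])
#' against subtype q vectors; `pathway_profile` and `distance_score` screen
#' each patient's q vector at the three cutoffs and match pathway profiles /
#' merged matrices against the subtype ones.
#'
#' @param mat,annotation Cohort intensity matrix (normalized) and annotation
#'   with `subtype`.
#' @param db Pathway database (pathway-based metrics).
#' @param metric One of the four metrics.
#' @param results Named list of per-subtype [diff_test()] tibbles (q-value /
#'   pathway metrics); computed if missing.
#' @param effects [fit_subtype_effects()] table (intensity metric); computed
#'   if missing.
#' @param B,seed,f_alpha Testing parameters for per-patient screens.
#' @param cutoffs Significance cutoffs for pathway-based metrics.
#' @param profile_cutoff Cutoff index used for pathway profiles.
#' @param mode Distance-score normalization.
#' @param loo Leave-one-out exemplars (intensity metric only).
#' @return A `"prediction_eval"` (see [evaluate_predictions()]).
#' @export
predict_cohort <- function(mat, annotation, db = NULL,
                           metric = c("protein_intensity", "q_value",
                                      "pathway_profile", "distance_score"),
                           results = NULL, effects = NULL,
                           B = 1000, seed = 1L, f_alpha = 0.05,
                           cutoffs = c(0.2, 0.1, 0.05), profile_cutoff = 2,
                           mode = c("mean", "sum"), loo = FALSE) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  ann <- annotation
  patients <- unique(ann$individual_id[ann$group == "cancer"])
  truth <- stats::setNames(
    as.character(ann$subtype[match(patients, ann$individual_id)]), patients)
  present <- intersect(subtype_levels(), unique(stats::na.omit(truth)))

  if (metric == "protein_intensity") {
    if (is.null(effects)) {
      effects <- fit_subtype_effects(mat, ann)
    }
    S <- effect_matrix(effects)
    preds <- purrr::map(patients, function(p) {
      cols <- ann$sample_id[ann$individual_id == p]
      prof <- rowMeans(mat[, cols, drop = FALSE])
      if (loo) {
        ex <- loo_intensity_exemplars(mat, ann, p, present)
      } else {
        ex <- lapply(present, function(s) S[, s])
        names(ex) <- present
      }
      nn_predict(prof, ex, metric = metric)
    })
  } else {
    if (is.null(results)) {
      results <- lapply(present, function(s) {
        diff_test(mat, ann, s, B = B, seed = seed + match(s, subtype_levels()),
                  f_alpha = f_alpha)
      })
      names(results) <- present
    }
    if (loo) {
      stop("leave-one-out exemplars are only implemented for the ",
           "protein_intensity metric", call. = FALSE)
    }
    if (metric == "q_value") {
      ex <- lapply(results, function(r) r$q)
    } else {
      if (is.null(db)) stop("pathway metrics need a pathway database",
                            call. = FALSE)
      all_declared <- lapply(results, declare_significant, cutoffs = cutoffs)
      prot_index <- sort(unique(unlist(lapply(all_declared, function(d) {
        unlist(d$proteins)
      }))))
      sub_Q <- lapply(names(results), function(s) {
        pathway_protein_matrix(all_declared[[s]], db, proteins = prot_index)
      })
      names(sub_Q) <- names(results)
    }
    preds <- purrr::map(patients, function(p) {
      pq <- patient_qvalue_profile(mat, ann, p, B = B,
                                   seed = seed + 1000L +
                                     match(p, patients), f_alpha = f_alpha)
      if (metric == "q_value") {
        return(nn_predict(pq$q, ex, metric = metric))
      }
      decl <- declare_significant(pq, cutoffs = cutoffs)
      Qp <- pathway_protein_matrix(decl, db, proteins = prot_index)
      if (metric == "pathway_profile") {
        prof <- pathway_profile(Qp, cutoff = profile_cutoff)
        exp_prof <- lapply(sub_Q, pathway_profile, cutoff = profile_cutoff)
        nn_predict(prof, exp_prof, metric = metric, on_zero_var = "one")
      } else {
        nn_predict(Qp, sub_Q, metric = metric, mode = mode)
      }
    })
  }
  out <- tibble::tibble(
    individual_id = patients,
    predicted = purrr::map_chr(preds, "label"),
    truth = unname(truth),
    tie = purrr::map_lgl(preds, "tie")
  )
  ev <- evaluate_predictions(out)
  ev$metric <- metric
  ev
}

loo_intensity_exemplars <- function(mat, ann, patient, present) {
  keep <- ann[ann$individual_id != patient, , drop = FALSE]
  eff <- fit_subtype_effects(mat[, keep$sample_id, drop = FALSE], keep,
                             method = "means")
  S <- effect_matrix(eff)
  ex <- lapply(intersect(present, colnames(S)), function(s) S[, s])
  names(ex) <- intersect(present, colnames(S))
  ex
}
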