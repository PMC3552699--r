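#' Pearson correlation distance
#'
#' `1 - cor(u, v)` over pairwise-complete entries, the distance underlying
#' the protein-intensity, q-value and pathway-profile metrics. Lies in
#' \[0, 2\].
#'
#' @param u,v Numeric vectors of equal length with at least `min_complete`
#'   shared finite entries.
#' @param min_complete Minimum number of pairwise-complete entries.
#' @param on_zero_var `"error"` (default) or `"one"`: what to do when either
#'   vector is constant over the complete entries.
#' @return The distance (scalar).
#' @export
corr_distance <- function(u, v, min_complete = 3,
                          on_zero_var = c("error", "one")) {
  on_zero_var <- match.arg(on_zero_var)
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(u) & is.finite(v)
  if (sum(ok) < min_complete) {
    stop("fewer than ", min_complete, " pairwise-complete entries",
         call. = FALSE)
  }
  u <- u[ok]; v <- v[ok]
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    if (on_zero_var == "one") {
      warning("zero variance; returning distance 1")
      return(1)
    }
    stop("undefined correlation distance: zero variance", call. = FALSE)
  }
  1 - stats::cor(u, v)
}

#' Distance score between two pathway-protein matrices
#'
#' Sum of absolute entry differences between the merged pathway-protein
#' matrices of two subtypes (or a subtype and a patient), optionally
#' normalized by the matrix size `m * n`. Entries are cutoff indices 0..3,
#' so the mean-mode distance lies in \[0, 3\] and the sum mode in
#' \[0, 3mn\]. Hierarchical clustering is invariant to the choice since the
#' two differ by the positive constant `1 / (m n)`.
#'
#' @param Qs,Qt Merged matrices on the same pathway x protein index.
#' @param mode `"mean"` (normalized, default) or `"sum"`.
#' @return The distance (scalar).
#' @export
dist_score <- function(Qs, Qt, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (!identical(dim(Qs), dim(Qt)) ||
      !identical(dimnames(Qs), dimnames(Qt))) {
    stop("matrices must share the same pathway x protein index", call. = FALSE)
  }
  total <- sum(abs(Qs - Qt))
  if (mode == "mean") total / (nrow(Qs) * ncol(Qs)) else total
}

#' Assemble a labelled distance matrix from per-label profiles
#'
#' Computes all pairwise distances between profiles under one of the four
#' metrics: `protein_intensity`, `q_value` and `pathway_profile` use the
#' Pearson correlation distance on their respective vectors; `distance_score`
#' uses [dist_score()] on merged pathway-protein matrices.
#'
#' @param profiles Named list (>= 2 labels) of numeric vectors (correlation
#'   metrics) or matrices (`distance_score`).
#' @param metric One of `"protein_intensity"`, `"q_value"`,
#'   `"pathway_profile"`, `"distance_score"`.
#' @param mode Normalization for `distance_score` (`"mean"` or `"sum"`).
#' @param ... Passed to [corr_distance()].
#' @return A `"subtype_dist"` object: the symmetric zero-diagonal matrix
#'   with `metric` and `mode` attributes.
#' @export
build_distance_matrix <- function(profiles,
                                  metric = c("protein_intensity", "q_value",
                                             "pathway_profile",
                                             "distance_score"),
                                  mode = c("mean", "sum"), ...) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  labels <- names(profiles)
  if (length(labels) < 2) stop("need at least 2 labelled profiles", call. = FALSE)
  pairfun <- if (metric == "distance_score") {
    function(a, b) dist_score(a, b, mode = mode)
  } else {
    function(a, b) corr_distance(a, b, ...)
  }
  n <- length(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pairfun(profiles[[i]], profiles[[j]])
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(D, metric = metric, mode = mode, class = c("subtype_dist", "matrix"))
}

#' Convert a plain labelled matrix into a subtype_dist object
#'
#' Validates symmetry, nonnegativity and a zero diagonal.
#'
#' @param m Square numeric matrix with identical row/column labels.
#' @param metric Metric tag to attach.
#' @param mode Normalization tag.
#' @return A `"subtype_dist"`.
#' @export
as_subtype_dist <- function(m, metric = "distance_score", mode = "sum") {
  m <- as.matrix(m)
  if (!isSymmetric(unname(m)) || any(diag(m) != 0) || any(m < 0)) {
    stop("not a valid distance matrix (symmetry / zero diagonal / >= 0)",
         call. = FALSE)
  }
  structure(m, metric = metric, mode = mode,
            class = c("subtype_dist", "matrix"))
}

#' Read/write labelled distance matrices as TSV
#'
#' @param D A `"subtype_dist"` (or plain labelled matrix) / a file path.
#' @param path Output path.
#' @name distance_io
#' @export
write_distance_tsv <- function(D, path) {
  readr::write_tsv(tibble::as_tibble(unclass(D), rownames = "label"), path)
  invisible(path)
}

#' @rdname distance_io
#' @export
read_distance_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  as_subtype_dist(m)
}

#' Per-patient q-value profile against the healthy cohort
#'
#' Runs the three-step significance procedure protein-by-protein between all
#' healthy individuals (replicates averaged) and one patient's replicate
#' measurements, giving the per-patient q vector used by the q-value and
#' pathway-based prediction metrics.
#'
#' @param mat Proteins x sample-replicate matrix.
#' @param annotation Annotation tibble (needs `sample_id`, `individual_id`,
#'   `group`).
#' @param patient Individual id of the patient.
#' @param B,seed,f_alpha,estimator Passed to [permutation_test_matrix()].
#' @return A tibble like [diff_test()]'s (protein_id, statistic, ...,
#'   q, direction).
#' @export
patient_qvalue_profile <- function(mat, annotation, patient, B = 1000,
                                   seed = NULL, f_alpha = 0.05,
                                   estimator = c("plain", "plus-one")) {
  estimator <- match.arg(estimator)
  healthy_ids <- unique(annotation$individual_id[annotation$group == "healthy"])
  if (length(healthy_ids) == 0) stop("no healthy samples", call. = FALSE)
  pat_cols <- annotation$sample_id[annotation$individual_id == patient]
  if (length(pat_cols) < 2) {
    stop("patient '", patient, "' needs >= 2 replicate measurements",
         call. = FALSE)
  }
  h_ann <- annotation[annotation$group == "healthy", , drop = FALSE]
  H <- collapse_replicates(mat[, h_ann$sample_id, drop = FALSE], h_ann)
  X <- cbind(H, mat[, pat_cols, drop = FALSE])
  res <- permutation_test_matrix(X, n1 = ncol(H), B = B, seed = seed,
                                 f_alpha = f_alpha, estimator = estimator)
  stor <- storey_qvalue(res$p_perm)
  tibble::tibble(
    protein_id = rownames(mat),
    statistic = res$statistic, df = res$df, branch = res$branch,
    p_obs = res$p_obs, p_perm = res$p_perm, p_bh = bh_adjust(res$p_perm),
    q = stor$qvalue,
    direction = ifelse(rowMeans(mat[, pat_cols, drop = FALSE]) >=
                         rowMeans(H), "up", "down")
  )
}
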