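#' Quantile-normalize a log2 intensity matrix
#'
#' Forces every column to the same distribution: each value is replaced by
#' the across-column mean of its rank, with ties within a column receiving
#' the mean of their rank values (delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`). Missing values are tolerated
#' and preserved in place.
#'
#' @param mat Numeric proteins x sample matrix of log2 intensities with >= 2
#'   columns.
#' @return The normalized matrix with attribute `scale = "log2qn"`.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) stop("need at least 2 columns", call. = FALSE)
  if (identical(attr(mat, "scale"), "log2qn")) return(mat)
  all_na <- colSums(!is.na(mat)) == 0
  if (any(all_na)) {
    stop("column(s) entirely missing: ",
         toString(colnames(mat)[all_na]), call. = FALSE)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  attr(out, "scale") <- "log2qn"
  out
}

#' Average peptide rows into protein rows
#'
#' Each protein's row is the arithmetic mean of its peptides' normalized
#' log2 rows; single-peptide proteins pass through unchanged.
#'
#' @param peptide_mat Peptides x samples matrix with peptide row names.
#' @param peptide_to_protein Named character vector or two-column data frame
#'   (`peptide`, `protein`) mapping every peptide to exactly one protein.
#' @return Proteins x samples matrix (rows ordered by first appearance).
#' @export
aggregate_to_protein <- function(peptide_mat, peptide_to_protein) {
  stopifnot(is.matrix(peptide_mat))
  if (is.data.frame(peptide_to_protein)) {
    map <- stats::setNames(as.character(peptide_to_protein[[2]]),
                           as.character(peptide_to_protein[[1]]))
  } else {
    map <- peptide_to_protein
  }
  if (length(map) == 0) stop("empty peptide-to-protein mapping", call. = FALSE)
  peptides <- rownames(peptide_mat)
  unmapped <- setdiff(peptides, names(map))
  if (length(unmapped)) {
    stop("unmapped peptide(s): ", toString(utils::head(unmapped, 10)),
         call. = FALSE)
  }
  prot <- map[peptides]
  groups <- split(seq_along(peptides), factor(prot, levels = unique(prot)))
  out <- t(vapply(groups, function(i) {
    colMeans(peptide_mat[i, , drop = FALSE])
  }, numeric(ncol(peptide_mat))))
  colnames(out) <- colnames(peptide_mat)
  attr(out, "scale") <- attr(peptide_mat, "scale")
  out
}

#' Collapse replicate injections to per-individual intensities
#'
#' Averages the replicate columns of every individual, yielding one column
#' per individual. Used by the differential tests so that permutations move
#' all replicates of an individual together.
#'
#' @param mat Proteins x sample-replicate matrix, columns named by
#'   `sample_id`.
#' @param annotation Annotation tibble with `sample_id`, `individual_id`,
#'   `group` (and optionally `subtype`).
#' @return Proteins x individuals matrix; attribute `"individuals"` holds a
#'   one-row-per-individual annotation tibble.
#' @export
collapse_replicates <- function(mat, annotation) {
  stopifnot(is.matrix(mat))
  miss <- setdiff(annotation$sample_id, colnames(mat))
  if (length(miss)) {
    stop("annotation sample(s) absent from matrix: ",
         toString(utils::head(miss, 5)), call. = FALSE)
  }
  ids <- unique(annotation$individual_id)
  out <- vapply(ids, function(i) {
    cols <- annotation$sample_id[annotation$individual_id == i]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat))
  rownames(out) <- rownames(mat)
  colnames(out) <- ids
  ind <- annotation[!duplicated(annotation$individual_id),
                    intersect(c("individual_id", "group", "subtype",
                                "ER", "PR", "HER2"), names(annotation))]
  attr(out, "individuals") <- tibble::as_tibble(ind)
  out
}

#' Per-protein subtype fixed effects from the mixed model
#'
#' Fits, for every protein on the cancer samples, the model
#' `y = mu + S_subtype + I_individual + error` with a random individual
#' intercept, by restricted maximum likelihood. Fixed subtype effects use a
#' sum-to-zero constraint so the per-protein effect vectors are directly
#' comparable across proteins. Each individual carries a single subtype, so
#' a subtype-by-individual interaction is not identifiable and is absorbed
#' into the individual effect (its variance is reported as `NA`).
#'
#' For designs with the same number of replicates for every individual the
#' REML solution is closed-form (residual mean square gives the residual
#' variance; the residual variance of per-individual means gives the
#' individual component; GLS fixed effects reduce to subtype means of
#' individual means) and is used directly. Unbalanced designs fall back to
#' `lme4::lmer`; a non-converging fit falls back to per-subtype means of
#' per-individual means and is flagged `converged = FALSE`.
#'
#' @param mat Proteins x sample-replicate log2 matrix.
#' @param annotation Annotation tibble with `sample_id`, `individual_id`,
#'   `group`, `subtype`.
#' @param method `"auto"` (closed form when balanced, else lmer),
#'   `"closed"`, `"lmer"`, or `"means"` (fixed effects only, no variance
#'   components).
#' @return A tibble with one row per protein: `protein_id`, `mu`,
#'   one `S_<subtype>` column per modelled subtype (sum-to-zero),
#'   `sigma_I`, `sigma_SI` (always `NA`, see above), `sigma_e`,
#'   `converged`, `method`.
#' @export
fit_subtype_effects <- function(mat, annotation,
                                method = c("auto", "closed", "lmer", "means")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat))
  ann <- annotation[!is.na(annotation$subtype), , drop = FALSE]
  subtypes <- unique(as.character(ann$subtype))
  if (length(subtypes) < 2) {
    stop("need at least 2 subtypes present", call. = FALSE)
  }
  subtypes <- intersect(subtype_levels(), subtypes)
  mat <- mat[, ann$sample_id, drop = FALSE]

  reps_per_ind <- table(ann$individual_id)
  balanced <- length(unique(as.integer(reps_per_ind))) == 1 && !anyNA(mat)
  r <- as.integer(reps_per_ind[1])
  if (method == "auto") method <- if (balanced) "closed" else "lmer"
  if (method == "closed" && !balanced) {
    stop("closed-form REML needs equal replicate counts and no missing values",
         call. = FALSE)
  }
  single_rep <- balanced && r == 1
  if (single_rep && method != "means") {
    message("one sample per individual: individual effect is confounded ",
            "with the residual; reporting their combined variance as sigma_e")
  }

  ind_of <- ann$individual_id[!duplicated(ann$individual_id)]
  sub_of <- as.character(ann$subtype[!duplicated(ann$individual_id)])
  names(sub_of) <- ind_of

  # per-individual means: GLS fixed effects for every method
  indmat <- collapse_replicates(mat, ann)
  sub_means <- vapply(subtypes, function(s) {
    rowMeans(indmat[, ind_of[sub_of == s], drop = FALSE])
  }, numeric(nrow(mat)))
  sub_means <- matrix(sub_means, nrow = nrow(mat),
                      dimnames = list(rownames(mat), subtypes))
  mu <- rowMeans(sub_means)            # unweighted mean over subtypes
  S <- sub_means - mu                  # sum-to-zero effects

  n_ind <- length(ind_of)
  J <- length(subtypes)

  if (method %in% c("closed", "means")) {
    if (method == "closed") {
      if (r > 1) {
        fitted_ind <- indmat[, ann$individual_id, drop = FALSE]
        sse_within <- rowSums((mat - fitted_ind)^2)
        sigma_e2 <- sse_within / (n_ind * (r - 1))
      } else {
        sigma_e2 <- rep(NA_real_, nrow(mat))
      }
      centered <- indmat - sub_means[, sub_of[colnames(indmat)], drop = FALSE]
      ms_ind <- rowSums(centered^2) / (n_ind - J)
      if (r > 1) {
        sigma_I2 <- pmax(0, ms_ind - sigma_e2 / r)
      } else {
        sigma_I2 <- rep(NA_real_, nrow(mat))
        sigma_e2 <- ms_ind   # combined individual + residual variance
      }
    } else {
      sigma_I2 <- rep(NA_real_, nrow(mat))
      sigma_e2 <- rep(NA_real_, nrow(mat))
    }
    out <- tibble::tibble(protein_id = rownames(mat), mu = unname(mu))
    for (s in subtypes) out[[paste0("S_", s)]] <- unname(S[, s])
    out$sigma_I <- unname(sqrt(sigma_I2))
    out$sigma_SI <- NA_real_
    out$sigma_e <- unname(sqrt(sigma_e2))
    out$converged <- TRUE
    out$method <- method
    return(out)
  }

  # lme4 path, one fit per protein
  df0 <- data.frame(
    subtype = factor(as.character(ann$subtype), levels = subtypes),
    individual = factor(ann$individual_id)
  )
  cm <- stats::contr.sum(J)
  rows <- purrr::map(seq_len(nrow(mat)), function(i) {
    df0$y <- mat[i, ]
    fit <- tryCatch(
      suppressMessages(lme4::lmer(
        y ~ subtype + (1 | individual), data = df0, REML = TRUE,
        contrasts = list(subtype = cm),
        control = lme4::lmerControl(calc.derivs = FALSE,
                                    check.conv.singular = "ignore"))),
      error = function(e) NULL)
    if (is.null(fit)) {
      list(S = S[i, ], mu = mu[i], sI = NA_real_, se = NA_real_,
           converged = FALSE)
    } else {
      fe <- lme4::fixef(fit)
      Sj <- c(cm %*% fe[-1])
      names(Sj) <- subtypes
      vc <- as.data.frame(lme4::VarCorr(fit))
      list(S = Sj, mu = unname(fe[1]),
           sI = vc$sdcor[vc$grp == "individual"],
           se = vc$sdcor[vc$grp == "Residual"], converged = TRUE)
    }
  })
  out <- tibble::tibble(
    protein_id = rownames(mat),
    mu = purrr::map_dbl(rows, "mu")
  )
  for (s in subtypes) {
    out[[paste0("S_", s)]] <- purrr::map_dbl(rows, function(rw) rw$S[[s]])
  }
  out$sigma_I <- purrr::map_dbl(rows, "sI")
  out$sigma_SI <- NA_real_
  out$sigma_e <- purrr::map_dbl(rows, "se")
  out$converged <- purrr::map_lgl(rows, "converged")
  out$method <- ifelse(out$converged, "lmer", "means")
  out
}

#' Extract the per-protein effect matrix from a fitted effect table
#'
#' @param effects Result of [fit_subtype_effects()].
#' @return Numeric matrix (proteins x subtypes) of the `S_` columns.
#' @export
effect_matrix <- function(effects) {
  scols <- grep("^S_", names(effects), value = TRUE)
  m <- as.matrix(effects[, scols])
  rownames(m) <- effects$protein_id
  colnames(m) <- sub("^S_", "", scols)
  m
}

#' Read and write intensity matrices and annotation tables
#'
#' TSV round trip for the two tabular inputs: an intensity matrix whose first
#' column (`protein_id`) holds row names and whose remaining columns are
#' sample-replicate intensities, and a sample annotation table.
#'
#' @param path File path.
#' @param mat Proteins x samples numeric matrix.
#' @param annotation Annotation data frame.
#' @name intensity_io
#' @export
read_intensity_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1])
  rownames(mat) <- df[[1]]
  attr(mat, "scale") <- "log2"
  mat
}

#' @rdname intensity_io
#' @export
write_intensity_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "protein_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname intensity_io
#' @export
read_annotation_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character(),
                                          replicate = readr::col_integer()))
}

#' @rdname intensity_io
#' @export
write_annotation_tsv <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}
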