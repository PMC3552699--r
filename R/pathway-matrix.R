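#' Read and write pathway databases in GMT format
#'
#' Standard GMT dialect: one pathway per line, tab-separated `name`,
#' `description`, then member identifiers. Duplicate members within a
#' pathway are removed; duplicate pathway names are an error; a line with
#' fewer than three fields is a parse error naming the line.
#'
#' @param path File path.
#' @param db A `"pathway_db"`: named list of character vectors with an
#'   optional `description` attribute.
#' @return `read_gmt()` returns a `"pathway_db"`; `write_gmt()` returns the
#'   path invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("malformed GMT line(s) with < 3 fields: line ",
         toString(utils::head(short, 5)), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicate pathway name(s): ", toString(unique(nm[duplicated(nm)])),
         call. = FALSE)
  }
  db <- lapply(fields, function(f) sort(unique(f[-(1:2)])))
  names(db) <- nm
  attr(db, "description") <- vapply(fields, `[[`, character(1), 2)
  class(db) <- "pathway_db"
  db
}

#' @rdname read_gmt
#' @export
write_gmt <- function(db, path) {
  desc <- attr(db, "description")
  if (is.null(desc)) desc <- rep("na", length(db))
  lines <- vapply(seq_along(db), function(i) {
    paste(c(names(db)[i], desc[i], db[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pathway-protein matrix at one significance cutoff
#'
#' Entry (i, j) is `k` when protein j belongs to pathway i in the database
#' and passed the cutoff-k significance screen, otherwise 0. Rows/columns
#' follow a fixed common index so that matrices from different subtypes and
#' cutoffs are directly comparable.
#'
#' @param significant Character vector of cutoff-k significant proteins.
#' @param db A `"pathway_db"`.
#' @param k Cutoff index in 1..3 (1: q<0.2, 2: q<0.1, 3: q<0.05).
#' @param pathways,proteins Row/column index; defaults to all pathways in
#'   the database and the significant proteins.
#' @return Integer matrix (pathways x proteins).
#' @export
build_cutoff_matrix <- function(significant, db, k,
                                pathways = names(db),
                                proteins = sort(unique(significant))) {
  stopifnot(k %in% 1:3)
  Q <- matrix(0L, length(pathways), length(proteins),
              dimnames = list(pathways, proteins))
  if (length(proteins) && length(significant) &&
      !any(significant %in% unlist(db, use.names = FALSE))) {
    warning("no overlap between significant proteins and the pathway database")
  }
  for (pw in intersect(pathways, names(db))) {
    hit <- intersect(intersect(db[[pw]], significant), proteins)
    if (length(hit)) Q[pw, hit] <- as.integer(k)
  }
  Q
}

#' Merge the three cutoff matrices by elementwise maximum
#'
#' Each merged entry is the strictest cutoff index the protein passes within
#' that pathway (`q_ij = max_k q_ijk`). Matrices are first padded with zero
#' rows/columns onto the union index.
#'
#' @param Q1,Q2,Q3 Cutoff matrices from [build_cutoff_matrix()].
#' @return Integer matrix on the union index with entries in 0..3.
#' @export
merge_cutoff_matrices <- function(Q1, Q2, Q3) {
  mats <- list(Q1, Q2, Q3)
  rows <- Reduce(union, lapply(mats, rownames))
  cols <- Reduce(union, lapply(mats, colnames))
  pad <- function(Q) {
    M <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
    if (nrow(Q) && ncol(Q)) M[rownames(Q), colnames(Q)] <- Q
    M
  }
  padded <- lapply(mats, pad)
  out <- pmax(padded[[1]], padded[[2]], padded[[3]])
  storage.mode(out) <- "integer"
  out
}

#' Merged pathway-protein matrix for one subtype
#'
#' Convenience wrapper: takes the three nested significant sets from
#' [declare_significant()], builds the three cutoff matrices on a shared
#' index and merges them. A parallel character matrix of per-protein
#' regulation direction is attached as attribute `"direction"`.
#'
#' @param declared Result of [declare_significant()].
#' @param db A `"pathway_db"`.
#' @param results Optional [diff_test()] tibble supplying directions.
#' @param pathways,proteins Common index (defaults: all db pathways; union
#'   of declared proteins).
#' @return Integer merged matrix with attribute `"direction"`.
#' @export
pathway_protein_matrix <- function(declared, db, results = NULL,
                                   pathways = names(db),
                                   proteins = NULL) {
  if (is.null(proteins)) {
    proteins <- sort(unique(unlist(declared$proteins)))
  }
  Qs <- lapply(1:3, function(k) {
    build_cutoff_matrix(declared$proteins[[k]], db, k,
                        pathways = pathways, proteins = proteins)
  })
  Q <- merge_cutoff_matrices(Qs[[1]], Qs[[2]], Qs[[3]])
  if (!is.null(results)) {
    dir <- matrix("none", nrow(Q), ncol(Q), dimnames = dimnames(Q))
    dd <- stats::setNames(results$direction, results$protein_id)
    hit <- Q > 0
    dir[hit] <- dd[colnames(Q)[col(Q)[hit]]]
    attr(Q, "direction") <- dir
  }
  Q
}

#' Pathway profile: significant-protein counts per pathway
#'
#' Counts, for each pathway, the proteins significant at the given cutoff.
#' Equivalently the per-row count of merged-matrix entries `>= cutoff`.
#'
#' @param x Either a merged pathway-protein matrix, or a character vector of
#'   significant proteins (then `db` is required).
#' @param db A `"pathway_db"` (only for the character-vector form).
#' @param cutoff Cutoff index in 1..3.
#' @param pathways Pathway index for the character-vector form.
#' @return Named integer vector of per-pathway counts.
#' @export
pathway_profile <- function(x, db = NULL, cutoff = 1, pathways = names(db)) {
  stopifnot(cutoff %in% 1:3)
  if (is.matrix(x)) {
    return(rowSums(x >= cutoff))
  }
  if (is.null(db)) stop("db required when x is a protein set", call. = FALSE)
  vapply(db[pathways], function(members) {
    length(intersect(members, x))
  }, integer(1))
}

#' Write a pathway-protein matrix (and its direction annotations) as TSV
#'
#' @param Q Merged matrix from [pathway_protein_matrix()].
#' @param path Output TSV; direction annotations (if present) go to
#'   `<path>.direction.tsv`.
#' @return Invisibly, the path.
#' @export
write_pathway_matrix_tsv <- function(Q, path) {
  readr::write_tsv(tibble::as_tibble(Q, rownames = "pathway"), path)
  dir <- attr(Q, "direction")
  if (!is.null(dir)) {
    readr::write_tsv(tibble::as_tibble(dir, rownames = "pathway"),
                     paste0(path, ".direction.tsv"))
  }
  invisible(path)
}
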