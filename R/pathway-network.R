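#' Jaccard similarity of two protein sets
#'
#' `|intersection| / |union|` with duplicates removed.
#'
#' @param a,b Non-empty character vectors.
#' @return Similarity in \[0, 1\].
#' @examples
#' jaccard_similarity(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
#' @export
jaccard_similarity <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("pathway protein sets must be non-empty", call. = FALSE)
  }
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Select top pathways by average changed-protein count
#'
#' Keeps pathways whose mean per-subtype count of changed proteins strictly
#' exceeds the threshold (default 5, the rule used to trim a pathway network
#' to its functionally loaded core).
#'
#' @param changed_counts Pathways x subtypes numeric matrix of
#'   changed-protein counts (e.g. cbind of [pathway_profile()] vectors at
#'   cutoff 1 over subtypes).
#' @param min_avg_count Strict lower bound on the row mean.
#' @return Character vector of selected pathway names.
#' @export
select_top_pathways <- function(changed_counts, min_avg_count = 5) {
  stopifnot(is.matrix(changed_counts))
  rownames(changed_counts)[rowMeans(changed_counts) > min_avg_count]
}

#' Pathway association network
#'
#' Complete graph on the selected pathways with edges weighted by the
#' Jaccard similarity of the pathways' protein sets, filtered to
#' `similarity > min_similarity` (default 0: any shared protein draws an
#' edge). Node attributes: `protein_count` (pathway size) and
#' `changed_count` (changed proteins in the given subtype context).
#'
#' @param db A `"pathway_db"`.
#' @param selected Pathway names (subset of the database).
#' @param changed_counts Named numeric vector of per-pathway changed-protein
#'   counts for one subtype (missing pathways count 0).
#' @param min_similarity Strict edge threshold.
#' @param subtype Context label stored on the graph.
#' @return An `igraph` graph with a `subtype` graph attribute.
#' @export
build_pathway_network <- function(db, selected = names(db),
                                  changed_counts = NULL, min_similarity = 0,
                                  subtype = NA_character_) {
  missing_pw <- setdiff(selected, names(db))
  if (length(missing_pw)) {
    stop("pathway(s) absent from the database: ",
         toString(utils::head(missing_pw, 5)), call. = FALSE)
  }
  n <- length(selected)
  edges <- list()
  w <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- jaccard_similarity(db[[selected[i]]], db[[selected[j]]])
        if (s > min_similarity) {
          edges[[length(edges) + 1]] <- c(selected[i], selected[j])
          w <- c(w, s)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = selected)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
    igraph::E(g)$jaccard <- w
  }
  igraph::V(g)$protein_count <- lengths(db[selected])
  cc <- rep(0, n)
  if (!is.null(changed_counts)) {
    hit <- intersect(selected, names(changed_counts))
    cc[match(hit, selected)] <- changed_counts[hit]
  }
  igraph::V(g)$changed_count <- cc
  g <- igraph::set_graph_attr(g, "subtype", subtype)
  g
}

#' Export a pathway network
#'
#' @param g An igraph pathway network.
#' @param path Output file.
#' @name network_io
#' @export
write_network_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname network_io
#' @export
write_network_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- tibble::tibble(
    pathway_a = if (nrow(el)) el[, 1] else character(0),
    pathway_b = if (nrow(el)) el[, 2] else character(0),
    jaccard = if (nrow(el)) igraph::E(g)$jaccard else numeric(0)
  )
  readr::write_tsv(df, path)
  invisible(path)
}
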