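#' Published cancer-subtype distance-score matrix
#'
#' A 5x5 distance-score matrix (sum mode) between the five IHC-approximated
#' breast cancer subtypes, computed from merged pathway-protein matrices of
#' a plasma proteomics cohort and shipped with the package as a worked
#' example for clustering: the luminal pair merges first, then the
#' HER2Plus/BasalLike pair, with Unknown joining last.
#'
#' @return A `"subtype_dist"` over
#'   `LuminalA, LuminalB, HER2Plus, BasalLike, Unknown`.
#' @examples
#' D <- example_subtype_distances()
#' hierarchical_cluster(D)$merges$height[1:2]  # 151, 302
#' @export
example_subtype_distances <- function() {
  path <- system.file("extdata", "subtype_distance_matrix.tsv",
                      package = "pathclust", mustWork = TRUE)
  read_distance_tsv(path)
}
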