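#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a subtype distance matrix into long pair form
#'
#' @param x A `"subtype_dist"`.
#' @param ... Unused.
#' @return Tibble with `label_a`, `label_b`, `distance`, `metric` (one row
#'   per unordered pair).
#' @method tidy subtype_dist
#' @export
tidy.subtype_dist <- function(x, ...) {
  m <- unclass(x)
  labs <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    label_a = labs[idx[, 1]],
    label_b = labs[idx[, 2]],
    distance = m[idx],
    metric = attr(x, "metric") %||% NA_character_
  )
}

#' Tidy a merge tree into one row per agglomeration step
#'
#' @param x A `"merge_tree"`.
#' @param ... Unused.
#' @return Tibble with `step`, `height`, `members_a`, `members_b` (list
#'   columns) and `linkage`.
#' @method tidy merge_tree
#' @export
tidy.merge_tree <- function(x, ...) {
  dplyr::mutate(x$merges, linkage = x$linkage)
}

#' Tidy / summarize a prediction evaluation
#'
#' `tidy()` returns the per-patient table; `glance()` the one-row summary
#' with both accuracy scopes.
#'
#' @param x A `"prediction_eval"`.
#' @param ... Unused.
#' @method tidy prediction_eval
#' @export
tidy.prediction_eval <- function(x, ...) {
  x$predictions
}

#' @rdname tidy.prediction_eval
#' @method glance prediction_eval
#' @export
glance.prediction_eval <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n = s$n[s$scope == "all_five_subtypes"],
    true_positives = s$true_positives[s$scope == "all_five_subtypes"],
    accuracy = s$accuracy[s$scope == "all_five_subtypes"],
    n_known = s$n[s$scope == "four_known_subtypes"],
    true_positives_known = s$true_positives[s$scope == "four_known_subtypes"],
    accuracy_known = s$accuracy[s$scope == "four_known_subtypes"],
    metric = x$metric %||% NA_character_
  )
}
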