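#' Breast cancer subtype labels
#'
#' Canonical ordering of the IHC-approximated intrinsic subtypes used
#' throughout the package (also the tie-breaking order for nearest-neighbor
#' prediction).
#'
#' @return Character vector of the five subtype labels.
#' @export
subtype_levels <- function() {
  c("LuminalA", "LuminalB", "HER2Plus", "BasalLike", "Unknown")
}

#' Assign breast cancer subtype from IHC receptor status
#'
#' Maps estrogen receptor (ER), progesterone receptor (PR) and HER2
#' immunohistochemistry calls to an intrinsic-subtype approximation:
#' (ER+ or PR+) with HER2- is LuminalA; (ER+ or PR+) with HER2+ is LuminalB;
#' triple ER-/PR-/HER2+ is HER2Plus; triple-negative is BasalLike. Any
#' combination left undecidable by a missing marker is labelled Unknown.
#'
#' @param er,pr,her2 Character vectors with values `"positive"`, `"negative"`
#'   or `"missing"` (the shorthand `"+"`, `"-"`, `NA` is also accepted).
#' @return A factor with levels [subtype_levels()].
#' @examples
#' assign_subtype("positive", "negative", "negative")  # LuminalA
#' assign_subtype("-", "+", "+")                       # LuminalB
#' @export
assign_subtype <- function(er, pr, her2) {
  er <- normalize_status(er)
  pr <- normalize_status(pr)
  her2 <- normalize_status(her2)
  n <- max(length(er), length(pr), length(her2))
  er <- rep_len(er, n); pr <- rep_len(pr, n); her2 <- rep_len(her2, n)

  lab <- rep("Unknown", n)
  any_pos <- er == "positive" | pr == "positive"
  both_neg <- er == "negative" & pr == "negative"
  # a rule fires only when every marker it reads is observed
  lab[any_pos & her2 == "negative"] <- "LuminalA"
  lab[any_pos & her2 == "positive"] <- "LuminalB"
  lab[both_neg & her2 == "positive"] <- "HER2Plus"
  lab[both_neg & her2 == "negative"] <- "BasalLike"
  # single positive hormone receptor decides any_pos even if the other is
  # missing, but HER2 must be observed; both_neg requires both observed
  factor(lab, levels = subtype_levels())
}

normalize_status <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "missing"
  map <- c("+" = "positive", "-" = "negative", "positive" = "positive",
           "negative" = "negative", "missing" = "missing", "pos" = "positive",
           "neg" = "negative")
  out <- unname(map[x])
  if (anyNA(out)) {
    stop("receptor status values must be 'positive', 'negative' or 'missing'",
         call. = FALSE)
  }
  out
}

#' Add a subtype column to a sample annotation table
#'
#' @param annotation A data frame with `ER`, `PR`, `HER2` columns (and
#'   typically `group`); healthy samples keep subtype `NA`.
#' @return The annotation as a tibble with a `subtype` factor column.
#' @export
add_subtype <- function(annotation) {
  annotation <- tibble::as_tibble(annotation)
  st <- assign_subtype(annotation$ER, annotation$PR, annotation$HER2)
  if ("group" %in% names(annotation)) {
    st[annotation$group == "healthy"] <- NA
  }
  annotation$subtype <- st
  annotation
}

#' Receptor status implied by a subtype label
#'
#' Inverse of [assign_subtype()]: returns a representative ER/PR/HER2 status
#' for each subtype (Unknown maps to all-missing), so that a round trip
#' through [assign_subtype()] recovers the label.
#'
#' @param subtype Character vector of subtype labels.
#' @return A tibble with columns `ER`, `PR`, `HER2`.
#' @export
receptor_status <- function(subtype) {
  subtype <- as.character(subtype)
  bad <- setdiff(subtype, subtype_levels())
  if (length(bad)) stop("unknown subtype label(s): ", toString(bad), call. = FALSE)
  tab <- list(
    LuminalA  = c("positive", "positive", "negative"),
    LuminalB  = c("positive", "positive", "positive"),
    HER2Plus  = c("negative", "negative", "positive"),
    BasalLike = c("negative", "negative", "negative"),
    Unknown   = c("missing", "missing", "missing")
  )
  m <- do.call(rbind, tab[subtype])
  tibble::tibble(ER = unname(m[, 1]), PR = unname(m[, 2]),
                 HER2 = unname(m[, 3]))
}
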