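#' Morphological phenotype labels
#'
#' Four trainable morphological phenotypes are recognised, each named after
#' the 3-D migration mode it corresponds to: actin-enriched leading edge
#' (`AE`), small blebbing (`BB`), filopodial (`FP`) and lamellipodial (`LA`).
#' `INT` marks the intermediate state assigned when no phenotype reaches a
#' definite calibrated probability; it is a valid dwell state in track data
#' but never a trainable class.
#'
#' @return `phenotype_levels()` returns the four trainable class labels;
#'   `phenotype_states()` returns the five dwell states (classes plus
#'   `"INT"`); `coarse_class()` maps labels to the coarse-grained classes
#'   `AM` (amoeboidal: AE, BB), `ME` (mesenchymal: FP, LA) or `INT`.
#' @export
#' @examples
#' phenotype_levels()
#' coarse_class(c("FP", "BB", "INT"))
phenotype_levels <- function() c("AE", "BB", "FP", "LA")

#' @rdname phenotype_levels
#' @export
phenotype_states <- function() c(phenotype_levels(), "INT")

#' @rdname phenotype_levels
#' @param labels character vector of phenotype labels.
#' @param map named character vector mapping each phenotype to a coarse
#'   class; the default groups FP and LA as mesenchymal (`ME`) and AE and BB
#'   as amoeboidal (`AM`).
#' @export
coarse_class <- function(labels, map = coarse_map_default()) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels[!is.na(labels)]), names(map))
  if (length(unknown)) {
    stop("unknown phenotype label(s): ", paste(unknown, collapse = ", "))
  }
  unname(map[labels])
}

#' @rdname phenotype_levels
#' @export
coarse_map_default <- function() {
  c(AE = "AM", BB = "AM", FP = "ME", LA = "ME", INT = "INT")
}

assert_states <- function(states) {
  stopifnot(is.character(states), length(states) >= 2L, !anyDuplicated(states))
  invisible(states)
}
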