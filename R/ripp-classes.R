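#' RiPP class labels
#'
#' The fixed label enumeration used throughout the package: nine RiPP
#' classes in alphabetical order followed by `"non-RiPP"` as the last
#' member. The position of each label is frozen so that serialized model
#' weights and probability matrices remain portable.
#'
#' @return A character vector of length 10.
#' @export
#' @examples
#' ripp_classes()
ripp_classes <- function() {
  c(
    "autoinducing peptide",
    "bacterial head-to-tail cyclized peptide",
    "cyanobactin",
    "graspetide",
    "lanthipeptide",
    "lasso peptide",
    "other RiPPs",
    "rSAM-modified peptide",
    "thiopeptide",
    "non-RiPP"
  )
}

#' @describeIn ripp_classes Index of the `"non-RiPP"` label (always the
#'   last class).
#' @export
non_ripp_index <- function() length(ripp_classes())

# Resolve labels or integer indices to validated integer class indices.
as_class_index <- function(x, n_classes = length(ripp_classes())) {
  if (is.character(x) || is.factor(x)) {
    idx <- match(as.character(x), ripp_classes())
    if (anyNA(idx)) {
      bad <- unique(as.character(x)[is.na(idx)])
      stop("unknown RiPP class label(s): ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  } else {
    idx <- as.integer(x)
    if (any(idx < 1L | idx > n_classes)) {
      stop("class index out of range 1..", n_classes, call. = FALSE)
    }
  }
  idx
}
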