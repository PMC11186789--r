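#' The nine direction component labels
#'
#' A medication direction (sig) decomposes into nine components. The first
#' four are the core clinical components; the remaining five are sub-entities
#' of the auxiliary information. The vector order is the canonical assembly
#' order: a standardized direction lists its components exactly in this
#' sequence.
#'
#' @return Character vector of the nine label names, in canonical order.
#' @examples
#' component_labels()
#' @export
component_labels <- function() {
  c("verb", "dose", "route", "frequency",
    "auxi-indic", "auxi-time", "auxi-period", "auxi-action", "auxi-maxdose")
}

#' @rdname component_labels
#' @export
core_labels <- function() component_labels()[1:4]

#' @rdname component_labels
#' @export
auxiliary_labels <- function() component_labels()[5:9]

is_component_label <- function(x) x %in% component_labels()

assert_labels <- function(x, what = "label") {
  bad <- setdiff(x, component_labels())
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s(s): %s (must be one of: %s)",
                 what, paste(bad, collapse = ", "),
                 paste(component_labels(), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# rank of a label in canonical assembly order
label_rank <- function(x) match(x, component_labels())

#' BIO tag inventory over the nine component labels
#'
#' Sequence taggers operate on Begin/Inside/Outside token tags: `O` plus
#' `B-<label>` and `I-<label>` for each of the nine labels (19 tags).
#'
#' @return Character vector of the 19 BIO tags; `O` first.
#' @export
bio_tags <- function() {
  c("O",
    paste0("B-", component_labels()),
    paste0("I-", component_labels()))
}
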