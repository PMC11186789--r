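#' Construct an extraction result
#'
#' The common currency between extraction, assembly and flagging: a table of
#' extracted component values. Values extracted from text carry their
#' character span and provenance `"extracted"`; values later added from the
#' medication catalog carry no span and provenance `"catalog-filled"`. A
#' label absent from the table means "not extracted".
#'
#' @param values `data.frame` with columns `label`, `surface`, `start`,
#'   `end`, `provenance`. Zero rows allowed.
#' @param backend Backend tag, e.g. `"dictionary"` or `"trained"`.
#' @return An object of class `extraction_result`.
#' @export
extraction_result <- function(values = empty_extraction_values(),
                              backend = "dictionary") {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (nrow(values) == 0L) values <- empty_extraction_values()
  assert_labels(values$label, what = "extracted label")
  if (!all(values$provenance %in% c("extracted", "catalog-filled"))) {
    stop("provenance must be 'extracted' or 'catalog-filled'", call. = FALSE)
  }
  if (any(values$provenance == "catalog-filled" & !is.na(values$start))) {
    stop("catalog-filled values must carry no span", call. = FALSE)
  }
  rownames(values) <- NULL
  structure(list(values = values, backend = backend),
            class = "extraction_result")
}

empty_extraction_values <- function() {
  data.frame(label = character(), surface = character(),
             start = integer(), end = integer(),
             provenance = character(), stringsAsFactors = FALSE)
}

#' Extracted values for one label
#'
#' @param x An `extraction_result`.
#' @param label A component label.
#' @return Character vector of values under `label` (possibly empty).
#' @export
extraction_values <- function(x, label) {
  x$values$surface[x$values$label == label]
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("<extraction_result backend=%s> %d value(s)\n",
              x$backend, nrow(x$values)))
  for (i in seq_len(nrow(x$values))) {
    cat(sprintf("  %-12s %-28s [%s]\n", x$values$label[i], x$values$surface[i],
                x$values$provenance[i]))
  }
  invisible(x)
}
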