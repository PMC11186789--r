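#' Deterministic dictionary tagger
#'
#' Extracts component spans from normalized direction text by greedy
#' longest-match, leftmost-first matching of library surfaces at word
#' boundaries. Matching is case-insensitive and never backtracks: at each
#' token position the longest matching surface (across all libraries) is
#' taken, the scan resumes after it, and unmatched tokens stay outside. The
#' tagger is the auditable, fully deterministic oracle backend: on
#' closed-world generated corpora it recovers every gold span exactly.
#'
#' A surface registered under two different labels makes a match ambiguous;
#' this is a hard error (fail loudly, never guess) reported with the
#' offending surface.
#'
#' @param text Normalized direction text.
#' @param libraries Named list of `component_library` objects, or a prebuilt
#'   index from [dictionary_index()] (cheaper when tagging many records).
#' @return An `extraction_result` with backend `"dictionary"`.
#' @examples
#' libs <- read_libraries(medic_fixture("libraries"))
#' tag_dictionary("take one tablet by mouth once daily for pain", libs)
#' @export
tag_dictionary <- function(text, libraries) {
  idx <- if (inherits(libraries, "dictionary_index")) libraries
         else dictionary_index(libraries)
  toks <- tokenize(text)
  n <- nrow(toks)
  vals <- empty_extraction_values()
  i <- 1L
  lower <- tolower(toks$token)
  while (i <= n) {
    best_len <- 0L; best_label <- NA_character_
    # longest window starting at token i whose joined text is a known surface
    max_j <- min(n, i + idx$max_tokens - 1L)
    for (j in i:max_j) {
      key <- paste(lower[i:j], collapse = " ")
      hit <- idx$table[[key]]
      if (!is.null(hit)) {
        if (length(hit) > 1L) {
          stop(sprintf("ambiguous surface '%s' registered under labels: %s",
                       key, paste(hit, collapse = ", ")), call. = FALSE)
        }
        best_len <- j - i + 1L
        best_label <- hit
      }
    }
    if (best_len > 0L) {
      j <- i + best_len - 1L
      vals <- rbind(vals, data.frame(
        label = best_label,
        surface = substring(text, toks$start[i] + 1L, toks$end[j]),
        start = toks$start[i], end = toks$end[j],
        provenance = "extracted", stringsAsFactors = FALSE))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  extraction_result(vals, backend = "dictionary")
}

#' Prebuild the dictionary-tagger lookup index
#'
#' Token-joined lookup table surface -> label(s). Ambiguity is detected at
#' match time, so only surfaces actually hit in a text can fail. Build once
#' when tagging many records.
#'
#' @param libraries Named list of `component_library` objects.
#' @return An object of class `dictionary_index`.
#' @export
dictionary_index <- function(libraries) {
  tab <- new.env(parent = emptyenv())
  max_tokens <- 1L
  for (lib in libraries) {
    if (is.null(lib) || length(lib$surfaces) == 0L) next
    for (s in lib$surfaces) {
      key <- paste(tolower(tokenize(s)$token), collapse = " ")
      ntok <- length(tokenize(s)$token)
      if (ntok > max_tokens) max_tokens <- ntok
      cur <- tab[[key]]
      tab[[key]] <- unique(c(cur, lib$label))
    }
  }
  structure(list(table = tab, max_tokens = max_tokens),
            class = "dictionary_index")
}
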