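#' Construct a labeled direction record
#'
#' A labeled direction is a direction text plus an ordered set of labeled,
#' non-overlapping character spans, one per component occurrence. Offsets are
#' 0-based and half-open (`start` inclusive, `end` exclusive), the usual
#' convention for NER corpora, so `surface == substr(text, start + 1, end)`.
#'
#' @param record_id Opaque record identifier (string).
#' @param text Direction text; must be non-empty after trimming.
#' @param spans `data.frame` with columns `label`, `start`, `end` (and
#'   optionally `surface`, which is recomputed from `text`). May have zero
#'   rows.
#' @param drug_id Optional drug identifier (string or `NA`).
#' @return An object of class `labeled_direction`.
#' @examples
#' labeled_direction("r1", "take one tablet",
#'   data.frame(label = c("verb", "dose"), start = c(0, 5), end = c(4, 15)))
#' @export
labeled_direction <- function(record_id, text, spans = empty_spans(),
                              drug_id = NA_character_) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop(sprintf("record '%s': text must be a non-empty string", record_id),
         call. = FALSE)
  }
  spans <- as.data.frame(spans, stringsAsFactors = FALSE)
  if (nrow(spans) == 0L) {
    spans <- empty_spans()
  } else {
    need <- c("label", "start", "end")
    miss <- setdiff(need, names(spans))
    if (length(miss) > 0L) {
      stop(sprintf("record '%s': spans missing column(s): %s",
                   record_id, paste(miss, collapse = ", ")), call. = FALSE)
    }
    spans$start <- as.integer(spans$start)
    spans$end <- as.integer(spans$end)
    spans <- spans[order(spans$start), c("label", "start", "end"), drop = FALSE]
    rownames(spans) <- NULL
    spans$surface <- substring(text, spans$start + 1L, spans$end)
  }
  x <- structure(
    list(record_id = as.character(record_id),
         drug_id = if (is.null(drug_id) || is.na(drug_id)) NA_character_
                   else as.character(drug_id),
         text = text, spans = spans),
    class = "labeled_direction")
  validate_direction(x)
}

empty_spans <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             surface = character(), stringsAsFactors = FALSE)
}

#' Validate a labeled direction
#'
#' Checks the span invariants: labels belong to the nine-member enumeration,
#' `0 <= start < end <= nchar(text)`, spans sorted by `start` and pairwise
#' non-overlapping, and each `surface` equals the corresponding substring.
#'
#' @param x A `labeled_direction`.
#' @return `x` invisibly; errors (naming the record and field) otherwise.
#' @export
validate_direction <- function(x) {
  sp <- x$spans
  id <- x$record_id
  if (nrow(sp) > 0L) {
    assert_labels(sp$label, what = sprintf("span label in record '%s'", id))
    if (any(sp$start < 0L) || any(sp$end > nchar(x$text)) ||
        any(sp$start >= sp$end)) {
      stop(sprintf("record '%s': span offsets must satisfy 0 <= start < end <= nchar(text)", id),
           call. = FALSE)
    }
    if (is.unsorted(sp$start)) {
      stop(sprintf("record '%s': spans must be sorted by start", id), call. = FALSE)
    }
    if (nrow(sp) > 1L && any(sp$start[-1L] < sp$end[-nrow(sp)])) {
      stop(sprintf("record '%s': spans overlap", id), call. = FALSE)
    }
    got <- substring(x$text, sp$start + 1L, sp$end)
    if (!identical(got, sp$surface)) {
      stop(sprintf("record '%s': span surface does not match text substring", id),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.labeled_direction <- function(x, ...) {
  cat(sprintf("<labeled_direction %s> %s\n", x$record_id, x$text))
  if (nrow(x$spans) > 0L) {
    cat(paste(sprintf("  [%d,%d) %-12s %s", x$spans$start, x$spans$end,
                      x$spans$label, x$spans$surface), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read a labeled-direction corpus from JSON Lines
#'
#' One JSON object per line:
#' `{"record_id": str, "drug_id": str|null, "text": str,
#'   "spans": [{"label": str, "start": int, "end": int}]}`.
#' Every record is validated on read; order is preserved. Duplicate
#' `record_id`s are kept but reported with a warning.
#'
#' @param path Path to a `.jsonl` corpus file.
#' @return List of `labeled_direction` objects.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop(sprintf("corpus file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) stop(sprintf(
                      "corpus line %d: malformed JSON (%s)", i, conditionMessage(e)),
                      call. = FALSE))
    for (f in c("record_id", "text")) {
      if (is.null(rec[[f]])) {
        stop(sprintf("corpus line %d (record_id '%s'): missing field '%s'",
                     i, if (is.null(rec$record_id)) "?" else rec$record_id, f),
             call. = FALSE)
      }
    }
    spans <- rec$spans
    if (is.null(spans) || length(spans) == 0L) {
      spans <- empty_spans()
    } else {
      spans <- as.data.frame(spans, stringsAsFactors = FALSE)
    }
    out[[i]] <- labeled_direction(rec$record_id, rec$text, spans,
                                  drug_id = rec$drug_id %||% NA_character_)
  }
  ids <- vapply(out, function(d) d$record_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    warning(sprintf("corpus contains duplicate record_id(s): %s",
                    paste(dup, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Write a labeled-direction corpus to JSON Lines
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p))` reproduces
#' the corpus exactly (text, ids and spans are preserved verbatim, UTF-8).
#'
#' @param corpus List of `labeled_direction` objects.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(d) {
    validate_direction(d)
    spans <- if (nrow(d$spans) == 0L) list() else
      lapply(seq_len(nrow(d$spans)), function(i) {
        list(label = d$spans$label[i],
             start = d$spans$start[i],
             end = d$spans$end[i])
      })
    jsonlite::toJSON(
      list(record_id = d$record_id,
           drug_id = if (is.na(d$drug_id)) NULL else d$drug_id,
           text = d$text,
           spans = spans),
      auto_unbox = TRUE, null = "null")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize direction text on whitespace and punctuation
#'
#' The corpus-level tokenizer used for BIO interop: maximal runs of
#' non-space, non-punctuation characters, plus each punctuation character as
#' its own token — except that numbers keep internal separators
#' (`2.5`, `1/2`, `1,000` are single tokens). Returns tokens with their
#' 0-based half-open character offsets so spans can be aligned.
#'
#' @param text A single string.
#' @return `data.frame` with columns `token`, `start`, `end`.
#' @export
tokenize <- function(text) {
  m <- gregexpr("[0-9]+(?:[./,][0-9]+)*|[^[:space:][:punct:]]+|[[:punct:]]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(token = substring(text, start + 1L, start + len),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

#' Convert a labeled direction to token/BIO-tag rows
#'
#' Tokenizes the text (see [tokenize()]) and tags each token in the BIO
#' scheme: the first token of a span gets `B-<label>`, subsequent tokens of
#' the same span `I-<label>`, tokens outside any span `O`. Every span must
#' start and end exactly on token boundaries.
#'
#' @param direction A `labeled_direction`.
#' @return `data.frame` with columns `token`, `start`, `end`, `tag`.
#' @seealso [conll_to_spans()] for the inverse mapping.
#' @export
to_conll <- function(direction) {
  toks <- tokenize(direction$text)
  tags <- rep("O", nrow(toks))
  sp <- direction$spans
  for (i in seq_len(nrow(sp))) {
    inside <- which(toks$start >= sp$start[i] & toks$end <= sp$end[i])
    covered <- if (length(inside) > 0L)
      toks$start[inside[1]] == sp$start[i] && toks$end[inside[length(inside)]] == sp$end[i]
    else FALSE
    if (!covered) {
      stop(sprintf("record '%s': span [%d,%d) '%s' does not align to token boundaries",
                   direction$record_id, sp$start[i], sp$end[i], sp$surface[i]),
           call. = FALSE)
    }
    tags[inside] <- c(paste0("B-", sp$label[i]),
                      rep(paste0("I-", sp$label[i]), length(inside) - 1L))
  }
  cbind(toks, tag = tags, stringsAsFactors = FALSE)
}

#' Decode BIO-tagged tokens back to labeled spans
#'
#' Inverse of [to_conll()] on token-aligned corpora. Orphan `I-` tags (an
#' inside tag with no preceding begin tag of the same label) are repaired by
#' promotion to `B-`; repairs are counted in the `repairs` attribute.
#'
#' @param tokens `data.frame` with columns `token`, `start`, `end`, `tag`.
#' @return Span `data.frame` (`label`, `start`, `end`) with attribute
#'   `repairs`.
#' @export
conll_to_spans <- function(tokens) {
  labels <- character(); starts <- integer(); ends <- integer()
  cur_label <- NA_character_; cur_start <- NA_integer_; cur_end <- NA_integer_
  repairs <- 0L
  flush <- function() {
    if (!is.na(cur_label)) {
      labels <<- c(labels, cur_label)
      starts <<- c(starts, cur_start)
      ends <<- c(ends, cur_end)
    }
    cur_label <<- NA_character_
  }
  for (i in seq_len(nrow(tokens))) {
    tag <- tokens$tag[i]
    if (tag == "O") {
      flush()
    } else {
      kind <- substr(tag, 1, 1)
      lab <- substr(tag, 3, nchar(tag))
      if (kind == "I" && identical(lab, cur_label)) {
        cur_end <- tokens$end[i]
      } else {
        if (kind == "I") repairs <- repairs + 1L  # orphan I- promoted to B-
        flush()
        cur_label <- lab; cur_start <- tokens$start[i]; cur_end <- tokens$end[i]
      }
    }
  }
  flush()
  structure(data.frame(label = labels, start = starts, end = ends,
                       stringsAsFactors = FALSE),
            repairs = repairs)
}

#' Write a corpus in CoNLL-2003-style format
#'
#' One `token<TAB>tag` row per token, blank line between records.
#'
#' @param corpus List of `labeled_direction` objects.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_conll <- function(corpus, path) {
  blocks <- vapply(corpus, function(d) {
    rows <- to_conll(d)
    paste(paste(rows$token, rows$tag, sep = "\t"), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
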