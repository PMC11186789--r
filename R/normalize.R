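#' Load a pharmalexical normalization rule set
#'
#' Rules live in a YAML file as an ordered list of
#' `{id, kind: literal|regex, match, replace, word_boundary: bool}` entries
#' and are applied in listed order. Literal rules match a fixed string
#' (case-insensitively); regex rules use POSIX/PCRE syntax. With
#' `word_boundary: true` (the default for literal rules) a match must not be
#' embedded in a longer word, so the abbreviation rule `po -> by mouth`
#' never rewrites "polish".
#'
#' @param path Path to the YAML rules file.
#' @param vocabulary Optional character vector of known tokens used by
#'   conservative spell correction during [normalize()].
#' @return An object of class `medic_rules`.
#' @examples
#' rules <- load_rules(system.file("extdata", "rules.yaml", package = "medic"))
#' length(rules$rules)
#' @export
load_rules <- function(path, vocabulary = character()) {
  if (!file.exists(path)) stop(sprintf("rules file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) stop("rules file contains no rules", call. = FALSE)
  ids <- vapply(raw, function(r) as.character(r$id %||% ""), character(1))
  if (any(!nzchar(ids))) stop("every rule needs an id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate rule id(s): %s", paste(dup, collapse = ", ")), call. = FALSE)
  }
  rules <- lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    kind <- r$kind %||% "literal"
    if (!kind %in% c("literal", "regex")) {
      stop(sprintf("rule '%s': kind must be literal or regex", r$id), call. = FALSE)
    }
    wb <- r$word_boundary %||% (kind == "literal")
    pattern <- if (kind == "literal") {
      p <- escape_regex(tolower(as.character(r$match)))
      if (isTRUE(wb)) paste0("\\b", p, "\\b") else p
    } else {
      p <- as.character(r$match)
      if (isTRUE(wb)) paste0("\\b", p, "\\b") else p
    }
    ok <- tryCatch({ suppressWarnings(grepl(pattern, "", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("rule '%s': pattern does not compile: %s", r$id, r$match),
                  call. = FALSE)
    list(rule_id = as.character(r$id), kind = kind,
         match = as.character(r$match), replace = as.character(r$replace %||% ""),
         word_boundary = isTRUE(wb), pattern = pattern, order = i)
  })
  structure(list(rules = rules, vocabulary = unique(tolower(vocabulary))),
            class = "medic_rules")
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' @export
print.medic_rules <- function(x, ...) {
  cat(sprintf("<medic_rules> %d rules, vocabulary of %d tokens\n",
              length(x$rules), length(x$vocabulary)))
  invisible(x)
}

#' Pharmalexical normalization of a raw direction
#'
#' Converts noisy prescriber sig text into clean, consistent English through
#' an ordered sequence of atomic pattern-based transformations: the text is
#' lower-cased and whitespace-collapsed, each rule is applied left-to-right
#' in rank order, and the whole pass repeats until a fixed point is reached
#' (at most `max_passes` passes). When the rule set carries a vocabulary,
#' remaining out-of-vocabulary alphabetic tokens get conservative spell
#' correction (see [spell_correct()]). Every change is recorded in a replayable
#' trace.
#'
#' @param text Raw direction text (non-empty).
#' @param rules A `medic_rules` object from [load_rules()].
#' @param max_passes Maximum number of full rule passes (default 5).
#' @return An object of class `normalized_direction` with fields `original`,
#'   `normalized` and `trace` (data.frame of rule_id/before/after).
#' @examples
#' rules <- load_rules(system.file("extdata", "rules.yaml", package = "medic"))
#' normalize("TAKE 1 TAB PO QD", rules)$normalized
#' @export
normalize <- function(text, rules, max_passes = 5L) {
  stopifnot(inherits(rules, "medic_rules"))
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("text must be a non-empty string", call. = FALSE)
  }
  trace <- list()
  push <- function(id, before, after) {
    trace[[length(trace) + 1L]] <<- list(rule_id = id, before = before, after = after)
  }
  cur <- collapse_ws(tolower(text))
  if (cur != text) push("<case-ws>", text, cur)
  for (pass in seq_len(max_passes)) {
    before_pass <- cur
    for (r in rules$rules) {
      nxt <- gsub(r$pattern, r$replace, cur, perl = TRUE, ignore.case = TRUE)
      nxt <- collapse_ws(nxt)
      if (nxt != cur) {
        push(r$rule_id, cur, nxt)
        cur <- nxt
      }
    }
    if (cur == before_pass) break
    if (pass == max_passes && cur != before_pass) {
      osc <- unique(vapply(trace, `[[`, character(1), "rule_id"))
      stop(sprintf("normalization did not reach a fixed point within %d passes (rules involved: %s)",
                   max_passes, paste(osc, collapse = ", ")), call. = FALSE)
    }
  }
  if (length(rules$vocabulary) > 0L) {
    toks <- strsplit(cur, " ", fixed = TRUE)[[1]]
    fixed <- vapply(toks, spell_correct, character(1),
                    vocabulary = rules$vocabulary, USE.NAMES = FALSE)
    if (!identical(fixed, toks)) {
      nxt <- paste(fixed, collapse = " ")
      push("<spell>", cur, nxt)
      cur <- nxt
    }
  }
  structure(list(original = text, normalized = cur,
                 trace = trace_df(trace)),
            class = "normalized_direction")
}

collapse_ws <- function(x) trimws(gsub("[[:space:]]+", " ", x))

trace_df <- function(trace) {
  if (length(trace) == 0L) {
    return(data.frame(rule_id = character(), before = character(),
                      after = character(), stringsAsFactors = FALSE))
  }
  data.frame(rule_id = vapply(trace, `[[`, character(1), "rule_id"),
             before = vapply(trace, `[[`, character(1), "before"),
             after = vapply(trace, `[[`, character(1), "after"),
             stringsAsFactors = FALSE)
}

#' @export
print.normalized_direction <- function(x, ...) {
  cat(sprintf("<normalized_direction>\n  raw:  %s\n  norm: %s\n  %d rule application(s)\n",
              x$original, x$normalized, nrow(x$trace)))
  invisible(x)
}

#' Conservative single-token spell correction
#'
#' Returns the unique vocabulary token within `max_edit` Levenshtein edits
#' of `token` if exactly one exists; in every other case (token already
#' known, no candidate, several equidistant candidates, numeric token) the
#' input is returned unchanged. In a prescription, a no-op is always safer
#' than a wrong correction.
#'
#' @param token Single token (string).
#' @param vocabulary Character vector of known tokens (lower-case).
#' @param max_edit Maximum edit distance considered (default 1).
#' @return The corrected token, or `token` unchanged.
#' @examples
#' spell_correct("tabet", c("tablet", "capsule"))
#' @export
spell_correct <- function(token, vocabulary, max_edit = 1L) {
  if (length(vocabulary) == 0L) stop("vocabulary must be non-empty", call. = FALSE)
  lt <- tolower(token)
  if (lt %in% vocabulary) return(token)
  if (grepl("[0-9]", token) || !grepl("[[:alpha:]]", token)) return(token)
  d <- utils::adist(lt, vocabulary)[1, ]
  best <- min(d)
  if (best > max_edit) return(token)
  cand <- vocabulary[d == best]
  if (length(cand) == 1L) cand else token
}

#' Replay a normalization trace
#'
#' Applies the recorded before/after steps to the original text, verifying
#' the trace invariant: replaying the trace reproduces the normalized text.
#'
#' @param x A `normalized_direction`.
#' @return The replayed final text (equals `x$normalized`).
#' @export
replay_trace <- function(x) {
  cur <- x$original
  for (i in seq_len(nrow(x$trace))) {
    if (!identical(cur, x$trace$before[i])) {
      stop(sprintf("trace step %d: expected text '%s', have '%s'",
                   i, x$trace$before[i], cur), call. = FALSE)
    }
    cur <- x$trace$after[i]
  }
  cur
}
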