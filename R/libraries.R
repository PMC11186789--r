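#' Construct a component library
#'
#' A component library L_c holds the set of unique surface values observed
#' (or curated) for one of the nine component labels, together with a
#' canonical-form mapping used for semantic comparison (identity unless a
#' surface has a preferred canonical value, e.g. "1 tab" -> "one tablet").
#'
#' @param label One of [component_labels()].
#' @param surfaces Character vector of surface strings.
#' @param canonical Named character vector mapping a subset of `surfaces` to
#'   canonical values; unnamed surfaces map to themselves.
#' @return An object of class `component_library`.
#' @export
component_library <- function(label, surfaces = character(), canonical = character()) {
  assert_labels(label)
  surfaces <- unique(as.character(surfaces))
  if (any(!nzchar(trimws(surfaces)))) {
    stop(sprintf("library '%s': surfaces must be non-empty strings", label),
         call. = FALSE)
  }
  canonical <- stats::setNames(as.character(canonical), names(canonical))
  if (length(canonical) > 0L) {
    bad <- setdiff(names(canonical), surfaces)
    if (length(bad) > 0L) {
      stop(sprintf("library '%s': canonical keys not in surfaces: %s",
                   label, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(label = label, surfaces = surfaces, canonical = canonical),
            class = "component_library")
}

#' Canonical form of a surface under a library
#'
#' @param library A `component_library` (or `NULL`, giving identity).
#' @param surface Surface string(s).
#' @return Canonical value(s); identity for unmapped surfaces.
#' @export
canonical_value <- function(library, surface) {
  if (is.null(library) || length(library$canonical) == 0L) return(surface)
  hit <- match(surface, names(library$canonical))
  ifelse(is.na(hit), surface, library$canonical[hit])
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library %s> %d surfaces (%d canonical mappings)\n",
              x$label, length(x$surfaces), length(x$canonical)))
  invisible(x)
}

#' Build the nine component libraries from a labeled corpus
#'
#' For each of the nine component labels, collects the unique surface values
#' appearing as spans of that label anywhere in the corpus. Labels never
#' observed yield empty libraries, so exactly nine libraries are always
#' returned.
#'
#' @param corpus List of `labeled_direction` objects.
#' @return Named list (one entry per component label, canonical order) of
#'   `component_library` objects.
#' @examples
#' d <- labeled_direction("r1", "take one tablet",
#'   data.frame(label = c("verb", "dose"), start = c(0, 5), end = c(4, 15)))
#' libs <- build_libraries(list(d))
#' libs$verb$surfaces
#' @export
build_libraries <- function(corpus) {
  acc <- stats::setNames(vector("list", 9L), component_labels())
  for (lab in component_labels()) acc[[lab]] <- character()
  for (d in corpus) {
    validate_direction(d)
    sp <- d$spans
    for (i in seq_len(nrow(sp))) {
      acc[[sp$label[i]]] <- c(acc[[sp$label[i]]], sp$surface[i])
    }
  }
  stats::setNames(
    lapply(component_labels(), function(lab) component_library(lab, unique(acc[[lab]]))),
    component_labels())
}

#' Merge expert-curated terms into a component library
#'
#' Libraries built from labeled data are expanded with surface values
#' identified by pharmacy quality specialists. New terms enter the canonical
#' map as identity; a term that is already canonical-mapped to a different
#' value is a conflict and errors.
#'
#' @param library A `component_library`.
#' @param additions Character vector of surfaces to add (non-empty strings).
#' @return The expanded `component_library`.
#' @export
merge_expert_terms <- function(library, additions) {
  additions <- as.character(additions)
  if (length(additions) == 0L || any(!nzchar(trimws(additions)))) {
    stop("additions must be non-empty strings", call. = FALSE)
  }
  for (a in additions) {
    mapped <- canonical_value(library, a)
    if (a %in% names(library$canonical) && !identical(unname(mapped), a)) {
      stop(sprintf("library '%s': term '%s' already canonical-mapped to '%s'",
                   library$label, a, mapped), call. = FALSE)
    }
  }
  component_library(library$label,
                    union(library$surfaces, additions),
                    library$canonical)
}

#' Extract the pattern library from a labeled corpus
#'
#' Each record contributes one pattern: the sequence of its span labels in
#' span order. Duplicate patterns collapse with frequency counts; the set of
#' unique patterns is the pattern library used for synthetic augmentation.
#'
#' @param corpus List of `labeled_direction` objects.
#' @return An object of class `pattern_library`: list with `patterns` (list
#'   of character vectors) and `freq` (integer counts, parallel).
#' @export
extract_patterns <- function(corpus) {
  keys <- vapply(corpus, function(d) {
    validate_direction(d)
    paste(d$spans$label, collapse = "\x1f")
  }, character(1))
  keys <- keys[nzchar(keys)]
  tab <- table(keys)
  pats <- lapply(names(tab), function(k) strsplit(k, "\x1f", fixed = TRUE)[[1]])
  pattern_library(pats, as.integer(tab))
}

#' @rdname extract_patterns
#' @param patterns List of character vectors (label sequences).
#' @param freq Optional integer weights, parallel to `patterns`.
#' @export
pattern_library <- function(patterns, freq = NULL) {
  if (length(patterns) > 0L) {
    for (p in patterns) {
      if (length(p) == 0L) stop("patterns must be non-empty", call. = FALSE)
      assert_labels(p, what = "pattern label")
    }
  }
  if (is.null(freq)) freq <- rep(1L, length(patterns))
  stopifnot(length(freq) == length(patterns))
  structure(list(patterns = patterns, freq = as.integer(freq)),
            class = "pattern_library")
}

#' @export
print.pattern_library <- function(x, ...) {
  cat(sprintf("<pattern_library> %d unique patterns, %d observations\n",
              length(x$patterns), sum(x$freq)))
  invisible(x)
}

#' Read/write component libraries as JSON
#'
#' File format: one JSON object `{label: {surface: canonical}}`; a surface
#' mapping to itself is an identity entry.
#'
#' @param path Path to the JSON libraries file.
#' @return Named list of nine `component_library` objects.
#' @export
read_libraries <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- stats::setNames(vector("list", 9L), component_labels())
  for (lab in component_labels()) {
    entry <- raw[[lab]]
    if (is.null(entry)) {
      out[[lab]] <- component_library(lab)
    } else {
      surfaces <- names(entry)
      canon <- vapply(entry, as.character, character(1))
      keep <- canon != surfaces
      out[[lab]] <- component_library(lab, surfaces,
                                      stats::setNames(canon[keep], surfaces[keep]))
    }
  }
  out
}

#' @rdname read_libraries
#' @param libraries Named list of `component_library` objects.
#' @export
write_libraries <- function(libraries, path) {
  obj <- lapply(libraries, function(l) {
    vals <- canonical_value(l, l$surfaces)
    as.list(stats::setNames(unname(vals), l$surfaces))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read/write a pattern library as JSON
#'
#' File format: JSON list of label arrays, optionally
#' `{"patterns": [...], "freq": [...]}`.
#'
#' @param path Path to the JSON patterns file.
#' @return A `pattern_library`.
#' @export
read_patterns <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.list(raw) && !is.null(raw$patterns)) {
    pattern_library(raw$patterns, raw$freq)
  } else {
    pattern_library(raw)
  }
}

#' @rdname read_patterns
#' @param patterns A `pattern_library`.
#' @export
write_patterns <- function(patterns, path) {
  jsonlite::write_json(patterns$patterns, path, pretty = TRUE)
  invisible(path)
}

#' Bundled fixture resources
#'
#' Paths to the fixture resources shipped with the package: a curated rule
#' set, component libraries, pattern library, medication catalog and noise
#' model. These stand in for production pharmacy content (which is
#' proprietary everywhere such systems run) and are sized for realistic
#' desk-scale experiments.
#'
#' @param name One of `"rules"`, `"libraries"`, `"patterns"`, `"catalog"`,
#'   `"noise"`.
#' @return Path to the bundled file.
#' @export
medic_fixture <- function(name = c("rules", "libraries", "patterns", "catalog", "noise")) {
  name <- match.arg(name)
  file <- switch(name,
                 rules = "rules.yaml", libraries = "libraries.json",
                 patterns = "patterns.json", catalog = "catalog.tsv",
                 noise = "noise.yaml")
  path <- system.file("extdata", file, package = "medic")
  if (!nzchar(path)) stop(sprintf("fixture '%s' not found", name), call. = FALSE)
  path
}
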