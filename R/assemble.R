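#' Fill missing required components from the medication catalog
#'
#' For every component label the catalog marks as required for this drug
#' that has no extracted value, the catalog's default value (when present)
#' is added with provenance `"catalog-filled"`. Extracted values are never
#' overwritten: the catalog completes the prescriber's direction, it does
#' not correct it (correction is the guardrails' job — a conflict halts).
#'
#' @param extraction An `extraction_result`.
#' @param entry A `catalog_entry`, or `NULL` (no fill-in).
#' @return The augmented `extraction_result`.
#' @export
fill_missing <- function(extraction, entry) {
  if (is.null(entry)) return(extraction)
  vals <- extraction$values
  for (lab in entry$required) {
    if (any(vals$label == lab)) next
    dft <- entry$defaults[[lab]]
    if (is.null(dft)) next
    vals <- rbind(vals, data.frame(
      label = lab, surface = dft, start = NA_integer_, end = NA_integer_,
      provenance = "catalog-filled", stringsAsFactors = FALSE))
  }
  extraction_result(vals, backend = extraction$backend)
}

#' Guardrail identifiers
#'
#' The five ordered safety guardrails. Evaluation order is fixed; a halted
#' suggestion reports the first guardrail to fire.
#'
#' * GR1 — catalog conflict: an extracted component value disagrees with the
#'   catalog's value for that component (canonical comparison).
#' * GR2 — multiple values extracted for one component (multi-line
#'   directions by design fall here).
#' * GR3 — a dose without a verb, when the catalog requires a verb.
#' * GR4 — missing frequency.
#' * GR5 — no dose while the dose form is tablet or capsule.
#'
#' @return Character vector `c("GR1", ..., "GR5")` in evaluation order.
#' @export
guardrail_ids <- function() paste0("GR", 1:5)

#' Apply the five safety guardrails
#'
#' Evaluates GR1..GR5 in order against the extraction before fill-in
#' (`raw_extraction`: what the prescriber actually conveyed) and after
#' fill-in (`extraction`: with catalog defaults added). GR1 and GR2 inspect
#' the raw extraction — a catalog default must neither mask a conflict nor
#' count as a duplicate; GR3, GR4 and GR5 inspect the post-fill view — a
#' catalog default legitimately satisfies a requirement. With no catalog
#' entry, the catalog-dependent guardrails GR1, GR3 and GR5 are skipped.
#'
#' @param extraction Post-fill `extraction_result`.
#' @param raw_extraction Pre-fill `extraction_result`.
#' @param entry A `catalog_entry` or `NULL`.
#' @param libraries Optional component libraries used for canonical
#'   comparison in GR1 (so "1 tab" vs "one tablet" is not a conflict).
#' @return An object of class `guardrail_report`: list with `triggered`
#'   (first guardrail id or `NA`), `reason`, and `all_triggered` (every
#'   guardrail that would fire, with reasons).
#' @export
apply_guardrails <- function(extraction, raw_extraction, entry,
                             libraries = NULL) {
  fired <- character(); reasons <- character()
  hit <- function(id, reason) {
    fired <<- c(fired, id); reasons <<- c(reasons, reason)
  }
  post <- extraction$values
  raw <- raw_extraction$values

  # GR1: raw extraction conflicts with a catalog value (canonical forms)
  if (!is.null(entry)) {
    for (lab in names(entry$defaults)) {
      ext <- raw$surface[raw$label == lab]
      if (length(ext) == 0L) next
      lib <- if (!is.null(libraries)) libraries[[lab]] else NULL
      cext <- unique(canonical_value(lib, normalize_number_words(ext)))
      ccat <- canonical_value(lib, normalize_number_words(entry$defaults[[lab]]))
      if (!all(cext == ccat)) {
        hit("GR1", sprintf("extracted %s '%s' conflicts with catalog '%s'",
                           lab, paste(ext, collapse = "', '"),
                           entry$defaults[[lab]]))
      }
    }
  }
  # GR2: multiple raw-extracted values for any component
  counts <- table(raw$label)
  multi <- names(counts)[counts >= 2L]
  for (lab in multi[order(label_rank(multi))]) {
    hit("GR2", sprintf("multiple values extracted for %s: '%s'",
                       lab, paste(raw$surface[raw$label == lab],
                                  collapse = "', '")))
  }
  # GR3: dose without verb where the catalog requires a verb
  if (!is.null(entry) && "verb" %in% entry$required &&
      any(post$label == "dose") && !any(post$label == "verb")) {
    hit("GR3", "dose present without a verb (verb required for this drug)")
  }
  # GR4: no frequency
  if (!any(post$label == "frequency")) {
    hit("GR4", "no value for the frequency component")
  }
  # GR5: no dose for a tablet/capsule dose form
  if (!is.null(entry) && !any(post$label == "dose") &&
      entry$dose_form %in% c("tablet", "capsule")) {
    hit("GR5", sprintf("no dose for %s dose form", entry$dose_form))
  }
  ord <- order(match(fired, guardrail_ids()))
  fired <- fired[ord]; reasons <- reasons[ord]
  structure(list(
    triggered = if (length(fired) > 0L) fired[[1L]] else NA_character_,
    reason = if (length(fired) > 0L) reasons[[1L]] else NA_character_,
    all_triggered = data.frame(id = fired, reason = reasons,
                               stringsAsFactors = FALSE)),
    class = "guardrail_report")
}

#' @export
print.guardrail_report <- function(x, ...) {
  if (is.na(x$triggered)) {
    cat("<guardrail_report> clear\n")
  } else {
    cat(sprintf("<guardrail_report> %s: %s\n", x$triggered, x$reason))
    if (nrow(x$all_triggered) > 1L) {
      cat(sprintf("  (also: %s)\n",
                  paste(x$all_triggered$id[-1L], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Assemble a standardized direction in canonical order
#'
#' Joins the present component values with single spaces in exactly the
#' canonical order (verb, dose, route, frequency, then the five auxiliary
#' sub-entities). At most one value per label is expected (GR2 fires
#' upstream otherwise); with duplicates, assembly refuses.
#'
#' @param extraction Post-fill `extraction_result`.
#' @return The assembled direction text (single string).
#' @examples
#' ex <- extraction_result(data.frame(
#'   label = c("frequency", "verb", "dose"),
#'   surface = c("once daily", "take", "one tablet"),
#'   start = NA_integer_, end = NA_integer_, provenance = "catalog-filled"))
#' assemble(ex)
#' @export
assemble <- function(extraction) {
  vals <- extraction$values
  if (nrow(vals) == 0L) stop("nothing to assemble: no components", call. = FALSE)
  if (any(table(vals$label) >= 2L)) {
    stop("cannot assemble: multiple values for one component", call. = FALSE)
  }
  vals <- vals[order(label_rank(vals$label)), , drop = FALSE]
  paste(vals$surface, collapse = " ")
}

#' End-to-end direction suggestion
#'
#' Runs the full three-stage pipeline on a raw prescriber direction:
#' pharmalexical normalization, component extraction (dictionary libraries
#' or a trained model), catalog fill-in, the five guardrails, and canonical
#' assembly. The outcome is either a suggested standardized direction or a
#' typed halt; every intermediate stage is kept for audit.
#'
#' A drug absent from the catalog does not halt the pipeline: fill-in and
#' the catalog-dependent guardrails are skipped and the outcome is noted
#' `"catalog-missing"`.
#'
#' @param raw List with `record_id`, `drug_id`, `text` (a raw direction), or
#'   a single string (then `drug_id` is taken from the argument).
#' @param rules A `medic_rules` rule set.
#' @param extractor Named list of component libraries, a `dictionary_index`,
#'   or a `tagger_model`.
#' @param catalog A `medic_catalog`.
#' @param drug_id Drug id override when `raw` is a plain string.
#' @return An object of class `suggestion_outcome`: `status`
#'   (`"suggested"`/`"halted"`), `direction` or `guardrail`, `components`
#'   (with provenance), plus the audit fields `normalized`, `extraction`,
#'   and `notes`.
#' @export
suggest <- function(raw, rules, extractor, catalog, drug_id = NULL) {
  if (is.character(raw)) {
    raw <- list(record_id = NA_character_, drug_id = drug_id, text = raw)
  }
  norm <- normalize(raw$text, rules)
  ext <- if (inherits(extractor, "tagger_model")) {
    tag_model(extractor, norm$normalized)
  } else {
    tag_dictionary(norm$normalized, extractor)
  }
  entry <- catalog_lookup(catalog, raw$drug_id)
  notes <- character()
  if (is.null(entry)) notes <- c(notes, "catalog-missing")
  filled <- fill_missing(ext, entry)
  report <- apply_guardrails(filled, ext, entry,
                             libraries = if (inherits(extractor, "tagger_model") ||
                                             inherits(extractor, "dictionary_index"))
                               NULL else extractor)
  if (!is.na(report$triggered)) {
    out <- list(record_id = raw$record_id, status = "halted", direction = NULL,
                guardrail = report, components = filled$values,
                normalized = norm, extraction = ext, notes = notes)
  } else {
    out <- list(record_id = raw$record_id, status = "suggested",
                direction = assemble(filled), guardrail = NULL,
                components = filled$values[order(label_rank(filled$values$label)), ,
                                           drop = FALSE],
                normalized = norm, extraction = ext, notes = notes)
  }
  structure(out, class = "suggestion_outcome")
}

#' @export
print.suggestion_outcome <- function(x, ...) {
  if (x$status == "suggested") {
    cat(sprintf("<suggestion> %s\n", x$direction))
  } else {
    cat(sprintf("<halted %s> %s\n", x$guardrail$triggered, x$guardrail$reason))
  }
  invisible(x)
}

# unify digit forms with number words for canonical comparison ("1" -> "one")
normalize_number_words <- function(x) {
  words <- c("1" = "one", "2" = "two", "3" = "three", "4" = "four",
             "5" = "five", "6" = "six", "7" = "seven", "8" = "eight",
             "9" = "nine", "10" = "ten", "0.5" = "one half", "1/2" = "one half")
  vapply(x, function(s) {
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    hit <- match(toks, names(words))
    toks[!is.na(hit)] <- words[hit[!is.na(hit)]]
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}
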