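#' Canonicalize extracted components for semantic comparison
#'
#' Maps every extracted surface through its component library's canonical
#' map (identity when unmapped) and unifies digit forms with number words
#' ("1 tablet" and "one tablet" compare equal). Multi-value labels are kept;
#' the comparison stage reports them as discrepancies.
#'
#' @param extraction An `extraction_result`.
#' @param libraries Named list of `component_library` objects (optional).
#' @param entry Optional `catalog_entry` (reserved for catalog-aware
#'   standardization; unused fields are ignored).
#' @return Named list label -> character vector of canonical values.
#' @export
canonicalize <- function(extraction, libraries = NULL, entry = NULL) {
  vals <- extraction$values
  out <- list()
  for (lab in unique(vals$label)) {
    surf <- vals$surface[vals$label == lab]
    lib <- if (!is.null(libraries)) libraries[[lab]] else NULL
    out[[lab]] <- unname(normalize_number_words(canonical_value(lib, surf)))
  }
  out
}

#' Flag semantic discrepancies between two directions
#'
#' The flagging pipeline: both directions are normalized, component
#' extracted, and canonicalized, then compared label by label across all
#' nine components. Any label whose canonical values differ is flagged as a
#' `mismatch`; a label present on one side only is `missing-in-a` /
#' `missing-in-b`. The Boolean verdict `equivalent` is true iff there are no
#' discrepancies.
#'
#' In `partial` mode the second direction is an in-progress data-entry
#' transcription: labels present in `a` but not yet typed in `b` are
#' reported as `pending`, not as errors, while any value already typed is
#' compared immediately. In `final` mode such labels count as
#' `missing-in-b`.
#'
#' @param direction_a,direction_b Direction texts (raw or normalized).
#' @param rules A `medic_rules` rule set.
#' @param extractor Libraries, `dictionary_index` or `tagger_model`.
#' @param libraries Component libraries used for canonicalization (defaults
#'   to `extractor` when that is a libraries list).
#' @param catalog Optional `medic_catalog`.
#' @param drug_id Optional drug id for catalog-aware standardization.
#' @param mode `"final"` or `"partial"`.
#' @return An object of class `flag_report`: `equivalent` (Boolean),
#'   `discrepancies` (data.frame label/value_a/value_b/kind), `pending`
#'   (labels), `mode`.
#' @examples
#' rules <- load_rules(medic_fixture("rules"))
#' libs <- read_libraries(medic_fixture("libraries"))
#' flag_compare("take 20 mg by mouth once weekly",
#'              "take 20 mg by mouth once daily", rules, libs)
#' @export
flag_compare <- function(direction_a, direction_b, rules, extractor,
                         libraries = NULL, catalog = NULL, drug_id = NULL,
                         mode = c("final", "partial")) {
  mode <- match.arg(mode)
  if (is.null(libraries) && !inherits(extractor, "tagger_model") &&
      !inherits(extractor, "dictionary_index")) {
    libraries <- extractor
  }
  entry <- if (!is.null(catalog)) catalog_lookup(catalog, drug_id) else NULL
  extract_one <- function(text) {
    norm <- normalize(text, rules)
    ext <- if (inherits(extractor, "tagger_model")) {
      tag_model(extractor, norm$normalized)
    } else {
      tag_dictionary(norm$normalized, extractor)
    }
    canonicalize(ext, libraries, entry)
  }
  ca <- extract_one(direction_a)
  cb <- extract_one(direction_b)
  disc <- list()
  pending <- character()
  add <- function(label, va, vb, kind) {
    disc[[length(disc) + 1L]] <<- data.frame(
      label = label, value_a = va, value_b = vb, kind = kind,
      stringsAsFactors = FALSE)
  }
  for (lab in component_labels()) {
    va <- ca[[lab]]; vb <- cb[[lab]]
    a_has <- length(va) > 0L; b_has <- length(vb) > 0L
    if (!a_has && !b_has) next
    if (a_has && !b_has) {
      if (mode == "partial") pending <- c(pending, lab)
      else add(lab, paste(va, collapse = " | "), NA_character_, "missing-in-b")
    } else if (!a_has && b_has) {
      add(lab, NA_character_, paste(vb, collapse = " | "), "missing-in-a")
    } else if (!identical(sort(va), sort(vb))) {
      add(lab, paste(va, collapse = " | "), paste(vb, collapse = " | "),
          "mismatch")
    }
  }
  disc <- if (length(disc) > 0L) do.call(rbind, disc) else
    data.frame(label = character(), value_a = character(),
               value_b = character(), kind = character(),
               stringsAsFactors = FALSE)
  structure(list(equivalent = nrow(disc) == 0L,
                 discrepancies = disc, pending = pending, mode = mode),
            class = "flag_report")
}

#' @export
print.flag_report <- function(x, ...) {
  cat(sprintf("<flag_report %s> %s\n", x$mode,
              if (x$equivalent) "equivalent" else "NOT equivalent"))
  for (i in seq_len(nrow(x$discrepancies))) {
    d <- x$discrepancies[i, ]
    cat(sprintf("  %-12s %-10s a='%s' b='%s'\n", d$label, d$kind,
                d$value_a, d$value_b))
  }
  if (length(x$pending) > 0L) {
    cat(sprintf("  pending: %s\n", paste(x$pending, collapse = ", ")))
  }
  invisible(x)
}

#' Map flag discrepancies onto the six error categories
#'
#' Collapses per-label discrepancies into the six categories used for
#' near-miss review: verb, dose-quantity, dose-form, route, frequency and
#' auxiliary. A dose discrepancy splits on its numeric and unit parts:
#' differing numeric tokens give `dose-quantity`, equal numerics with
#' differing unit tokens give `dose-form` (both differing counts as
#' quantity). The five auxiliary labels aggregate into `auxiliary`.
#'
#' @param report A `flag_report`.
#' @return Character vector of error categories (unique, possibly empty).
#' @export
categorize_errors <- function(report) {
  cats <- character()
  for (i in seq_len(nrow(report$discrepancies))) {
    d <- report$discrepancies[i, ]
    cats <- c(cats, switch(
      d$label,
      verb = "verb",
      route = "route",
      frequency = "frequency",
      dose = {
        if (d$kind != "mismatch") "dose-quantity"
        else {
          pa <- split_dose(d$value_a); pb <- split_dose(d$value_b)
          if (!identical(pa$num, pb$num)) "dose-quantity"
          else if (!identical(pa$unit, pb$unit)) "dose-form"
          else "dose-quantity"
        }
      },
      "auxiliary"))
  }
  unique(cats)
}

# numeric vs unit tokens of a dose value
split_dose <- function(value) {
  toks <- strsplit(normalize_number_words(value), " ", fixed = TRUE)[[1]]
  number_words <- c("one", "two", "three", "four", "five", "six", "seven",
                    "eight", "nine", "ten", "half")
  is_num <- grepl("^[0-9][0-9.,/]*$", toks) | toks %in% number_words
  list(num = toks[is_num], unit = toks[!is_num])
}

#' Detection-rate harness for the flagger
#'
#' Given labeled pairs (two direction texts plus the gold error category of
#' their single perturbation, or `"none"` for unperturbed pairs), runs
#' [flag_compare()] on each and reports, per category, the fraction of
#' pairs flagged with a discrepancy in that category, plus the overall
#' detection rate and the false-flag rate on unperturbed pairs.
#'
#' @param pairs data.frame with columns `a`, `b`, `category`.
#' @param rules,extractor,libraries,catalog See [flag_compare()].
#' @return List with `per_category` (data.frame category/n/detected/rate),
#'   `overall_rate`, `false_flag_rate`.
#' @export
evaluate_flagger <- function(pairs, rules, extractor, libraries = NULL,
                             catalog = NULL) {
  if (nrow(pairs) == 0L) stop("no evaluation pairs supplied", call. = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    rep <- flag_compare(pairs$a[i], pairs$b[i], rules, extractor,
                        libraries = libraries, catalog = catalog)
    list(flagged = !rep$equivalent, cats = categorize_errors(rep))
  })
  perturbed <- pairs$category != "none"
  per_category <- do.call(rbind, lapply(
    unique(pairs$category[perturbed]), function(cat) {
      idx <- which(pairs$category == cat)
      det <- vapply(res[idx], function(r) cat %in% r$cats, logical(1))
      data.frame(category = cat, n = length(idx), detected = sum(det),
                 rate = mean(det), stringsAsFactors = FALSE)
    }))
  flagged <- vapply(res, `[[`, logical(1), "flagged")
  list(per_category = per_category,
       overall_rate = if (any(perturbed)) mean(flagged[perturbed]) else NA_real_,
       false_flag_rate = if (any(!perturbed)) mean(flagged[!perturbed]) else NA_real_)
}
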