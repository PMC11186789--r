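#' Run a named end-to-end experiment
#'
#' Orchestrates the three stock experiment pipelines over the bundled (or
#' user-supplied) resources and writes machine-readable JSON reports. Every
#' stochastic stage derives its seed from `config$seed`, so a rerun with the
#' same config reproduces the report exactly; the report embeds the config
#' and a corpus fingerprint.
#'
#' * `augment-train-eval`: generate a training and a disjoint test corpus by
#'   pattern sampling, train the scratch tagger, report entity-level
#'   precision/recall/F1.
#' * `suggest-eval`: generate a labeled corpus, degrade it into raw
#'   prescriber style, run the full suggestion pipeline, and score the
#'   suggested directions against the gold texts with BLEU/METEOR (over all
#'   records and over the non-halted subset) plus a guardrail-halt tally.
#' * `flag-eval`: build single-perturbation pairs from a generated corpus
#'   and report per-category detection rates.
#'
#' @param config List with paths (`rules`, `libraries`, `patterns`,
#'   `catalog`, `noise`; defaults are the bundled fixtures), sizes
#'   (`n_train`, `n_test`), and `seed`.
#' @param experiment One of `"augment-train-eval"`, `"suggest-eval"`,
#'   `"flag-eval"`.
#' @param out Optional path for the JSON report.
#' @return The report (list), invisibly written to `out` when given.
#' @export
run_experiment <- function(config = list(),
                           experiment = c("augment-train-eval", "suggest-eval",
                                          "flag-eval"),
                           out = NULL) {
  experiment <- match.arg(experiment)
  cfg <- utils::modifyList(list(
    rules = medic_fixture("rules"),
    libraries = medic_fixture("libraries"),
    patterns = medic_fixture("patterns"),
    catalog = medic_fixture("catalog"),
    noise = medic_fixture("noise"),
    n_train = 10000L, n_test = 10000L, seed = 1L), config)
  libs <- read_libraries(cfg$libraries)
  pats <- read_patterns(cfg$patterns)
  rules <- load_rules(cfg$rules, vocabulary = library_vocabulary(libs))
  report <- switch(
    experiment,
    "augment-train-eval" = {
      train <- generate_corpus(pats, libs, cfg$n_train, seed = cfg$seed,
                               prefix = "train")
      test <- generate_corpus(pats, libs, cfg$n_test, seed = cfg$seed + 1L,
                              prefix = "test")
      model <- train_tagger(train, hyperparameters(seed = cfg$seed))
      ev <- evaluate_tagger(model, test)
      list(experiment = experiment,
           micro = ev$micro, macro = ev$macro, per_label = ev$per_label,
           n_gold = ev$n_gold,
           corpus_fingerprint = corpus_fingerprint(train))
    },
    "suggest-eval" = {
      catalog <- load_catalog(cfg$catalog)
      noise <- read_noise_model(cfg$noise)
      gold <- generate_corpus(pats, libs, cfg$n_test, seed = cfg$seed,
                              prefix = "gold")
      drug_ids <- names(catalog)
      outcomes <- vector("list", length(gold))
      for (i in seq_along(gold)) {
        gold[[i]]$drug_id <- drug_ids[((i - 1L) %% length(drug_ids)) + 1L]
        raw <- degrade(gold[[i]], noise, seed = cfg$seed + i)
        outcomes[[i]] <- suggest(raw, rules, libs, catalog)
      }
      status <- vapply(outcomes, `[[`, character(1), "status")
      active <- status == "suggested"
      halts <- vapply(outcomes[!active], function(o) o$guardrail$triggered,
                      character(1))
      refs <- vapply(gold, `[[`, character(1), "text")
      cands <- ifelse(active,
                      vapply(outcomes, function(o) o$direction %||% "", character(1)),
                      "")
      sc_all <- score_generation(cands, refs)
      sc_act <- if (any(active)) score_generation(cands[active], refs[active]) else NULL
      list(experiment = experiment,
           n = length(gold), n_active = sum(active),
           halt_tally = as.list(table(factor(halts, levels = guardrail_ids()))),
           bleu_all = sc_all$summary$bleu, meteor_all = sc_all$summary$meteor,
           bleu_active = sc_act$summary$bleu, meteor_active = sc_act$summary$meteor)
    },
    "flag-eval" = {
      pairs <- perturbation_pairs(pats, libs, n_per_category = 10L,
                                  seed = cfg$seed)
      ev <- evaluate_flagger(pairs, rules, libs)
      list(experiment = experiment, per_category = ev$per_category,
           overall_rate = ev$overall_rate,
           false_flag_rate = ev$false_flag_rate)
    })
  report$config <- cfg
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)
  }
  invisible(report)
}

#' Union vocabulary of all component-library surfaces
#'
#' The token vocabulary used for conservative spell correction during
#' normalization.
#'
#' @param libraries Named list of `component_library` objects.
#' @return Character vector of unique lower-case tokens.
#' @export
library_vocabulary <- function(libraries) {
  unique(tolower(unlist(lapply(libraries, function(l) {
    unlist(strsplit(l$surfaces, "[[:space:]]+"))
  }))))
}

#' Build single-perturbation direction pairs for flagger evaluation
#'
#' Generates gold directions, then for each error category perturbs exactly
#' one component by swapping its surface for a different library value of
#' the same label (for `dose-quantity` the swap changes the numeric part
#' only; for `dose-form` the unit part only). Also emits unperturbed pairs
#' (`category == "none"`) for the specificity check.
#'
#' @param patterns A `pattern_library`.
#' @param libraries Named list of `component_library` objects.
#' @param n_per_category Pairs per category.
#' @param seed Integer seed.
#' @return data.frame with columns `a`, `b`, `category`.
#' @export
perturbation_pairs <- function(patterns, libraries, n_per_category = 10L,
                               seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  categories <- c("verb", "dose-quantity", "dose-form", "route", "frequency",
                  "auxiliary", "none")
  label_for <- c(verb = "verb", `dose-quantity` = "dose", `dose-form` = "dose",
                 route = "route", frequency = "frequency")
  rows <- list()
  for (cat in categories) {
    made <- 0L
    guard <- 0L
    while (made < n_per_category && guard < 1000L) {
      guard <- guard + 1L
      lab <- if (cat == "none") NA_character_
             else if (cat == "auxiliary") sample(auxiliary_labels(), 1L)
             else label_for[[cat]]
      # draw a pattern containing the label to perturb
      ok <- if (is.na(lab)) rep(TRUE, length(patterns$patterns))
            else vapply(patterns$patterns, function(p) lab %in% p, logical(1))
      if (!any(ok)) break
      p <- patterns$patterns[ok][[sample.int(sum(ok), 1L)]]
      surfaces <- vapply(p, function(l) {
        s <- libraries[[l]]$surfaces
        s[[sample.int(length(s), 1L)]]
      }, character(1))
      a <- paste(surfaces, collapse = " ")
      if (cat == "none") {
        rows[[length(rows) + 1L]] <- data.frame(a = a, b = a, category = cat,
                                                stringsAsFactors = FALSE)
        made <- made + 1L
        next
      }
      i <- which(p == lab)[[1L]]
      alt <- perturb_surface(surfaces[[i]], libraries[[lab]], cat)
      if (is.na(alt)) next
      surfaces[[i]] <- alt
      rows[[length(rows) + 1L]] <- data.frame(
        a = a, b = paste(surfaces, collapse = " "), category = cat,
        stringsAsFactors = FALSE)
      made <- made + 1L
    }
  }
  do.call(rbind, rows)
}

perturb_surface <- function(surface, library, category) {
  pool <- setdiff(library$surfaces, surface)
  cs <- canonical_value(library, surface)
  # exclude synonyms of the original: the perturbation must change meaning
  pool <- pool[canonical_value(library, pool) != cs]
  if (category %in% c("dose-quantity", "dose-form")) {
    orig <- split_dose(surface)
    parts <- lapply(pool, split_dose)
    keep <- if (category == "dose-quantity") {
      vapply(parts, function(x) identical(x$unit, orig$unit) &&
               !identical(x$num, orig$num), logical(1))
    } else {
      vapply(parts, function(x) identical(x$num, orig$num) &&
               !identical(x$unit, orig$unit), logical(1))
    }
    pool <- pool[keep]
  }
  if (length(pool) == 0L) return(NA_character_)
  pool[[sample.int(length(pool), 1L)]]
}
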