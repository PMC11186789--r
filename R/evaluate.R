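#' Entity-level evaluation of an extraction backend
#'
#' Scores predictions against gold spans by entity-level exact match: a
#' predicted entity counts as correct only when label, start and end all
#' match a gold entity. Reports per-label and micro-averaged precision,
#' recall and F1, entity counts, and a confusion matrix over labels plus an
#' outside class (each gold entity is attributed to the label of the
#' predicted entity with the same boundaries, or to `O` when no predicted
#' entity shares its boundaries; row sums therefore equal gold entity
#' counts).
#'
#' @param model A `tagger_model`, a `dictionary_index`, or a named list of
#'   `component_library` objects (evaluated through the dictionary tagger).
#' @param corpus Non-empty list of gold `labeled_direction` objects.
#' @return An object of class `extraction_eval`: list with `per_label`
#'   (data.frame), `micro` (precision/recall/f1), `confusion`,
#'   `n_gold`, `n_pred`, and `degenerate` (TRUE when the model predicted
#'   nothing, in which case precision is reported as 0).
#' @export
evaluate_tagger <- function(model, corpus) {
  if (length(corpus) == 0L) stop("evaluation corpus is empty", call. = FALSE)
  tagger <- if (inherits(model, "tagger_model")) {
    function(text) tag_model(model, text)
  } else {
    idx <- if (inherits(model, "dictionary_index")) model else dictionary_index(model)
    function(text) tag_dictionary(text, idx)
  }
  labs <- component_labels()
  tp <- fp <- fn <- stats::setNames(rep(0L, 9L), labs)
  conf <- matrix(0L, 9L, 10L, dimnames = list(labs, c(labs, "O")))
  n_pred_total <- 0L
  for (d in corpus) {
    gold <- d$spans
    pred <- tagger(d$text)$values
    n_pred_total <- n_pred_total + nrow(pred)
    gkey <- sprintf("%d:%d", gold$start, gold$end)
    pkey <- if (nrow(pred) > 0L) sprintf("%d:%d", pred$start, pred$end) else character()
    for (g in seq_len(nrow(gold))) {
      gl <- gold$label[g]
      hit <- match(gkey[g], pkey)
      if (!is.na(hit) && pred$label[hit] == gl) {
        tp[gl] <- tp[gl] + 1L
        conf[gl, gl] <- conf[gl, gl] + 1L
      } else {
        fn[gl] <- fn[gl] + 1L
        conf[gl, if (is.na(hit)) "O" else pred$label[hit]] <-
          conf[gl, if (is.na(hit)) "O" else pred$label[hit]] + 1L
      }
    }
    for (p in seq_len(nrow(pred))) {
      pl <- pred$label[p]
      hit <- match(pkey[p], gkey)
      if (is.na(hit) || gold$label[hit] != pl) fp[pl] <- fp[pl] + 1L
    }
  }
  prf <- function(tp, fp, fn) {
    tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  per_label <- do.call(rbind, lapply(labs, function(l) {
    data.frame(label = l, t(prf(tp[l], fp[l], fn[l])),
               gold = tp[l] + fn[l], predicted = tp[l] + fp[l],
               stringsAsFactors = FALSE)
  }))
  micro <- prf(sum(tp), sum(fp), sum(fn))
  structure(list(per_label = per_label,
                 micro = as.list(micro),
                 macro = list(precision = mean(per_label$precision[per_label$gold > 0]),
                              recall = mean(per_label$recall[per_label$gold > 0]),
                              f1 = mean(per_label$f1[per_label$gold > 0])),
                 confusion = conf,
                 n_gold = sum(tp) + sum(fn),
                 n_pred = n_pred_total,
                 degenerate = n_pred_total == 0L),
            class = "extraction_eval")
}

#' @export
print.extraction_eval <- function(x, ...) {
  cat(sprintf("<extraction_eval> %d gold entities, %d predicted\n",
              x$n_gold, x$n_pred))
  cat(sprintf("  micro P=%.4f R=%.4f F1=%.4f%s\n",
              x$micro$precision, x$micro$recall, x$micro$f1,
              if (x$degenerate) " [degenerate: no predictions]" else ""))
  invisible(x)
}
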