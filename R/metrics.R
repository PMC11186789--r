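#' Sentence-level BLEU
#'
#' Smoothed sentence BLEU for short generated directions: modified n-gram
#' precisions up to order `min(4, length(candidate))`, add-one smoothing on
#' the higher-order precisions (order >= 2), geometric mean, and the usual
#' brevity penalty. Unsmoothed BLEU degenerates to zero on short sentences
#' the moment one 4-gram is absent, which is why the smoothed variant is the
#' default for direction-length text.
#'
#' @param candidate,reference Sentence strings; tokenized on whitespace and
#'   punctuation.
#' @return BLEU score in `[0, 1]`; an empty candidate scores 0.
#' @examples
#' bleu_sentence("take one tablet by mouth", "take one tablet by mouth")
#' @export
bleu_sentence <- function(candidate, reference) {
  ct <- metric_tokens(candidate)
  rt <- metric_tokens(reference)
  if (length(ct) == 0L || length(rt) == 0L) return(0)
  max_n <- min(4L, length(ct))
  logp <- numeric(max_n)
  for (n in seq_len(max_n)) {
    cg <- ngrams(ct, n); rg <- ngrams(rt, n)
    Ln <- length(cg)
    # clipped matches: per distinct n-gram, min(count in c, count in r)
    tc <- table(cg); tr <- table(rg)
    m <- sum(vapply(names(tc), function(g) {
      min(tc[[g]], if (g %in% names(tr)) tr[[g]] else 0L)
    }, numeric(1)))
    if (n == 1L) {
      if (m == 0) return(0)
      logp[n] <- log(m / Ln)
    } else {
      logp[n] <- log((m + 1) / (Ln + 1))
    }
  }
  bp <- if (length(ct) < length(rt)) exp(1 - length(rt) / length(ct)) else 1
  bp * exp(mean(logp))
}

metric_tokens <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  tokenize(tolower(x))$token
}

ngrams <- function(tokens, n) {
  k <- length(tokens) - n + 1L
  if (k <= 0L) return(character())
  vapply(seq_len(k), function(i) paste(tokens[i:(i + n - 1L)], collapse = " "),
         character(1))
}

#' Sentence-level METEOR (exact-match variant)
#'
#' Unigram alignment on exact (lower-cased) token matches, harmonic
#' precision/recall mean weighted toward recall (alpha = 0.9), and a
#' fragmentation penalty `gamma * (chunks / matches)^beta` with gamma = 0.5,
#' beta = 3. Stemming and synonym modules of the full metric are not used —
#' normalized direction text has little inflectional variety and synonym
#' knowledge lives in the component libraries instead.
#'
#' @param candidate,reference Sentence strings.
#' @return METEOR score in `[0, 1]`; empty candidate scores 0.
#' @export
meteor_sentence <- function(candidate, reference) {
  ct <- metric_tokens(candidate)
  rt <- metric_tokens(reference)
  if (length(ct) == 0L || length(rt) == 0L) return(0)
  # greedy in-order alignment: each candidate token takes the earliest
  # unused identical reference token
  align <- integer(length(ct))
  used <- logical(length(rt))
  for (i in seq_along(ct)) {
    j <- which(rt == ct[i] & !used)
    align[i] <- if (length(j) > 0L) j[[1L]] else NA_integer_
    if (!is.na(align[i])) used[align[i]] <- TRUE
  }
  m <- sum(!is.na(align))
  if (m == 0L) return(0)
  p <- m / length(ct)
  r <- m / length(rt)
  fmean <- p * r / (0.9 * p + 0.1 * r)
  ai <- which(!is.na(align))
  chunks <- 1L
  if (length(ai) > 1L) {
    for (k in 2L:length(ai)) {
      if (ai[k] != ai[k - 1L] + 1L || align[ai[k]] != align[ai[k - 1L]] + 1L) {
        chunks <- chunks + 1L
      }
    }
  }
  penalty <- 0.5 * (chunks / m)^3
  fmean * (1 - penalty)
}

#' Score generated directions against references
#'
#' Computes per-record sentence BLEU and METEOR plus corpus summaries
#' (mean, median, quartiles). Records with an empty candidate score 0 and
#' are flagged degenerate.
#'
#' @param candidates,references Equal-length character vectors.
#' @return An object of class `generation_eval`: `per_record` (data.frame
#'   bleu/meteor/degenerate), `summary` (list of summary stats), `n`.
#' @export
score_generation <- function(candidates, references) {
  if (length(candidates) != length(references)) {
    stop(sprintf("length mismatch: %d candidates vs %d references",
                 length(candidates), length(references)), call. = FALSE)
  }
  if (length(candidates) == 0L) stop("no records to score", call. = FALSE)
  bleu <- mapply(bleu_sentence, candidates, references, USE.NAMES = FALSE)
  meteor <- mapply(meteor_sentence, candidates, references, USE.NAMES = FALSE)
  degen <- !nzchar(trimws(ifelse(is.na(candidates), "", candidates)))
  qs <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    list(mean = mean(x), q1 = q[1], median = q[2], q3 = q[3])
  }
  structure(list(
    per_record = data.frame(bleu = bleu, meteor = meteor, degenerate = degen),
    summary = list(bleu = qs(bleu), meteor = qs(meteor)),
    n = length(candidates)),
    class = "generation_eval")
}

#' @export
print.generation_eval <- function(x, ...) {
  cat(sprintf("<generation_eval> n=%d  BLEU mean=%.4f median=%.4f  METEOR mean=%.4f median=%.4f\n",
              x$n, x$summary$bleu$mean, x$summary$bleu$median,
              x$summary$meteor$mean, x$summary$meteor$median))
  invisible(x)
}
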