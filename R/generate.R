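#' Generate a synthetic labeled corpus by pattern sampling
#'
#' Reproduces the combinatorial augmentation procedure used to expand a
#' small expert-labeled direction set: each record is built by drawing a
#' pattern (a label sequence) from the pattern library, then drawing one
#' surface from each component's library, and joining the surfaces with
#' single spaces in pattern order. Character spans are computed exactly, so
#' every generated record is a fully labeled direction. Draws are uniform
#' unless `weighted = TRUE`, in which case patterns are drawn proportionally
#' to their observed frequency.
#'
#' @param patterns A `pattern_library`.
#' @param libraries Named list of `component_library` objects (from
#'   [build_libraries()] or [read_libraries()]).
#' @param n Number of records to generate (>= 0).
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @param weighted Draw patterns by observed frequency instead of uniformly.
#' @param prefix Record-id prefix (default "syn").
#' @return List of `n` `labeled_direction` objects.
#' @examples
#' libs <- read_libraries(medic_fixture("libraries"))
#' pats <- read_patterns(medic_fixture("patterns"))
#' corpus <- generate_corpus(pats, libs, n = 5, seed = 1)
#' corpus[[1]]$text
#' @export
generate_corpus <- function(patterns, libraries, n, seed, weighted = FALSE,
                            prefix = "syn") {
  stopifnot(inherits(patterns, "pattern_library"), n >= 0L)
  used <- unique(unlist(patterns$patterns))
  for (lab in used) {
    lib <- libraries[[lab]]
    if (is.null(lib) || length(lib$surfaces) == 0L) {
      stop(sprintf("cannot generate: library for label '%s' is empty", lab),
           call. = FALSE)
    }
  }
  if (n == 0L) return(list())
  rng <- local_rng(seed)
  on.exit(rng())
  npat <- length(patterns$patterns)
  w <- if (weighted) patterns$freq else NULL
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- patterns$patterns[[sample.int(npat, 1L, prob = w)]]
    surfaces <- vapply(p, function(lab) {
      s <- libraries[[lab]]$surfaces
      s[[sample.int(length(s), 1L)]]
    }, character(1))
    text <- paste(surfaces, collapse = " ")
    ends <- cumsum(nchar(surfaces) + 1L) - 1L   # +1 for joining space
    starts <- ends - nchar(surfaces)
    out[[i]] <- labeled_direction(
      sprintf("%s-%06d", prefix, i), text,
      data.frame(label = p, start = starts, end = ends,
                 stringsAsFactors = FALSE))
  }
  out
}

# Run code under a locally-seeded RNG, restoring the global state after.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Define a prescriber-noise model
#'
#' Emulates raw prescriber text for end-to-end tests: canonical phrases are
#' replaced by raw variants (typically the inverse of the normalization
#' rules, e.g. "by mouth" -> "po"), characters are perturbed with a
#' per-token typo probability, and a casing policy is applied.
#'
#' @param abbrev Named list: canonical phrase -> character vector of raw
#'   variants.
#' @param typo_rate Per-token typo probability in `[0, 1]`.
#' @param casing One of `"keep"`, `"upper"`, `"title"`, `"random"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(abbrev = list(), typo_rate = 0, casing = "keep") {
  stopifnot(typo_rate >= 0, typo_rate <= 1)
  casing <- match.arg(casing, c("keep", "upper", "title", "random"))
  structure(list(abbrev = abbrev, typo_rate = typo_rate, casing = casing),
            class = "noise_model")
}

#' Read a noise model from YAML
#'
#' File format: `abbrev: {canonical: [variants...]}`, `typo_rate: p`,
#' `casing: keep|upper|title|random`.
#'
#' @param path Path to the YAML noise-model file.
#' @return A `noise_model`.
#' @export
read_noise_model <- function(path) {
  raw <- yaml::read_yaml(path)
  noise_model(abbrev = lapply(raw$abbrev %||% list(), as.character),
              typo_rate = raw$typo_rate %||% 0,
              casing = raw$casing %||% "keep")
}

#' Degrade a clean direction into raw prescriber style
#'
#' Applies the noise model to a labeled direction and returns an unlabeled
#' raw record (noise invalidates the character spans). With a zero typo rate
#' and an empty abbreviation map the text passes through unchanged; a fixed
#' seed reproduces the output exactly.
#'
#' @param direction A `labeled_direction`.
#' @param noise A `noise_model`.
#' @param seed Integer seed.
#' @return List with `record_id`, `drug_id`, `text` (a raw direction).
#' @export
degrade <- function(direction, noise, seed = 1L) {
  validate_direction(direction)
  rng <- local_rng(seed)
  on.exit(rng())
  text <- direction$text
  for (canon in names(noise$abbrev)) {
    variants <- noise$abbrev[[canon]]
    if (grepl(paste0("\\b", escape_regex(canon), "\\b"), text, perl = TRUE)) {
      v <- variants[[sample.int(length(variants), 1L)]]
      text <- gsub(paste0("\\b", escape_regex(canon), "\\b"), v, text, perl = TRUE)
    }
  }
  if (noise$typo_rate > 0) {
    toks <- strsplit(text, " ", fixed = TRUE)[[1]]
    hit <- stats::runif(length(toks)) < noise$typo_rate
    toks[hit] <- vapply(toks[hit], inject_typo, character(1))
    text <- paste(toks, collapse = " ")
  }
  text <- switch(noise$casing,
                 keep = text,
                 upper = toupper(text),
                 title = gsub("\\b([a-z])", "\\U\\1", text, perl = TRUE),
                 random = {
                   ch <- strsplit(text, "")[[1]]
                   up <- stats::runif(length(ch)) < 0.5
                   ch[up] <- toupper(ch[up])
                   paste(ch, collapse = "")
                 })
  list(record_id = direction$record_id, drug_id = direction$drug_id, text = text)
}

# single seeded character-level typo: delete, duplicate or swap
inject_typo <- function(token) {
  n <- nchar(token)
  if (n < 3L) return(token)
  ch <- strsplit(token, "")[[1]]
  op <- sample.int(3L, 1L)
  i <- sample.int(n - 1L, 1L) + 1L
  if (op == 1L) ch <- ch[-i]
  else if (op == 2L) ch <- append(ch, ch[i], after = i)
  else { tmp <- ch[i]; ch[i] <- ch[i - 1L]; ch[i - 1L] <- tmp }
  paste(ch, collapse = "")
}

#' Cluster-stratified corpus split
#'
#' Splits a corpus into parts with the given fractions, stratified over
#' clusters of a low-dimensional text representation: records are embedded
#' as term-frequency vectors, clustered with k-means into `k` groups, and
#' each group is split proportionally. The partition is disjoint,
#' exhaustive and reproducible under a fixed seed. `k = 1` reduces to a
#' plain seeded random split.
#'
#' @param corpus List of `labeled_direction` objects.
#' @param fractions Numeric vector summing to 1.
#' @param k Number of clusters (default 8).
#' @param seed Integer seed.
#' @return List of sub-corpora (same classes), one per fraction.
#' @export
stratified_split <- function(corpus, fractions, k = 8L, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, k >= 1L)
  n <- length(corpus)
  if (n < length(fractions)) {
    stop(sprintf("corpus of %d records cannot be split into %d parts",
                 n, length(fractions)), call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng())
  cl <- if (k == 1L || n <= k) {
    rep(1L, n)
  } else {
    texts <- vapply(corpus, `[[`, character(1), "text")
    toks <- strsplit(texts, " ", fixed = TRUE)
    vocab <- sort(unique(unlist(toks)))
    tf <- matrix(0, nrow = n, ncol = length(vocab))
    for (i in seq_len(n)) {
      tt <- table(factor(toks[[i]], levels = vocab))
      tf[i, ] <- as.numeric(tt)
    }
    stats::kmeans(tf, centers = k, nstart = 1L)$cluster
  }
  parts <- vector("list", length(fractions))
  for (p in seq_along(parts)) parts[[p]] <- integer()
  for (g in sort(unique(cl))) {
    idx <- sample(which(cl == g))
    cuts <- round(cumsum(fractions) * length(idx))
    lo <- c(0L, cuts[-length(cuts)]) + 1L
    for (p in seq_along(fractions)) {
      if (lo[p] <= cuts[p]) parts[[p]] <- c(parts[[p]], idx[lo[p]:cuts[p]])
    }
  }
  lapply(parts, function(ix) corpus[sort(ix)])
}
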