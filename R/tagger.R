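#' Training hyper-parameters for the sequence tagger
#'
#' Defaults are the tuned configuration for the extraction model: batch size
#' 16, learning rate 1e-4, 3 training epochs and weight decay 1e-5.
#'
#' @param batch_size Mini-batch size (sentences per update step).
#' @param learning_rate Step size applied to every weight update.
#' @param epochs Number of full passes over the training corpus.
#' @param weight_decay L2 shrinkage applied once per epoch, scaled by the
#'   number of update steps.
#' @param seed Integer seed controlling shuffling and the train/validation
#'   split.
#' @return An object of class `hyperparameters`.
#' @export
hyperparameters <- function(batch_size = 16L, learning_rate = 1e-4,
                            epochs = 3L, weight_decay = 1e-5, seed = 42L) {
  stopifnot(batch_size >= 1L, learning_rate > 0, epochs >= 1L,
            weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "hyperparameters")
}

# ---- featurization ---------------------------------------------------------

token_features <- function(tokens) {
  n <- length(tokens)
  prev <- c("<s>", tokens[-n])
  nxt <- c(tokens[-1L], "</s>")
  shape <- ifelse(grepl("^[0-9.,/]+$", tokens), "d",
                  ifelse(grepl("[0-9]", tokens), "m", "a"))
  suf <- substr(tokens, pmax(1L, nchar(tokens) - 2L), nchar(tokens))
  lapply(seq_len(n), function(i) {
    c(paste0("w=", tokens[i]), paste0("p=", prev[i]), paste0("n=", nxt[i]),
      paste0("s=", suf[i]), paste0("sh=", shape[i]))
  })
}

# sentence -> list(feats = list of int vectors, gold = int vector)
prepare_sentences <- function(corpus, dict = NULL) {
  tags <- bio_tags()
  grow <- is.null(dict)
  if (grow) dict <- new.env(parent = emptyenv())
  nfeat <- length(ls(dict))
  sents <- vector("list", length(corpus))
  for (s in seq_along(corpus)) {
    d <- corpus[[s]]
    rows <- to_conll(d)
    toks <- tolower(rows$token)
    gold <- match(rows$tag, tags)
    if (anyNA(gold)) {
      stop(sprintf("record '%s': tag outside the BIO inventory", d$record_id),
           call. = FALSE)
    }
    feats <- token_features(toks)
    ids <- lapply(feats, function(fv) {
      out <- integer(length(fv))
      for (k in seq_along(fv)) {
        id <- dict[[fv[k]]]
        if (is.null(id)) {
          if (grow) {
            nfeat <<- nfeat + 1L
            dict[[fv[k]]] <- nfeat
            id <- nfeat
          } else id <- 0L
        }
        out[k] <- id
      }
      out[out > 0L]
    })
    sents[[s]] <- list(feats = ids, gold = gold,
                       starts = rows$start, ends = rows$end)
  }
  list(sentences = sents, dict = dict, nfeat = nfeat)
}

# emission score matrix (T x L) for one sentence given weight matrix W
emission_scores <- function(W, feats) {
  Tn <- length(feats)
  L <- ncol(W)
  flat <- unlist(feats, use.names = FALSE)
  if (length(flat) == 0L) return(matrix(0, Tn, L))
  grp <- rep.int(seq_len(Tn), lengths(feats))
  E <- matrix(0, Tn, L)
  S <- rowsum(W[flat, , drop = FALSE], grp)
  E[as.integer(rownames(S)), ] <- S
  E
}

viterbi_decode <- function(E, Tr, start) {
  Tn <- nrow(E); L <- ncol(E)
  if (Tn == 1L) return(which.max(E[1L, ] + start))
  bp <- matrix(0L, Tn, L)
  delta <- E[1L, ] + start
  for (t in 2L:Tn) {
    M <- Tr + delta             # M[from, to]; delta recycles down columns
    tM <- t(M)
    from <- max.col(tM, ties.method = "first")
    delta <- tM[cbind(seq_len(L), from)] + E[t, ]
    bp[t, ] <- from
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  for (t in Tn:2L) path[t - 1L] <- bp[t, path[t]]
  path
}

# ---- training --------------------------------------------------------------

#' Train the scratch sequence tagger
#'
#' Trains an averaged structured perceptron over BIO tags: word, context,
#' suffix and shape features feed per-tag emission scores, first-order
#' transition weights are learned jointly, and decoding is exact Viterbi.
#' Sentences are processed in seeded shuffled order in mini-batches (each
#' batch decoded against the weights at batch start, updates applied
#' together, scaled by the learning rate); parameter averaging over all
#' batch steps gives the final weights. A seeded 90/10 train/validation
#' split is made and validation token accuracy is recorded in the metadata;
#' the epoch count is fixed (no early stopping).
#'
#' @param corpus Non-empty list of `labeled_direction` objects with
#'   token-aligned spans.
#' @param hp A [hyperparameters()] object.
#' @param backend `"scratch"` (implemented) or `"transformer"` (not
#'   implemented in this package).
#' @return An object of class `tagger_model`.
#' @seealso [tag_model()], [evaluate_tagger()]
#' @export
train_tagger <- function(corpus, hp = hyperparameters(), backend = "scratch") {
  if (length(corpus) == 0L) stop("training corpus is empty", call. = FALSE)
  backend <- match.arg(backend, c("scratch", "transformer"))
  if (backend == "transformer") {
    stop("backend 'transformer' is not implemented in this package; use 'scratch'",
         call. = FALSE)
  }
  rng <- local_rng(hp$seed)
  on.exit(rng())
  L <- length(bio_tags())
  prep <- prepare_sentences(corpus)
  sents <- prep$sentences
  n <- length(sents)
  # seeded 90/10 split; validation is for logging only
  val_idx <- if (n >= 10L) sample.int(n, max(1L, floor(n / 10))) else integer()
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0L) train_idx <- seq_len(n)

  W <- matrix(0, max(1L, prep$nfeat), L)
  Tr <- matrix(0, L, L)
  S0 <- numeric(L)
  Wa <- W; Tra <- Tr; S0a <- S0
  lr <- hp$learning_rate
  nbatch <- 0L

  for (epoch in seq_len(hp$epochs)) {
    order_ <- sample(train_idx)
    batches <- split(order_, ceiling(seq_along(order_) / hp$batch_size))
    for (b in batches) {
      upd_i <- integer(0); upd_j <- integer(0); upd_d <- numeric(0)
      dTr <- NULL; dS0 <- NULL
      for (s in b) {
        sent <- sents[[s]]
        E <- emission_scores(W, sent$feats)
        pred <- viterbi_decode(E, Tr, S0)
        gold <- sent$gold
        if (identical(pred, gold)) next
        if (is.null(dTr)) { dTr <- matrix(0, L, L); dS0 <- numeric(L) }
        for (t in seq_along(gold)) {
          if (pred[t] != gold[t]) {
            f <- sent$feats[[t]]
            upd_i <- c(upd_i, f, f)
            upd_j <- c(upd_j, rep.int(gold[t], length(f)),
                       rep.int(pred[t], length(f)))
            upd_d <- c(upd_d, rep.int(1, length(f)), rep.int(-1, length(f)))
          }
        }
        dS0[gold[1L]] <- dS0[gold[1L]] + 1
        dS0[pred[1L]] <- dS0[pred[1L]] - 1
        if (length(gold) > 1L) {
          for (t in 2L:length(gold)) {
            dTr[gold[t - 1L], gold[t]] <- dTr[gold[t - 1L], gold[t]] + 1
            dTr[pred[t - 1L], pred[t]] <- dTr[pred[t - 1L], pred[t]] - 1
          }
        }
      }
      if (!is.null(dTr)) {
        agg <- rowsum(upd_d, paste(upd_i, upd_j))
        key <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
        cells <- cbind(as.integer(key[, 1L]), as.integer(key[, 2L]))
        W[cells] <- W[cells] + lr * agg[, 1L]
        Tr <- Tr + lr * dTr
        S0 <- S0 + lr * dS0
      }
      nbatch <- nbatch + 1L
      Wa <- Wa + W; Tra <- Tra + Tr; S0a <- S0a + S0
    }
    # L2 shrinkage once per epoch, scaled by the update steps it covers
    shrink <- (1 - lr * hp$weight_decay)^length(batches)
    W <- W * shrink; Tr <- Tr * shrink; S0 <- S0 * shrink
  }
  Wavg <- Wa / max(1L, nbatch)
  Travg <- Tra / max(1L, nbatch)
  S0avg <- S0a / max(1L, nbatch)

  model <- structure(
    list(backend = "scratch",
         dict = prep$dict, nfeat = prep$nfeat,
         W = Wavg, Tr = Travg, S0 = S0avg,
         hp = hp,
         meta = list(n_train = length(train_idx), n_val = length(val_idx),
                     corpus_fingerprint = corpus_fingerprint(corpus),
                     seed = hp$seed)),
    class = "tagger_model")
  if (length(val_idx) > 0L) {
    acc <- mean(unlist(lapply(sents[val_idx], function(sent) {
      E <- emission_scores(model$W, sent$feats)
      viterbi_decode(E, model$Tr, model$S0) == sent$gold
    })))
    model$meta$validation_token_accuracy <- acc
  }
  model
}

corpus_fingerprint <- function(corpus) {
  texts <- vapply(corpus, `[[`, character(1), "text")
  sprintf("n=%d;chars=%d;sum=%.0f", length(corpus), sum(nchar(texts)),
          sum(vapply(texts, function(t) sum(utf8ToInt(t)), numeric(1))))
}

#' @export
print.tagger_model <- function(x, ...) {
  cat(sprintf("<tagger_model backend=%s> %d features, trained on %d sentences\n",
              x$backend, x$nfeat, x$meta$n_train))
  if (!is.null(x$meta$validation_token_accuracy)) {
    cat(sprintf("  validation token accuracy: %.4f\n",
                x$meta$validation_token_accuracy))
  }
  invisible(x)
}

#' Tag a direction with a trained model
#'
#' Tokenizes the text, predicts BIO tags by Viterbi decoding under the
#' trained weights, and decodes the tags to character spans. Invalid BIO
#' sequences are repaired (an orphan `I-x` is promoted to `B-x`); adjacent
#' same-label entities remain separate. Total on any text: unknown features
#' simply contribute no score. A decoded entity none of whose tokens carries
#' a word identity seen in training is discarded — with zero lexical
#' evidence an entity assertion would be a fabrication, and text written
#' entirely outside the training vocabulary (e.g. a bare ".") yields no
#' spans.
#'
#' @param model A `tagger_model`.
#' @param text Direction text (normalized).
#' @return An `extraction_result` with backend `"trained"`.
#' @export
tag_model <- function(model, text) {
  toks <- tokenize(text)
  if (nrow(toks) == 0L) return(extraction_result(backend = "trained"))
  feats <- token_features(tolower(toks$token))
  ids <- lapply(feats, function(fv) {
    out <- unlist(lapply(fv, function(f) model$dict[[f]]), use.names = FALSE)
    if (is.null(out)) integer() else out
  })
  E <- emission_scores(model$W, ids)
  path <- viterbi_decode(E, model$Tr, model$S0)
  rows <- cbind(toks, tag = bio_tags()[path], stringsAsFactors = FALSE)
  spans <- conll_to_spans(rows)
  known_word <- vapply(feats, function(fv) !is.null(model$dict[[fv[1L]]]),
                       logical(1))
  if (nrow(spans) > 0L && !all(known_word)) {
    keep <- vapply(seq_len(nrow(spans)), function(i) {
      any(known_word[toks$start >= spans$start[i] & toks$end <= spans$end[i]])
    }, logical(1))
    spans <- structure(spans[keep, , drop = FALSE],
                       repairs = attr(spans, "repairs"))
  }
  vals <- if (nrow(spans) == 0L) empty_extraction_values() else
    data.frame(label = spans$label,
               surface = substring(text, spans$start + 1L, spans$end),
               start = spans$start, end = spans$end,
               provenance = "extracted", stringsAsFactors = FALSE)
  res <- extraction_result(vals, backend = "trained")
  res$repairs <- attr(spans, "repairs")
  res
}

#' Save / load a trained tagger model
#'
#' The model artifact is a directory holding a JSON manifest (backend,
#' hyper-parameters, seed, corpus fingerprint) and the weight payload.
#'
#' @param model A `tagger_model`.
#' @param dir Artifact directory.
#' @return `dir` (save) or the restored `tagger_model` (load).
#' @export
save_tagger <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(backend = model$backend, hp = unclass(model$hp),
                   meta = model$meta, nfeat = model$nfeat)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  keys <- ls(model$dict)
  payload <- list(dict_keys = keys,
                  dict_ids = vapply(keys, function(k) model$dict[[k]], integer(1)),
                  W = model$W, Tr = model$Tr, S0 = model$S0)
  saveRDS(payload, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  payload <- readRDS(file.path(dir, "weights.rds"))
  dict <- new.env(parent = emptyenv())
  for (k in seq_along(payload$dict_keys)) {
    dict[[payload$dict_keys[k]]] <- payload$dict_ids[k]
  }
  hp <- do.call(hyperparameters, as.list(manifest$hp))
  structure(list(backend = manifest$backend, dict = dict,
                 nfeat = manifest$nfeat, W = payload$W, Tr = payload$Tr,
                 S0 = payload$S0, hp = hp, meta = manifest$meta),
            class = "tagger_model")
}
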