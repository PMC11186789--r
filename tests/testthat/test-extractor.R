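test_that("dictionary tagger extracts the worked example components", {
  res <- tag_dictionary("take one tablet by mouth once daily for pain", fx_index())
  expect_identical(nrow(res$values), 5L)
  expect_identical(res$values$label,
                   c("verb", "dose", "route", "frequency", "auxi-indic"))
  expect_identical(res$values$surface,
                   c("take", "one tablet", "by mouth", "once daily", "for pain"))
  # out-of-domain text yields nothing
  expect_identical(nrow(tag_dictionary("hello world", fx_index())$values), 0L)
})

test_that("dictionary matching is longest-match leftmost-first", {
  libs <- list(
    verb = component_library("verb", "take"),
    dose = component_library("dose", c("tablet", "one tablet")))
  res <- tag_dictionary("take one tablet", libs)
  expect_identical(res$values$surface, c("take", "one tablet"))
  expect_identical(res$values$label, c("verb", "dose"))
})

test_that("a surface under two labels is an ambiguity error, never a guess", {
  libs <- list(
    frequency = component_library("frequency", "daily"),
    `auxi-period` = component_library("auxi-period", "daily"))
  expect_error(tag_dictionary("take daily", libs), "ambiguous.*daily")
})

test_that("dictionary oracle recovers every gold span on generated corpora", {
  corpus <- generate_corpus(fx_patterns(), fx_libs(), 400, seed = 17)
  ev <- evaluate_tagger(fx_index(), corpus)
  expect_identical(ev$micro$f1, 1)
  expect_identical(ev$micro$precision, 1)
  expect_identical(ev$micro$recall, 1)
  # per-label F1 all 1 where entities exist
  expect_true(all(ev$per_label$f1[ev$per_label$gold > 0] == 1))
  # confusion rows sum to gold counts
  expect_identical(unname(rowSums(ev$confusion)),
                   as.numeric(ev$per_label$gold))
})

test_that("extracted surfaces are verbatim substrings of the input", {
  corpus <- generate_corpus(fx_patterns(), fx_libs(), 60, seed = 19)
  model <- train_tagger(corpus, hyperparameters(epochs = 1L, seed = 3))
  for (d in corpus[1:20]) {
    for (res in list(tag_dictionary(d$text, fx_index()), tag_model(model, d$text))) {
      v <- res$values
      if (nrow(v) == 0L) next
      expect_identical(v$surface, substring(d$text, v$start + 1L, v$end))
    }
  }
})

test_that("training is seeded and deterministic", {
  corpus <- generate_corpus(fx_patterns(), fx_libs(), 150, seed = 23)
  test <- generate_corpus(fx_patterns(), fx_libs(), 100, seed = 24)
  hp <- hyperparameters(seed = 9)
  m1 <- train_tagger(corpus, hp)
  m2 <- train_tagger(corpus, hp)
  e1 <- evaluate_tagger(m1, test)
  e2 <- evaluate_tagger(m2, test)
  expect_identical(e1$micro, e2$micro)
  expect_identical(e1$per_label, e2$per_label)
  expect_identical(m1$W, m2$W)
})

test_that("degenerate training inputs are handled per contract", {
  expect_error(train_tagger(list()), "empty")
  expect_error(train_tagger(list(worked_example()), backend = "transformer"),
               "not implemented")
  m <- train_tagger(list(worked_example()), hyperparameters(seed = 1))
  expect_s3_class(m, "tagger_model")
  # model trained on one sentence reproduces it
  res <- tag_model(m, worked_example()$text)
  expect_identical(res$values$label, worked_example()$spans$label)
})

test_that("model tagging is total and decodes BIO to spans", {
  corpus <- generate_corpus(fx_patterns(), fx_libs(), 400, seed = 29)
  model <- train_tagger(corpus, hyperparameters(seed = 4))
  expect_identical(nrow(tag_model(model, ".")$values), 0L)
  # two dose mentions stay two values (multi-line input; GR2 material)
  res <- tag_dictionary(
    "take one tablet in the morning and two tablets at bedtime", fx_index())
  expect_identical(sum(res$values$label == "dose"), 2L)
  # trained model agrees with the oracle on the worked example
  got <- tag_model(model, worked_example()$text)
  expect_identical(got$values$label, worked_example()$spans$label)
  expect_identical(got$values$surface, worked_example()$spans$surface)
})

test_that("evaluation flags a predictor that never predicts", {
  empty_libs <- stats::setNames(
    lapply(component_labels(), component_library), component_labels())
  corpus <- generate_corpus(fx_patterns(), fx_libs(), 20, seed = 37)
  ev <- evaluate_tagger(empty_libs, corpus)
  expect_true(ev$degenerate)
  expect_identical(ev$micro$recall, 0)
  expect_identical(ev$micro$precision, 0)
  expect_error(evaluate_tagger(empty_libs, list()), "empty")
})

test_that("hyper-parameter defaults match the training configuration", {
  hp <- hyperparameters()
  expect_identical(hp$batch_size, 16L)
  expect_identical(hp$learning_rate, 1e-4)
  expect_identical(hp$epochs, 3L)
  expect_identical(hp$weight_decay, 1e-5)
  expect_error(hyperparameters(batch_size = 0), "batch_size")
})

test_that("model artifacts round trip through save/load", {
  corpus <- generate_corpus(fx_patterns(), fx_libs(), 80, seed = 41)
  model <- train_tagger(corpus, hyperparameters(epochs = 1L, seed = 6))
  dir <- withr::local_tempdir()
  save_tagger(model, dir)
  back <- load_tagger(dir)
  txt <- corpus[[1]]$text
  expect_identical(tag_model(back, txt)$values, tag_model(model, txt)$values)
  expect_identical(back$hp$batch_size, model$hp$batch_size)
})
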