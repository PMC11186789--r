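test_that("component libraries are built from labeled spans", {
  libs <- build_libraries(list(worked_example()))
  expect_named(libs, component_labels())
  expect_identical(libs$verb$surfaces, "take")
  expect_identical(libs$dose$surfaces, "one tablet")
  expect_identical(libs$route$surfaces, "by mouth")
  expect_identical(libs$frequency$surfaces, "once daily")
  expect_identical(libs[["auxi-indic"]]$surfaces, "for pain")
  for (lab in c("auxi-time", "auxi-period", "auxi-action", "auxi-maxdose")) {
    expect_length(libs[[lab]]$surfaces, 0L)
  }

  # empty corpus -> nine empty libraries; duplicates collapse (set semantics)
  empty <- build_libraries(list())
  expect_length(empty, 9L)
  expect_true(all(vapply(empty, function(l) length(l$surfaces) == 0L, logical(1))))
  two <- build_libraries(list(worked_example(), worked_example()))
  expect_identical(two$verb$surfaces, "take")
})

test_that("expert terms merge as identity-canonical additions", {
  lib <- component_library("verb", "take")
  merged <- merge_expert_terms(lib, "chew")
  expect_setequal(merged$surfaces, c("take", "chew"))
  expect_identical(merge_expert_terms(merged, "take")$surfaces, merged$surfaces)
  expect_error(merge_expert_terms(lib, ""), "non-empty")
  conflicted <- component_library("dose", c("1 tab"),
                                  canonical = c("1 tab" = "one tablet"))
  expect_error(merge_expert_terms(conflicted, "1 tab"), "canonical")
})

test_that("pattern extraction reads label sequences in span order", {
  pl <- extract_patterns(list(worked_example()))
  expect_length(pl$patterns, 1L)
  expect_identical(pl$patterns[[1]],
                   c("verb", "dose", "route", "frequency", "auxi-indic"))
  # duplicates collapse with counts
  pl2 <- extract_patterns(list(worked_example(), worked_example()))
  expect_length(pl2$patterns, 1L)
  expect_identical(pl2$freq, 2L)
  # hand-labeled three-component direction
  d <- labeled_direction("t-1", "apply topically twice daily",
                         data.frame(label = c("verb", "route", "frequency"),
                                    start = c(0L, 6L, 16L),
                                    end = c(5L, 15L, 27L)))
  pl3 <- extract_patterns(list(d))
  expect_identical(pl3$patterns[[1]], c("verb", "route", "frequency"))
})

test_that("forced generation reproduces the worked example exactly", {
  libs <- build_libraries(list(worked_example()))
  pats <- extract_patterns(list(worked_example()))
  out <- generate_corpus(pats, libs, 1, seed = 1)
  expect_identical(out[[1]]$text, "take one tablet by mouth once daily for pain")
  expect_identical(out[[1]]$spans$label, worked_example()$spans$label)
  expect_identical(out[[1]]$spans$start, worked_example()$spans$start)
  expect_identical(out[[1]]$spans$end, worked_example()$spans$end)
  expect_length(generate_corpus(pats, libs, 10, seed = 1), 10L)
})

test_that("generated corpora satisfy span consistency and closure", {
  libs <- fx_libs()
  pats <- fx_patterns()
  corpus <- generate_corpus(pats, libs, 300, seed = 31)
  pattern_keys <- vapply(pats$patterns, paste, character(1), collapse = "|")
  for (d in corpus) {
    validate_direction(d)
    # concatenating surfaces with single spaces reproduces the text
    expect_identical(paste(d$spans$surface, collapse = " "), d$text)
    # every surface belongs to its label's library
    for (i in seq_len(nrow(d$spans))) {
      expect_true(d$spans$surface[i] %in% libs[[d$spans$label[i]]]$surfaces)
    }
    # label sequence is a library pattern
    expect_true(paste(d$spans$label, collapse = "|") %in% pattern_keys)
  }
  # libraries rebuilt from generated data are subsets of the generators
  rebuilt <- build_libraries(corpus)
  for (lab in component_labels()) {
    expect_true(all(rebuilt[[lab]]$surfaces %in% libs[[lab]]$surfaces))
  }
})

test_that("generation is seed-reproducible and seed-sensitive", {
  a <- generate_corpus(fx_patterns(), fx_libs(), 50, seed = 7)
  b <- generate_corpus(fx_patterns(), fx_libs(), 50, seed = 7)
  expect_identical(a, b)
  c <- generate_corpus(fx_patterns(), fx_libs(), 50, seed = 8)
  expect_false(identical(vapply(a, `[[`, character(1), "text"),
                         vapply(c, `[[`, character(1), "text")))
})

test_that("generation refuses patterns over empty libraries", {
  libs <- build_libraries(list(worked_example()))
  pats <- pattern_library(list(c("verb", "auxi-maxdose")))
  expect_error(generate_corpus(pats, libs, 5, seed = 1), "auxi-maxdose")
})

test_that("degrade applies abbreviations and typos reproducibly", {
  d <- worked_example()
  # identity noise model passes text through
  clean <- degrade(d, noise_model(), seed = 3)
  expect_identical(clean$text, d$text)
  # forced single substitution
  nm <- noise_model(abbrev = list("by mouth" = "po"))
  expect_identical(degrade(d, nm, seed = 3)$text,
                   "take one tablet po once daily for pain")
  # typo noise is seed-reproducible
  nm2 <- noise_model(typo_rate = 1, casing = "upper")
  expect_identical(degrade(d, nm2, seed = 5), degrade(d, nm2, seed = 5))
})

test_that("stratified split partitions the corpus with requested fractions", {
  corpus <- generate_corpus(fx_patterns(), fx_libs(), 100, seed = 13)
  parts <- stratified_split(corpus, c(0.5, 0.5), k = 4, seed = 2)
  sizes <- lengths(parts)
  expect_identical(sum(sizes), 100L)
  expect_true(all(abs(sizes - 50L) <= 4L))  # +/-1 rounding per cluster
  # disjoint and exhaustive
  ids <- unlist(lapply(parts, function(p) vapply(p, `[[`, character(1), "record_id")))
  expect_identical(sort(ids), sort(vapply(corpus, `[[`, character(1), "record_id")))
  # k = 1 degenerates to a plain seeded split
  plain <- stratified_split(corpus, c(0.3, 0.7), k = 1, seed = 2)
  expect_identical(lengths(plain), c(30L, 70L))
  # reproducibility
  expect_identical(stratified_split(corpus, c(0.5, 0.5), k = 4, seed = 2), parts)
  expect_error(stratified_split(corpus[1], c(0.5, 0.5), k = 1, seed = 1),
               "cannot be split")
})
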