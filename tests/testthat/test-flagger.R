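test_that("canonicalization maps surfaces through the library canonical map", {
  libs <- list(dose = component_library(
    "dose", c("1 tab", "one tablet"), canonical = c("1 tab" = "one tablet")))
  ext <- make_extraction("dose", "1 tab", with_spans = TRUE)
  expect_identical(canonicalize(ext, libs), list(dose = "one tablet"))
  # already-canonical components are unchanged
  ext2 <- make_extraction("dose", "one tablet", with_spans = TRUE)
  expect_identical(canonicalize(ext2, libs), list(dose = "one tablet"))
  # multi-value labels keep both values for downstream flagging
  ext3 <- make_extraction(c("dose", "dose"), c("1 tab", "one tablet"),
                          with_spans = TRUE)
  expect_length(canonicalize(ext3, libs)$dose, 2L)
  # digit/word unification without any canonical map
  ext4 <- make_extraction("dose", "1 tablet", with_spans = TRUE)
  expect_identical(canonicalize(ext4, NULL), list(dose = "one tablet"))
})

test_that("a frequency transcription error is flagged", {
  rep <- flag_compare("take 20 mg by mouth once weekly",
                      "take 20 mg by mouth once daily",
                      fx_rules(), fx_libs())
  expect_false(rep$equivalent)
  expect_identical(rep$discrepancies$label, "frequency")
  expect_identical(rep$discrepancies$kind, "mismatch")
})

test_that("flagging is reflexive and symmetric in final mode", {
  corpus <- generate_corpus(fx_patterns(), fx_libs(), 25, seed = 47)
  for (d in corpus[1:10]) {
    expect_true(flag_compare(d$text, d$text, fx_rules(), fx_libs())$equivalent)
  }
  a <- "take one tablet by mouth once daily"
  b <- "take two tablets by mouth once daily for pain"
  ab <- flag_compare(a, b, fx_rules(), fx_libs())
  ba <- flag_compare(b, a, fx_rules(), fx_libs())
  expect_identical(ab$equivalent, ba$equivalent)
  expect_setequal(ab$discrepancies$label, ba$discrepancies$label)
})

test_that("normalization-level variants compare as equivalent", {
  rep <- flag_compare("TAKE 1 TAB PO QD",
                      "take one tablet by mouth once daily",
                      fx_rules(), fx_libs())
  expect_true(rep$equivalent)
  rep2 <- flag_compare("take one tablet po once daily",
                       "take one tablet by mouth once daily",
                       fx_rules(), fx_libs())
  expect_true(rep2$equivalent)
})

test_that("partial mode warns on typed mismatches without penalizing gaps", {
  rep <- flag_compare("take one tablet by mouth daily", "take two tablets",
                      fx_rules(), fx_libs(), mode = "partial")
  expect_false(rep$equivalent)
  expect_identical(rep$discrepancies$label, "dose")
  expect_setequal(rep$pending, c("route", "frequency"))
  # final mode counts the gaps as missing-in-b
  repf <- flag_compare("take one tablet by mouth daily", "take two tablets",
                       fx_rules(), fx_libs(), mode = "final")
  expect_true(all(c("route", "frequency") %in%
                  repf$discrepancies$label[repf$discrepancies$kind == "missing-in-b"]))
})

test_that("discrepancies map onto the six error categories", {
  mk <- function(a, b) flag_compare(a, b, fx_rules(), fx_libs())
  expect_identical(
    categorize_errors(mk("take one tablet by mouth once daily",
                         "take two tablets by mouth once daily")),
    "dose-quantity")
  expect_identical(
    categorize_errors(mk("take one tablet by mouth once daily",
                         "take one capsule by mouth once daily")),
    "dose-form")
  expect_identical(
    categorize_errors(mk("chew one tablet by mouth once daily",
                         "take one tablet by mouth once daily")),
    "verb")
  expect_identical(
    categorize_errors(mk("take one tablet by mouth once daily",
                         "take one tablet under the tongue once daily")),
    "route")
  expect_identical(
    categorize_errors(mk("take one tablet by mouth once daily for pain",
                         "take one tablet by mouth once daily for anxiety")),
    "auxiliary")
})

test_that("single perturbations are localized to the perturbed label", {
  pairs <- perturbation_pairs(fx_patterns(), fx_libs(), n_per_category = 10L,
                              seed = 53)
  perturbed <- pairs[pairs$category != "none", ]
  label_for <- c(verb = "verb", `dose-quantity` = "dose",
                 `dose-form` = "dose", route = "route",
                 frequency = "frequency")
  for (i in seq_len(nrow(perturbed))) {
    rep <- flag_compare(perturbed$a[i], perturbed$b[i], fx_rules(), fx_libs())
    expect_false(rep$equivalent)
    expect_identical(nrow(rep$discrepancies), 1L)
    if (perturbed$category[i] == "auxiliary") {
      expect_true(rep$discrepancies$label %in% auxiliary_labels())
    } else {
      expect_identical(rep$discrepancies$label,
                       unname(label_for[[perturbed$category[i]]]))
    }
  }
})

test_that("the detection harness reports per-category rates", {
  pairs <- perturbation_pairs(fx_patterns(), fx_libs(), n_per_category = 10L,
                              seed = 59)
  ev <- evaluate_flagger(pairs, fx_rules(), fx_libs())
  expect_identical(sort(ev$per_category$category),
                   sort(c("verb", "dose-quantity", "dose-form", "route",
                          "frequency", "auxiliary")))
  expect_true(all(ev$per_category$n == 10L))
  # library-swap perturbations are fully detectable with the oracle backend
  expect_identical(ev$overall_rate, 1)
  expect_identical(ev$per_category$rate, rep(1, 6))
  # unperturbed pairs never flag
  expect_identical(ev$false_flag_rate, 0)
  expect_error(evaluate_flagger(pairs[0, ], fx_rules(), fx_libs()), "no evaluation")
})
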