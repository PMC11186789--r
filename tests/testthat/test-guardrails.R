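test_that("catalog fill-in adds required defaults without overriding", {
  entry <- catalog_lookup(fx_catalog(), "D001")  # defaults: take / by mouth
  ext <- make_extraction(c("dose", "frequency"), c("one tablet", "once daily"),
                         with_spans = TRUE)
  filled <- fill_missing(ext, entry)
  expect_identical(extraction_values(filled, "route"), "by mouth")
  route_row <- filled$values[filled$values$label == "route", ]
  expect_identical(route_row$provenance, "catalog-filled")
  expect_true(is.na(route_row$start))

  # an extracted route is never overwritten
  ext2 <- make_extraction(c("dose", "route"), c("one tablet", "under the tongue"),
                          with_spans = TRUE)
  filled2 <- fill_missing(ext2, entry)
  expect_identical(extraction_values(filled2, "route"), "under the tongue")

  # required label with no default stays missing (guardrails decide)
  expect_identical(extraction_values(fill_missing(ext2, entry), "frequency"),
                   character())
})

test_that("each guardrail fires on its own construction", {
  catalog <- fx_catalog()
  tablet <- catalog_lookup(catalog, "D001")

  # GR1: extracted verb conflicts with catalog verb for a tablet drug
  raw <- make_extraction(c("verb", "dose", "frequency"),
                         c("apply", "one tablet", "once daily"),
                         with_spans = TRUE)
  rep1 <- apply_guardrails(fill_missing(raw, tablet), raw, tablet)
  expect_identical(rep1$triggered, "GR1")

  # GR2: two dose values (multi-line direction)
  raw2 <- make_extraction(c("verb", "dose", "dose", "frequency"),
                          c("take", "one tablet", "two tablets", "once daily"),
                          with_spans = TRUE)
  rep2 <- apply_guardrails(fill_missing(raw2, tablet), raw2, tablet)
  expect_identical(rep2$triggered, "GR2")

  # GR3: dose without verb, verb required (use entry without verb default)
  entry3 <- tablet
  entry3$defaults$verb <- NULL
  raw3 <- make_extraction(c("dose", "frequency"), c("one tablet", "once daily"),
                          with_spans = TRUE)
  rep3 <- apply_guardrails(fill_missing(raw3, entry3), raw3, entry3)
  expect_identical(rep3$triggered, "GR3")

  # GR4: no frequency extracted or defaulted
  raw4 <- make_extraction(c("verb", "dose"), c("take", "one tablet"),
                          with_spans = TRUE)
  rep4 <- apply_guardrails(fill_missing(raw4, tablet), raw4, tablet)
  expect_identical(rep4$triggered, "GR4")

  # GR5: no dose for a capsule dose form
  capsule <- catalog_lookup(catalog, "D003")
  raw5 <- make_extraction(c("verb", "frequency"), c("take", "once daily"),
                          with_spans = TRUE)
  rep5 <- apply_guardrails(fill_missing(raw5, capsule), raw5, capsule)
  expect_identical(rep5$triggered, "GR5")
})

test_that("guardrail precedence reports the lowest-numbered of many", {
  tablet <- catalog_lookup(fx_catalog(), "D001")
  # verb conflict (GR1) + double dose (GR2) + no frequency (GR4)
  raw <- make_extraction(c("verb", "dose", "dose"),
                         c("apply", "one tablet", "two tablets"),
                         with_spans = TRUE)
  rep <- apply_guardrails(fill_missing(raw, tablet), raw, tablet)
  expect_identical(rep$triggered, "GR1")
  expect_identical(rep$all_triggered$id, c("GR1", "GR2", "GR4"))
  # report invariant: primary is first of all_triggered under GR order
  expect_identical(rep$triggered, rep$all_triggered$id[[1]])
})

test_that("catalog comparison is canonical: formatting is not a conflict", {
  tablet <- catalog_lookup(fx_catalog(), "D009")  # frequency default once daily
  raw <- make_extraction(c("verb", "dose", "frequency"),
                         c("take", "2 capsules", "daily"), with_spans = TRUE)
  rep <- apply_guardrails(fill_missing(raw, tablet), raw, tablet, fx_libs())
  # "daily" canonicalizes to "once daily": no GR1
  expect_true(is.na(rep$triggered))
})

test_that("assembly joins components in canonical order", {
  scrambled <- make_extraction(
    c("frequency", "verb", "route", "dose", "auxi-indic"),
    c("once daily", "take", "by mouth", "one tablet", "for pain"))
  expect_identical(assemble(scrambled),
                   "take one tablet by mouth once daily for pain")
  expect_identical(
    assemble(make_extraction(c("frequency", "route", "verb"),
                             c("twice daily", "topically", "apply"))),
    "apply topically twice daily")
  expect_error(assemble(extraction_result()), "nothing to assemble")
  expect_error(assemble(make_extraction(c("dose", "dose"),
                                        c("one tablet", "two tablets"))),
               "multiple values")
})

test_that("end-to-end suggestion standardizes an abbreviated sig", {
  out <- suggest("TAKE 1 TAB PO QD for pain", fx_rules(), fx_libs(),
                 fx_catalog(), drug_id = "D001")
  expect_identical(out$status, "suggested")
  expect_identical(out$direction,
                   "take one tablet by mouth once daily for pain")
  expect_true(all(out$components$provenance == "extracted"))
})

test_that("incomplete and multi-line directions halt with the right guardrail", {
  halted <- suggest("500 mg before procedure", fx_rules(), fx_libs(),
                    fx_catalog(), drug_id = "D001")
  expect_identical(halted$status, "halted")
  expect_identical(halted$guardrail$triggered, "GR4")

  multi <- suggest("take one tablet in the morning and two tablets at bedtime",
                   fx_rules(), fx_libs(), fx_catalog(), drug_id = "D001")
  expect_identical(multi$status, "halted")
  expect_identical(multi$guardrail$triggered, "GR2")
})

test_that("a drug missing from the catalog degrades gracefully", {
  out <- suggest("take one tablet by mouth once daily", fx_rules(), fx_libs(),
                 fx_catalog(), drug_id = "UNKNOWN")
  expect_identical(out$status, "suggested")
  expect_true("catalog-missing" %in% out$notes)
})

test_that("suggestion outcomes are total with a single primary guardrail", {
  noise <- read_noise_model(medic_fixture("noise"))
  corpus <- generate_corpus(fx_patterns(), fx_libs(), 60, seed = 43)
  drug_ids <- names(fx_catalog())
  for (i in seq_along(corpus)) {
    raw <- degrade(corpus[[i]], noise, seed = 500 + i)
    raw$drug_id <- drug_ids[((i - 1L) %% length(drug_ids)) + 1L]
    out <- suggest(raw, fx_rules(), fx_libs(), fx_catalog())
    expect_true(out$status %in% c("suggested", "halted"))
    if (out$status == "halted") {
      expect_true(out$guardrail$triggered %in% guardrail_ids())
      expect_identical(out$guardrail$triggered, out$guardrail$all_triggered$id[[1]])
    } else {
      # no hallucination: every token traces to an extracted surface or a
      # catalog default
      allowed <- unlist(strsplit(out$components$surface, " ", fixed = TRUE))
      toks <- strsplit(out$direction, " ", fixed = TRUE)[[1]]
      expect_true(all(toks %in% allowed))
      # assembly/extraction round trip: re-extraction recovers the same
      # component values
      re <- tag_dictionary(out$direction, fx_index())
      expect_identical(
        stats::setNames(re$values$surface, re$values$label),
        stats::setNames(out$components$surface, out$components$label))
    }
  }
})
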