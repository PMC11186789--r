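# shared fixture accessors (loaded once per test run) and hand-built records

fixture_env <- new.env(parent = emptyenv())

fx_libs <- function() {
  if (is.null(fixture_env$libs)) {
    fixture_env$libs <- read_libraries(medic_fixture("libraries"))
  }
  fixture_env$libs
}

fx_patterns <- function() {
  if (is.null(fixture_env$pats)) {
    fixture_env$pats <- read_patterns(medic_fixture("patterns"))
  }
  fixture_env$pats
}

fx_rules <- function() {
  if (is.null(fixture_env$rules)) {
    fixture_env$rules <- load_rules(medic_fixture("rules"),
                                    vocabulary = library_vocabulary(fx_libs()))
  }
  fixture_env$rules
}

fx_catalog <- function() {
  if (is.null(fixture_env$catalog)) {
    fixture_env$catalog <- load_catalog(medic_fixture("catalog"))
  }
  fixture_env$catalog
}

fx_index <- function() {
  if (is.null(fixture_env$index)) {
    fixture_env$index <- dictionary_index(fx_libs())
  }
  fixture_env$index
}

# the canonical worked example: one direction, all five top-level components
worked_example <- function() {
  labeled_direction(
    "ex-1", "take one tablet by mouth once daily for pain",
    data.frame(
      label = c("verb", "dose", "route", "frequency", "auxi-indic"),
      start = c(0L, 5L, 16L, 25L, 36L),
      end = c(4L, 15L, 24L, 35L, 44L)),
    drug_id = "D001")
}

# extraction_result built from label/surface pairs (extracted provenance,
# spans synthesized as dummies only when with_spans = TRUE)
make_extraction <- function(labels, surfaces, with_spans = FALSE) {
  n <- length(labels)
  extraction_result(data.frame(
    label = labels, surface = surfaces,
    start = if (with_spans) seq_len(n) * 10L else NA_integer_,
    end = if (with_spans) seq_len(n) * 10L + nchar(surfaces) else NA_integer_,
    provenance = if (with_spans) "extracted" else "extracted",
    stringsAsFactors = FALSE))
}
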