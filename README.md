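# medic

Medication directions ("sigs") are the instruction portion of a
prescription — *take one tablet by mouth once daily*. Transcribing the raw
prescriber text into a standardized direction at the pharmacy data-entry
stage is a known source of medication errors: an abbreviation misread, a
dropped frequency, *once weekly* typed as *once daily*. `medic` is an R
implementation of a direction-standardization copilot for pharmacy
informatics work: it turns noisy prescriber sigs into clean, standardized
directions under explicit safety guardrails, and flags semantic
discrepancies between two directions.

The pipeline has three stages plus a comparison facet:

1. **Pharmalexical normalization** — an ordered set of atomic,
   pattern-based rewrite rules (abbreviation expansion, numeral/word
   unification, case and whitespace hygiene) applied to a fixed point, with
   conservative edit-distance-1 spell correction against the component
   vocabulary. Every change is recorded in a replayable trace.
2. **Component extraction** — a named-entity tagger over nine component
   labels (`verb`, `dose`, `route`, `frequency`, and five auxiliary
   sub-entities: indication, timing, period, action, maximum dose), in BIO
   encoding. Two backends: a deterministic dictionary tagger
   (longest-match, leftmost-first over the component libraries) and a
   trainable sequence tagger (averaged structured perceptron with Viterbi
   decoding; defaults: batch 16, learning rate 1e-4, 3 epochs, weight
   decay 1e-5).
3. **Semantic assembly and safety enforcement** — missing required
   components are filled from a medication catalog, components are joined
   in canonical order, and five ordered guardrails halt the suggestion on:
   catalog conflict (GR1), multiple values per component (GR2), dose
   without required verb (GR3), missing frequency (GR4), missing dose for
   tablet/capsule forms (GR5).
4. **Flagging** — two directions are normalized, extracted and
   canonicalized, then compared component-wise; the output is a Boolean
   equivalence plus per-component discrepancies, mappable onto six error
   categories (verb, dose quantity, dose form, route, frequency,
   auxiliary).

Because production training data for such systems is proprietary, the
package includes a **corpus factory**: it builds per-label component
libraries and a pattern library (the set of observed label sequences) from
labeled data, generates synthetic labeled corpora by pattern sampling
(draw a pattern, draw one surface per component, join, compute exact
spans), and degrades clean directions into prescriber-style raw text
(abbreviations, typos, casing) for end-to-end tests. Entity-level
precision/recall/F1 evaluation and sentence-level BLEU/METEOR scoring are
included.

## Worked example

```r
library(medic)

libs    <- read_libraries(medic_fixture("libraries"))
rules   <- load_rules(medic_fixture("rules"),
                      vocabulary = library_vocabulary(libs))
catalog <- load_catalog(medic_fixture("catalog"))

suggest("TAKE 1 TAB PO QD for pain", rules, libs, catalog, drug_id = "D001")
#> <suggestion> take one tablet by mouth once daily for pain

suggest("500 mg before procedure", rules, libs, catalog, drug_id = "D001")
#> <halted GR4> no value for the frequency component

flag_compare("take 20 mg by mouth once weekly",
             "take 20 mg by mouth once daily", rules, libs)
#> <flag_report final> NOT equivalent
#>   frequency    mismatch   a='once weekly' b='once daily'
```

The first call normalizes the abbreviated sig (`tab` → `tablet`, `po` →
`by mouth`, `qd` → `once daily`, `1 tablet` → `one tablet`), extracts all
five components, finds no catalog conflict for drug `D001`, and assembles
the standardized direction in canonical order. The second lacks any
frequency and no catalog default supplies one, so guardrail GR4 halts
rather than guess. The third is the classic transcription near-miss: the
only differing component is the frequency, and it is flagged.

Training the sequence tagger on synthetic data:

```r
pats  <- read_patterns(medic_fixture("patterns"))
train <- generate_corpus(pats, libs, 10000, seed = 1)
test  <- generate_corpus(pats, libs, 10000, seed = 2)
model <- train_tagger(train, hyperparameters())
evaluate_tagger(model, test)
#> <extraction_eval> 45395 gold entities, 45395 predicted
#>   micro P=0.9999 R=0.9999 F1=0.9999
```

A command-line front end over the same functions is installed at
`system.file("cli", "medic.R", package = "medic")` with subcommands
`normalize`, `augment`, `train`, `extract`, `suggest`, `flag`, `eval` and
`run`.

## Scope notes

Multi-line directions (different doses at different times) are detected
and halted by GR2, never assembled. Live drug-database ingestion is out of
scope: the catalog loader reads a TSV snapshot, and the bundled catalog,
rule set and component libraries are fixtures — realistic but synthetic
stand-ins for proprietary pharmacy content. See the methods vignette
(`vignettes/medic-methods.Rmd`) for the model, its assumptions, and design
decisions.
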