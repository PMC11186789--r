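---
title: "Methods: direction standardization, extraction and guardrails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direction standardization, extraction and guardrails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medic)
```

## The problem and the model

A prescription direction (sig) carries a small number of semantically
distinct components. `medic` models exactly nine: four core components —
**verb**, **dose**, **route**, **frequency** — and five sub-entities of the
auxiliary information — **indication** (`auxi-indic`), **timing**
(`auxi-time`), **period** (`auxi-period`), **action** (`auxi-action`) and
**maximum dose** (`auxi-maxdose`). The order of this list is not cosmetic:
it is the canonical assembly order, and a standardized direction is by
definition the present components joined in this order.

The central design commitment is *extraction fidelity*: the extractor's
job is to capture what the prescriber wrote, verbatim, even when what they
wrote is wrong. All correction authority lives downstream, in the
deterministic assembly-and-guardrails layer where it can be audited. This
is the opposite of letting a generative model "fix" a prescription, and it
is what makes the no-hallucination property checkable: every token of a
suggested direction must trace to an extracted span or a named catalog
default.

## Pharmalexical normalization

Raw sigs mix everyday English, pharmacy jargon, abbreviations and typos.
The normalizer applies an ordered list of atomic rules — each a literal or
regex rewrite with word-boundary semantics — after lower-casing and
whitespace collapsing. A full pass over the rule list repeats until a
fixed point, with a hard cap of 5 passes; a rule set that still changes
text at the cap is reported as non-confluent rather than looped. In
practice well-formed rule sets converge in one pass; the cap exists to
make pathological rule interactions a loud error.

Spell correction is deliberately conservative: a token is corrected only
when it is non-numeric, outside the vocabulary (the union of all component
library tokens), and has exactly one vocabulary token within edit distance
1 (`utils::adist`). Ties and distance-2 candidates are left alone — in a
prescription, a no-op is always safer than a wrong correction. Stop-word
removal is not performed: dropping words from a prescription risks
dropping clinical content, and any genuinely ignorable filler can be
handled by an explicit rule where a pharmacist has approved it.

Two dialect invariants tie the normalizer to the rest of the system and
are enforced by tests:

* every component-library surface is a fixed point of the rule set (up to
  canonical equivalence), so generated gold text and normalized raw text
  live in the same dialect;
* the normalizer never invents tokens: each output token is an input
  token, an explicit rule replacement, or a vocabulary spell target, and
  the recorded trace replays to the output exactly.

The shipped rule set (49 rules) is a curated fixture covering the common
sig abbreviations (`po`, `qd`, `bid`, `tid`, `qid`, `prn`, `hs`, dose-unit
contractions, count-word unification, duration shorthand like `x 7 days`).
Production deployments of such rule engines run to hundreds of
pharmacist-verified rules; the engine, file format and convergence policy
here are the reusable part, and the rule file is declared open for
extension.

## Component and pattern libraries, synthetic corpora

From any labeled corpus the package builds one **component library** per
label (the set of unique surfaces observed, plus a canonical map used for
semantic comparison, e.g. `1 tab → one tablet`, `daily → once daily`) and
a **pattern library** (the set of unique label sequences, one per record,
with frequencies). Expert-curated terms can be merged in afterwards; a
term that collides with an existing canonical mapping is a hard error.

The generator inverts this: draw a pattern, draw one surface per
component from its library, join with single spaces, compute spans
exactly. Draws are uniform by default — the least-assumption reading of
random sampling — with optional frequency weighting. No clinical
consistency filter is applied to generated directions, deliberately: the
extractor must learn to capture text as written, including combinations no
pharmacist would approve, because real prescriber input contains such
text too. Degradation into raw prescriber style (abbreviation
substitution, seeded character typos, casing) is a separate, seeded step
so that raw→ideal pairs exist for end-to-end tests.

The bundled fixture libraries hold roughly 700 surfaces across the nine
labels (dose being the largest, built combinatorially from counts and
units) and 24 patterns. The sizing is deliberate: a 1,000-sample generated
corpus leaves genuine coverage gaps in the larger libraries, a
5,000-sample corpus nearly closes them, and a 10,000-sample corpus closes
them — which is what gives the extraction quality its characteristic
growth with augmentation size rather than immediate saturation.

What the synthetic corpora do *not* emulate: real prescriber syntax
variation beyond the pattern inventory (free-order components,
parenthetical asides), multi-line dose schedules, misspellings inside
gold labels, and cross-component grammatical agreement. Passing tests on
generated data therefore demonstrate the machinery (span bookkeeping,
training, scoring, guardrail logic) under a controlled distribution; they
are not a claim about performance on any particular pharmacy's live feed.

## The two extraction backends

The **dictionary tagger** matches library surfaces at word boundaries,
case-insensitively, greedy longest-match leftmost-first with no
backtracking. It is fully deterministic and auditable, and on closed-world
generated corpora it recovers every gold span exactly (micro-F1 = 1.0), so
it serves as the oracle backend against which the trained backend and the
downstream stages are checked. A surface registered under two labels makes
a match ambiguous; this errors loudly rather than guessing.

The **trainable tagger** is an averaged structured perceptron over BIO
tags (19 tags: `O` plus B/I for nine labels): sparse indicator features
per token (word identity, previous and next word, 3-character suffix,
digit/alpha shape), learned first-order transition weights, exact Viterbi
decoding. Training uses the package's default hyper-parameters — batch
size 16, learning rate 1e-4, 3 epochs, weight decay 1e-5 — with seeded
shuffling, a seeded 90/10 train/validation split (validation is logged
only; the epoch count is fixed, no early stopping), and parameter
averaging over all mini-batch steps. For a perceptron the learning rate is
an argmax-invariant scale factor; it is applied anyway so the stored
weights correspond to the declared configuration, and weight decay is
applied as a per-epoch L2 shrinkage scaled by the number of update steps.
A transformer fine-tune occupies the same interface slot in principle
(`backend = "transformer"`), but is not implemented in this package; the
scratch backend is the supported trainable path.

Two decoding policies matter for safety. Orphan `I-x` tags are repaired by
promotion to `B-x` (favoring recall; repairs are counted). And a decoded
entity none of whose tokens has a word identity seen in training is
discarded: with zero lexical evidence, asserting an entity would be
fabrication — a bare `"."` yields no spans.

Evaluation is entity-level exact match (label and both boundaries), the
strictest standard convention, reported per label and micro-averaged, with
a confusion matrix whose rows sum to gold entity counts. At the study
sizes used throughout the tests — 10,000 generated training and 10,000
held-out samples — the scratch tagger reaches micro-F1 ≥ 0.99; at 5,000
training samples it stays ≥ 0.90; the seed-averaged F1 over three seeds is
non-decreasing across 1,000 → 5,000 → 10,000 training samples. The
monotonicity suite uses a 2,000-sample held-out corpus, sized to keep nine
train/evaluate rounds comfortably inside a desk-scale run.

## Assembly and the five guardrails

Assembly first fills, from the medication catalog, any *required*
component that was not extracted and has a catalog default — the catalog
completes, never overwrites. Then the guardrails run, in fixed order, and
the first to fire halts the suggestion (all firing guardrails are kept for
audit):

| id | condition | view |
|----|-----------|------|
| GR1 | an extracted value conflicts with the catalog's value for that component | pre-fill |
| GR2 | any component has ≥ 2 extracted values (multi-line directions) | pre-fill |
| GR3 | dose present, verb absent, verb required for this drug | post-fill |
| GR4 | no frequency | post-fill |
| GR5 | no dose while dose form is tablet or capsule | post-fill |

Two interpretation choices deserve notice. First, GR1 and GR2 inspect the
extraction *before* fill-in (a catalog default must neither mask a
conflict nor count as a duplicate), while GR3–GR5 inspect the post-fill
view (a catalog default legitimately satisfies a requirement); this
reconciles "fill in first" with "no value is extracted" in the guardrail
definitions. Second, GR1 compares canonical forms — `2 capsules` vs `two
capsules`, `daily` vs `once daily` are formatting variants, not conflicts
— because the catalog is a verification mechanism for meaning, not for
spelling. GR1 covers exactly the components for which the catalog has a
value for that drug.

A drug missing from the catalog degrades gracefully: fill-in and the
catalog-dependent guardrails (GR1, GR3, GR5) are skipped and the outcome
is annotated `catalog-missing`, preserving auditability without inventing
a halt the guardrail definitions do not prescribe. Assembly itself is a
single-space join in canonical order, lower-case, no terminal punctuation
— matching the generated-corpus dialect; display casing is presentation,
not content.

## Flagging

Flagging runs both directions through normalization, extraction and
canonicalization, then compares the nine labels pairwise. Semantic
equivalence is equality of canonical strings — deliberately not an
embedding similarity, so there are no unauditable false equivalences, and
all synonym knowledge lives in the editable canonical maps. `partial` mode
models an in-progress transcription: labels present in the reference but
not yet typed are `pending`, not errors, while anything already typed is
compared immediately; `final` mode counts them as `missing-in-b`.
Discrepancies map onto six review categories, with the dose label split by
comparing numeric and unit token parts (numeric difference → quantity;
unit-only difference → form; both → quantity).

On generated single-perturbation pairs (one component swapped for a
different-canonical library value), the dictionary-backed flagger
localizes the discrepancy to the perturbed label in 100% of cases and
never flags an unperturbed pair — by construction, and verified as a
property test rather than assumed.

## Generation metrics

Suggested directions are scored against references with sentence-level
BLEU (orders up to `min(4, candidate length)`, add-one smoothing on the
higher orders, brevity penalty) and an exact-match METEOR (recall-weighted
harmonic mean, alpha = 0.9; fragmentation penalty gamma = 0.5, beta = 3;
no stemming or synonym modules — normalized sig text has little
inflection, and synonymy is already handled by canonical maps). Both are
implemented in-package and pinned by hand-computed n-gram oracles in the
tests. Experiment reports compute metrics both over all records and over
the non-halted subset, with a separate guardrail tally — a halt is a
safety outcome, not a zero-quality generation, and averaging it as zero
would misstate both.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open everywhere; corpus JSONL
  round-trips bit-exactly, and BIO encode/decode is a bijection on
  token-aligned corpora.
* The tokenizer splits on whitespace and punctuation but keeps numeric
  tokens whole (`2.5`, `1/2`, `1,000`): decimal doses must be single
  tokens, both for sane BIO spans and so that the training vocabulary does
  not accidentally contain bare punctuation.
* Duplicate corpus `record_id`s warn but load; duplicate catalog
  `drug_id`s keep the first row and report the conflict; catalog rows with
  missing ids or unparseable fields are dropped and counted.
* All sampling (generation, degradation, splits, training shuffles) is
  locally seeded and restores the caller's RNG state.
* The cluster-stratified splitter embeds records as term-frequency
  vectors and uses `stats::kmeans` (k = 8 by default); `k = 1` reduces to
  a plain seeded split.
* Ties in Viterbi decoding resolve to the first index deterministically.

## Known limitations

Pattern-sampled corpora inherit the pattern inventory's word order;
extraction quality on free-order or multi-line text is untested here by
design (GR2 halts multi-line input rather than assembling it). The
dictionary backend cannot extract surfaces outside its libraries, and the
scratch tagger, while strong on the generated distribution, is not a
substitute for evaluation on real, consented pharmacy data before any
operational use. Catalog semantics are modeled at drug level; dose-form
level requirements and dose-strength arithmetic (mg → tablet conversion)
are out of scope.
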