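---
title: "Methods: a character-enhanced BiLSTM-CRF for Spanish clinical drug NER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a character-enhanced BiLSTM-CRF for Spanish clinical drug NER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the modelling, numerical and design choices in
`drugner` at the level of detail a maintainer or reviewer needs. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Task and representation

The tagger assigns each token of a sentence a BIO/BIOES tag over a set
of entity labels; spans are recovered from tags and reported as
character offsets (0-based, end-exclusive — the BRAT convention;
newlines count). Tagging, not span classification, is used because it
composes with a linear-chain CRF whose exact inference is cheap.

The default scheme is **BIOES**: the explicit `E`/`S` tags give the
model a direct boundary signal, which matters for multi-token mentions
like *receptores de progesterona*. BIO remains selectable
(`model_config(scheme = "BIO")`) since both are common in corpus
distributions.

## Architecture

Per token: a character BiLSTM (final forward and backward states,
concatenated) over character embeddings; a token-embedding lookup
(lowercased by default — public Spanish embedding releases are
lowercased — while the character channel keeps the original case); and
three *fixed* (untrainable) feature channels: a POS one-hot, a
gazetteer bit and an affix bit. The channels join the representation
*before* the token BiLSTM, so the recurrent layer can combine lexicon
membership with context; they are raw indicator vectors rather than
learned embeddings because their semantics ("is in the dictionary") is
already binary, and keeping them untrained preserves interpretability
of the ablation (`use_pos` / `use_gazetteer` / `use_affixes`). A
disabled channel contributes zero *width*, not zero values, so ablated
models are strictly smaller and their resource files are never read.

Defaults: `d_char = 25`, `d_char_lstm = 25`, `d_token = 100`,
`d_token_lstm = 100` (per direction), dropout 0.5 on the concatenated
embedding and on the token-BiLSTM output. These are conventional sizes
for BiLSTM-CRF taggers of this family; all are configuration fields,
and the package's own experiments (below) use smaller sizes suited to
desk-scale corpora.

## CRF layer

A path `y` is scored `start[y1] + Σ E[i, yi] + Σ T[y(i-1), yi] +
stop[yn]`. The log-partition uses the forward recursion entirely in
log space (`logsumexp` with max-shifting), so scores of magnitude
±10^2 cannot overflow. Gradients are expected-minus-observed counts
from the forward–backward recursions; no autodiff framework is
involved, which is why the test suite checks the analytic gradient
against central finite differences (tolerance 1e-4 relative; observed
agreement is far tighter).

**Transition masking.** Scheme-invalid transitions (e.g. `O → I-X`,
or in BIOES `B-X → O`) receive an additive penalty of −10⁴ on the
transition/start/stop scores. The value is large enough that no
emission pattern arising in practice can override it — decoded output
is always grammatical, which the suite verifies on random emissions —
yet finite, so log-space arithmetic stays NaN-free even when a whole
row is masked. Masking-by-default was chosen over decode-then-repair
because it guarantees decodable output without a second mechanism; the
repair path still exists for tags read from files.

**Ties.** Viterbi backpointers and the final state take the *lowest*
tag index on exact ties, making decoding deterministic.

## Tokenization and I/O

The tokenizer is rule-based and deliberately explicit: split on Unicode
whitespace, then isolate every punctuation/symbol character as its own
token, with two exceptions — an intra-word hyphen (letter on both
sides, as in *mg-kg*, *anti-TNF*) and a decimal comma (digit on both
sides, as in *2,5*) stay attached. Hyphenated segments and variable
parenthesis use are known failure sources in chemical text, so the
rules are tested rather than delegated to a third-party tokenizer.

BRAT entity boundaries that fall inside a token are a hard error by
default; an `expand_boundaries` flag snaps them outward to token
boundaries with one warning per entity. Silent snapping was rejected
because it corrupts evaluation: a snapped span that then scores as
correct hides a real boundary disagreement.

Invalid tag sequences read from files (a stray `I-X` with no open
span) are repaired as `B-X` — standard CoNLL practice — keeping the
decoder total. The CoNLL dialect writes explicit `start`/`end` offset
columns so that round trips are lossless; document text is rebuilt
from offsets with spaces in gaps (newlines are not representable in a
token-per-line format, which is why generated corpora are
single-line).

## Lexical resources

* **Gazetteer**: terms are NFC-normalized and lowercased; accents are
  *preserved* by default because they are lexically meaningful in
  Spanish (`strip_accents = TRUE` exists for noisy corpora). Lookup is
  per token, so multi-word entries are additionally exploded into
  component words of length ≥ 3 — otherwise an entry like *ácido
  acetilsalicílico* could never fire. Lookup is a hashed environment,
  O(1) per token; the test suite proves equivalence with a linear scan
  of the raw file.
* **Affixes**: prefix entries anchor at the start, suffixes at the
  end, roots match anywhere but only in tokens of ≥ 3 characters
  (caps false positives on fragments). A token equal to the bare affix
  *does* match — the simplest total rule. One combined bit is emitted
  (any entry matched); a per-kind variant was considered and left out
  to keep the channel's width and semantics minimal.

## Training

* **Split**: document-level greedy iterative stratification — process
  labels from rarest to most frequent; assign each document carrying
  that label to the split with the greatest remaining need for it,
  breaking ties by remaining document capacity and then by a seeded
  random order. Document granularity (not sentence) was chosen because
  annotation and prediction both operate on whole clinical cases.
  Fractions default to 0.8/0.1/0.1.
* **Early stopping**: training stops when the development entity-level
  micro-F1 has not *strictly* improved (tolerance 1e-6) for `patience`
  epochs (default 10); the best-epoch parameters are returned. The
  stopping rule is a pure function of the metric sequence
  (`early_stop_status()`), and `ner_train()` accepts an injectable
  metric function, so the state machine is tested with synthetic
  sequences, independent of any model.
* **Optimization**: minibatches of 16 sentences, shuffled per epoch
  under the run seed; gradients averaged per batch and clipped at
  global norm 5. The package default is SGD with learning rate 0.005;
  the package's own experiments use Adam (lr 0.002–0.01), selected
  once at design time because plain SGD needs far more epochs to
  converge on the small corpora these experiments use.
* **Rare classes**: `discard_rare_classes()` removes the mentions of
  listed labels (tokens revert to `O`) without touching text or
  offsets; the list is a configuration choice, never hard-coded.

All randomness — initialization (Glorot-uniform for LSTM/projection
weights, forget-gate bias 1, embeddings uniform in ±√(3/d)), dropout,
shuffling, splitting, generation — flows from explicit integer seeds,
and seeded construction restores the caller's RNG state.

## Evaluation

Strict CoNLL-style scoring: an entity is a true positive iff label and
exact character span both match; micro-averaged P/R/F1 overall and per
label; token-tag accuracy *includes* `O` tokens (the conlleval
behaviour). Matching is on character offsets rather than token
indices, so external predictions with a different tokenization can
still be scored. A partial-overlap mode exists purely as a diagnostic
and is never used for headline numbers.

## The synthetic test-bed

Real annotated Spanish clinical corpora are not redistributable, so
the generator produces corpora that emulate their *statistical* shape:
four mention classes at proportions 4398 : 50 : 167 : 3009-scale
imbalance, ~0.5 mentions per sentence (≈7.5 per 15-sentence document),
entity surfaces correlated with an emitted gazetteer and affix table,
multi-token protein forms (*receptores de X*) and multi-word gazetteer
entries (*ácido X*), and Spanish-like orthography (accented vowels, ñ)
from syllable templates so normalization and tokenization are
genuinely exercised. Class counts are allocated by largest-remainder
rounding and shuffling rather than multinomial draws, so realized
proportions track the targets even for the 50-weight class.

The **separability dial** fixes three regimes: `trivial` (every entity
is a single-token exact gazetteer term, no gazetteer word outside
entities — a dictionary rule is Bayes-optimal, giving a ceiling check
for the model), `easy` (90% cue-bearing entities: 60% gazetteer + 30%
affix; 5% of sentences carry an unannotated gazetteer distractor) and
`hard` (50% cue-bearing, 20% distractor sentences). Distractors are
the mechanism that keeps learning nontrivial: the model must combine
the gazetteer bit with context instead of copying it.

What the generator does **not** emulate: grammar, discourse, genuine
clinical vocabulary, abbreviations, spelling noise, or annotator
disagreement. Passing the end-to-end checks therefore demonstrates
that the architecture, gradients, I/O and training loop are correct
and that the feature channels carry signal — not that any particular
F1 would be reached on real clinical text.

## Problem sizes used by the checks

The package's experiments are sized for a single CPU: CRF/enumeration
agreement on instances of ≤ 5 tokens × ≤ 4 tags (hundreds of seeded
instances); round trips on 200 generated documents; capacity overfit
of 10 sentences (≤ 200 updates, small dimensions); the end-to-end run
on the 200-document trivial corpus with `d_token = 32`,
`d_token_lstm = 32`, Adam lr 0.003, patience 10; and the
gazetteer/affix ablation on a 120-document easy corpus at a fixed
8-epoch budget and matched seed. These sizes are the package's
reference configuration for its own verification, chosen to train in
minutes while leaving the learning problem non-degenerate.

## Known limitations

* No nested or discontinuous entities; no normalization of mentions to
  database identifiers (class names are opaque strings).
* No transformer/contextual encoders; out-of-vocabulary tokens fall
  back to the UNK embedding (no subword composition beyond the
  character channel).
* Prediction quality on real clinical Spanish depends on resources the
  user supplies (embeddings, nomenclator, affix table, POS tags);
  the package validates their formats but cannot validate their
  coverage.
* Resource fingerprints in saved models use MD5 (`tools::md5sum`),
  which is an integrity check against accidental file drift, not a
  cryptographic guarantee.
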