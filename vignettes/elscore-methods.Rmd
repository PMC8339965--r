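---
title: "Scoring expressive-language subtests: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring expressive-language subtests: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elscore)
```

# The scoring problem

Clinical expressive-language batteries elicit short spoken responses from a
child and score them on small ordinal scales. `elscore` models four subtest
types and their conventional scoring rules:

| Subtest | Task | Item scores | Items | Raw scale | Discontinuation |
|---|---|---|---|---|---|
| EV | name a pictured object | 0/1/2 | 27 | 0–54 | 7 consecutive zeros |
| WS | complete a sentence with an inflected form | 0/1 | 32 | 0–32 | none |
| RS | repeat a heard sentence verbatim | 0–3 | 32 | 0–96 | 5 consecutive zeros |
| FS | produce a sentence using a target word | 0/1/2 | 24 | 0–48 | 5 consecutive zeros |

Item scores are summed to a raw score per subtest (items after a
discontinuation point are dropped), raw scores are converted to age-normed
scaled scores on 1–19 (population mean 10, SD 3), and the FS + RS + WS
scaled sum is converted by a second lookup to the Expressive Language Index
(ELI), a standard score on 45–155 (mean 100, SD 15). EV contributes to no
composite. Item counts per subtest are inferred from the raw scales divided
by the maximum item score and are configurable.

Two transcript variants of each response matter in practice: the *clean*
transcript (only the scorable response, as an examiner would log it) and
the *verbatim* transcript (everything the child said — "i think that one's
a pirate" where the clean transcript is "pirate"). Scoring verbatim
transcripts is strictly harder, and the package keeps both variants
first-class so that difference can be measured.

# Rule-based RS scoring

RS responses are scored from the error count of a token alignment:

1. `normalize_tokens()`: lowercase, strip punctuation (word-internal
   apostrophes survive), split on whitespace.
2. `collapse_repetitions()`: adjacent identical tokens collapse to one,
   because repetitions are not counted as errors. Only adjacent duplicates
   collapse; non-adjacent recurrence is legitimate content. Collapsing
   maximal runs is a fixpoint, so token-level restarts need no phrase
   detection.
3. `align_tokens()`: unit-cost Levenshtein alignment returning operation
   counts (insertions, deletions/omissions, substitutions, correct words),
   not just a distance. Ties among minimum-cost alignments are broken
   deterministically — substitution is preferred over an
   insertion+deletion pair, and the backtrace examines diagonal, up, left
   in that order — because the counts double as classifier features and
   must be reproducible.
4. `rs_item_score()`: the total error count maps to 0–3. The published
   scale does not print its thresholds, so the default map (0 → 3, 1 → 2,
   2–3 → 1, ≥4 → 0) follows the standard sentence-recall convention and is
   overridable everywhere.

Transpositions are not a primitive edit operation: a swapped adjacent pair
surfaces as two substitutions under plain Levenshtein, and the synthetic
generator counts it accordingly. The alternative (unit-cost swaps) is
deliberately not the default; whether a clinical scorer counts a
transposition as one error or two is convention-dependent, and the plain
operation set keeps the feature semantics of the RS baseline classifier
simple.

# Item classifiers

All backends implement one contract — `fit_scorer(spec, pairs, config)`,
`predict_item_scores(scorer, pairs)` — and all predictions lie in the
subtest's score classes.

**Attention pair encoder** (`"attention"`). Responses are scored in the
context of their prompt, so the input is the pair
`<cls> prompt <sep> response` with segment flags, truncated response-last.
The encoder is a deliberately small single-head, single-block
self-attention network (token + position + segment embeddings, residual
attention and feed-forward blocks, mean pooling, softmax head) trained
from random initialization with Adam. It is the architectural counterpart
of fine-tuned transformer pair classification at a size that trains in
seconds on one CPU with no pretrained weights; it is not a pretrained
language model, and nothing in the package depends on one.

**Training protocol** (shared by the attention and MLP backends): a
stratified-on-demand random 10% validation holdout, an L2 penalty on
weight matrices, and early stopping — when validation loss has not
improved for 4 consecutive epochs (`patience_epochs`), training stops and
the parameters are restored to the epoch with the lowest validation loss.
`early_stopping_trace()` is the executable specification of that rule, and
the training loops are tested against it with stubbed loss trajectories.
Optimizer settings (`learning_rate` 0.005, `batch_size` 16, `max_epochs`
50, `l2_weight` 0.01) are conventional defaults, all exposed in
`train_config()`.

**Baselines.** `svm_mean_embedding` fits an SVM (via e1071/libsvm) on the
300-dimensional arithmetic mean of the response's word vectors — the
classical short-answer baseline for EV/WS. `svm_edit_features` (RS only)
fits an SVM on the four alignment counts. `mlp_static_embedding` fits a
one-hidden-layer MLP on a static (never fine-tuned) sentence embedding of
the response; following the convention for this baseline family, the
embedding covers the response only, not the prompt. `ngram` is a
deterministic nearest-profile model over response n-grams plus
prompt-overlap features; an exact training duplicate always receives its
training label, which makes it a useful reference point and a fast default.

**Embeddings.** The embedding provider is an interface. The default is a
seeded hash projection: every token maps to a reproducible Gaussian vector
keyed by a hash of its string. Hash vectors carry no lexical semantics;
they give the baselines a well-defined, download-free feature space that
is sufficient for vocabulary-separable data. A word-vectors file can be
plugged in through `file_embedding_provider()`. Out-of-vocabulary tokens
and empty responses map to the zero vector, so the mean is always defined
and an empty response is always scorable (as 0 by every backend in
practice).

# Synthetic data: what it does and does not emulate

No child-speech corpus ships with the package — such data is protected —
so `generate_corpus()` produces corpora with the *scoring-relevant*
structure of the real thing, with gold scores correct by construction:

- EV/WS/FS responses are drawn from per-stimulus exemplar banks,
  pre-labeled by score class, with disjoint vocabulary pools per class
  (e.g. EV: the target itself for 2, an under-specific category word like
  "fruit" for "lime" for 1, an unrelated word for 0; WS: "fixed" vs. the
  bare stem "fix").
- RS responses are built by `inject_rs_errors()`: exactly `k` scored
  operations are applied to the target, where `k` is drawn from the error
  band of the item's gold score under the active score map, and the result
  is re-checked against the rule scorer (re-sampling on accidental
  collisions). Injected adjacent repetitions are free by construction.
- Verbatim variants prepend (and sometimes append) chatter phrases with
  probability `chatter_prob`; clean and verbatim variants share gold
  scores item for item.
- With probability `zero_run_prob` an administration enters a terminal
  all-zero run, so corpora exercise every discontinuation rule; the
  administration record ends where the rule fires, as a real one would.

Default conditions, chosen once: 25 children per corpus (configurable),
ages uniform over 60–119 months, mildly top-heavy score distributions
(EV .15/.20/.65, WS .25/.75, RS .15/.20/.25/.40, FS .20/.25/.55),
`chatter_prob` 0.8, `rs_repetition_prob` 0.15, `zero_run_prob` 0.15, and a
70/30 TD/non-TD group tag used only by stratified reporting. Published
studies do not report per-item score distributions, so these are
realism-motivated conventions, not estimates.

What the generator does *not* emulate: English semantics (exemplars are
pseudo-words, so embedding-based backends cannot exploit lexical
similarity), age-conditioned ability, acoustic or transcription noise, and
within-child correlation beyond the terminal zero run. Consequently,
passing tests on generated corpora demonstrate that the pipeline's
mechanics are correct — separable classes are recovered, gold scores
propagate to perfect tiers, rules fire where they must — not that any
backend reaches a particular accuracy on real child speech. The RS
gold-consistency guarantee is asserted on clean transcripts; verbatim RS
responses contain chatter that the rule scorer counts as insertions, which
is precisely the clean/verbatim contrast the classifiers are meant to
absorb.

# Synthetic norms

Real normative tables are proprietary, so `build_norm_tables()` constructs
synthetic ones by quantile matching: within each subtest × age band, a raw
score whose mid-quantile in the reference distribution is $q$ receives the
scaled score $s$ whose normal band
$\Phi\!\left(\frac{s-10.5}{3}\right) < q \le \Phi\!\left(\frac{s-9.5}{3}\right)$
contains it (clamped to 1 and 19 at the tails; boundary ties break toward
the lower score). The ELI table is built the same way (mean 100, SD 15)
over the FS + RS + WS scaled-sum distribution the scaled tables induce on
the same population. This construction guarantees the published moments up
to integer discretization for *any* non-degenerate reference distribution;
the tests verify scaled mean 10 ± 0.1, SD 3 ± 0.3, ELI mean 100 ± 1, SD
15 ± 1.5 on 100,000 fresh draws.

The reference population is binomial per subtest over the raw scale, in
two age bands (60–89, 90–119 months), 10,000 children per band by default.
The default success probabilities (EV .75, WS .75, RS .63, FS .68) equal
the mean per-item score fraction of the generator's defaults, so the
reference population describes the same kind of children the generator
simulates and generated corpora land mid-scale rather than at the table
ceilings. Raw draws are independent across subtests within a child; the
quantile transform pins the ELI moments regardless of inter-subtest
correlation, so independence costs nothing for calibration (it does make
extreme scaled sums rarer than in strongly correlated real populations).
These tables are explicitly *not* the proprietary normative tables and
carry no clinical meaning.

Age bands exist so the machinery handles age-dependent lookup; both bands
share a raw-score distribution by default because the generator is not
age-conditioned. Bands are half-open `[min, max)`: a child exactly on a
boundary falls in the upper band.

# Aggregation choices

- Items after a discontinuation point are dropped, not zero-filled; raw
  scores agree either way, but dropped items are excluded from item-level
  metrics, mirroring real administration. `ceiling_on = "none"` scores
  everything for research use.
- The zero run can be detected on the predicted stream (default: the
  system consumes its own scores, as a fully automated scorer must) or on
  the gold stream (`ceiling_on = "gold"`, replicating manual
  administration). The interaction is a genuine design choice, so both
  modes exist and are tested.
- Basal/starting rules are not modeled.
- The ELI requires all three of FS, RS, WS; nothing is imputed.

# Evaluation harness

`cross_validate()` implements repeated k-fold evaluation: per repetition
the children are reshuffled (repetition $r$ derives its seed as
`seed + r`) and partitioned into folds *by child*, so no child contributes
items to both the training and test side of a fold — the conservative
choice, since the unit of folding is not stated in the conventions this
follows; item-level folding is reproducible by treating each item as its
own child. Per fold, one scorer per subtest is trained and the test
children's items are predicted; item metrics are computed on the
concatenated test folds, tiers by pushing predicted item scores through
`score_reports()` and comparing with the gold-derived tiers.

Averaging for precision/recall defaults to support-weighted — under which
recall equals accuracy identically, a pattern visible whenever published
per-subtest tables show the two coinciding — with macro available. An
undefined Spearman correlation (zero variance in either vector) returns
`NA` and is excluded from the repetition mean, with the exclusion count
reported. The repetition mean ± SD is the primary summary.

# Numerical and degenerate-input choices

- All randomness flows through explicit integer seeds; sub-seeds are
  derived by hashing `(seed, label, index)` into 31-bit integers, so
  parallel stages never share streams and every artifact is reproducible
  byte for byte.
- Empty responses: legal everywhere; tokenize to an empty list; align as
  all-deletions; embed as the zero vector.
- Single-class training data is an error (no classifier can be fit); a
  validation split that would empty a class falls back to a stratified
  split with a warning.
- Probability vectors must sum to 1 within 1e-9; norm tables must cover
  their scales exactly (gaps, overlaps, and non-monotone entries are
  rejected with the offending interval named).
- Alignment tie-breaks are fixed (see above); equal validation losses do
  not count as improvement for early stopping.

# Problem sizes used in the tests

The shipped suite runs at sizes a laptop CPU handles comfortably: the
alignment oracle check enumerates all 14,641 sequence pairs up to length 4
over a 3-symbol alphabet; RS gold-score recovery uses ~5,400 generated
items; pipeline closure uses 200 children; the separable-recovery check
runs the full 5-fold protocol with 3 repetitions over ~400 items per
subtest; calibration uses 100,000 reference children. The attention and
MLP backends are exercised on small corpora (a few hundred pairs, few
epochs) — enough to verify the contract and the training protocol, not to
benchmark accuracy.

# Known limitations

- The attention encoder is randomly initialized; without pretraining it
  has no lexical knowledge and needs vocabulary overlap between train and
  test to generalize. On real data one would substitute a pretrained
  encoder behind the same contract.
- Hash embeddings make semantically related words orthogonal, so the
  embedding baselines underperform their real-world counterparts by
  construction on tasks where partial credit is semantic (EV's
  "fruit"/"lime").
- Synthetic norms are placeholders: internally consistent and correctly
  calibrated, but not clinically interpretable.
- The generator's independence assumptions (across items and subtests)
  make synthetic tier correlations optimistic relative to real cohorts.
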