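---
title: "Event extraction with pattern-based sample selection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event extraction with pattern-based sample selection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioevex)
```

This vignette documents the models implemented in bioevex, the choices
made where the design was genuinely open, and what the synthetic corpus
used by the test suite does and does not establish about behaviour on
real annotated literature.

## Task and pipeline

The package extracts GENIA-style events from documents in BioNLP-ST
standoff form: plain text, protein annotations (`.a1`), and — for
training — event annotations (`.a2`).  Dependency parses are consumed as
an input file per document (one block of `gov dep label` edges per
sentence, token indices 0-based within the sentence): parsing itself is
out of scope, as extractors in this family take the output of an external
biomedical parser.  All character offsets are 0-based, half-open and
document-level.

Training runs: tokenize → generate candidate pairs/triplets from a
trigger dictionary → build the sequence database from labeled pairs →
mine patterns → select negative candidates → extract features → fit
one-vs-rest linear models.  Prediction runs the same front end, then
integrates pair and triplet decisions, scores each event jointly, and
drops events under a threshold.

## Sequential-pattern sample selection

A dependency path is the sequence of typed-dependency labels along the
shortest path (unweighted, undirected view of the parse) between trigger
and argument tokens.  Containment is order-preserving, non-contiguous
embedding; support of a pattern is the number of database sequences
containing it, with multiset semantics (a repeated path counts each
time, and a sequence contains itself).  Mining is PrefixSpan: recursive
prefix projection, no candidate generation; the mined set is exactly the
non-empty sequences with support ≥ `minsup`, each with its true support.

Selection keeps an unlabeled candidate when strictly more than `theta`
mined patterns embed into its path.  Defaults `minsup = 4`, `theta = 2`
are the operating point established on development data in this family
of systems; both are exposed.  Tunables and their semantics:

* `minsup` (count ≥ 1): absolute support threshold of the miner.  Raising
  it shrinks the pattern set and therefore the selected set
  (monotonicity is covered by tests).
* `theta` (count ≥ 0): strict lower bound on the match count.  Selection
  is monotone in it as well.

Design points worth stating explicitly:

* The sequence database is built from **positive** (annotated) pairs
  only; the filter's purpose is to retain the negatives that resemble
  positives.  Labeled positives are never routed through the filter —
  they always enter training.
* Candidates with no dependency path between trigger and argument are
  discarded before filtering: the match count is undefined without a
  path, and such pairs are overwhelmingly negative.
* Path labels carry no edge-direction markers by default (the path is a
  bare label sequence).
* Triplets carry two paths; a triplet is selected when **both** paths
  pass the pair criterion.  This conservative AND is the default; a
  `rule = "sum"` alternative (total match count over both paths above
  `2 * theta`) is available.  Nothing in the pair criterion forces either
  choice; the AND was chosen because a triplet with one implausible
  argument path is usually wrong as a whole.
* The mined set is the full frequent set (no closed/maximal pruning),
  and the empty pattern is excluded as vacuously frequent.
* Output ordering of patterns is canonical (length, then lexicographic)
  so that serialized pattern sets are reproducible.

## Candidates and features

Trigger candidates are single tokens whose stem matches the dictionary
built from training annotations (multi-token triggers are out of scope;
GENIA triggers are predominantly single tokens).  Candidate arguments
are annotated proteins, plus — for triggers whose dictionary types
include a regulation type — other dictionary-matched tokens, which is
how nested regulation (an event as Theme) becomes reachable.  Candidate
causes are restricted to proteins.

Feature groups (binary, sparse):

* token: stem, POS tag (a small rule-based tagger), character 1–3-grams,
  word shape, has-digit/has-hyphen/initial-capital, for trigger and
  argument;
* sentence: bag of stems, candidate-entity count;
* dependency: the shortest-path label sequence (whole path, its labels,
  label bigrams, length), a `nopath` flag for disconnected pairs, and
  label chains up to depth 3 from the trigger (the depth matches the
  convention of the feature system this group follows; configurable in
  code);
* external resource: hypernym features from a user-supplied stem →
  hypernyms lookup; off by default so that nothing is downloaded.

Extraction is pure: identical input yields an identical map.

## Classifiers and integration

One linear model per event type, one-vs-rest, fitted as L2-regularised
(ridge) logistic regressions on the sparse feature matrix
(`glmnet`, fixed `lambda = 1e-3`, no standardization).  A candidate is
assigned the argmax type when the best margin is positive, otherwise
negative; the margin-0 decision boundary is the natural logistic
threshold, and it avoids comparing margins against a separately fitted
negative-class discriminant, which is not calibrated on the same scale.
Class weights are a damped version of "balanced"
(`(n / 2 n_c)^0.5`): the heavy rebalancing has already been done by the
pattern filter, so only mild residual weighting is applied.  Both
`lambda` and the damping exponent were fixed on a held-out split of a
development fixture corpus and are exposed as arguments.  The fits are
deterministic; no seed is involved in training.

The triplet model covers Binding and the regulation types.  Integration
follows three rules: a predicted Binding triplet (c, a1, a2) becomes a
two-Theme event and removes the Binding pairs (c, a1) and (c, a2); a
regulation triplet emits a1 as Theme and a2 as Cause and removes the
same-type pair (c, a1) (the pair restates the triplet's Theme; removing
it avoids emitting the same event once with and once without its Cause);
pairs untouched by a triplet, and all SVT pairs, are emitted directly.
When pair and triplet models disagree on the type of the identical
(trigger, argument), the higher decision margin wins — the tie-break is
documented rather than principled, as nothing in the model makes the two
margins comparable beyond their shared scale.

Nested regulation is resolved in one bottom-up pass: SVT and Binding
events are instantiated first, then regulation events whose Theme is a
trigger token link to the highest-margin event at that trigger;
unresolvable event Themes drop the prediction.  One pass matches the
depth-2 nesting the corpus exhibits and cannot create reference cycles.

## Joint scoring

For each predicted event with trigger stem *t* and type *typ*:

* `P1 = f(t, typ) / Σ_typ' f(t, typ')` — the type-conditional fraction
  of *t*'s annotated instances; `Σ_typ P1 = 1` for any seen trigger.
* `P2 = Σ_typ' f(t, typ') / Σ_t' f(t')` — *t*'s share of all annotated
  event instances.  Counts come from training `.a2` events (instance
  counts, not token frequency).
* `P_t = (w1 P1 + w2 P2) / (w1 + w2)`, with `w1` the number of
  predictions of (t, typ) and `w2` the number of predictions of *t* in
  the current result set; `w2 ≥ 1` always holds because the event itself
  is in the set.  Unseen triggers get `P1 = P2 = 0` and a flag.
* `Sim` is the maximum cosine relevance between the event's sentence and
  the training sentences containing the same trigger stem, exactly 0
  when that set is empty.  "Same trigger" means same stem by default; a
  `same_type` switch additionally requires the predicted type among the
  trigger's training types.  The sentence set spans the whole training
  corpus (not just the same document); a per-document scope would
  starve the maximum on short documents.
* `Score = (1 − σ) P_t + σ Sim`, with σ = 0.7 by default: similarity is
  the stronger corrector of false positives, so it carries the larger
  weight.  Negative cosines are clamped to 0 first so the score lies in
  [0, 1] and δ ∈ [0, 1] is meaningful.  Events with `Score < δ`
  (δ = 0.5 default) are removed; both parameters are meant to be tuned
  on a development split.

The default similarity backend is a letter-trigram bag-of-words cosine:
each token is hashed to its boundary-marked letter trigrams and a
sentence is the sum of its token vectors.  It is fully deterministic and
needs no trained weights.  The convolutional backend implements the
word-hashing → token-window convolution → element-wise max-pooling →
semantic-layer architecture with tanh activation (the convention of the
semantic models this follows; the activation is configurable since it is
not forced by anything).  Its weights can be loaded from file or drawn
seeded-random — training such a model requires large-scale relevance
supervision that is out of scope here.  In the degenerate configuration
(identity weights, whole-sentence window, linear activation) it
reproduces the hashed trigram-bag representation exactly, which the test
suite asserts; with random weights only determinism and dimensional
contracts are asserted.

## The synthetic corpus

The generator writes standoff corpora that emulate the features the
method actually exercises:

* a trigger lexicon with type-skewed frequencies over all nine types;
  the first nine event sentences cycle deterministically through the
  types so even small corpora contain each one (and a one-document
  corpus contains a simple event);
* Binding events with a second Theme (probability 0.5), regulation
  events with a Cause (0.7) and nested regulation over a simple event
  (0.25) — values chosen as plausible mid-range rates for multi-argument
  and nested structure, fixed once;
* dependency graphs built as per-pair label chains sharing only their
  endpoint tokens.  Positive pairs draw their 2–3-label paths from a
  pool of six sequences over a six-label alphabet; negative paths are
  2–3 labels with each item drawn with probability 0.6 from the positive
  alphabet and otherwise from nine extra labels.  Chain lengths are
  capped at 3 so the planted chain is always the unique shortest path
  (any detour concatenates at least two chains, length ≥ 4).  The pool
  sizes were fixed a priori from the expected match-count distribution:
  a negative path then matches about one mined pattern on average, so a
  threshold of 1–3 separates meaningfully, while every positive path
  matches at least three patterns;
* a configurable candidate-pair imbalance (default 1 : 13.163, the ratio
  of annotated corpora).  The per-sentence plan chooses the number of
  distractor proteins so the cumulative realized ratio tracks the
  target; the tests require agreement within 20%.

What the fixture does **not** emulate: real syntax (sentences are token
sequences with planted parse chains, not grammatical text), parser
errors, multi-token or ambiguous triggers, secondary arguments (Site and
friends are out of scope entirely), inter-sentence events, and the long
tail of trigger vocabulary.  Passing the end-to-end tests therefore
shows that the machinery is correct and that the filter/classifier/score
stages compose as designed under the stated imbalance — not that the
published corpus-level scores transfer; those depend on the shared-task
corpora, an external parser and the official scorer.

## Internal evaluator

Event-level matching with one token of trigger-span slack and recursive
argument matching: protein arguments must reference the same `.a1`
annotation, event arguments must match recursively, Binding Themes are
order-insensitive, and each gold event is matched greedily at most once.
Recall/precision/F are reported per type, per class and in total (in
percent, F = 2PR/(P+R), 0 when degenerate).  The official shared-task
scorer's approximate-recursive criterion is not restated publicly in
enough detail to claim identity; this evaluator is used on fixtures
only, and its semantics are as documented here.

## Numerical and degenerate-input choices

* Pattern order: length then lexicographic; support ties carry no
  meaning.
* `max.col` tie-break in prediction is "first" (deterministic).
* Zero vectors in cosine relevance yield 0 with a warning.
* Empty sequence databases mine to an empty pattern set; `minsup < 1`
  and σ, δ outside [0, 1] are parameter errors.
* An event type with fewer than two training examples is dropped from
  its model with a warning (a one-example logistic fit is meaningless).
* Documents without proteins or dictionary matches yield empty candidate
  sets, empty predictions and empty `.a2` output, not errors.

## Problem sizes in the tests

The suite exercises the miner against brute-force enumeration on 200+
random databases (≤ 8 sequences, alphabet 5, length ≤ 6), the filter
grid on a 120-document corpus, and the full pipeline on a 200-document
corpus split 150/50 — sizes at which every stage's behaviour
(imbalance, filter signal, classifier generalization) is already stable
while the whole suite stays conveniently fast.

## Known limitations

* Only primary arguments are extracted; Site/AtLoc/ToLoc/CSite are out
  of scope by design.
* Triggers are single tokens matched by stem; a lexicalized stemmer
  would be needed for morphologically richer trigger variation.
* The joint score's trigger statistics are corpus-level; a trigger that
  is systematically ambiguous across domains would need
  document-conditional statistics.
* The pair and triplet models are trained independently; disagreements
  are resolved by margin, not by a joint objective.
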