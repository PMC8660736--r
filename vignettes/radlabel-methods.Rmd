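---
title: "Labelling neuroradiology reports: models, evaluation protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labelling neuroradiology reports: models, evaluation protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

radlabel derives dataset labels from free-text neuroradiology reports: one
binary `abnormal` label plus seven specialised abnormality categories
(acute stroke, mass, atrophy, vascular, small vessel disease, white matter
inflammation, encephalomalacia). This vignette explains the model, the
evaluation protocol, the synthetic corpus that everything is tested on, and
the design decisions taken where more than one reasonable choice existed.

## The classifier

Each category gets its own model — eight in total, sharing code but not
parameters. A model is three stages trained end-to-end on binary
cross-entropy with Adam:

1. **Contextual encoder.** Reports are lower-cased, tokenised and mapped to
   integer identifiers (the only preprocessing a transformer encoder
   requires; no stemming, no stop-word removal). A transformer encoder
   turns each token into a d-dimensional contextual vector. At full scale
   this stage is a large pretrained biomedical encoder (d = 768); the
   package's desk scale uses a randomly initialised encoder (default 2
   layers, d = 64, 4 heads) small enough to train from scratch on a
   synthetic corpus in minutes on one CPU. The architecture contract —
   not any particular set of pretrained weights — is what the package
   tests: one finite vector per position, deterministic in inference, and
   padding excluded from every attention key set, so a token's vector never
   depends on how much padding follows it.
2. **Attention pooling.** An additive scorer
   `s_i = v' tanh(W h_i + b)` is softmax-normalised over non-padding
   positions into weights `a_i >= 0`, `sum a_i = 1`, and the report vector
   is `sum a_i h_i`. Padding receives exactly zero weight. The weights
   double as word-level interpretability: `attention_report()` maps them
   back to surface tokens.
3. **Classification head.** One hidden layer (default width 256, rectified)
   and a sigmoid output in (0, 1).

Attention logits carry a fixed distance-decay bias per head (slopes
`2^-h`, the linear-bias scheme used by position-interpolation-free
transformers): steeply sloped heads act locally, which is what lets a
desk-scale encoder bind a negation frame to the finding phrase *in its own
sentence* rather than to identical frame words elsewhere in the report;
shallow heads retain a global view. A large pretrained encoder learns the
same behaviour from data; a 1-2 layer randomly initialised one benefits
from having it built in.

The forward and backward passes are written as plain matrix arithmetic;
the analytic gradients of every block (attention, LayerNorm, pooling,
head) are verified against central-difference numerical gradients in the
test suite. Residual blocks use the pre-LayerNorm arrangement because it
trains stably from random initialisation without warm-up schedules, which
matters at desk scale where no pretrained weights damp early updates.

### Hyperparameters

* `learning_rate` — default `1e-5`, the fine-tuning rate for a large
  pretrained encoder (small enough to avoid catastrophic forgetting).
  A randomly initialised desk-scale encoder has nothing to forget and
  needs `~1e-3` to converge in a few epochs; examples and tests pass this
  explicitly. No learning-rate schedule is used.
* `batch_size` — default 16. The final partial batch is averaged per
  example, so batch composition does not bias the gradient scale.
* `max_epochs` — default 10 and deliberately configurable: a checkpoint is
  taken after every epoch and `train_model()` returns the checkpoint with
  the lowest validation loss, so extra epochs cost time, not accuracy.
* `seed` — controls initialisation and the per-epoch shuffles (each epoch
  reseeds from the run seed), making whole histories reproducible.
* `max_len` — default 512 in the tokenizer (the ceiling of encoder
  positional tables at full scale). Over-long reports are truncated from
  the tail by default: findings sentences dominate the start of a report
  while conclusions largely repeat them; a head-keeping policy is
  available. Desk-scale runs use 48-128 tokens, chosen to cover the
  synthetic reports they process.

## The baseline comparator

The comparison model is a logistic regression over (i) the arithmetic mean
of static per-word embeddings and (ii) N-gram counts (N = 1, 2, 3).
Static embeddings are trained by skip-gram with negative sampling on the
training corpus (d = 100 default), or fixed random vectors — both modes
are *context-independent*, which is the property under study: the mean
block of "no features suggestive of acute stroke" is identical under any
permutation of the same words. The logistic fit is unregularised maximum
likelihood by default; designs wider than 300 columns are estimated by
glmnet's coordinate descent at a vanishing ridge (1e-6), because exact
IRLS QR decompositions do not scale to text-sized feature spaces. An
explicit `l2` option gives ridge estimation at any width. N-gram features
are raw counts; frequency weighting is configurable upstream of the fit.

## The synthetic corpus generator

The hospital report corpora the method was designed for are not
distributable, so the package ships a seeded generator whose output has
the statistical and linguistic structure the models and statistics assume:

* reports of 5-10 sentences: optional clinical-history and protocol
  sentences, findings sentences, normal-anatomy filler, and a neutral
  conclusion;
* several reporter styles (template preferences vary by a per-report
  style id) and optionally several sites;
* multiple reports per patient — `1 + Geometric(0.5)` capped at 6 — so
  patient-level splitting is non-trivial;
* abnormal reports carry `1 + min(Poisson(m - 1), 4)` distinct granular
  categories (1 to 5), where `m` is `mean_granular_per_abnormal`
  (default 1.56). This one-parameter family reproduces the published
  mean/maximum/mode shape (1.56 / 5 / 1) of granular labels per abnormal
  report;
* per-category prevalences are *derived*: the generator takes category
  weights and computes `prev_c = prev_abnormal * E[k] * w_c`, because a
  free prevalence vector would over-determine the co-occurrence model.
  The derived values are exposed on the config and recovered empirically
  within binomial noise. Pairwise category correlations are not modelled
  (they are not published); categories are conditionally independent given
  the per-report count;
* **distant negation**: with probability `distant_negation_rate` a report
  mentions one or two categories it does *not* have, inside negation
  frames whose negating token sits at least three tokens before the
  finding phrase ("there are no features in either hemisphere suggestive
  of ..."). The label bit for a negated mention is false by construction.

Two template-design constraints are deliberate and load-bearing:

1. Every bridge bigram immediately before a finding phrase ("suggestive
   of", "evidence of", "in keeping with", "to suggest", "concern for",
   "features of") occurs in both assertion and negation frames, so no
   N-gram (N <= 3) local to a finding phrase reveals its polarity.
2. Benign assertions ("preserved parenchymal volumes", "a structurally
   normal brain") occur inside the same assertion frames in normal *and*
   abnormal reports, as in real reporting practice — assertion-frame
   vocabulary on its own therefore carries no class signal.

Together these make the granular labelling task genuinely ambiguous for
any bag-of-words model: a report asserting category A while negating
category B has exactly the same trigram profile as one asserting B while
negating A. Resolving it requires sentence-level context — the mechanism
by which the contextual classifier earns its advantage. The comparative
tests run on a granular category for precisely this reason: for the
*binary* abnormal/normal task in a template world, the number of asserted
findings is linearly recoverable from word counts alone, so a bag-of-words
model can do essentially perfectly there; that is an artefact of template
generation, not a property of clinical text.

What the generator does **not** emulate: true lexical richness
(hospital-scale corpora have hundreds of thousands of word types; the
template vocabulary has a few hundred), voice-recognition artefacts,
spelling noise, inter-annotator label noise, report-image discrepancies
(satisfaction-of-search omissions), or realistic clinical co-occurrence
structure. Passing tests on synthetic corpora therefore demonstrates the
*mechanisms* — negation handling, leakage-free evaluation, calibration —
not clinical-grade performance on real reports.

## Evaluation protocol

* **Patient-level splits.** Every patient (and all their reports) goes to
  exactly one of train (60%) / validation (20%) / test (20%); patients
  with reference-standard image labels are excluded into a fixed hold-out.
  Report-count fractions match targets to within one patient group.
* **Repeated splits.** The split-train-evaluate cycle repeats (default 10
  times) with the image-label hold-out bit-identical across repeats.
  Summary intervals are `mean +/- 1.96 sd / sqrt(n_repeats)` — a
  normal-approximation 95% CI of the mean, recorded as such in the output
  metadata since published "+/-" values rarely state their definition.
  With a single repeat the half-width is reported as `NA`.
* **AUC.** Mann-Whitney form with ties credited 1/2, identical to
  exhaustive positive-negative pair enumeration (tested).
* **Operating threshold** for sensitivity/specificity/F1: 0.5 by default;
  an optional Youden-J threshold is chosen on validation scores only.
* **DeLong tests.** Paired comparisons (two classifiers, same test cases)
  use the structural-component covariance; unpaired comparisons (report-
  label vs image-label test sets) sum independent variances. Two-sided p
  from the normal reference. Degenerate zero-variance comparisons return
  p = 1 when the AUCs are equal and raise an error otherwise.
* **Fleiss' kappa** for multi-rater agreement, with an explicit undefined
  marker when all ratings fall in one category.
* **2-D embedding export.** The reduction is delegated to established
  implementations — principal components (`stats::prcomp`, default) or
  classical MDS (`stats::cmdscale`). Both satisfy the export contract
  (deterministic, one 2-D point per report, class clusters separate); a
  stochastic-neighbour method can be swapped in behind the same contract
  where available.

## Numerical choices and degenerate inputs

* Attention softmax subtracts the row maximum before exponentiation;
  LayerNorm uses eps = 1e-5; BCE clamps probabilities at 1e-12.
* An all-padding mask, an empty report after normalisation, a single-class
  label vector, and a rater matrix concentrated in one category all raise
  typed errors rather than returning NaN.
* Yule's I uses the inverse-characteristic form `M1^2 / (M2 - M1)` over
  the frequency spectrum (`M1` types, `M2 = sum i^2 V(i)`), reported as
  `Inf` for all-singleton corpora. The published head-MRI corpus row
  prints a type-token ratio (0.019) that does not equal unique/total from
  the same row (0.014); the package computes TTR = M1/N and documents the
  discrepancy without attempting to resolve it.
* Words for lexical statistics are lower-cased, punctuation-stripped
  whitespace tokens, independent of the model tokenizer.

## Problem sizes in the shipped tests

The test suite and the acceptance script train desk-scale encoders on
corpora of 32 to 2,000 reports (the comparative experiment uses 2,000
reports with a 40% distant-negation rate, five seeds, eight epochs,
max_len 128, one encoder layer), sizes at which a full run completes on a
single CPU in minutes while still exercising every mechanism at the
fidelity the properties require.

## Known limitations

* The desk-scale encoder shares the architecture, not the representational
  power, of a pretrained biomedical encoder; absolute AUCs on synthetic
  corpora say nothing about hospital corpora.
* Granular categories are conditionally independent in the generator;
  real co-occurrence (e.g. encephalomalacia after stroke) is not modelled.
* The CLI's `--encoder pretrained` preset requires an external weight
  archive; without one it falls back to the desk-scale encoder with a
  notice.
* Training is single-threaded and in-memory; corpora far beyond 10^4
  reports are better handled by exporting the corpus and batching.
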