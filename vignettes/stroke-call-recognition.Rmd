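---
title: "Recognising stroke in helpline call transcripts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising stroke in helpline call transcripts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Stroke treatment is strongly time-dependent, and the gateway to rapid
treatment is a telephone call — in Copenhagen either the 1-1-2 emergency
line or the medical helpline for non-acute complaints. Call-takers
recognise roughly half of stroke calls; a text classifier that scores the
call transcript for stroke likelihood can, in principle, flag many of the
misses while keeping precision at or above the human level. `strokecall`
implements that full analysis as a reusable, tested pipeline: cohort
simulation, registry linkage, bag-of-words featurisation, an ensemble of
multi-layer perceptrons (MLPs) with fold-rotated early stopping, decision
threshold calibration against the call-taker operating point, resampling
based evaluation, and occlusion explainability.

The original study population is legally restricted (Danish patient
privacy law), so the package ships a synthetic-data module as a
first-class, tested component. Every quantitative claim in this vignette
is computed by the test suite or by `scripts/acceptance.R`; nothing is
copied from external runs.

## The synthetic cohort

`generator_config()` + `generate_cohort()` produce calls, registry entries
and transcripts with the joint structure the analysis relies on:

* **Prevalence.** Helpline stroke prevalence defaults to 0.25%, the
  published test-year figure; the emergency line carries 6.6% of calls at
  2.5% prevalence, matching the published cohort table's ratios.
* **Demographics.** Ages are truncated normal (stroke: mean 71, sd 13.4;
  non-stroke: mean 44, sd 20; truncated to 18–105), female fractions
  46.1% / 55.5% by status — the published test-column values.
* **Call-taker triage.** The call-taker is simulated from a sensitivity /
  PPV pair (defaults 52.7% / 17.1%). The false positive rate is *derived*,
  `FPR = prev·sens·(1−ppv) / ((1−prev)·ppv)` (≈ 0.0064 at the defaults),
  because triage performance is reported as sensitivity and PPV, not FPR.
  An infeasible triple (implied FPR > 1) is rejected at configuration
  time. Calls without a registered diagnostic category (40% by default,
  the published test-year ratio) cannot be call-taker positive.
* **Onset noise.** Stroke onsets are uniform on −48 h…+12 h around the
  call, with 5% drawn outside the −72 h/+24 h linkage window so that the
  window-exclusion code path is exercised; 5% of registry entries are
  subarachnoid haemorrhage (SAH), which ground-truth labelling must
  exclude. No published distribution exists for either; these are the
  package's own choices, fixed once.
* **Transcripts.** Background text is Zipf-distributed (exponent 1.05)
  over a 250-word synthetic lexicon, with negative-binomial document
  lengths (mean 40 tokens). Ten indicator words (seeded from English
  translations of high-ranking stroke words: *ambulance*, *blood_clot*,
  *left*, …) are injected into stroke transcripts at rate 0.4 per word
  (1–2 copies), and leak into non-stroke transcripts at rate 0.002 — so a
  single leaked marker is, by Bayes' rule, overwhelmingly likely to be a
  false lead, and a good classifier must learn to require corroboration.
  Ten distractor words are injected into non-stroke calls at rate 0.15.

What the generator does **not** emulate: real (Danish) speech, automatic
speech recognition error structure, correlated symptom narratives, repeat
callers, or temporal drift. Passing tests on this cohort therefore
demonstrate that the pipeline's machinery is correct and that it recovers
planted structure at realistic prevalence — not that the classifier would
reach any particular performance on real calls.

The cohort spans 2019–2021 with 2021 as the test year. The published
study used seven years and 2.4 million calls; at the package's standard
50,000-call scale a three-year window keeps both sides of the split
adequately powered (the test year holds ≈ 9,000 category-carrying calls
and ≈ 20 ground-truth strokes; a seven-year window would leave fewer than
ten).

## Linkage and splitting

A call is ground-truth stroke positive when a registry entry shares its
patient id, is not SAH, and has onset within 72 h before to 24 h after
call start. Both window endpoints are closed (the source is silent on
boundary inclusion). When several entries qualify, the nearest onset is
kept — only the boolean matters downstream. A call whose only match is an
SAH entry is negative, but an SAH entry never masks a qualifying non-SAH
entry (the exclusion is read as applying to calls that are *only* SAH).
A call-taker positive requires both the stroke diagnostic category and an
appropriately prioritised ambulance dispatch; the cited response-level
taxonomy is collapsed to one boolean.

`split_dataset()` reserves helpline calls of the test year for testing
(those without a diagnostic category go to a separate `test_no_category`
side set), splits earlier helpline calls into a validation set (10% —
matching the published validation:training ratio) and five training
folds, stratified on (ground truth, category present). Category-less
calls train but never validate or test. Emergency-line calls are
training-only; those from the test year are discarded to avoid temporal
overlap. The fold round-robin processes ground-truth-positive strata
first with a rotation counter that persists across strata, which keeps
per-fold positive counts within one call of equal even though positives
span several strata.

## Features

Transcripts are tokenised (lowercase, whitespace split, flanking
punctuation stripped — the rule makes "word" well defined for occlusion)
and encoded as counts of word n-grams and *within-word* character n-grams
with explicit boundary markers (`_word_`). Keeping character n-grams
inside word boundaries means every feature is attributable to exactly the
tokens it came from, which the occlusion analysis depends on; whether the
original features crossed word boundaries is unpublished, so this is a
documented reconstruction choice. Counts (not binary presence) are the
module-level default cell values, with binary presence as a flag; the
pipeline turns the flag on (see below).

The vocabulary is built from training folds only: features below a
document-frequency threshold are dropped, and an oversized vocabulary is
capped keeping the highest document frequencies (lexicographic
tie-break) — a deterministic stand-in for an unpublished feature-selection
procedure. Module defaults are word 1–2-grams, character 3–5-grams,
`min_doc_freq = 5`, cap 50,000. The *pipeline* default uses word
1–2-grams only with `min_doc_freq = 50`: at the 50k-call scale the
planted markers appear in well over 100 training documents, while a small
threshold would admit tens of thousands of noise bigrams; a
document-frequency *cap*, by contrast, is the wrong instrument here
because it preferentially keeps common background features and can crowd
out rare informative ones. The pipeline also encodes *presence* rather
than counts (the features module's binary flag): with only ~100 training
positives, counts of common background words act as a document-length
proxy that binary cross-entropy cannot unlearn, systematically punishing
long transcripts; presence features remove that channel while preserving
the distinct-marker evidence the decision actually needs.

## Classifier

Each ensemble member is an MLP ending in a single sigmoid output, trained
with Adam on (optionally class-weighted) binary cross-entropy over sparse
feature matrices. Five members rotate the early-stopping fold: member *k*
stops on fold *k* and trains on the other four plus the emergency-line
data (omitting it reproduces the ablation arm). Members share nothing but
the data; retraining one in isolation reproduces it bit for bit.

Early stopping evaluates the stop fold's F1-score at threshold 0.5 after
every epoch (whether the original used 0.5 or a calibrated threshold is
unstated; 0.5 is chosen). The best-F1 weights are checkpointed, an epoch
*tying* the best refreshes the checkpoint, and training stops after
`patience` epochs strictly below the best. The tie-refresh convention
matters at extreme class imbalance: with only a dozen positives in the
stop fold, F1 plateaus early while the decision boundary is still
consolidating, and keeping the latest plateau checkpoint retains that
consolidation instead of freezing a barely-trained model.

Minibatches are drawn by shuffling once per training run and fixing the
partition across epochs: row-slicing a compressed sparse matrix costs a
full non-zero scan per slice, so per-epoch reshuffling would dominate the
runtime at no measurable benefit on these data.

Pipeline defaults: one hidden layer of 32 ReLU units, no dropout,
learning rate 0.01, batch 1024, ≤ 30 epochs, patience 6, L2 10⁻³, no
class reweighting. The L2 strength is deliberately firm: it compresses
the score noise floor of uninformative features so that background
negatives cluster tightly, which keeps the calibrated threshold (see
below) out of the noise and the calibrated operating point sharp. The
module-level `mlp_config()` default (2×256 units, dropout 0.3) documents
a conventional architecture for larger corpora; a grid search over
arbitrary configuration lists is provided (`grid_search()`, demonstration
grids only — the original 96-point grid is unpublished).

## Calibration and ensembling

For each member, two thresholds are located on the validation split
(which split the original calibrated on is unstated; validation is the
package's choice, and the test split is never touched): `t_sens`, the
largest threshold with sensitivity ≥ the call-taker's 52.7%, and
`t_ppv`, the smallest threshold with PPV ≥ the call-taker's 17.1%.
Exact equality is unattainable on a finite sample, so "matching" is
defined by this ≥-with-extremal-selection convention over the finite
candidate set of observed scores plus 1 (a zero candidate is redundant
under `score ≥ t` decisions and would make the harmonic mean ill
defined). An unattainable reference PPV raises an error naming the
maximum attainable value. The member threshold is the harmonic mean
`τ = 2·t_sens·t_ppv/(t_sens + t_ppv)`.

Members are combined in logit space: each member's logit is centred by
`logit(τ_n)`, giving every member the common threshold 0.5, and the
ensemble score is `sigmoid(mean_n(z_n − logit(τ_n)))`. The exact centring
equations are unpublished in the main text; these formulas are a literal
reconstruction of its description, and the identity "all members at their
thresholds ⇒ ensemble score 0.5" is enforced by test.

## Evaluation

Reported metrics are F1, sensitivity, PPV, FOR (= 1 − NPV) and FPR
(= 1 − specificity); at 99%+ NPV/specificity the complements carry the
usable variance. Comparisons on the same calls use one-sided *paired*
approximate permutation tests: the null swaps each call's prediction pair
with probability ½, the same swap mask is applied to every training run,
the statistic is the run-averaged metric difference, and p-values use
add-one smoothing, `p = (1 + #{null ≥ obs}) / (1 + n_perm)` (defaults
n_perm = 10,000; the alternative direction is always an explicit
argument, never inferred from the data). Comparisons across disjoint
subsets use one-sided *independent* permutation tests that reassign calls
preserving group sizes. 95% CIs come from a percentile bootstrap that
resamples calls with replacement (as multinomial weights, shared across
runs) and averages the metric over runs; undefined replicates are skipped
and counted. Following the original, means, tests and CIs aggregate 11
randomly initialised training runs, the call-taker contributes one
deterministic prediction vector broadcast across runs, and no
multiple-testing correction is applied.

## Occlusion explainability

The impact of word *w* on document *d* is the mean over members of the
logit change when every instance of *w* is removed *before*
vectorisation, so all word and character n-grams touching *w* disappear:
`i(d,w) = (1/N) Σ_n (z(n,d) − z(n,d,w))`. Logits, not sigmoid scores, are
differenced — near-saturated scores would bias score-space differences
toward zero, and a test pins the implementation to logit space. Words are
ranked by the signed-square sum `r(w) = Σ_d sgn(i)·i²`, which favours
rare high-impact words over common low-impact ones. `D_w` counts
*documents* containing the word (the ranking sums over documents, making
that the natural reading of an ambiguous printed column). Candidate words
are the vocabulary's unigrams; words occurring in no analysed document
are excluded. The analysis runs on the run with the median validation F1
of the 11 (even run counts are an error at the module level; the pipeline
smoke path falls back to the lower median). The predicted-non-stroke
group is orders of magnitude larger than the predicted-stroke group, so
the negative list is computed on a deterministic 500-document subsample.

## Problem sizes and numerical choices

The standard study is 50,000 calls with 11 training runs (≈ 10 minutes on
one CPU); the smoke configuration is 2,000 calls, 2 runs, and a 5%
prevalence so that every stratum is populated at that size. Scores and
logits agree through a numerically guarded sigmoid to < 10⁻¹²; metric
ratios are exact doubles; permutation and bootstrap machinery is
vectorised (swap masks and multinomial weights as matrices) and chunked
to bound memory. All randomness flows from one integer: every stage
derives its seed as a deterministic function of the global seed and the
stage name, and generation, training and evaluation are bit-reproducible
under a fixed seed.

## Known limitations

The synthetic transcripts make the planted signal conditionally
independent given the label, which is kinder to a bag-of-words model than
real speech; sensitivity near 1 on synthetic cohorts says nothing about
real-world sensitivity. Ground-truth positives at 0.25% prevalence are
scarce (≈ 20 in the test year), so test-set metrics carry wide intervals
and the paired tests lean on large effect sizes. The calibration
transfers a validation threshold to the test year under a stationarity
assumption the generator satisfies by construction but real data need
not. The speech-recognition stage of the original system is out of scope
throughout: transcripts are taken as given.
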