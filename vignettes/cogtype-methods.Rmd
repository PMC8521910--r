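---
title: "Digital biomarkers from typing and written speech: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital biomarkers from typing and written speech: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cogtype` implements a screening pipeline for mild cognitive impairment
(MCI) built on two unobtrusive data streams: keystroke timing collected
while a person types on a touchscreen, and short free-form texts they
write. This vignette documents the models, the tunable parameters and the
design decisions, so that a user can judge what the pipeline assumes and
what its validation on synthetic cohorts does and does not establish.

## Keystroke dynamics

A typing session is a sequence of paired press/release timestamps in
integer milliseconds; no character content is ever represented. From a
session with $N$ key events we derive, in seconds,

* hold times $HT_n = t^r_n - t^p_n$ for $n = 1 \dots N$, and
* flight times $FT_n = t^p_{n+1} - t^r_n$ for $n = 1 \dots N-1$.

Flight times may be negative under rollover typing (the next key is
pressed before the previous one is released); the filter below keeps
them, since only an upper bound is meaningful.

Three preprocessing parameters matter:

* `min_presses = 40` — sessions with 40 or fewer key presses are dropped
  (strictly more than 40 are kept). Short sessions carry too little
  signal for the sequence models.
* `ht_max = 0.700` s, `ft_max = 3.0` s — hold times and flight times at
  or above these bounds are removed (strict `<`). The hold-time bound is
  read as 700 ms: typical key holds are on the order of 100 ms, so a
  microsecond-scale bound would be physically meaningless, and 700 ms is
  the conventional upper bound in the keystroke-dynamics literature. The
  flight-time bound removes between-burst pauses (thinking, app
  switching) that do not reflect motor execution.
* `length = 100` — filtered series are zero-padded at the tail to fixed
  length 100; longer series are truncated to their first 100 values,
  keeping the earliest, least-fatigued typing. Whether long sessions
  should instead be split is an open question; truncation is the
  simplest choice that preserves a fixed input dimensionality.

## Linguistic features

Texts arrive as dependency-parsed CoNLL-U documents (the package does not
tokenize, tag or parse; any UD-style tagger can produce its input). Word
tokens are all non-`PUNCT` tokens, and the vocabulary is the set of
case-folded surface forms; both choices are configurable in spirit but
fixed here because the worked example that anchors the arithmetic counts
words without punctuation. With $W$ word tokens, $V$ distinct forms and
$hap$ forms occurring exactly once:

* lexical diversity $dvrst = V/W$;
* Brunet index $BI = W^{V^{-0.165}}$ — lower for richer language;
* Honoré statistic $HS = 100 \ln W / (1 - hap/V)$ — higher for richer
  language; the natural logarithm is the classical choice. When every
  form is a hapax ($hap = V$) the statistic is undefined and flagged
  `NA` rather than raised as an error;
* mean words per sentence `wrd_sent`;
* `nonstop` — the fraction of the vocabulary that is not in a
  user-supplied stopword list (plain text, one word per line);
* word-class ratios $NnVrb = nn/vrb$, $Nn = nn/(vrb+nn)$,
  $Prn = prn/(nn+prn)$ over tokens tagged `NOUN`, `VERB`, `PRON`. Only
  `NOUN` counts as a noun by default; `PROPN` can be added through
  `noun_tags` for tagsets that separate proper nouns. Zero denominators
  yield `NA` sentinels.
* mean dependency distance: per sentence,
  $MDD = \frac{1}{N-1}\sum_i |DD_i|$, where $DD_i$ is the difference of
  the 1-based positions (counted over word tokens) of a non-root token
  and its head, and $N$ is the sentence's word-token count; the document
  value is the mean over sentences. Tokens are enumerated by pre-order
  traversal of the dependency tree, which visits each node once, so the
  result provably equals the direct per-token sum — the test suite
  asserts that equality on random trees. The root contributes no
  distance term; sentences with fewer than two word tokens are skipped.

Per-subject features are the field-wise means over the subject's
documents, ignoring `NA` sentinels per field, so one degenerate text
cannot poison a subject's profile.

## Fine-motor-impairment indices

Three severity indices — rigidity (R), bradykinesia (B) and alternate
finger tapping (AFT), each on the clinical 0–4 scale — are estimated per
typing session by a small neural network:

* **Encoder**: two 1-D convolutional layers (kernel size 5, 16 filters,
  "same" padding, no pooling) over a 2×100 input whose channels are the
  padded hold-time and flight-time series.
* **Pretraining**: a mirrored two-layer convolutional decoder is
  attached and the autoencoder is trained to reconstruct sessions
  (mean-squared error, RMSprop, learning rate $10^{-3}$, 50 epochs,
  mini-batches of 64, 80/20 train/validation split). This stage is
  unsupervised and needs only unlabeled sessions.
* **Fine-tuning**: for each symptom separately, the decoder is replaced
  by a temporal mean pool followed by a dense layer of 50 hidden units
  (ReLU) and a linear output; the whole network is fine-tuned end-to-end
  (RMSprop, 50 epochs, mini-batches of 32) against the symptom's 0–4
  score, with leave-one-subject-out (LOSO) cross-validation. Predictions
  are clipped — not squashed — to $[0, 4]$.

The mean pool between encoder and head is a deliberate choice: flattening
the 16×100 encoding would put ~80k parameters into the first dense layer,
far beyond what tens of scored subjects can constrain, while pooling
keeps the whole model in the 10³–10⁴-parameter range and makes the head
insensitive to where in the padded window the typing mass sits. The
model object reports its exact parameter count.

Training runs in compiled code (convolutions evaluated as im2col matrix
products through BLAS) with every shuffle order drawn from the R RNG, so
a fixed seed reproduces training bit-for-bit; a pure-R reference
implementation of the same loop is kept internally and the test suite
asserts the two paths agree to machine precision.

The clinical regression targets are UPDRS Part III single-item scores
(item 22 → R, item 23 → AFT, item 31 → B). Because clinical keystroke
datasets are private, the package validates the estimator by parameter
recovery on synthetic severity data (below): LOSO Spearman correlation
between predicted indices and generator ground truth, with a
label-shuffled control. Correlations reported for real clinical cohorts
elsewhere are not binding for this artifact.

Subject-level keystroke features for classification are the per-subject
means of the session indices; alternatives (medians, distribution
summaries) would slot into the same interface.

## Classification experiments

Cohorts are tables with one row per subject, binary labels (MCI = 1,
HC = 0), linguistic features and/or index features. The machinery:

* **Univariate selection** ranks features by their one-way ANOVA F
  statistic against the label; constant features score 0. The
  experiment presets (`feature_preset()`) record the documented optimal
  sets: `nonstop, dvrst, HS, MDD` for the language experiment; the `B`
  and `R` indices for the keystroke experiment; `nonstop, dvrst, MDD`
  and `B, R` for the two first-stage models of the fused experiment.
* **Classifiers**: ridge logistic regression (L2 strength 1.0 — the
  penalty also tames quasi-separation, which otherwise produces
  confident wrong-side predictions on strongly separated cohorts),
  random forest (100 trees), and k-nearest neighbours with $k = 7$.
  Within every training fold, features are standardized to zero mean and
  unit variance using that fold's statistics only.
* **LOSO**: each subject is scored by a model never trained on them.

### Calibration under leave-one-subject-out

Two artifacts make naive LOSO pipelines anti-predictive on label-free
data, and both are corrected by construction:

1. *Prior tilt.* Holding out a subject leaves the training fold with one
   fewer member of their class, biasing every score toward the opposite
   class. All fits are therefore prior-balanced: class-weighted
   logistic regression, stratified balanced bagging in the forest, and
   prior-corrected vote shares for k-NN.
2. *Composition coding in cascades.* In a stacked (cascaded) model, the
   held-out subject's first-stage probability is produced by a fit whose
   class composition differs from the fits that produced the training
   rows' probabilities. That difference shifts the feature's
   calibration — and, for k-NN vote shares, the exact discrete support
   of its values — in a way that encodes the held-out label, and a
   flexible second-stage learner decodes it (on synthetic label-free
   cohorts this drove cascade AUCs to 0.01–0.03, i.e. near-perfect
   anti-prediction). The package therefore balances the inner folds:
   every first-stage fit leaves out exactly one subject of each class
   (the scored subject plus a rotating opposite-class partner), making
   all stacking features exchangeable. With this construction null
   cascades are calibrated while fully separable cohorts still reach
   AUC 1, as the test suite asserts.

The `nested = FALSE` variant of `cascade_predict()` computes first-stage
probabilities once, by a single LOSO over the whole cohort, and reuses
them in every outer fold. Its second stage then trains on features whose
fits saw the held-out subject; on null data this inflates the AUC well
above 0.5. It exists solely as the regression test documenting why
nesting matters.

The probability forest uses enlarged terminal nodes
(`nodesize = max(5, n/5)`): with a few dozen training subjects, a fully
grown forest returns near-0/1 step-function vote shares whose
fold-to-fold jitter dominates stacked scores; larger leaves give smoother
probability estimates, standard practice for probability machines at
small n.

### Cascade designs

With first-stage models *just-language* (ridge logistic regression on
`nonstop, dvrst, MDD`) and *just-keys* (7-NN on `B, R`):

* **A** — probability of just-language + the `B` index → random forest;
* **B** — probability of just-keys + `dvrst, nonstop, MDD` → 7-NN;
* **C** — probability of just-language + probability of just-keys →
  random forest.

### Evaluation

Out-of-fold scores are summarized by bootstrap ROC analysis: subjects
are resampled with replacement 1,000 times (one-class resamples are
redrawn, not skipped), and the mean AUC with 2.5/97.5-percentile bounds
is reported. The operating point maximizes the Youden index
$J = SE + SP - 1$ over all distinct score thresholds, with a
score $\ge$ cutoff predicting MCI and `Inf` (predict nobody) as an extra
candidate; ties are broken toward the higher-specificity point, matching
the screening use case where false alarms are the costlier error.
Accuracy, specificity and sensitivity are computed at that cutoff on the
pooled out-of-fold scores. Because the bootstrap resamples subjects of
one realized prediction set, it does not see model-refit variability; at
cohorts of ~50 subjects the across-cohort spread of stacked-cascade AUCs
is comparable to the bootstrap interval's width, so single-cohort CIs
should be read with that in mind.

`clinical_correlation()` reports the Pearson r (with two-sided p)
between per-subject predictions or features and clinical scale scores
(MMSE, FUCAS, FRSSD), returning `NA` when either side has zero variance.

## The synthetic cohort generator

Every model above is exercisable without any private data through a
generator whose defaults were fixed once, before validation, at values a
practitioner would call realistic:

* **Typing**: hold times and inter-key gaps are log-normal — the
  standard model for keystroke latencies — with base medians 0.10 s (HT)
  and 0.35 s (FT), within-session log-SDs 0.25/0.45, and subject-level
  log-location SD 0.08. Long pauses (> 3 s) are injected at rate 0.04 to
  exercise the flight-time filter; session lengths are log-normal around
  80 key events so the 40-press QC bar is exercised from both sides.
  Timestamps are quantized to whole milliseconds and assembled so the
  hold/flight equations recover the drawn values exactly.
* **Texts**: token forms are Zipf-distributed over 500 content forms
  (base exponent 1.05) plus a 40-form stopword lexicon inserted at rate
  0.35; POS tags are drawn from a subject-level multinomial (content
  base rates NOUN 0.32, VERB 0.24, PRON 0.10); each sentence gets a
  random single-root attachment tree whose exponential distance-decay
  scale controls the mean dependency distance, with a trailing `PUNCT`
  full stop attached to the root.
* **Severity data**: subjects span severities 0–4; severity acts
  monotonically on the typing parameters (+0.12 per point on the
  hold-time log-location, +0.06 on its log-SD, +0.10 on the flight-time
  log-location), and the three item scores are noisy integer readings of
  one latent severity, which induces their inter-item correlation.
* **Group effects** are standardized shifts (Cohen's d on the
  subject-parameter scale) applied to the MCI group in the directions
  reported for cognitive impairment: longer and more variable key
  holds, slower flights, steeper Zipf exponent (poorer lexical
  richness), fewer stopwords, lower noun rate, higher pronoun rate,
  shorter dependency distances. Clinical scores are generated from the
  same latent impairment with the expected signs (MMSE down; FUCAS and
  FRSSD up). The hold-time dial is calibrated: the measured standardized
  group difference on session-mean hold times tracks the requested d,
  which the test suite checks at 200 subjects per cohort averaged over
  three seeds.

Two presets define the validation conditions: `null_cohort_spec()` (25 +
25 subjects, every effect zero — the groups are exchangeable, so any
experiment's AUC interval must cover 0.5) and `powered_cohort_spec()`
(study-sized cohort, d = 3 on hold-time location and d = 2 on the other
dials — the group difference dominates sampling noise, so language- and
keystroke-experiment AUCs must be high).

What the generator does **not** emulate: real (Greek) morphology and
syntax, within-session autocorrelation of timings, typing fatigue,
demographic or depression covariates, and inter-feature dependence
beyond what the shared latent parameters induce. Passing the synthetic
validation therefore establishes that the pipeline recovers known signal
and stays calibrated on known noise — not that it attains any particular
accuracy on clinical data.

## Problem sizes in the test suite

The suite fixes its own scales: 30 subjects × 20 sessions for the
severity-recovery experiment (with a session-level label-shuffle
control), 50-subject null cohorts and study-sized powered cohorts for
the classification checks, 500 random documents and 1,000 random
sessions for the formula oracles, and 50 random prediction sets for the
threshold-enumeration oracle. Seeds are fixed throughout; all training
is deterministic given the seed.

## Known limitations

* The architecture description leaves the exact head wiring open; the
  pooled head chosen here is small and length-robust, but it is one of
  several defensible readings, and the package reports its own
  parameter count rather than matching a printed total.
* Aggregating session indices by the mean is a choice; subjects with
  many sessions could also be summarized by robust statistics.
* The cascade's balanced inner folds remove the label-coding artifact
  but cannot remove the genuine variance of stacking at a few dozen
  subjects; cascade intervals at this scale are wide and their point
  estimates unstable across cohorts.
* CoNLL-U input is trusted: the package validates tree invariants
  (single root, in-range heads) but cannot detect tagging errors, which
  propagate into the word-class ratios.
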