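# cogtype

Digital biomarkers for cognitive screening from touchscreen typing and
spontaneous written speech.

Mild cognitive impairment (MCI), the prodromal stage of Alzheimer's
disease, degrades both language production and fine motor control years
before clinical tests catch it. `cogtype` turns two streams of routine
smartphone data into screening features and evaluates how well they
separate MCI patients from healthy controls:

* **Keystroke dynamics** — per-session hold times
  (`HT_n = t_r(n) − t_p(n)`, press-to-release) and flight times
  (`FT_n = t_p(n+1) − t_r(n)`, release-to-next-press), filtered
  (`HT < 0.7 s`, `FT < 3 s`), zero-padded to length 100, and mapped by a
  1-D convolutional autoencoder with fine-tuned regression heads to three
  fine-motor-impairment indices on the clinical 0–4 scale: rigidity (R),
  bradykinesia (B) and alternate finger tapping (AFT).
* **Linguistic biomarkers** — nine features from dependency-parsed
  CoNLL-U texts: lexical diversity `V/W`, Brunet index `W^(V^-0.165)`,
  Honoré statistic `100·ln(W)/(1 − hap/V)`, mean words per sentence,
  non-stopword vocabulary fraction, noun/verb and pronoun ratios, and
  the mean dependency distance `MDD = Σ|DD_i|/(N−1)` averaged over
  sentences.
* **Cascaded classification** — leave-one-subject-out experiments with
  ridge logistic regression, random forest and 7-NN; stacked designs
  that fuse language-model and keystroke-model probabilities; bootstrap
  ROC analysis (1,000 resamples) with Youden-optimal operating points;
  Pearson correlation against clinical scales (MMSE, FUCAS, FRSSD).
* **A synthetic cohort generator** with controllable standardized group
  effects, so the entire pipeline is testable end-to-end without any
  clinical data.

The intended users are researchers prototyping remote screening methods
and anyone who needs a reproducible, fully synthetic testbed for
keystroke/language biomarker pipelines.

## Worked example

```r
library(cogtype)

# --- mean dependency distance of a parsed sentence ---------------------
sentence <- data.frame(
  id   = 1:8,
  form = c("I", "am", "the", "grandmother", "of", "a", "wonderful", "grandson"),
  upos = c("PRON", "AUX", "DET", "NOUN", "ADP", "DET", "ADJ", "NOUN"),
  head = c(4L, 4L, 4L, 0L, 8L, 8L, 8L, 4L))
doc <- parsed_document("demo", "subj1", list(sentence))
compute_mdd(doc)
#> [1] 2.285714

# --- keystroke dynamics of one session ---------------------------------
session <- typing_session("s1", "subj1",
                          press   = c(0, 350, 720, 1100, 5600),
                          release = c(130, 480, 840, 1230, 5750))
dyn <- pad_series(filter_dynamics(compute_dynamics(session)))
dyn$ht
#> [1] 0.13 0.13 0.12 0.13 0.15
dyn$ft   # the 4.37 s pause before the last key was filtered out
#> [1] 0.22 0.24 0.26

# --- a language-features experiment on a synthetic cohort --------------
cohort <- simulate_cohort(powered_cohort_spec(seed = 7))
tab <- cohort_feature_table(cohort)
run_experiment(tab, classifier = "logistic_regression",
               features = feature_preset("exp1"), seed = 7)
#> AUC 0.95 (bootstrap mean 0.95, 95% CI 0.85-1.00, 1000 resamples)
#> accuracy 0.87, specificity 0.75, sensitivity 1.00 at cutoff 0.34
#> classifier: logistic_regression; features: nonstop, dvrst, HS, MDD
```

The MDD of the example sentence is 16/7 ≈ 2.29: the root "grandmother"
heads "I", "am", "the" and "grandson" (distances 3, 2, 1, 4) and
"grandson" heads "of", "a" and "wonderful" (3, 2, 1), giving
(3+2+1+4+3+2+1)/7. The experiment output reads: across
leave-one-subject-out folds, the ridge logistic-regression model ranks
MCI subjects above controls with a bootstrap-mean AUC of 0.95, and at
the Youden-optimal probability cutoff of 0.34 it classifies 87% of
subjects correctly. On a null cohort (`null_cohort_spec()`) the same
call produces an AUC interval straddling 0.5.

Training the fine-motor models end-to-end and the fused cascade designs
(`cascade_predict()`, designs A/B/C) follow the same pattern; see the
methods vignette (`vignettes/cogtype-methods.Rmd`) for the full model
descriptions, calibration design and generator details. A thin
command-line front-end is provided in `inst/cli/cogtype.R`.

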