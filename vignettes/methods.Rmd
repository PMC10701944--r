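---
title: "Attention models for clinical risk prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention models for clinical risk prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
assumptions behind them, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The prediction problem

Each observation is a (person, index date) pair with a binary outcome
ascertained over a fixed time-at-risk after the index date; the label is
assumed precomputed. Predictors are drawn exclusively from the observation
window — the 365 days up to and including the index date. Including the
index date itself is a deliberate default (`include_index_date = TRUE`):
events recorded on the day of the anchoring visit are usually legitimate
predictors in primary-care data, but the flag exists because same-day
coding can leak the outcome in some designs.

Two representations are built from the same events:

* **Windowed binary matrix.** Feature `(c, w)` is 1 iff concept `c` occurs
  in `[index − w, index]`, for `w` in {365, 180, 30}. Both window endpoints
  are inclusive. Features present in fewer than 0.1% of observations are
  removed (a column at exactly the cutoff is kept — removal is
  strictly-less-than). Numeric columns (age) are divided by their maximum
  absolute value **computed on training rows only**; held-out values may
  exceed 1 and are left as they are. Fitting the scaler on all rows would
  leak information from the evaluation folds, so the scaler object is
  carried with the matrix for reuse.
* **Visit sequences.** One visit = one calendar date per person. Flat event
  files carry no visit identifiers, and general-practice records are
  effectively date-keyed, so the calendar date is the natural visit key.
  Concepts are deduplicated within a visit. Sequences are capped at
  `max_visits = 50` by default (20 in the desk-scale experiments),
  truncating the *oldest* visits, since recent history is the more
  predictive end. Visits are padded and masked for batching.

Splits are by person, never by observation: a person's visits all land in
one fold. Test persons are drawn first (25%), then 33% of the remaining
persons go to validation.

## Architectures

**Two-level attention recurrent model (`fit_retain`).** Visit embeddings
are sums of the embeddings of the concepts in the visit; scaled age, sex
and the scaled visit time (`days_before_index / 365`) are concatenated —
the time encoding is a design choice, as only "visit times are
concatenated" is conventionally specified. Two *bidirectional* LSTMs read
the sequence; bidirectionality makes the classic reversed-time processing
of this architecture moot, so visits are processed oldest-to-newest. One
LSTM produces a scalar per visit, softmax-normalized over real (unpadded)
visits into the visit-level attention α; the other produces a per-dimension
tanh gate β. The risk score is a logistic read-out of
Σ_t α_t (β_t ⊙ v_t). Padded visits receive exactly zero attention; an
observation with no qualifying events gets a single learned null-visit
token so that age and sex still drive a prediction.

**Transformer (`fit_transformer`).** The concatenated visit vector (summed
concept embeddings, age, sex) is projected to the model width; a sinusoidal
embedding of the day offset is added (the standard interleaved sin/cos
encoding evaluated at `days_before_index`). Statics are concatenated
per visit rather than appended once at the head — the open choice was
resolved for symmetry with the recurrent model. Blocks are **pre-norm**
(layer norm inside the residual branch), chosen for training stability at
small scale. The prediction head is convolutional: two kernel-3
convolutions over the visit axis, ReLU, masked max-pool over visits,
linear read-out. A diagnostic mean-pool head (`head = "mean"`) exists
because it makes the permutation-equivariance of the attention stack
directly testable.

**Reverse distillation (`fit_sard`).** The transformer student is first
trained to match a linear teacher's predictions on the training fold, then
finetuned on the validation fold with
`alpha * teacher-matching + (1 − alpha) * weighted BCE`. The
teacher-matching loss is **MSE on logits**: the distillation loss form is
an open choice, and MSE on logits matches the teacher's predictions exactly
at its optimum and is scale-stable near saturated probabilities
(soft-label cross-entropy is available conceptually but was not needed).
`alpha` multiplies the teacher term, so high `alpha` constrains the student
to stay near the linear model. Finetuning on the validation fold reuses
rows later used for Platt recalibration; that is the stated recipe and is
implemented as stated, but it is worth flagging as a methodological caveat.

All networks and their backpropagation are implemented directly in R matrix
code; every analytic gradient is checked against central finite differences
in the test suite (worst-case error around 1e-10 at `eps = 1e-6`).

## Training procedure

The objective is class-weighted binary cross-entropy with the
positive-class weight equal to the negative:positive ratio of the training
labels; scores are clamped at 1e-7 before logs. The optimizer is Adam
(adaptive moments); an optional decoupled weight decay on weight matrices
exists for heavily overparameterized settings but defaults to off. Early
stopping monitors validation loss with patience 3; the learning rate is
divided by 10 after a single stagnant epoch; best-validation weights are
restored. The controller is factored into a pure function
(`schedule_trace`) so the stopping and decay rules can be verified on
scripted loss traces independently of any model.

One consequence worth knowing: patience is counted in *epochs*, so on
small data — where an epoch is a few dozen optimizer steps — the protocol
is far more aggressive than on millions of observations. The desk-scale
experiments therefore use moderately small batches (more steps per epoch)
and learning rates at which the first epochs improve validation loss
steadily.

Hyperparameter search (`tpe_search`) is a tree-of-Parzen-estimators
sampler: trials are split at the top-25% quantile of the objective,
one-dimensional Parzen (Gaussian-mixture) densities are fit to the good and
bad trials, candidates are drawn from the good density and ranked by the
good/bad density ratio, dimension-wise. A random-search backend is the
fallback. The desk-scale default budget is 20 trials; large-scale practice
would use 100 or more. After selection, `refit_final` replays the recorded
epoch count and learning-rate schedule on train+validation without
monitoring.

## Evaluation

* **AUC** is the Mann–Whitney statistic (ties count one half); its interval
  is DeLong's, with placement values computed by the fast midrank
  algorithm, verified in tests against the quadratic structural-components
  form.
* **AUPRC** is average precision (step-wise, no interpolation — trapezoidal
  interpolation is optimistic for precision–recall curves). The interval is
  a normal interval on the logit of average precision with standard error
  `1/sqrt(n_pos · AP · (1 − AP))`; a stratified bootstrap is available via
  `n_boot` since interval variants for average precision differ across the
  literature.
* **Recalibration.** Class-weighted training deliberately miscalibrates, so
  every model (baselines included, for fairness) is Platt-recalibrated:
  slope and intercept on the logit scale, fit by maximum likelihood on the
  validation fold. The logistic score equation guarantees the mean
  recalibrated score equals the event rate on the fitting fold; the test
  suite asserts this to 1e-6.
* **Smooth calibration** regresses the outcome on a restricted cubic spline
  basis of logit(score), 5 knots at Harrell's standard quantiles (0.05,
  0.275, 0.5, 0.725, 0.95), with a pointwise normal band on the link scale
  and a density summary of the predictions. With too few distinct scores
  the knot count is reduced with a warning; near-constant scores fall back
  to the event-rate line.
* **Decision curves** report NB(t) = TP/N − FP/N · t/(1−t) for score ≥ t,
  against treat-all (π − (1−π)·t/(1−t)) and treat-none (zero). The default
  grid is 0.001–0.5 in steps of 0.001: beyond 50% threshold probability no
  strategy in this setting retains benefit, and the grid is configurable.
* **Hyperparameter importance** fits a random-forest surrogate of
  validation AUC on the trial log and attributes predictions by *exact*
  interventional Shapley values (exhaustive coalition enumeration against a
  background sample, feasible for ≤ 12 hyperparameters). Exhaustive
  enumeration makes the efficiency property — attributions plus base value
  equal the surrogate's prediction — exact rather than approximate.

## The synthetic generator, and what passing tests mean

`generate_ehr` emulates the regime of sparse primary-care data: a
power-law concept popularity (rank^−0.6) over 1000 concepts, Poisson visits
(mean 8/year) with Poisson concepts per visit (mean 2), giving a
365-day-window matrix density of 1–2%; outcome prevalence targeted at
1–10% by solving the intercept via bisection (tolerance 1e-4) on the mean
sigmoid risk. The risk mechanism has three parts: static log-odds on
concept presence, an extra boost when any causal concept occurs within 30
days of index, and an age effect. Two canned regimes are shipped:
`config_static_signal` (five effects with |β| ≥ 1; used for sign-recovery
checks) and `config_recency_signal` (small static effects, recency boost
1.5; used for the temporal-mechanism experiments).

The generator does **not** simulate medical ontologies, care pathways,
comorbidity structure, informative visit timing, censoring, or
measurement values. Passing tests therefore demonstrate that the
implementations are correct and that the architectures can exploit the
mechanisms the generator plants — not that any architecture will beat a
baseline on real records.

One generator subtlety is deliberate: the 30-day recency mechanism is
exactly representable by the `(c, 30)` window feature, so a three-window
static model captures it fully and temporal models have no headroom against
it — which mirrors the practical finding that well-featurized static
baselines are competitive. The temporal-advantage experiments therefore
compare against the static linear model on the **365-day window only**, the
static representation informationally equivalent to the sequences' concept
content; what the temporal models add on top is precisely the event timing.
At desk scale the vanilla networks land at or just below that baseline, and
the reverse-distilled transformer — initialized at the linear model's
function and finetuned on labels — clears it; the acceptance suite asserts
the advantage in at least 2 of 3 training seeds, and non-inferiority of the
distilled model to the from-scratch transformer in all 3.

## Numerical choices and degenerate inputs

* Probabilities are clamped to [1e-7, 1 − 1e-7] before logits and logs.
* Constant scores make the Platt slope unidentifiable: the fit degrades to
  intercept-only with a warning.
* All-zero numeric columns are left unscaled with a warning.
* Ties in top-k coefficient selection break toward the lower feature index.
* Empty visit sequences are scored through a learned null-visit token.
* A non-finite training loss aborts with a diagnostic rather than
  continuing silently.
* Fold assignment, generation, initialization, shuffling and dropout are
  all driven by explicit integer seeds; identical seeds reproduce runs
  bit-for-bit (the pipeline test asserts byte-identical report JSON).

## Problem sizes used by the shipped experiments

The acceptance experiments use 20,000-person fixtures (the static one for
sign recovery, the recency one for the temporal experiments), a sequence
cap of 20 visits, and a transformer of width 16 (2 heads, depth 1,
feed-forward 32, conv channels 16/16): small enough to run on one CPU in
minutes per model, large enough that the planted mechanisms are
statistically recoverable. Distillation runs 25 epochs at learning rate
5e-3 (batch 256) — chosen so the student actually converges onto the
teacher (train-fold Spearman above 0.9) — followed by 5 finetuning epochs
at 3e-4.

## Known limitations

* Training is CPU-bound, dense-matrix R; it is meant for method study at
  desk scale, not for millions of observations.
* The TPE sampler treats dimensions independently (as the classic
  implementation does); correlated hyperparameters are explored less
  efficiently.
* The AUPRC interval is asymptotic; at very low positive counts prefer the
  bootstrap flag.
* Finetuning and recalibration share the validation fold, as stated in the
  recipe; with abundant data one would split them.
* The graph-attention family of models is intentionally out of scope.
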