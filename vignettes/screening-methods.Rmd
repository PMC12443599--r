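---
title: "Attention-based slide classification and dual-threshold screening triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based slide classification and dual-threshold screening triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milscreen)
```

# The problem

Targeted therapy for lung adenocarcinoma hinges on knowing the tumor's
*EGFR* mutation status before first-line treatment. Comprehensive
sequencing (NGS) is the ground truth but takes weeks; cartridge PCR
rapid tests return within days but consume scarce biopsy tissue and miss
uncommon variants. A classifier that predicts mutation probability
directly from the routine H&E slide costs nothing per sample, consumes
no tissue, and is available within the hour.

`milscreen` implements this stack at desk scale: weakly supervised
multiple-instance learning (MIL) over slide tiles with gated attention
pooling, attention-map introspection, ROC evaluation with bootstrap
confidence intervals, and — the clinical-translation core — a
dual-threshold triage calibrator that decides when the slide score alone
can replace the rapid test without degrading predictive values.

# The model

A slide is represented as a bag of $K$ tiles at the working resolution
(224 px at 0.5 µm/px, i.e. 112 µm squares). An encoder maps tile $k$ to
a feature vector $h_k \in \mathbb{R}^D$. The gated attention aggregator
scores each tile

$$ e_k = w^\top\!\left(\tanh(V h_k) \odot \sigma(U h_k)\right), \qquad
   a_k = \frac{\exp e_k}{\sum_j \exp e_j}, $$

pools the bag as $z = \sum_k a_k h_k$, and a logistic linear head maps
$z$ to the slide-level mutation probability. The probability is
invariant to tile order (the bag property), and the attention vector
$a$ is a probability distribution over tiles that supports
introspection: which regions drove the call.

Training minimizes per-slide binary cross-entropy with AdamW, sampling
a fixed number of tiles per slide per step. At reference scale such
models sample thousands of patches per step through a frozen or
fine-tuned foundation-model encoder; at desk scale the package ships
two pluggable encoders — a deterministic 27-feature statistics
descriptor (color moments, saturation, gray histogram, gradient and
high-frequency energy) and a seeded random convolutional filter bank —
and the encoder interface accepts any function from a tile to a
fixed-width vector, so externally computed foundation-model features
drop in unchanged. Training operates on the frozen encoder's features;
end-to-end encoder fine-tuning across GPU workers is deliberately out
of scope.

Defaults follow the reference configuration where one exists (tile size
224, mpp 0.5, attention hidden width H = 128, AdamW at learning rate
1e-4, 20 epochs); the fixtures in the test suite use a smaller,
faster configuration (H = 32, learning rate 1e-2, 30 epochs, 672 px
slides giving a 3×3 tile grid) chosen once as a realistic desk-scale
problem. The documented per-step patch budget of the reference system
is 6,624, with a reported split of 96 patches across 23 encoding
workers; those two figures are mutually inconsistent (23 × 96 = 2,208)
and we surface both in `train_config()` docs without resolving intent.
The desk default is 256 patches per step. When a slide holds fewer
tiles than the budget, the default mode uses every tile exactly once;
a with-replacement mode keeps the step size exact instead.

# Synthetic data: what it emulates and what it does not

Because clinical slides and cohorts are not redistributable, every
stage is testable against generators with known ground truth.

**Slides.** `generate_slide()` lays contiguous tissue blobs (a smooth
random field thresholded at the exact quantile of the requested tissue
fraction) in eosin-pink over a near-white background, and stamps a
high-frequency checker texture on a chosen fraction of tissue tiles of
mutant slides, recording the exact signal mask. This gives the MIL
training a planted, recoverable signal and gives tissue detection a
pixel-level ground truth. It does **not** emulate real histology:
nuclei, stain variation, scanner color profiles, pen marks and blur are
all absent. A pass on these fixtures demonstrates that the machinery —
tiling, encoding, attention, optimization, localization — works as
specified; it says nothing about accuracy on real tissue, which is
bounded by the encoder and data, not by this code.

**Cohorts.** `simulate_cohort()` draws NGS labels Bernoulli(prevalence)
and scores from the probit-transformed binormal model: latents
$z \sim N(\pm\mu/2, 1)$ by label, score $= \Phi(z)$. The separation is
calibrated in closed form, $\mu = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$,
so a cohort hits any target AUC exactly in expectation (a Beta-mixture
score model was rejected for lacking this closed form). Rapid-test
calls are independent Bernoulli at the configured sensitivity and
specificity; invalid/failed cartridges are not modeled. Variant
subtypes are assigned to mutants by a configurable categorical
distribution, uniform by default over the five clinically grouped
subtypes, because no per-variant prevalence is available to us;
variants are therefore *independent of the score*, which is exactly the
null hypothesis the variant-robustness analyses should not reject on
synthetic data. Event timestamps place median turnaround at 0.74 h
(AI), 48.78 h (rapid) and 435.26 h (NGS) with lognormal spread.

**Prevalence.** The default prevalence 0.39 is not a reported number:
it is obtained by inverting the PPV identity
$\mathrm{PPV} = \mathrm{sens}\,p / (\mathrm{sens}\,p +
(1-\mathrm{spec})(1-p))$ at the historical rapid-test benchmark
(sens 0.918, spec 0.993, PPV 0.988), giving $p \approx 0.386$
(`implied_prevalence()`).

**Seeding.** A single run seed fans out through `split_seed()` (a
deterministic hash of seed and component name) so each stage owns an
independent stream; adding a stage never perturbs another stage's
draws, and every stage is byte-reproducible.

# Tiling

The tissue detector computes per-pixel saturation, thresholds it by
Otsu's method floored at an absolute minimum saturation of 0.07 (so a
blank slide yields an empty mask rather than a split of sensor noise),
and removes connected components below 256 px. The grid includes the
cells of a regular 224 px lattice whose tissue coverage is at least
0.25 — both the inclusion rule and the per-tile threshold are our
choices, configurable, since no reference rule is available. Tiles are
0-based, origin top-left, half-open $[x, x+224)$, row-major. Inputs at
other resolutions are resampled to 0.5 µm/px before gridding, the
simplest consistent treatment of mixed 20×/40× scanners. Tissue
surface area is $n_{\text{tiles}} \times (224 \times 0.5/1000)^2$ mm²,
and per-cohort decile bucketing supports the area-stratified analyses;
fully tied areas collapse to one bucket and are flagged degenerate.

# Attention maps

Attention weights are standardized per slide — population standard
deviation, clipped to $[-4, 4]$ — and thresholded at $z > 3$ for the
high-attention region; the densest-region box maximizes contained
high-attention pixels over all placements of a square window (default
10% of the longer slide side), ties broken by smallest $(y, x)$.
Whether the $[-4,4]$ display scale of reference implementations is a
z-score of softmax weights, of pre-softmax logits, or a fixed display
transform is not decidable from public information; we compute it on
softmax weights and expose the choice. Zero-variance weight vectors
(uniform attention) map to all-zero z-scores by convention. Overlays
(full spectrum on a diverging map anchored at 0, high-only, and
inverted/obscured modes) are pure functions of their inputs, so repeat
renders are byte-identical.

# Evaluation

`roc_auc()` is the rank-based (Mann–Whitney) estimator, ties counted
½, exactly equal to pairwise enumeration. CIs are percentile bootstrap
with 1,000 resamples by default (BCa offers no closed-form match to a
stated procedure and was not used); resamples on which a statistic is
undefined are redrawn and counted, and a statistic undefined on more
than the requested number of draws errors out. Variant-restricted AUC
compares one variant's positives against the full wild-type pool by
default (the comparator is otherwise ambiguous); a within-group mode is
the alternative. Score-distribution comparisons default to
Kruskal–Wallis with pairwise Mann–Whitney follow-ups and no
multiplicity correction (Benjamini–Hochberg by flag).

# Triage calibration

The assisted workflow is a three-branch rule with two thresholds:
score $< t_{\text{neg}}$ → negative without rapid testing; score
$> t_{\text{pos}}$ → positive without rapid testing; otherwise the
rapid test decides. Boundary scores go to the rapid branch
(conservative: the strict inequalities are taken literally). Samples
in the rapid zone without a rapid result abort metric computation
rather than being dropped — silently dropping unresolved samples would
bias predictive values in exactly the unsafe direction.

`grid_evaluate()` computes assisted NPV, PPV and rapid-test reduction
over the full threshold grid ($t_{\text{neg}} \in [0, 0.5]$,
$t_{\text{pos}} \in [0.5, 1]$, step 0.001 — the corners are forced by
the corner identities, the step is our choice) by category-wise
threshold counting; a test asserts cell-for-cell equality with direct
per-sample screening. Two identities anchor the surfaces: at
$(0, 1)$ the workflow reduces nothing and equals the rapid test alone;
at $(0.5, 0.5)$ it replaces the rapid test by the score at cut 0.5.
Reduction is monotone along each threshold axis by skipped-set
inclusion. One empirical property is worth reporting but is not a
theorem and is not asserted: on label-informative score models,
widening the mid-zone does not push assisted NPV below rapid-alone
NPV in our simulations.

The noninferiority region marks cells whose assisted NPV *and* PPV
reach the benchmark values minus a margin (default 0; a CI-lower-bound
mode covers the case where the benchmark itself carries bootstrap
uncertainty). Operating points are selected as a constrained
maximization: `select_operating_points()` picks $k$ reduction levels
(the $i/k$ quantiles of the distinct feasible reductions, so the last
point is the most aggressive feasible one) and at each level returns
the feasible cell maximizing
$\min(\mathrm{NPV} - \mathrm{NPV}_b, \mathrm{PPV} - \mathrm{PPV}_b)$,
lexicographic tie-break. The balancing "line" of the original
deployment analysis is not parameterized anywhere public; this
formalization reproduces its qualitative behavior (increasing reduction
at maximal joint slack) and is exhaustively checkable.

A subtlety the closure experiments exposed: the four printed benchmark
fractions (sens 0.918, spec 0.993, PPV 0.988, NPV 0.954) are rounded
and mutually inconsistent — at the PPV-implied prevalence 0.386 the
true NPV of such a test is 0.9507, and no simulated world can exhibit
all four at once. Self-contained simulation loops therefore benchmark
against `benchmark_from_params()`, which derives PPV and NPV from
(sens, spec, prevalence) by Bayes' rule; `run_pipeline()` goes one step
further and benchmarks against the rapid test's *empirical* performance
on its own calibration cohort, which guarantees by the corner identity
that the noninferiority region is never empty. The printed values
remain available verbatim in `idylla_benchmark()`.

`evaluate_deployment()` re-computes the three metrics with bootstrap
CIs on an independent cohort and warns when the evaluation cohort label
matches the selection cohort label (leakage guard, warn-only since
reusing a cohort is legitimate in exploration).

# Numerical choices and degenerate inputs

- Scores are clamped to the open interval (0, 1) at machine epsilon;
  `pnorm` saturates to exactly 1 beyond $z \approx 8$ otherwise.
- Softmax subtracts the max logit before exponentiation.
- Bootstrap percentile CIs use quantile type 7.
- `area_deciles()` with tied breaks merges the affected buckets and
  flags the result; constant input is a single flagged bucket.
- An empty tile grid raises "no tissue" rather than producing an empty
  feature matrix; a single-tile bag gets attention weight exactly 1.
- The checkpoint format is JSON + CSV at full double precision, so a
  saved and reloaded model predicts identically.

# Problem sizes

The test suite and pipeline run on sizes chosen to exercise every code
path in a few minutes on one core: 448–672 px slides (4–9 tiles), MIL
fixtures of 12–100 slides, cohorts of 200–200,000 samples, bootstrap
at 100–1,000 resamples, grid step 0.001 for calibration and 0.002–0.01
for orchestration demos. The one large-scale check — the rapid-test
simulator's convergence to its configured operating characteristics —
uses 200,000 samples, where binomial standard error is below the
assertion tolerances.

# Known limitations

- The synthetic slides' planted texture is trivially separable by the
  statistics encoder; recovery demonstrates correctness of the MIL
  machinery, not clinical performance.
- The statistics encoder is not a histology representation; real-data
  use requires plugging in a pathology foundation-model encoder via
  the encoder interface or precomputed features.
- Training is single-process and CPU-bound by design; no distributed
  gradient synchronization.
- Rapid-test failures/invalids, pen-mark artifacts and stain
  normalization are out of scope.
- The noninferiority comparison treats the benchmark as fixed unless
  the CI-lower-bound mode is used; it does not perform a formal paired
  noninferiority test.
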