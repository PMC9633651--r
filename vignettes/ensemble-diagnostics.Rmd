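---
title: "Probability-averaging ensembles and agreement diagnostics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-averaging ensembles and agreement diagnostics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softvote)
```

This vignette documents the statistical models, the numerical choices and
the design decisions behind `softvote`, in the spirit of a methods section:
what is computed, under which assumptions, and what the synthetic evidence
does and does not show.

## 1. The combination rules

All inputs are *confidence cubes*: the stacked softmax outputs of $n$
learners over $N$ samples and $K$ classes, with each (learner, sample) row
on the probability simplex. The arithmetic ensemble averages rows
component-wise; the geometric ensemble takes the component-wise geometric
mean and is reported **unnormalized**, because normalization — and the
$n$-th root itself — multiplies all components by the same positive factor
and therefore cannot move the argmax. That scale-invariance is also why the
product rule (the bare product of confidences) is implemented as an alias
for the geometric prediction rather than a third code path: one
implementation, one set of edge cases.

Assumptions worth making explicit:

* Confidences are taken at face value. No recalibration (e.g. temperature
  scaling) is applied; if two learners are differently calibrated, the
  arithmetic rule implicitly trusts the more peaked one more, and the
  geometric rule more still.
* All learners are weighted equally. Validation-score weighting and learner
  selection are deliberately out of scope.

### Numerical choices

* The geometric mean is computed in the log domain
  ($\exp(\tfrac1n\sum_i \log c_{i,\alpha})$) so that products of hundreds of
  small confidences cannot underflow.
* Exact zeros are not floored with an epsilon: they short-circuit the
  combined component to exactly zero, preserving the veto property as an
  identity rather than an approximation.
* If *every* class of a sample is vetoed the combined row is all zeros and
  carries no ranking information. The prediction for that sample falls back
  to the arithmetic rule with a warning. Erroring out would make a single
  degenerate row abort a whole run on real files, where hard zeros from
  rounded exports are common.
* Argmax ties break to the smallest class index, deterministically. Ties
  have measure zero for continuous confidences but occur in hand-built
  fixtures and rounded files; a documented tie-break keeps reruns
  byte-identical.
* Cube validation renormalizes rows whose sums deviate from 1 by less than
  a tolerance (default $10^{-6}$) and rejects larger deviations, naming the
  learner and sample. Softmax outputs round-tripped through text are off by
  $10^{-8}$ or less, so the default separates formatting noise from
  genuinely malformed files.

## 2. Diagnostics

**Similarity.** The per-sample similarity is the mean pairwise dot product
of the learners' confidence vectors, reported as its test-set average. The
pairwise form generalizes the three-learner definition (mean of the three
dot products) to any $n \ge 2$ and reduces to it exactly at $n = 3$; the
generalization exists because the file interface accepts any learner count.
The quoted $\pm$ is the standard error of the per-sample mean (sample
standard deviation over $\sqrt N$). That convention is a package choice —
an uncertainty over test samples, not over re-trained model triplets; with
only one cohort of learners in hand, the sample-wise spread is the only
uncertainty that can be estimated from the data.

**Agreement patterns.** Per sample, the number of learners whose argmax
misses the truth, histogrammed over $0..n$ and labelled R/W-style (RRR,
RRW, RWW, WWW at $n=3$; RR/RW/WW at $n=2$). Conditional variants restrict
to samples the ensemble classifies correctly; by construction conditional
counts never exceed unconditional ones.

**RWW rescue.** For three-learner cohorts, samples with exactly one correct
learner are scored by the ratio of the second- to the third-largest
component of the combined vector, and by whether the ensemble prediction is
correct. The ratio is scale-invariant, so it is identical for raw and
renormalized geometric vectors (both component values are stored anyway).
Ratios are binned into equal-count quantile bins (default 5) so that sparse
RWW sets still populate every bin; a zero third component is flagged as an
infinite ratio and lands in the top bin. The expected direction of the
dependence follows from the mechanism: a ratio near 1 means the two wrong
learners spread their confidence over *different* wrong classes, which is
precisely when the single correct learner can tip the argmax, so the rescue
frequency is highest in the low-ratio bins and falls as the ratio grows —
a large ratio signals two learners agreeing on the same wrong class, which
usually defeats the third. The test suite checks exactly this
direction on the quintile extremes. For $n \neq 3$ the analysis refuses to
run rather than silently redefining what "RWW" means; binary problems are
likewise rejected because a third-largest component does not exist.

**Top-1 profiles.** Mean, median and deciles of each learner's largest
confidence component. Flat profiles (low top-1) retain ranking information
beyond the argmax, which is what averaging exploits; this summary is the
package's only calibration-adjacent statistic — proper calibration metrics
are out of scope.

**Report comparison.** `compare_reports()` places two cohorts' pattern
counts side by side with count ratios (undefined ratios on zero
denominators are `NA`, not errors), similarity means with standard errors,
and mean top-1 — the tabular form of the "which cohort ensembles better,
and why" comparison.

## 3. The synthetic cohort generator

The generator exists because the phenomena above are properties of *sets*
of classifiers, and real sets require training runs the package
deliberately avoids. It draws, per sample $s$ with true class $y_s$:

$$z_s \sim \mathcal N(\mu\, e_{y_s},\, I_K), \qquad
  \epsilon_i \sim \mathcal N(0, I_K), \qquad
  g_i = \sqrt{\rho}\, z_s + \sqrt{1-\rho}\,(\mu\, e_{y_s} + \epsilon_i),$$

and sets learner $i$'s confidence vector to $\mathrm{softmax}(g_i / T)$.
A latent-Gaussian-logit model was chosen over, say, Dirichlet sampling
because it gives *independent* knobs for the three quantities the
diagnostics tie together: $\mu$ moves single-learner accuracy, $\rho$ moves
inter-learner similarity (the shared fraction of logit variance), and $T$
moves peakedness. $\mu$ enters both the shared and the idiosyncratic part
so that accuracy is approximately invariant to $\rho$; the residual drift —
the effective true-class boost is $(\sqrt\rho + \sqrt{1-\rho})\,\mu$, which
peaks at $\rho = 1/2$ — is absorbed by `calibrate_signal()`, which bisects
$\mu$ on pilot cohorts with a fixed seed schedule (accuracy is exactly
nondecreasing in $\mu$ at fixed noise draws, so the bisection is
deterministic and convergent).

One consequence is worth flagging: at *fixed* $\mu > 0$, empirical
similarity is monotone in $\rho$ only up to $\rho = 1/2$; beyond it the
falling boost flattens the vectors and can pull $S$ down again near
$\rho = 1$. The property tests therefore assert full-grid monotonicity at
$\mu = 0$ (where correlation is the only alignment source) and on
$\rho \le 1/2$ otherwise, while the mechanism experiment
(`sweep_correlation()`) recalibrates $\mu$ per $\rho$ — the scientifically
meaningful comparison is at matched accuracy anyway.

**Seeding.** One master seed expands into prefix-stable substreams (labels,
shared latents, one per learner) via sequential uniform draws, so the same
seed gives bit-identical cohorts and adding learners perturbs neither the
labels nor the existing learners' noise.

**Default study sizes.** $K = 10$ classes, $N = 2000$ samples, 3 learners,
pilot cohorts of 4000 for calibration, and 3 seeds for Monte-Carlo
properties. These sizes put standard errors on accuracies around 0.008 and
keep every experiment in the package — including the full correlation sweep
— within seconds on a single core, which is what routine re-running of the
suite demands.

**What the generator does not emulate.** Real confidence vectors from deep
networks are not Gaussian in logit space: they carry class-dependent
confusion structure (mistakes concentrate on visually similar classes),
heavy upper tails of overconfidence, and data-shift effects. The generator
reproduces the *mechanism* — lower inter-learner overlap and flatter
vectors increase ensembling gain at matched accuracy — not the
distributions of any particular model family. Passing tests therefore
validate the algebra and the qualitative mechanism, not quantitative claims
about any real dataset; no attempt is made to fit the generator to real
cohorts.

## 4. Evaluation conventions

Accuracy is the fraction of correct predictions; macro-F1 the unweighted
mean of per-class F1. Classes absent from both truth and predictions are
excluded from the macro average (the common convention when evaluating on
a label subset); a class with zero precision and recall contributes
F1 = 0. Class weights follow the balanced inverse-frequency form
$w_\alpha = N/(K_{\text{present}} N_\alpha)$, with zero-count classes
assigned weight 0 plus a warning rather than an error, so subset fixtures
load. These conventions are declared rather than inherited: different
toolkits disagree on the edge cases, and silent divergence in macro-F1 is a
classic source of irreproducible comparisons.

## 5. Interfaces and determinism

`run_pipeline()` ties the stages together on files: per-learner confidence
CSV/TSVs (aligned by `sample_id`, never row order) plus a labels file in,
combined matrices, a JSON report and a text pattern table out. Reports
contain no timestamps, so identical inputs give byte-identical outputs —
determinism is treated as a testable contract, not an aspiration. The
`exec/softvote` script exposes the same functions as shell subcommands
(`ensemble`, `diagnose`, `simulate`, `sweep`, `report`) for use outside R;
it is a thin wrapper, and the R functions remain the primary interface.
A `normalize_geometric` flag renormalizes the *written* geometric matrix
for display; predictions and reports always use the raw vectors, and the
rescue ratio is unaffected either way.

## 6. Known limitations

* Equal-weight rules only; no stacking, no learner selection.
* No hypothesis test comparing two ensembles' accuracies — the diagnostics
  are descriptive.
* The rescue analysis is defined only for three learners and $K \ge 3$.
* Synthetic evidence supports the mechanism, not dataset-specific numbers;
  see §3.
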