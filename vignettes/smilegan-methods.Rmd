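---
title: "Semi-supervised adversarial clustering of disease subtypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised adversarial clustering of disease subtypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smilegan)
```

## The problem

Neurodegenerative diseases are heterogeneous: patients who share a clinical
diagnosis can carry distinct spatial patterns of brain atrophy with
different prognoses. Given regional volumes (here: 145 atlas ROIs — 119
gray matter, 20 white matter, 6 ventricles) for a cognitively normal (CN)
reference group and a patient group, we want to discover M latent
*patterns* — subtypes of disease-related change — and assign every patient
a probability of expressing each pattern. The difficulty is that most of
the variance in ROI volumes is not disease: head size, age, sex, scanner
noise, and anatomical variability are shared by both groups. A clustering
of patient volumes splits along those nuisance directions; the method must
instead cluster the *transformation* from normal to patient.

## The model

Let $x \sim p_{CN}$ be a CN feature vector, $y \sim p_{PT}$ a patient
vector, and $z$ a one-hot subtype code of dimension $M$ drawn uniformly
(probability $1/M$ per position, independent of $x$). Three networks are
trained jointly:

* a **mapping** $f(x, z)$ producing a synthetic patient vector $y'$,
* a **discriminator** $D(y) \in (0,1)$ separating real from synthetic
  patients,
* a **clustering function** $g(y)$ mapping a patient vector to the
  $M$-simplex.

The full objective is

$$L(D, f, g) = L_{GAN}(D, f) + \mu\, L_{change}(f) + \lambda\,
L_{cluster}(f, g), \qquad f, g = \arg\min_{f,g} \max_D L$$

with the adversarial value
$L_{GAN} = E[\log D(y)] + E[\log(1 - D(f(x,z)))]$ (the generator descends
the non-saturating form $-E[\log D(f(x,z))]$), the sparsity penalty
$L_{change} = E\lVert f(x,z) - x\rVert_1$, and the inverse-consistency
term $L_{cluster} = E[\ell_c(z, g(f(x,z)))]$ where $\ell_c$ is
cross-entropy. $L_{change}$ keeps the learned transformation a sparse,
small departure from normal anatomy; $L_{cluster}$ forces the $M$
transformations to be mutually distinguishable, which is what makes the
subtype recoverable from real data: after training, $g$ applied to a real
patient vector yields the pattern probabilities. Lipschitz continuity of
$D$ is enforced by clamping its weights to $[-c, c]$ after every update.

Assignment conventions used throughout: a row's *dominant pattern* is its
argmax pattern when that probability strictly exceeds 0.5, otherwise the
row is *unassigned* and excluded from survival analyses; exact argmax ties
go to the lowest pattern index.

## Architecture and training choices

The network shapes are deliberately small, feed-forward, leaky-ReLU
($\alpha = 0.2$) stacks sized relative to the feature count $R$:
$f: (R{+}M) \to R/2 \to R/4 \to R/2 \to R$ (linear head),
$g: R \to R/2 \to R/4 \to M$ (softmax head), and
$D: R \to R/2 \to R/8 \to 1$ (sigmoid head). All widths are configurable
in `smileGANControl()`.

Design choices that were genuinely open, and how we resolved them:

* **Residual mapping.** `residual = TRUE` parameterizes
  $f(x,z) = x + \delta(x,z)$ with the head of $\delta$ initialized near
  zero. The plain MLP form cannot even represent the identity through its
  $R/4$ bottleneck, while the sparse-transformation prior says the optimal
  $f$ *is* a small departure from the identity; the skip makes that the
  starting point. The plain form remains available (`residual = FALSE`).
* **Adversarial form.** The conventional value
  $E[\log D] + E[\log(1-D)]$ is the default; a published variant that
  writes the second term as $1 - \log D(y')$ is kept behind
  `ganForm = "printed"`. For the generator the two prescriptions yield the
  same non-saturating gradient; for the discriminator the printed form is
  unbounded below and non-standard, so it is not the default.
* **Discriminator warm-up and pacing.** `dWarmup` discriminator-only
  updates (default 300) precede the joint loop, and each generator update
  is paced by `dSteps = 3` discriminator updates. Without this the mapping
  can outrun the discriminator early and "fool" it with transformations
  unrelated to the real patient modes; the cluster loss then locks in an
  arbitrary z-parameterization (observed as near-chance ARI with a
  near-equilibrium adversarial value).
* **Loss weights.** $\mu = 0.5$, $\lambda = 2$. On the CN-referenced scale
  (below) the per-ROI disease displacement is of order 0.1–0.3, so an L1
  change loss of a few units is typical; $\mu$ of order one balances it
  against adversarial gradients that pass through the weight-clipped
  discriminator ($c = 0.5$). These values, the learning rates (Adam,
  `lrG = 1e-3`, `lrD = 1e-3`), batch size 25, and the iteration budget
  were calibrated once on the synthetic harness such that planted
  disjoint-mask subtypes are recovered, then frozen; they are exposed, not
  hard-coded.
* **Stopping.** Training stops at `maxIter` (default 8000) or earlier
  when a loss plateau is corroborated by stable assignments: the moving
  averages of the change and cluster losses over the last
  `plateauWindow = 1000` iterations move by less than `plateauTol = 0.05`
  against the previous window, AND the dominant-pattern labels of the
  training patient rows agree across two consecutive checks (ARI at least
  `labelStabilityARI = 0.995`) with every pattern above the collapse
  floor. The plateau criterion alone cannot work at desk scale: minibatch
  noise floors the window deltas near 0.02 both in converged and in
  stalled runs, so a pure loss plateau cannot tell "aligned and done"
  from "stuck before alignment". Label stability is the quantity the
  method actually promises, and it is cheap to monitor.
* **Collapse handling.** After training, if any pattern dominates fewer
  than 5% of the patient rows the run counts as collapsed and is restarted
  with seed + 1, up to `maxRestarts = 3` times; if every attempt
  collapses, training fails loudly rather than returning a degenerate
  model.
* **Numerical safety.** Probabilities are clipped to $[10^{-12}, 1]$
  before logarithms; any non-finite loss aborts with a diagnostic.
* **Engines.** The training loop exists twice: a compiled loop
  (RcppArmadillo, the default) and a plain-R reference implementation with
  identical mechanics (`engine = "R"`), kept because the update equations
  are easiest to audit in R. Each engine is a deterministic function of
  (data, control, seed); the test suite cross-checks that both recover the
  same planted subtypes.

## Preprocessing

Age and sex associations are estimated per ROI by ordinary least squares
*on the CN reference group only*, and all data (CN and patient,
cross-sectional and longitudinal, each scan at its actual age) are
residualized by covariate deviations from the CN means:
$v' = v - \beta_{age}(age - \overline{age}) - \beta_{sex}(sex -
\overline{sex})$. Subtracting deviations rather than the full fitted value
keeps the CN-referenced intercept, so that after the second step — the
affine map $v'' = 1 + 0.1\,(v' - \mu_{ROI})/\sigma_{ROI}$ with moments
taken over the residualized CN scans (sample SD, $n-1$) — the CN group has
per-ROI mean exactly 1 and SD exactly 0.1, and a value of 1.0 reads as
"typical CN volume". Patient rows never enter either fit. The published
description ("residualized by age and sex effects") is ambiguous between
the two residual conventions; ours is the one that makes the documented
"mean 1" normalization hold on CN.

## Choosing M and building the consensus

The number of patterns is chosen by clustering stability: for each
candidate M, repeated holdout cross-validation leaves out 20% of the
pooled discovery set per fold (unstratified, CN and patient rows jointly —
the published protocol does not state the subsampling unit), trains a
model on the rest, labels *all* discovery patient rows, and scores all
fold pairs by the adjusted Rand index (ARI). The M with the highest mean
pairwise ARI wins; ties go to the smaller M. Labelings are compared on the
full patient set so that pairwise ARIs are comparable across folds.

The final model is a consensus: `trainEnsemble()` fits 30 models with
different seeds; the model with the highest mean pairwise ARI against the
others (argmax labels on the reference patients) becomes the template;
every other model's patterns are reordered by `matchLabels()` — an exact
search over all $M!$ label bijections for the maximal contingency-diagonal
overlap (at $M \le 8$ exhaustive search is both exact and cheap; ties take
the lexicographically first permutation) — and the aligned probabilities
are averaged. The mean of simplex points is a simplex point, so consensus
rows still sum to 1.

`permutationReproducibility()` is a reconstruction of the reproducibility
permutation test: the null reassigns CN/patient group labels (preserving
sizes) and recomputes the stability statistic;
$p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$. The original test's design
is described only in supplementary material not available here, so this
operation is documented as a reconstruction.

## The synthetic cohort generator

`cohortSpec()` defines the study conditions; `generateCrossSectional()`
and `generateLongitudinal()` are deterministic functions of (spec, seed).
The generator emulates the structure of the validation experiments on
synthetic and semi-synthetic data: both groups share every non-disease
component, patients additionally carry subtype-specific atrophy.

* **Shared (non-disease) law.** Per-ROI baseline means are drawn once per
  spec (log-uniform in 2–30, fixed thereafter so replicates differ only in
  noise); each subject gets a global multiplicative scale factor
  (log-normal, SD 0.05 — head-size variation), an age effect (tissue
  −0.4%/yr from age 70, ventricles +1.5%/yr), a sex offset (+8%), rank-5
  correlated noise (SD 0.03) and independent noise (SD 5%).
* **Disease effect (patients only).** Three disjoint 15-ROI gray-matter
  masks, one per subtype; masked ROIs are multiplied by $(1-a)$ with a
  per-subject atrophy fraction $a \sim U(0.1, 0.3)$; ventricle ROIs in a
  mask flip sign (disease enlarges ventricles). Defaults: 300 CN, 400
  patients (134/133/133).
* **Longitudinal pathways.** Each subject follows one of two routes (70%
  via mask 2, 30% via mask 3) at a per-subject speed
  $s \sim U(0.04, 0.12)$/yr: early-mask atrophy $a(t) = \min(st, 0.3)$;
  the subject leaves the preserved stage when $a$ crosses 0.1 and enters
  the late stage when $a$ reaches 0.3, after which the other route's mask
  atrophies too — emulating two progression pathways that converge on a
  common advanced pattern. Six annual visits by default; noise is redrawn
  per visit, the scale factor is per subject.

What the generator does *not* emulate: site/scanner effects, registration
or segmentation error, spatially smooth (non-mask) atrophy gradients,
diagnosis noise, and dropout-dependent censoring. Passing the recovery
tests therefore shows the machinery is correct and the method avoids the
simulated nuisance structure; it does not certify performance on real
cohorts.

The supplementary atrophy magnitudes and mask choices of the original
validation are not reproduced in the main text; the defaults above were
chosen once to be demanding but passable (atrophy comparable to 2–3
CN-SDs per masked ROI) and are all exposed in the spec.

## Progression analysis

Longitudinal pattern probabilities become event tables by the published
rules: baseline assignment requires the source-pattern probability to
exceed 0.7 (analyses originating from the preserved pattern); conversion
to a target pattern is the *first* visit whose probability strictly
exceeds 0.5, with no interpolation between visits; never-converting
subjects are censored at their last visit; competing targets are distinct
event types. Survival machinery is delegated to the survival package
behind thin wrappers: Kaplan–Meier with Greenwood bands and log-rank
tests, and multi-state Aalen–Johansen cumulative incidence for competing
conversions. Harrell's concordance (ties in risk count 0.5) and the
100×2-fold cross-validated Cox concordance protocol — the fitted partial
hazard on the validation half is the composite risk score — are
implemented in-package, as is horizon discrimination: per horizon X the
outcome is "converted before X" (subjects censored before X are excluded;
the published handling is unstated, exclusion is ours), scored by the raw
baseline probability with no further model, reporting AUC and the
operating threshold at which TPR + FPR = 1 (read as sensitivity =
specificity; raw counts summing to 1 would not be meaningful), located by
linear interpolation on the ROC.

## Problem sizes used by the test-suite and acceptance runs

Unit tests run on a reduced cohort (50 ROIs, 120 CN / 180 patients, a few
hundred to 1500 iterations). The acceptance harness uses the full default
cohort (145 ROIs, 300 CN / 400 patients) with a reduced iteration budget
and 5 seeds for recovery medians, 4-fold stability CV over M ∈ {2, 3, 4}
on a reduced cohort for model selection, and n = 500 subjects for the
longitudinal closed loop. These sizes are the package's chosen desk-scale
study conditions; all of them are parameters, not constants.

## Known limitations

* The adversarial optimum is a saddle point; convergence is stochastic.
  Seeds that lock into a collapsed or misaligned basin are detected by the
  minimum-cluster-fraction rule and restarted, but a non-collapsed yet
  suboptimal basin is possible under heavy nuisance variance — the
  consensus ensemble exists precisely to average over basin variability.
* Recovery degrades gracefully as the shared global-scale confound grows;
  at several times the realistic head-size variation the desk-scale
  iteration budget no longer reliably aligns the mapping with the true
  masks (the stability CV and the benchmark harness make this visible
  rather than hiding it).
* The exact architecture, optimizer settings, and stopping criteria of the
  original implementation live in supplementary material that is not
  reproduced here; the defaults are this package's own calibrated
  choices.
* `permutationReproducibility()` reconstructs a protocol whose original
  definition is unavailable.
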