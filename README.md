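# smilegan

Semi-supervised adversarial clustering of disease subtypes from regional
brain volumes, for neuroimaging researchers studying disease heterogeneity
(and anyone clustering *changes from a reference group* rather than raw
features).

## The problem and the model

Patients sharing a diagnosis often carry distinct spatial patterns of
brain atrophy. Clustering patients directly fails because most variance in
ROI volumes is not disease (head size, age, sex, anatomy). Smile-GAN
instead clusters the *transformation* from the cognitively normal (CN)
domain X to the patient domain Y: a mapping f : X × Z → Y takes a CN
feature vector x and a one-hot subtype code z (uniform over M positions)
and synthesizes a patient-like vector y' = f(x, z), while a discriminator
D is trained to tell y' from real patient data and a clustering function
g : Y → Z must recover z from y'. Training solves

    f, g = arg min_{f,g} max_D  L_GAN(D, f) + mu * L_change(f) + lambda * L_cluster(f, g)

with L_GAN the adversarial value E[log D(y)] + E[log(1 − D(f(x,z)))],
L_change = E‖f(x,z) − x‖₁ (sparse transformations), and L_cluster the
cross-entropy E[ℓ_c(z, g(f(x,z)))] (inverse consistency — what makes
subtypes identifiable). After training, g applied to real patients yields
M pattern probabilities per scan, the method's primary output biomarker.

Around the core model the package implements the full protocol: CN-fitted
age/sex residualization and normalization to CN mean 1 / SD 0.1; model
selection for M by clustering stability (mean pairwise adjusted Rand index
over repeated 20%-holdout CV); a 30-model consensus with exact
label-permutation alignment to a template; a synthetic ROI cohort
generator (145 ROIs: 119 GM, 20 WM, 6 ventricles) with planted
ground-truth subtypes and two longitudinal progression pathways; and
survival-based progression analysis (Kaplan–Meier, Aalen–Johansen
competing risks, Harrell's C with a 100×2-fold cross-validated Cox
protocol, horizon AUC with the TPR + FPR = 1 operating threshold).

See `vignettes/smilegan-methods.Rmd` for the model assumptions, every
tunable parameter, and the design decisions.

## Worked example

Simulate a small cohort with three planted atrophy subtypes, preprocess it
against its CN scans, train, and compare the recovered patterns with the
ground truth:

```r
library(smilegan)

spec <- cohortSpec(nCN = 120L, nPTPerSubtype = c(60L, 60L, 60L),
                   nGM = 40L, nWM = 6L, nVent = 4L, maskSize = 10L,
                   atrophyRange = c(0.15, 0.3))
sim  <- generateCrossSectional(spec, seed = 1)
prep <- preprocessCohort(sim$data)
dx   <- SummarizedExperiment::colData(prep$data)$diagnosis
cn   <- prep$data[, dx == "CN"]
pt   <- prep$data[, dx == "MCI"]

fit <- smileGAN(cn, pt, M = 3, smileGANControl(maxIter = 1500L), seed = 1)
fit
#> SmileGANModel: M = 3 patterns, 50 ROIs
#>   seed 1 | 1500 iterations | iteration cap | 0 restart(s)
#>   final losses: adversarial -1.104 change 2.387 cluster 0.003726

probs <- predictProbabilities(fit, pt)
round(head(probs, 3), 3)
#>         P1 P2 P3
#> PT_0001  1  0  0
#> PT_0002  1  0  0
#> PT_0003  1  0  0

adjustedRandIndex(patternLabels(probs), sim$truth$subtype)
#> [1] 1
```

The final adversarial value sits near the GAN equilibrium (2·ln 0.5 ≈
−1.386), the cluster loss is near 0 (the subtype code is recoverable), and
the argmax labels reproduce the planted subtypes exactly (ARI 1; the
label *names* are arbitrary — alignment across models is what
`buildConsensus()` does). Each probability row sums to 1 and is the degree
to which that scan expresses each pattern.

Downstream, `selectM()` picks M by stability, `trainEnsemble()` +
`buildConsensus()` average 30 aligned models, and
`buildPatternEventTable()` + `kaplanMeier()` / `cumulativeIncidence()` /
`repeatedCVCoxCindex()` / `horizonDiscrimination()` turn longitudinal
probabilities into progression-risk analyses.

A thin CLI over the same functions lives at `inst/cli/smilegan.R`
(subcommands `simulate`, `preprocess`, `select-m`, `train`, `consensus`,
`predict`, `progression`, `benchmark`, `run-all`).

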