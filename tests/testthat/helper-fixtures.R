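# Small synthetic fixtures shared across tests. Everything is generated in
# code at test time; sizes are kept small so the default run stays fast.

# tiny ROI experiment with explicit volumes
tinyROIExperiment <- function(n = 20, R = 4, seed = 42, diagnosis = "CN") {
  set.seed(seed)
  vol <- matrix(rnorm(R * n, mean = 10, sd = 1), R, n,
                dimnames = list(sprintf("ROI_%d", 1:R), NULL))
  roiExperiment(vol, sprintf("S%03d", 1:n), rep(0, n),
                rep(diagnosis, n), runif(n, 60, 80), rbinom(n, 1, 0.5))
}

# small, quickly separable cohort for training tests: fewer ROIs, larger
# atrophy, mild noise
quickSpec <- function(...) {
  args <- utils::modifyList(
    list(nCN = 120L, nPTPerSubtype = c(60L, 60L, 60L), nGM = 40L,
         nWM = 6L, nVent = 4L, maskSize = 10L,
         atrophyRange = c(0.15, 0.3)),
    list(...))
  do.call(cohortSpec, args)
}

quickControl <- function(...) {
  args <- list(...)
  defaults <- list(maxIter = 1500L, batchSize = 25L, maxRestarts = 2L)
  do.call(smileGANControl, utils::modifyList(defaults, args))
}

# preprocessed CN/PT split of a simulated cohort
preppedCohort <- function(spec, seed = 1) {
  sim <- generateCrossSectional(spec, seed = seed)
  prep <- preprocessCohort(sim$data)
  dx <- SummarizedExperiment::colData(prep$data)$diagnosis
  list(cn = prep$data[, dx == "CN"], pt = prep$data[, dx == "MCI"],
       truth = sim$truth, prep = prep, raw = sim$data)
}
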