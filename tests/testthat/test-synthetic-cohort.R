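test_that("default atlas composition is 145 = 119 GM + 20 WM + 6 ventricle", {
  sim <- generateCrossSectional(cohortSpec(nCN = 12L,
                                           nPTPerSubtype = c(5L, 5L, 5L)),
                                seed = 1)
  tissue <- SummarizedExperiment::rowData(sim$data)$tissue
  expect_equal(nrow(sim$data), 145)
  expect_equal(sum(tissue == "GM"), 119)
  expect_equal(sum(tissue == "WM"), 20)
  expect_equal(sum(tissue == "VENT"), 6)
})

test_that("generation is byte-identical under a fixed seed", {
  s1 <- generateCrossSectional(quickSpec(), seed = 5)
  s2 <- generateCrossSectional(quickSpec(), seed = 5)
  expect_identical(SummarizedExperiment::assay(s1$data, "volumes"),
                   SummarizedExperiment::assay(s2$data, "volumes"))
  expect_identical(s1$truth, s2$truth)
  s3 <- generateCrossSectional(quickSpec(), seed = 6)
  expect_false(identical(SummarizedExperiment::assay(s1$data, "volumes"),
                         SummarizedExperiment::assay(s3$data, "volumes")))
})

test_that("zero atrophy makes patient and CN laws identical", {
  spec <- quickSpec(atrophyRange = c(0, 0))
  sim <- generateCrossSectional(spec, seed = 3)
  v <- SummarizedExperiment::assay(sim$data, "volumes")
  dx <- SummarizedExperiment::colData(sim$data)$diagnosis
  # two-sample t-test per masked ROI: p-values behave like the null
  ps <- sapply(unlist(spec$masks), function(r)
    t.test(v[r, dx == "CN"], v[r, dx == "MCI"])$p.value)
  expect_lt(mean(ps < 0.01), 0.1)  # nominal 1% rate, generous band
})

test_that("noise-free atrophy is exact multiplicative arithmetic", {
  spec <- quickSpec(atrophyRange = c(0.2, 0.2), globalScaleSd = 0,
                    corrSd = 0, iidSd = 0, ageSlopeTissue = 0,
                    ageSlopeVent = 0, sexOffset = 0)
  sim <- generateCrossSectional(spec, seed = 2)
  v <- SummarizedExperiment::assay(sim$data, "volumes")
  dx <- SummarizedExperiment::colData(sim$data)$diagnosis
  cnV <- v[, dx == "CN"][, 1]
  for (k in 1:3) {
    cols <- which(dx == "MCI")[sim$truth$subtype == k]
    m <- spec$masks[[k]]
    expect_equal(v[m, cols], matrix(cnV[m] * 0.8, length(m), length(cols),
                                    dimnames = dimnames(v[m, cols])),
                 tolerance = 1e-12)
    # unmasked ROIs are untouched
    other <- setdiff(seq_len(nrow(v)), m)
    expect_equal(v[other, cols][, 1], cnV[other], tolerance = 1e-12)
  }
})

test_that("ventricle ROIs in a mask enlarge under disease", {
  R <- 20L
  spec <- cohortSpec(nCN = 30L, nPTPerSubtype = 30L, nGM = 14L, nWM = 2L,
                     nVent = 4L, masks = list(c(1:5, 17:18)),
                     atrophyRange = c(0.2, 0.2), globalScaleSd = 0,
                     corrSd = 0, iidSd = 0, ageSlopeTissue = 0,
                     ageSlopeVent = 0, sexOffset = 0)
  sim <- generateCrossSectional(spec, seed = 4)
  v <- SummarizedExperiment::assay(sim$data, "volumes")
  dx <- SummarizedExperiment::colData(sim$data)$diagnosis
  cnV <- v[, dx == "CN"][, 1]
  ptV <- v[, dx == "MCI"][, 1]
  expect_equal(ptV[1:5], cnV[1:5] * 0.8, tolerance = 1e-12)    # GM shrinks
  expect_equal(ptV[17:18], cnV[17:18] * 1.2, tolerance = 1e-12) # VENT grows
})

test_that("mask constraints are validated", {
  expect_error(cohortSpec(masks = list(1:5, 3:8), nPTPerSubtype = c(10L, 10L)),
               "overlap")
  expect_error(cohortSpec(masks = list(1:5), nPTPerSubtype = c(10L, 10L)),
               "one mask per subtype")
  expect_error(cohortSpec(masks = list(c(1, 500)), nPTPerSubtype = 10L),
               "out of range")
})

test_that("longitudinal trajectories obey the planted kinetics", {
  spec <- quickSpec(speedRange = c(0, 0))
  lsim <- generateLongitudinal(spec, nSubjects = 10, seed = 1)
  expect_true(all(lsim$truth$stage == 1))          # frozen trajectory

  # a subject at speed 2s reaches the late stage in half the time
  spec2 <- cohortSpec()
  tr <- generateLongitudinal(spec2, nSubjects = 50, seed = 2)$truth
  tLate <- spec2$aMax / tr$speed[!duplicated(tr$participant_id)]
  s <- tr$speed[!duplicated(tr$participant_id)]
  expect_equal(tLate * s, rep(spec2$aMax, 50))     # construction identity

  # ages advance with visit time and stages are monotone per subject
  lsim3 <- generateLongitudinal(cohortSpec(), nSubjects = 20, seed = 3)
  t3 <- lsim3$truth
  for (id in unique(t3$participant_id)) {
    st <- t3$stage[t3$participant_id == id]
    expect_true(all(diff(ifelse(st == 1, 1, ifelse(st == 4, 3, 2))) >= 0))
  }
  cd <- SummarizedExperiment::colData(lsim3$data)
  expect_true(all(cd$visit_time >= 0))
})

test_that("pathway routes only atrophy their own mask before the late stage", {
  spec <- cohortSpec(globalScaleSd = 0, corrSd = 0, iidSd = 0,
                     ageSlopeTissue = 0, ageSlopeVent = 0, sexOffset = 0)
  lsim <- generateLongitudinal(spec, nSubjects = 40, seed = 9)
  v <- SummarizedExperiment::assay(lsim$data, "volumes")
  tr <- lsim$truth
  st <- smilegan:::.cohortStructure(spec)
  base <- st$baseMean
  mid <- which(tr$stage %in% c(2, 3))
  for (i in mid[1:min(20, length(mid))]) {
    own <- spec$masks[[tr$route[i]]]
    other <- spec$masks[[ifelse(tr$route[i] == 2, 3, 2)]]
    expect_true(all(v[own, i] < base[own] * (1 - 1e-9)))
    expect_equal(v[other, i], setNames(base[other], st$roiNames[other]),
                 tolerance = 1e-9)
  }
})
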