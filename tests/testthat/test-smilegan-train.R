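# Training tests run on a reduced cohort (50 ROIs, 300 patients) with a
# reduced iteration budget so the whole file stays within a few minutes.

test_that("residual mapping with a zeroed head is the identity in x", {
  ctrl <- quickControl()
  set.seed(1)
  nets <- smilegan:::.initNetworks(10L, 3L, ctrl)
  # zero the head exactly: f(x, z) = x for every z
  L <- length(nets$f$W)
  nets$f$W[[L]] <- nets$f$W[[L]] * 0
  nets$f$b[[L]] <- nets$f$b[[L]] * 0
  x <- matrix(rnorm(50), 5, 10)
  for (k in 1:3) {
    z <- matrix(0, 5, 3); z[, k] <- 1
    expect_equal(smilegan:::.fForward(nets$f, x, z, TRUE)$out, x)
  }
})

test_that("forward passes are deterministic given fixed parameters", {
  co <- preppedCohort(quickSpec(), seed = 2)
  fit <- smileGAN(co$cn, co$pt, 3, quickControl(maxIter = 300L,
                                                collapseThreshold = 0),
                  seed = 11)
  X <- smilegan:::.sampleMatrix(co$pt)
  z <- sampleSubtypes(3, nrow(X), seed = 1)
  expect_identical(synthesize(fit, X, z), synthesize(fit, X, z))
  p1 <- predictProbabilities(fit, co$pt)
  p2 <- predictProbabilities(fit, co$pt)
  expect_identical(p1, p2)
  # duplicated input row gives an identical probability row
  X2 <- rbind(X[1, , drop = FALSE], X[1, , drop = FALSE])
  pp <- predictProbabilities(fit, X2)
  expect_identical(pp[1, ], pp[2, ])
  expect_error(synthesize(fit, X[, -1], z), "mismatch")
})

test_that("training is a deterministic function of (data, control, seed)", {
  co <- preppedCohort(quickSpec(), seed = 3)
  ctrl <- quickControl(maxIter = 250L, collapseThreshold = 0)
  f1 <- smileGAN(co$cn, co$pt, 3, ctrl, seed = 7)
  f2 <- smileGAN(co$cn, co$pt, 3, ctrl, seed = 7)
  expect_identical(lossHistory(f1), lossHistory(f2))
  expect_identical(f1@mapping$W, f2@mapping$W)
  f3 <- smileGAN(co$cn, co$pt, 3, ctrl, seed = 8)
  expect_false(identical(lossHistory(f1), lossHistory(f3)))
})

test_that("discriminator weights respect the clip radius after training", {
  co <- preppedCohort(quickSpec(), seed = 4)
  ctrl <- quickControl(maxIter = 300L, clipRadius = 0.3,
                       collapseThreshold = 0)
  fit <- smileGAN(co$cn, co$pt, 3, ctrl, seed = 1)
  expect_true(smilegan:::.allWithin(fit@discriminator, 0.3))
})

test_that("probability rows stay on the simplex everywhere", {
  co <- preppedCohort(quickSpec(), seed = 5)
  fit <- smileGAN(co$cn, co$pt, 3, quickControl(maxIter = 300L,
                                                collapseThreshold = 0),
                  seed = 2)
  p <- predictProbabilities(fit, co$pt)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  expect_equal(dim(p), c(ncol(co$pt), 3))
})

test_that("matched CN/PT distributions drive the mapping toward identity", {
  # no disease signal: the patient group is drawn from the CN law
  spec <- quickSpec(atrophyRange = c(0, 0))
  co <- preppedCohort(spec, seed = 6)

  # plain (non-residual) mapping: the L1 displacement starts large at the
  # random initialization and training drives it down
  fitP <- smileGAN(co$cn, co$pt, 3,
                   quickControl(maxIter = 800L, collapseThreshold = 0,
                                residual = FALSE),
                   seed = 3)
  lh <- lossHistory(fitP)
  early <- mean(lh[1:50, "change"])
  late <- mean(lh[(nrow(lh) - 49):nrow(lh), "change"])
  expect_lt(late, early)

  # residual mapping: f stays near the identity it started from
  fit <- smileGAN(co$cn, co$pt, 3,
                  quickControl(maxIter = 800L, collapseThreshold = 0),
                  seed = 3)
  X <- smilegan:::.sampleMatrix(co$pt)
  z <- sampleSubtypes(3, nrow(X), seed = 4)
  expect_lt(mean(abs(synthesize(fit, X, z) - X)), 0.05)
})

test_that("separable subtypes are recovered and z modulates the mapping", {
  co <- preppedCohort(quickSpec(), seed = 7)
  fit <- smileGAN(co$cn, co$pt, 3, quickControl(maxIter = 1500L), seed = 1)
  p <- predictProbabilities(fit, co$pt)
  ari <- adjustedRandIndex(patternLabels(p), co$truth$subtype)
  expect_gt(ari, 0.8)
  # prediction argmax reproduces the labels stored at train time
  expect_equal(patternLabels(p), fit@trainLabels)
  # identical x, different z: outputs differ (the cluster loss forces
  # z-dependence)
  X <- smilegan:::.sampleMatrix(co$cn)[1:2, ]
  X[2, ] <- X[1, ]
  z <- rbind(c(1, 0, 0), c(0, 1, 0))
  y <- synthesize(fit, X, z)
  expect_gt(max(abs(y[1, ] - y[2, ])), 0.01)
})

test_that("preconditions are enforced", {
  co <- preppedCohort(quickSpec(), seed = 8)
  expect_error(smileGAN(co$cn, co$pt[, 1:10], 3, quickControl()),
               "at least 5\\*M")
  Xcn <- smilegan:::.sampleMatrix(co$cn)
  colnames(Xcn)[1] <- "OTHER"
  expect_error(smileGAN(Xcn, co$pt, 3, quickControl()), "share the same ROI")
  expect_error(smileGANControl(mu = -1))
})

test_that("model archives round-trip at full precision", {
  co <- preppedCohort(quickSpec(), seed = 9)
  fit <- smileGAN(co$cn, co$pt, 3, quickControl(maxIter = 200L,
                                                collapseThreshold = 0),
                  seed = 5)
  f <- tempfile(fileext = ".json")
  saveSmileGANModel(fit, f)
  back <- readSmileGANModel(f)
  expect_equal(predictProbabilities(back, co$pt),
               predictProbabilities(fit, co$pt), tolerance = 1e-10)
  expect_equal(lossHistory(back), lossHistory(fit))
  expect_error(readSmileGANModel(f, expectedRoiNames = c("a", "b")),
               "do not match")
})

test_that("the plain-R reference engine matches the compiled engine", {
  co <- preppedCohort(quickSpec(), seed = 20)
  fR <- smileGAN(co$cn, co$pt, 3, quickControl(engine = "R"), seed = 2)
  fC <- smileGAN(co$cn, co$pt, 3, quickControl(engine = "cpp"), seed = 2)
  aR <- adjustedRandIndex(patternLabels(predictProbabilities(fR, co$pt)),
                          co$truth$subtype)
  aC <- adjustedRandIndex(patternLabels(predictProbabilities(fC, co$pt)),
                          co$truth$subtype)
  expect_gt(aR, 0.8)
  expect_gt(aC, 0.8)
  # both engines honor the discriminator clip and reach a low cluster loss
  expect_true(smilegan:::.allWithin(fR@discriminator, 0.5))
  expect_true(smilegan:::.allWithin(fC@discriminator, 0.5))
  expect_lt(lossHistory(fR)[nrow(lossHistory(fR)), "cluster"], 0.3)
  expect_lt(lossHistory(fC)[nrow(lossHistory(fC)), "cluster"], 0.3)
})
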