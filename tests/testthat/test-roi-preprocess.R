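test_that("covariate model recovers planted linear age effects", {
  n <- 50
  age <- seq(60, 80, length.out = n)
  sex <- rep(c(0, 1), n / 2)
  vol <- rbind(ROI_1 = 100 - 0.5 * age,          # exact linear response
               ROI_2 = rep(7, n))                # constant response
  se <- roiExperiment(vol, sprintf("S%d", 1:n), rep(0, n), rep("CN", n),
                      age, sex)
  cm <- fitCovariateModel(se)
  co <- cm@coefficients
  expect_equal(unname(co["ROI_1", "age"]), -0.5, tolerance = 1e-12)
  expect_equal(unname(co["ROI_1", "sex"]), 0, tolerance = 1e-10)
  expect_equal(unname(co["ROI_2", c("age", "sex")]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(co["ROI_2", "intercept"]), 7, tolerance = 1e-12)
})

test_that("covariate slope estimate lands in its sampling band under noise", {
  set.seed(7)
  n <- 500
  age <- runif(n, 55, 85)
  vol <- rbind(ROI_1 = 100 - 0.5 * age + rnorm(n, sd = 2),
               ROI_2 = rnorm(n, 50, 1))
  se <- roiExperiment(vol, sprintf("S%d", 1:n), rep(0, n), rep("CN", n),
                      age, rbinom(n, 1, 0.5))
  cm <- fitCovariateModel(se)
  # se(beta) = 2 / (sd(age) sqrt(n)) ~ 0.0103; +-0.05 is ~5 sigma
  expect_lt(abs(cm@coefficients["ROI_1", "age"] + 0.5), 0.05)
})

test_that("covariate fitting refuses non-CN rows and tiny samples", {
  se <- tinyROIExperiment(n = 8)
  expect_error(fitCovariateModel(se), "at least 10")
  se2 <- tinyROIExperiment(n = 20, diagnosis = "MCI")
  expect_error(fitCovariateModel(se2), "CN scans only")
})

test_that("constant sex is dropped with a warning, coefficient 0", {
  n <- 30
  set.seed(1)
  vol <- matrix(rnorm(2 * n, 10), 2, n, dimnames = list(c("ROI_1", "ROI_2")))
  se <- roiExperiment(vol, sprintf("S%d", 1:n), rep(0, n), rep("CN", n),
                      runif(n, 60, 80), rep(1, n))
  expect_warning(cm <- fitCovariateModel(se), "collinear")
  expect_equal(unname(cm@coefficients[, "sex"]), c(0, 0))
})

test_that("residualization follows the stated formula and orthogonality", {
  co <- cbind(intercept = c(100, 50), age = c(-0.5, 0), sex = c(0, 2))
  rownames(co) <- c("ROI_1", "ROI_2")
  cm <- methods::new("CovariateModel", coefficients = co,
                     covariateMeans = c(age = 70, sex = 0), nFit = 20L)
  vol <- matrix(c(95, 40), 2, 1, dimnames = list(c("ROI_1", "ROI_2")))
  se <- roiExperiment(vol, "S1", 0, "CN", age = 80, sex = 0)
  out <- SummarizedExperiment::assay(residualize(se, cm), "volumes")
  expect_equal(unname(out["ROI_1", 1]), 95 - (-0.5) * 10)  # hand arithmetic
  expect_equal(unname(out["ROI_2", 1]), 40)

  # a row at the CN covariate means is unchanged
  se0 <- roiExperiment(vol, "S1", 0, "CN", age = 70, sex = 0)
  expect_equal(SummarizedExperiment::assay(residualize(se0, cm), "volumes"),
               vol)

  # on the fitting rows, residualized values are uncorrelated with age
  cohort <- tinyROIExperiment(n = 40, seed = 3)
  ages <- SummarizedExperiment::colData(cohort)$age
  fit <- fitCovariateModel(cohort)
  res <- SummarizedExperiment::assay(residualize(cohort, fit), "volumes")
  for (r in seq_len(nrow(res)))
    expect_lt(abs(cor(res[r, ], ages)), 1e-10)
})

test_that("normalizer moments and refusals", {
  vol <- matrix(c(0.9, 5, 1.1, 5), 2, 2, dimnames = list(c("A", "B")))
  se <- roiExperiment(vol, c("S1", "S2"), c(0, 0), c("CN", "CN"),
                      c(70, 71), c(0, 1))
  expect_error(fitNormalizer(se), "zero-variance ROI.*B")
  vol["B", 2] <- 6
  se <- roiExperiment(vol, c("S1", "S2"), c(0, 0), c("CN", "CN"),
                      c(70, 71), c(0, 1))
  nrm <- fitNormalizer(se)
  expect_equal(unname(nrm@mu["A"]), 1.0)
  expect_equal(unname(nrm@sigma["A"]), sd(c(0.9, 1.1)))  # n-1 convention
})

test_that("normalization maps the CN block to mean 1 / SD 0.1 exactly", {
  cn <- tinyROIExperiment(n = 30, R = 5, seed = 11)
  cm <- fitCovariateModel(cn)
  res <- residualize(cn, cm)
  nrm <- fitNormalizer(res)
  out <- SummarizedExperiment::assay(normalizeROIs(res, nrm), "volumes")
  expect_equal(rowMeans(out), setNames(rep(1, 5), rownames(out)),
               tolerance = 1e-12)
  expect_equal(apply(out, 1, sd), setNames(rep(0.1, 5), rownames(out)),
               tolerance = 1e-12)

  # value at mu maps to 1; mu + 2 sigma maps to 1.2
  v1 <- matrix(c(nrm@mu), 5, 1, dimnames = list(names(nrm@mu)))
  se1 <- roiExperiment(v1, "X", 0, NULL, 70, 0)
  expect_equal(unname(SummarizedExperiment::assay(
    normalizeROIs(se1, nrm), "volumes")[, 1]), rep(1, 5))
  v2 <- matrix(nrm@mu + 2 * nrm@sigma, 5, 1, dimnames = list(names(nrm@mu)))
  se2 <- roiExperiment(v2, "X", 0, NULL, 70, 0)
  expect_equal(unname(SummarizedExperiment::assay(
    normalizeROIs(se2, nrm), "volumes")[, 1]), rep(1.2, 5))

  # idempotence in parameters: refitting on the normalized CN block gives
  # mu = 1, sigma = 0.1
  nrm2 <- fitNormalizer(normalizeROIs(res, nrm))
  expect_equal(unname(nrm2@mu), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(nrm2@sigma), rep(0.1, 5), tolerance = 1e-12)
})

test_that("patient rows never enter preprocessing fits", {
  sim <- generateCrossSectional(quickSpec(), seed = 5)
  prep <- preprocessCohort(sim$data)
  dx <- SummarizedExperiment::colData(sim$data)$diagnosis
  cnOnly <- sim$data[, dx == "CN"]
  cmRef <- fitCovariateModel(cnOnly)
  expect_equal(prep$covariateModel@coefficients, cmRef@coefficients)
  expect_equal(prep$covariateModel@nFit, sum(dx == "CN"))
  # mismatch of ROI names is refused
  sub <- sim$data[-1, ]
  expect_error(residualize(sub, prep$covariateModel), "do not match")
  expect_error(normalizeROIs(sub, prep$normalizer), "do not match")
})

test_that("CSV and JSON round trips preserve data and parameters", {
  se <- tinyROIExperiment(n = 6, R = 3, seed = 2)
  f <- tempfile(fileext = ".csv")
  writeROITable(se, f)
  back <- readROITable(f)
  expect_equal(SummarizedExperiment::assay(back, "volumes"),
               SummarizedExperiment::assay(se, "volumes"),
               tolerance = 1e-12)
  expect_equal(SummarizedExperiment::colData(back)$age,
               SummarizedExperiment::colData(se)$age)

  cm <- fitCovariateModel(tinyROIExperiment(n = 25, R = 3, seed = 9))
  fj <- tempfile(fileext = ".json")
  writeCovariateModel(cm, fj)
  cm2 <- readCovariateModel(fj)
  expect_equal(cm2@coefficients, cm@coefficients)
  expect_equal(cm2@covariateMeans, cm@covariateMeans)

  res <- residualize(tinyROIExperiment(n = 25, R = 3, seed = 9), cm)
  nrm <- fitNormalizer(res)
  fn <- tempfile(fileext = ".json")
  writeNormalizer(nrm, fn)
  nrm2 <- readNormalizer(fn)
  expect_equal(nrm2@mu, nrm@mu)
  expect_equal(nrm2@sigma, nrm@sigma)
})
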