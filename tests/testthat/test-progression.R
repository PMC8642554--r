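test_that("dominant-pattern assignment uses the strict > 0.5 rule", {
  p <- rbind(c(0.7, 0.1, 0.1, 0.1),
             c(0.4, 0.3, 0.2, 0.1),
             c(0.5, 0.5, 0.0, 0.0))
  lab <- assignDominantPattern(p)
  expect_equal(as.character(lab), c("P1", "unassigned", "unassigned"))
  # exact argmax ties break to the lowest index when above threshold
  p2 <- rbind(c(0.51, 0.49), c(0.49, 0.51))
  expect_warning(lab2 <- assignDominantPattern(p2, threshold = 0.45),
                 "1/M")
  expect_equal(as.character(lab2), c("P1", "P2"))
  expect_error(assignDominantPattern(rbind(c(0.5, 0.2))), "simplex")
})

test_that("event table records first crossing, censoring, baseline filter", {
  probs <- data.frame(
    participant_id = rep(c("A", "B", "C"), each = 3),
    visit_time = rep(c(0, 1.5, 3), 3),
    P1 = c(0.9, 0.6, 0.2,  0.8, 0.7, 0.6,  0.5, 0.4, 0.3),
    P2 = c(0.05, 0.3, 0.7, 0.1, 0.2, 0.3,  0.3, 0.4, 0.5),
    P3 = c(0.05, 0.1, 0.1, 0.1, 0.1, 0.1,  0.2, 0.2, 0.2))
  ev <- buildPatternEventTable(probs)
  # A converts to P2 at year 3; B never converts -> censored at 3;
  # C fails the baseline P1 > 0.7 filter
  expect_equal(nrow(ev), 2)
  a <- ev[ev$participant_id == "A", ]
  expect_equal(as.character(a$event), "P2")
  expect_equal(a$time, 3)
  b <- ev[ev$participant_id == "B", ]
  expect_equal(as.character(b$event), "censored")
  expect_equal(b$time, 3)
  expect_equal(a$baseline_P2, 0.05)
  # unordered visits refuse
  bad <- probs[c(2, 1, 3), ]
  bad$participant_id <- "Z"
  expect_error(buildPatternEventTable(rbind(probs, bad)), "unordered")
})

test_that("Kaplan-Meier product-limit hand example and properties", {
  ev <- data.frame(time = 1:4, status = 1L)
  km <- kaplanMeier(ev)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$time, 1:4)
  # all censored: flat at 1 with warning
  evc <- data.frame(time = c(2, 3), status = 0L)
  expect_warning(kmc <- kaplanMeier(evc), "censored")
  expect_true(all(kmc$surv == 1))
  # monotone non-increasing from 1
  set.seed(8)
  ev2 <- data.frame(time = rexp(50), status = rbinom(50, 1, 0.6))
  km2 <- kaplanMeier(ev2)
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_true(all(km2$surv <= 1))
})

test_that("log-rank test separates different hazards", {
  set.seed(9)
  t1 <- rexp(80, 1); t2 <- rexp(80, 3)
  ev <- data.frame(time = c(t1, t2), status = 1L)
  g <- rep(c("a", "b"), each = 80)
  lr <- logRankTest(ev, g)
  expect_lt(lr$p, 1e-6)
  expect_equal(lr$df, 1)
})

test_that("cumulative incidence: conservation and single-cause reduction", {
  set.seed(12)
  n <- 120
  ev <- data.frame(
    time = round(rexp(n, 0.5), 2) + 0.01,
    event = factor(sample(c("censored", "P2", "P3"), n, replace = TRUE,
                          prob = c(0.3, 0.45, 0.25)),
                   levels = c("censored", "P2", "P3")))
  ci <- cumulativeIncidence(ev)
  tot <- ci$eventFree + ci$P2 + ci$P3
  expect_true(all(abs(tot - 1) < 1e-10))
  expect_true(all(diff(ci$P2) >= -1e-12))

  # one event type, no censoring: incidence = 1 - KM
  ev1 <- data.frame(time = c(1, 2, 3, 4),
                    event = factor(c("P2", "P2", "P2", "P2"),
                                   levels = c("censored", "P2")),
                    status = 1L)
  ci1 <- cumulativeIncidence(ev1)
  km <- kaplanMeier(ev1)
  expect_equal(ci1$P2, 1 - km$surv, tolerance = 1e-12)
})

test_that("planted 70/30 pathway split is recovered from the generator", {
  spec <- cohortSpec()
  lsim <- generateLongitudinal(spec, nSubjects = 500, seed = 7)
  probs <- stageProbabilities(lsim$truth)
  ev <- buildPatternEventTable(probs, baselineThreshold = 0.7)
  ci <- cumulativeIncidence(ev)
  expect_lt(abs(ci$P2[nrow(ci)] - 0.7), 0.05)
  expect_lt(abs(ci$P3[nrow(ci)] - 0.3), 0.05)
  # noise-free ground truth: conversion observed at the first visit whose
  # planted atrophy crossed the stage threshold
  tr <- lsim$truth
  firstConv <- tapply(seq_len(nrow(tr)), tr$participant_id, function(i) {
    j <- i[tr$pattern[i] != 1]
    if (length(j)) tr$visit_time[j[1]] else NA_real_
  })
  conv <- ev[ev$status > 0, ]
  expect_equal(conv$time, as.numeric(firstConv[conv$participant_id]))
})

test_that("concordance index: closed cases and exhaustive pair oracle", {
  # perfect inverse ordering of risk and time
  tm <- c(5, 4, 3, 2, 1)
  expect_equal(concordanceIndex(1:5, tm, rep(1, 5)), 1)
  # constant risk: every comparable pair ties -> 0.5
  expect_equal(concordanceIndex(rep(2, 5), tm, rep(1, 5)), 0.5)
  expect_error(concordanceIndex(1, 5, 0), "no comparable pairs")

  bruteC <- function(risk, time, status) {
    conc <- 0; n <- 0
    for (i in seq_along(time)) for (j in seq_along(time)) {
      if (status[i] == 1 && time[i] < time[j]) {
        n <- n + 1
        conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      }
    }
    conc / n
  }
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    risk <- round(rnorm(n), 1)          # ties occur
    time <- round(rexp(n), 1) + 0.1
    status <- rbinom(n, 1, 0.7)
    if (!any(status == 1)) status[1] <- 1
    expect_equal(concordanceIndex(risk, time, status),
                 bruteC(risk, time, status), tolerance = 1e-12)
  }
})

test_that("concordance agrees with the survival package on random data", {
  set.seed(15)
  n <- 150
  risk <- rnorm(n); time <- rexp(n); status <- rbinom(n, 1, 0.6)
  ours <- concordanceIndex(risk, time, status)
  ref <- survival::concordance(survival::Surv(time, status) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("null risks give concordance ~0.5", {
  set.seed(16)
  vals <- replicate(500, {
    time <- rexp(200); status <- rbinom(200, 1, 0.5)
    concordanceIndex(rnorm(200), time, status)
  })
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})

test_that("repeated CV Cox concordance: determinism, signal and null", {
  set.seed(17)
  n <- 200
  x <- rnorm(n)
  # proportional hazards generator: hazard ratio e^x
  time <- rexp(n, rate = exp(x))
  status <- rep(1L, n)
  cens <- rexp(n, 0.3)
  status[cens < time] <- 0L
  time <- pmin(time, cens)
  feats <- cbind(x = x, junk = rnorm(n))

  r1 <- repeatedCVCoxCindex(feats, time, status, nRepeats = 10, seed = 3)
  r2 <- repeatedCVCoxCindex(feats, time, status, nRepeats = 10, seed = 3)
  expect_identical(r1$cindex, r2$cindex)
  expect_length(r1$cindex, 20)
  # the true-feature model discriminates clearly
  expect_gt(r1$mean, 0.65)
  # an uninformative feature sits at 0.5 (averaged over independent
  # datasets: within one dataset a junk feature that correlates by chance
  # stays correlated in both halves)
  nullMeans <- vapply(1:10, function(k) {
    tm <- rexp(n); st <- rbinom(n, 1, 0.7)
    repeatedCVCoxCindex(cbind(z = rnorm(n)), tm, st, nRepeats = 10,
                        seed = k)$mean
  }, numeric(1))
  expect_lt(abs(mean(nullMeans) - 0.5), 0.03)
})

test_that("horizon discrimination: perfect score, threshold property, null", {
  # score identical to outcome indicator -> AUC 1 at every usable horizon
  time <- c(1, 1, 2, 5, 5, 6, 7, 8)
  status <- c(1, 1, 1, 0, 0, 0, 0, 0)
  score <- as.numeric(status)
  hd <- horizonDiscrimination(score, time, status, horizons = c(3, 4))
  expect_equal(hd$auc, c(1, 1))
  expect_true(all(hd$threshold > 0 & hd$threshold <= 1))

  # the returned operating point satisfies TPR + FPR = 1 up to interpolation
  set.seed(18)
  n <- 300
  sc <- rnorm(n)
  tm <- rexp(n, exp(sc))
  st <- rep(1L, n)
  hd2 <- horizonDiscrimination(sc, tm, st, horizons = c(0.5, 1))
  expect_true(all(abs(hd2$tprPlusFpr - 1) < 1e-8))
  expect_true(all(hd2$auc > 0.5))

  # a horizon with no positives is reported missing
  hd3 <- horizonDiscrimination(score, time, status, horizons = 0.5)
  expect_true(is.na(hd3$auc))
})

test_that("horizon AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  n <- 250
  sc <- rnorm(n)
  tm <- rexp(n, exp(sc)); st <- rep(1L, n)
  X <- 1
  pos <- st == 1 & tm <= X; neg <- tm > X
  keep <- pos | neg
  ref <- as.numeric(pROC::auc(pROC::roc(pos[keep], sc[keep], quiet = TRUE,
                                        direction = "<")))
  hd <- horizonDiscrimination(sc, tm, st, horizons = X)
  expect_equal(hd$auc, ref, tolerance = 1e-10)
})

test_that("null scores give horizon AUC ~0.5", {
  set.seed(20)
  vals <- replicate(200, {
    n <- 500
    tm <- rexp(n); st <- rbinom(n, 1, 0.7)
    horizonDiscrimination(rnorm(n), tm, st, horizons = 1)$auc
  })
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})
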