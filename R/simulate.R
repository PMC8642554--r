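#' Recipe for a synthetic ROI-volume cohort with ground-truth subtypes
#'
#' Describes a CN reference group and a patient group that share all
#' non-disease variation (age and sex effects, a global multiplicative
#' scale factor emulating head-size differences, low-rank correlated noise,
#' independent noise) while the patient group additionally carries
#' subtype-specific atrophy: each subtype multiplies its mask of ROIs by
#' (1 - a) with a per-subject atrophy fraction a (ventricle ROIs, which
#' enlarge under disease, are flipped to (1 + a)). The default atlas
#' composition is 145 ROIs: 119 gray matter, 20 white matter, 6 ventricle.
#' Structural constants (per-ROI baseline means, correlated-noise loadings,
#' masks) are drawn once per recipe from \code{structureSeed} and fixed, so
#' replicates generated with different seeds differ only in subjects and
#' noise.
#'
#' @param nCN number of CN subjects (default 300).
#' @param nPTPerSubtype patient count per subtype (default 134/133/133,
#'   i.e. 400 patients in 3 subtypes).
#' @param nGM,nWM,nVent atlas composition (defaults 119/20/6).
#' @param masks list of ROI index sets, one per subtype; default 3 disjoint
#'   gray-matter masks of \code{maskSize} ROIs.
#' @param maskSize ROIs per default mask (15).
#' @param overlap allow overlapping masks (default FALSE; overlapping
#'   masks are refused otherwise).
#' @param atrophyRange per-subject atrophy fraction drawn uniformly from
#'   this interval (default [0.1, 0.3]).
#' @param ageRange,maleFrac age draw interval (years) and P(sex = 1).
#' @param ageSlopeTissue,ageSlopeVent relative volume change per year from
#'   age 70 for tissue and ventricle ROIs (defaults -0.4%/yr, +1.5%/yr).
#' @param sexOffset relative volume offset for sex = 1 (default +8%).
#' @param globalScaleSd SD of the per-subject log global scale factor.
#' @param corrRank,corrSd rank and strength of the low-rank correlated
#'   noise; \code{iidSd} SD of the independent relative noise.
#' @param baselineRange log-uniform range of per-ROI baseline means.
#' @param visits,yearsBetween longitudinal design (default 6 visits, 1 yr).
#' @param pathwayMix fraction of longitudinal subjects following the
#'   mask-2 route (the rest follow the mask-3 route; default 0.7).
#' @param speedRange per-subject atrophy growth per year, uniform.
#' @param stageEnter atrophy fraction at which a subject leaves the
#'   preserved stage (default 0.1).
#' @param aMax atrophy ceiling of the early mask; reaching it starts the
#'   late stage in which the other route's mask atrophies too.
#' @param structureSeed seed of the fixed structural constants.
#' @return a list of class \code{cohortSpec}.
#' @export
cohortSpec <- function(nCN = 300L, nPTPerSubtype = c(134L, 133L, 133L),
                       nGM = 119L, nWM = 20L, nVent = 6L,
                       masks = NULL, maskSize = 15L, overlap = FALSE,
                       atrophyRange = c(0.1, 0.3),
                       ageRange = c(55, 85), maleFrac = 0.5,
                       ageSlopeTissue = -0.004, ageSlopeVent = 0.015,
                       sexOffset = 0.08, globalScaleSd = 0.05,
                       corrRank = 5L, corrSd = 0.03, iidSd = 0.05,
                       baselineRange = c(2, 30),
                       visits = 6L, yearsBetween = 1,
                       pathwayMix = 0.7, speedRange = c(0.04, 0.12),
                       stageEnter = 0.1, aMax = 0.3,
                       structureSeed = 1001L) {
  R <- nGM + nWM + nVent
  if (is.null(masks)) {
    K <- length(nPTPerSubtype)
    if (K * maskSize > nGM) stop("default masks do not fit in the GM ROIs")
    masks <- lapply(seq_len(K), function(k)
      ((k - 1L) * maskSize + 1L):(k * maskSize))
  }
  if (length(masks) != length(nPTPerSubtype))
    stop("one mask per subtype is required")
  for (m in masks) if (any(m < 1L | m > R)) stop("mask indices out of range")
  if (!overlap && length(masks) > 1L) {
    all_idx <- unlist(masks)
    if (anyDuplicated(all_idx))
      stop("overlapping masks require overlap = TRUE")
  }
  stopifnot(atrophyRange[1] >= 0, atrophyRange[2] < 1,
            atrophyRange[1] <= atrophyRange[2],
            pathwayMix >= 0, pathwayMix <= 1, visits >= 1)
  structure(as.list(environment()), class = "cohortSpec")
}

# fixed structural constants: baseline means, noise loadings, tissue tags
.cohortStructure <- function(spec) {
  R <- spec$nGM + spec$nWM + spec$nVent
  tissue <- rep(c("GM", "WM", "VENT"), c(spec$nGM, spec$nWM, spec$nVent))
  .withSeed(spec$structureSeed, {
    baseMean <- exp(stats::runif(R, log(spec$baselineRange[1]),
                                 log(spec$baselineRange[2])))
    loadings <- matrix(stats::rnorm(R * spec$corrRank), R, spec$corrRank) /
      sqrt(spec$corrRank)
    list(R = R, tissue = tissue, baseMean = baseMean, loadings = loadings,
         roiNames = sprintf("ROI_%03d", seq_len(R)))
  })
}

# shared non-disease generative law for n subjects (one visit each);
# returns R x n volume matrix given per-subject covariates
.nonDiseaseVolumes <- function(spec, st, age, sex, scale) {
  n <- length(age)
  slope <- ifelse(st$tissue == "VENT", spec$ageSlopeVent, spec$ageSlopeTissue)
  covar <- outer(slope, age - 70) + spec$sexOffset * outer(rep(1, st$R), sex)
  noise <- spec$corrSd * (st$loadings %*%
             matrix(stats::rnorm(spec$corrRank * n), spec$corrRank, n)) +
           spec$iidSd * matrix(stats::rnorm(st$R * n), st$R, n)
  st$baseMean * rep(scale, each = st$R) * (1 + covar + noise)
}

#' Generate a cross-sectional synthetic cohort
#'
#' CN subjects follow the shared non-disease law; patient subjects follow
#' the identical law plus subtype-specific mask atrophy (a strict
#' super-process: the disease effect exists only in patients). Fully
#' reproducible from \code{seed}.
#'
#' @param spec a [cohortSpec()].
#' @param seed integer seed.
#' @return list with \code{data} (ROI \code{SummarizedExperiment}; CN
#'   scans have diagnosis \code{"CN"}, patients \code{"MCI"}) and
#'   \code{truth} (data.frame per patient row: \code{participant_id},
#'   \code{subtype}, \code{atrophy}).
#' @export
generateCrossSectional <- function(spec, seed = 1L) {
  st <- .cohortStructure(spec)
  .withSeed(seed, {
    nPT <- sum(spec$nPTPerSubtype)
    n <- spec$nCN + nPT
    age <- stats::runif(n, spec$ageRange[1], spec$ageRange[2])
    sex <- stats::rbinom(n, 1, spec$maleFrac)
    scale <- exp(stats::rnorm(n, 0, spec$globalScaleSd))
    vol <- .nonDiseaseVolumes(spec, st, age, sex, scale)
    subtype <- rep(seq_along(spec$nPTPerSubtype), spec$nPTPerSubtype)
    a <- stats::runif(nPT, spec$atrophyRange[1], spec$atrophyRange[2])
    for (k in seq_along(spec$masks)) {
      cols <- spec$nCN + which(subtype == k)
      mask <- spec$masks[[k]]
      sgn <- ifelse(st$tissue[mask] == "VENT", 1, -1)
      vol[mask, cols] <- vol[mask, cols] *
        (1 + outer(sgn, a[subtype == k]))
    }
    rownames(vol) <- st$roiNames
    ids <- c(sprintf("CN_%04d", seq_len(spec$nCN)),
             sprintf("PT_%04d", seq_len(nPT)))
    se <- roiExperiment(vol, ids, rep(0, n),
                        rep(c("CN", "MCI"), c(spec$nCN, nPT)),
                        age, sex, tissue = st$tissue)
    truth <- data.frame(participant_id = ids[spec$nCN + seq_len(nPT)],
                        subtype = subtype, atrophy = a)
    list(data = se, truth = truth)
  })
}

#' Generate a longitudinal synthetic cohort with two progression pathways
#'
#' Each subject follows one of two routes: atrophy grows linearly in the
#' route's early mask (mask 2 or mask 3) at a per-subject speed; once it
#' reaches the ceiling \code{aMax}, the late stage begins and the other
#' route's mask atrophies too — emulating the common advanced end-stage
#' pattern. The per-visit stage is encoded as a pattern index: 1 preserved,
#' 2 mask-2 route, 3 mask-3 route, 4 late stage. Ages advance with visit
#' time; noise is redrawn per visit; the global scale factor is fixed per
#' subject.
#'
#' @param spec a [cohortSpec()] (needs at least 3 masks so that masks 2 and
#'   3 define the two routes; with exactly 2 masks they are masks 1 and 2).
#' @param nSubjects number of longitudinal patients (default: total patient
#'   count of the spec).
#' @param seed integer seed.
#' @return list with \code{data} (ROI experiment, one column per visit)
#'   and \code{truth} (per visit: \code{participant_id}, \code{visit_time},
#'   \code{route}, \code{stage}, \code{pattern}, \code{aEarly},
#'   \code{aLate}, \code{speed}).
#' @export
generateLongitudinal <- function(spec, nSubjects = NULL, seed = 1L) {
  stopifnot(spec$visits >= 2L)
  st <- .cohortStructure(spec)
  K <- length(spec$masks)
  routeMasks <- if (K >= 3L) spec$masks[c(2L, 3L)] else spec$masks[c(1L, 2L)]
  if (is.null(nSubjects)) nSubjects <- sum(spec$nPTPerSubtype)
  .withSeed(seed, {
    route <- 1L + stats::rbinom(nSubjects, 1, 1 - spec$pathwayMix)  # 1=mask2 route
    speed <- stats::runif(nSubjects, spec$speedRange[1], spec$speedRange[2])
    age0 <- stats::runif(nSubjects, spec$ageRange[1], spec$ageRange[2])
    sex <- stats::rbinom(nSubjects, 1, spec$maleFrac)
    scale <- exp(stats::rnorm(nSubjects, 0, spec$globalScaleSd))
    times <- (seq_len(spec$visits) - 1) * spec$yearsBetween
    rows <- list(); vols <- list()
    for (v in seq_along(times)) {
      t <- times[v]
      aE <- pmin(speed * t, spec$aMax)
      tLate <- ifelse(speed > 0, spec$aMax / speed, Inf)
      aL <- ifelse(is.finite(tLate),
                   pmin(pmax(speed * (t - tLate), 0), spec$aMax), 0)
      stage <- ifelse(aE < spec$stageEnter, 1L,
                      ifelse(aE < spec$aMax, ifelse(route == 1L, 2L, 3L), 4L))
      vol <- .nonDiseaseVolumes(spec, st, age0 + t, sex, scale)
      for (i in seq_len(nSubjects)) {
        em <- routeMasks[[route[i]]]
        om <- routeMasks[[3L - route[i]]]
        sgnE <- ifelse(st$tissue[em] == "VENT", 1, -1)
        sgnO <- ifelse(st$tissue[om] == "VENT", 1, -1)
        vol[em, i] <- vol[em, i] * (1 + sgnE * aE[i])
        if (aL[i] > 0) vol[om, i] <- vol[om, i] * (1 + sgnO * aL[i])
      }
      vols[[v]] <- vol
      rows[[v]] <- data.frame(
        participant_id = sprintf("LP_%04d", seq_len(nSubjects)),
        visit_time = t, route = route + 1L, stage = stage,
        pattern = ifelse(stage == 1L, 1L,
                         ifelse(stage == 4L, 4L, route + 1L)),
        aEarly = aE, aLate = aL, speed = speed,
        age = age0 + t, sex = sex)
    }
    truth <- do.call(rbind, rows)
    ord <- order(truth$participant_id, truth$visit_time)
    truth <- truth[ord, ]
    vol <- do.call(cbind, vols)[, ord, drop = FALSE]
    rownames(vol) <- st$roiNames
    se <- roiExperiment(vol, truth$participant_id, truth$visit_time,
                        rep("MCI", nrow(truth)), truth$age, truth$sex,
                        tissue = st$tissue)
    list(data = se,
         truth = truth[, c("participant_id", "visit_time", "route", "stage",
                           "pattern", "aEarly", "aLate", "speed")])
  })
}

#' Ground-truth stage probabilities for closed-loop checks
#'
#' Turns the per-visit ground-truth pattern of a longitudinal cohort into a
#' noise-free probability table (probability 1 on the active pattern), the
#' format consumed by [buildPatternEventTable()].
#'
#' @param truth the \code{truth} component of [generateLongitudinal()].
#' @param M number of patterns (default 4).
#' @return data.frame: \code{participant_id}, \code{visit_time}, and
#'   columns \code{P1..PM}.
#' @export
stageProbabilities <- function(truth, M = 4L) {
  p <- matrix(0, nrow(truth), M, dimnames = list(NULL, paste0("P", seq_len(M))))
  p[cbind(seq_len(nrow(truth)), truth$pattern)] <- 1
  cbind(truth[, c("participant_id", "visit_time")], as.data.frame(p))
}

#' Benchmark subtype recovery against baseline clusterings
#'
#' Head-to-head comparison on replicated synthetic cohorts: the adversarial
#' model (trained on preprocessed data) versus k-means on raw volumes,
#' k-means on preprocessed volumes, and (if \pkg{mclust} is installed) a
#' Gaussian mixture on preprocessed volumes. Reported as ARI against the
#' planted subtype per method and replicate.
#'
#' @param spec a [cohortSpec()].
#' @param methods subset of \code{c("smilegan", "kmeans_raw",
#'   "kmeans_norm", "gmm")}.
#' @param replicates number of simulated cohorts.
#' @param control a [smileGANControl()] for the adversarial model.
#' @param seed base seed; replicate r uses seed + r.
#' @return data.frame with columns \code{method}, \code{replicate},
#'   \code{ari}.
#' @export
benchmarkBaselines <- function(spec,
                               methods = c("smilegan", "kmeans_raw",
                                           "kmeans_norm"),
                               replicates = 5L,
                               control = smileGANControl(), seed = 1L) {
  stopifnot(length(methods) >= 1L)
  K <- length(spec$masks)
  out <- list()
  for (r in seq_len(replicates)) {
    sim <- generateCrossSectional(spec, seed = seed + r)
    prep <- preprocessCohort(sim$data)
    cnP <- .diagnosisSubset(prep$data, "CN")
    ptP <- .diagnosisSubset(prep$data, "MCI")
    rawPT <- .sampleMatrix(.diagnosisSubset(sim$data, "MCI"))
    normPT <- .sampleMatrix(ptP)
    for (m in methods) {
      labs <- switch(m,
        smilegan = patternLabels(predictProbabilities(
          smileGAN(cnP, ptP, K, control, seed = seed + r), normPT)),
        kmeans_raw = .withSeed(seed + r,
          stats::kmeans(rawPT, centers = K, nstart = 10)$cluster),
        kmeans_norm = .withSeed(seed + r,
          stats::kmeans(normPT, centers = K, nstart = 10)$cluster),
        gmm = {
          if (!requireNamespace("mclust", quietly = TRUE))
            stop("method 'gmm' requires the mclust package")
          .withSeed(seed + r,
            mclust::Mclust(normPT, G = K, modelNames = "EII",
                           verbose = FALSE)$classification)
        },
        stop("unknown method: ", m))
      out[[length(out) + 1L]] <- data.frame(
        method = m, replicate = r,
        ari = adjustedRandIndex(labs, sim$truth$subtype))
    }
  }
  do.call(rbind, out)
}
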