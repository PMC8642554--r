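#' Clustering stability of one candidate M by repeated holdout CV
#'
#' Runs \code{folds} training folds. In each fold 20% (by default) of the
#' pooled discovery set (CN and patient rows jointly, unstratified) is left
#' out to add variability, a model is trained on the remaining 80%, and ALL
#' discovery patient rows are labeled by the fold model's dominant pattern.
#' Stability is the mean (and SD) of the adjusted Rand index over all fold
#' pairs. A fold whose training collapses beyond the restart budget is
#' recorded as missing and excluded from the pairs.
#'
#' @param cn,pt preprocessed CN and patient data (experiment or matrix).
#' @param M candidate number of patterns.
#' @param folds number of CV folds (default 10).
#' @param holdoutFrac fraction left out per fold (default 0.2).
#' @param control a [smileGANControl()].
#' @param seed base seed; fold k uses seed + k.
#' @return list with \code{labelings} (folds x nPT, NA rows for failed
#'   folds), \code{pairwiseARI}, \code{meanARI}, \code{sdARI},
#'   \code{failedFolds}.
#' @export
holdoutStability <- function(cn, pt, M, folds = 10L, holdoutFrac = 0.2,
                             control = smileGANControl(), seed = 1L) {
  stopifnot(folds >= 2L)
  Xcn <- .sampleMatrix(cn); Xpt <- .sampleMatrix(pt)
  nCN <- nrow(Xcn); nPT <- nrow(Xpt); nAll <- nCN + nPT
  labelings <- matrix(NA_integer_, folds, nPT)
  failed <- integer(0)
  for (k in seq_len(folds)) {
    keep <- .withSeed(seed + k, sample.int(nAll, round((1 - holdoutFrac) * nAll)))
    keepCN <- keep[keep <= nCN]
    keepPT <- keep[keep > nCN] - nCN
    fit <- tryCatch(
      smileGAN(Xcn[keepCN, , drop = FALSE], Xpt[keepPT, , drop = FALSE],
               M, control, seed = seed + k),
      error = function(e) {
        message("fold ", k, " failed: ", conditionMessage(e)); NULL
      })
    if (is.null(fit)) { failed <- c(failed, k); next }
    labelings[k, ] <- patternLabels(predictProbabilities(fit, Xpt))
  }
  ok <- setdiff(seq_len(folds), failed)
  pairs <- utils::combn(ok, 2, simplify = FALSE)
  ari <- vapply(pairs, function(p)
    adjustedRandIndex(labelings[p[1], ], labelings[p[2], ]), numeric(1))
  list(labelings = labelings, pairwiseARI = ari,
       meanARI = mean(ari), sdARI = stats::sd(ari), failedFolds = failed)
}

# argmax of mean ARI with ties broken toward smaller M
.chooseM <- function(MRange, meanARI) {
  o <- order(MRange)
  MRange <- MRange[o]; meanARI <- meanARI[o]
  MRange[which.max(meanARI)]
}

#' Choose the number of patterns by clustering stability
#'
#' Runs [holdoutStability()] for every candidate M and picks the argmax of
#' the mean pairwise ARI, breaking ties toward the smaller M.
#'
#' @inheritParams holdoutStability
#' @param MRange integer vector of candidate pattern counts.
#' @return a [StabilityReport-class].
#' @export
selectM <- function(cn, pt, MRange, folds = 10L, holdoutFrac = 0.2,
                    control = smileGANControl(), seed = 1L) {
  stopifnot(length(MRange) >= 1L)
  MRange <- as.integer(sort(MRange))
  res <- lapply(seq_along(MRange), function(i)
    holdoutStability(cn, pt, MRange[i], folds, holdoutFrac, control,
                     seed = seed + 1000L * (i - 1L)))
  stats <- data.frame(
    M = MRange,
    meanARI = vapply(res, `[[`, numeric(1), "meanARI"),
    sdARI = vapply(res, `[[`, numeric(1), "sdARI"),
    nPairs = vapply(res, function(r) length(r$pairwiseARI), integer(1)),
    nFolds = folds - vapply(res, function(r) length(r$failedFolds), integer(1)))
  if (all(!is.finite(stats$meanARI))) stop("stability failed for every M")
  methods::new("StabilityReport", stats = stats,
               labelings = lapply(res, `[[`, "labelings"),
               pairwise = lapply(res, `[[`, "pairwiseARI"),
               chosenM = as.integer(.chooseM(MRange, stats$meanARI)))
}

#' Train an ensemble of Smile-GAN models
#'
#' Independently trains \code{nModels} models (seeds \code{seed},
#' \code{seed + 1}, ...) on the full discovery set, the input to
#' [buildConsensus()]. The published protocol uses 30 models.
#'
#' @inheritParams holdoutStability
#' @param nModels ensemble size (default 30).
#' @return list of [SmileGANModel-class] objects.
#' @export
trainEnsemble <- function(cn, pt, M, nModels = 30L,
                          control = smileGANControl(), seed = 1L) {
  lapply(seq_len(nModels) - 1L, function(k)
    smileGAN(cn, pt, M, control, seed = seed + 100L * k))
}

#' Build the label-aligned consensus ensemble
#'
#' Labels the reference patient rows with every model, chooses as template
#' the model with the highest mean pairwise ARI against all others, and
#' reorders every other model's patterns by [matchLabels()] so their
#' clustering overlaps the template maximally. Consensus probabilities are
#' the arithmetic mean of the aligned per-model probabilities (rows stay on
#' the simplex).
#'
#' @param models list of [SmileGANModel-class] objects sharing M and ROI
#'   names.
#' @param referencePt preprocessed patient data used for template selection
#'   and alignment.
#' @return a [SmileGANEnsemble-class].
#' @export
buildConsensus <- function(models, referencePt) {
  stopifnot(length(models) >= 1L)
  M <- models[[1]]@M
  rn <- models[[1]]@roiNames
  for (m in models) {
    if (m@M != M) stop("all models must share M")
    if (!identical(m@roiNames, rn)) stop("all models must share ROI names")
  }
  X <- .sampleMatrix(referencePt)
  labs <- lapply(models, function(m) patternLabels(predictProbabilities(m, X)))
  k <- length(models)
  template <- 1L
  if (k > 1L) {
    ariMat <- matrix(1, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      ariMat[i, j] <- ariMat[j, i] <- adjustedRandIndex(labs[[i]], labs[[j]])
    meanARI <- (rowSums(ariMat) - 1) / (k - 1)
    template <- which.max(meanARI)
  }
  perms <- lapply(seq_len(k), function(i)
    if (i == template) seq_len(M) else matchLabels(labs[[template]], labs[[i]], M))
  methods::new("SmileGANEnsemble", models = models,
               templateIndex = as.integer(template), permutations = perms,
               M = M, roiNames = rn)
}

#' @describeIn predictProbabilities ensemble: per-model probabilities are
#'   column-permuted onto the template's label order and averaged.
#' @export
setMethod("predictProbabilities", "SmileGANEnsemble",
          function(object, newdata, ...) {
  X <- .sampleMatrix(newdata)
  acc <- NULL
  for (i in seq_along(object@models)) {
    q <- predictProbabilities(object@models[[i]], X)
    aligned <- q
    aligned[, object@permutations[[i]]] <- q
    acc <- if (is.null(acc)) aligned else acc + aligned
  }
  q <- acc / length(object@models)
  colnames(q) <- paste0("P", seq_len(object@M))
  q
})

#' Permutation test of clustering reproducibility
#'
#' Tests whether the observed holdout-CV stability exceeds what group
#' structure alone would produce. The observed statistic is the mean
#' pairwise ARI from [holdoutStability()]; the null distribution is built
#' by randomly reassigning the CN/patient group labels (preserving group
#' sizes) and recomputing the statistic. Note this protocol is a
#' reconstruction: the original permutation design is described only in
#' supplementary material that does not accompany the main text.
#'
#' @inheritParams holdoutStability
#' @param nPermutations number of null draws (>= 19).
#' @return list with \code{observed}, \code{null} (vector), \code{p}
#'   where \code{p = (1 + #\{null >= observed\}) / (1 + nPermutations)}.
#' @export
permutationReproducibility <- function(cn, pt, M, nPermutations = 19L,
                                       folds = 10L, holdoutFrac = 0.2,
                                       control = smileGANControl(),
                                       seed = 1L) {
  stopifnot(nPermutations >= 19L)
  Xcn <- .sampleMatrix(cn); Xpt <- .sampleMatrix(pt)
  obs <- holdoutStability(Xcn, Xpt, M, folds, holdoutFrac, control,
                          seed = seed)$meanARI
  pooled <- rbind(Xcn, Xpt)
  nCN <- nrow(Xcn); nAll <- nrow(pooled)
  null <- vapply(seq_len(nPermutations), function(b) {
    idx <- .withSeed(seed + 10000L + b, sample.int(nAll))
    holdoutStability(pooled[idx[seq_len(nCN)], , drop = FALSE],
                     pooled[idx[(nCN + 1):nAll], , drop = FALSE],
                     M, folds, holdoutFrac, control,
                     seed = seed + 20000L * b)$meanARI
  }, numeric(1))
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (1 + nPermutations))
}
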