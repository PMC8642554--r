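#' Number of patterns (subtypes) of a model or ensemble
#' @param object a [SmileGANModel-class] or [SmileGANEnsemble-class].
#' @return integer M.
#' @export
setGeneric("nPatterns", function(object) standardGeneric("nPatterns"))

#' ROI feature names of a fitted object
#' @param object a fitted smilegan object.
#' @return character vector of ROI names in model order.
#' @export
setGeneric("roiNames", function(object) standardGeneric("roiNames"))

#' Per-iteration training loss history
#' @param object a [SmileGANModel-class].
#' @return numeric matrix with columns adversarial, change, cluster.
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' Predict pattern pseudo-probabilities
#'
#' Applies the clustering network g to preprocessed patient features and
#' returns the n x M matrix of pattern probabilities (rows on the simplex).
#' For an ensemble, each member's columns are first aligned to the template
#' by its stored label permutation, then averaged.
#'
#' @param object a [SmileGANModel-class] or [SmileGANEnsemble-class].
#' @param newdata ROI \code{SummarizedExperiment} or scans x ROI matrix on
#'   the same normalized scale (CN mean 1, SD 0.1) as the training data.
#' @param ... unused.
#' @return numeric matrix, scans x M, each row summing to 1.
#' @export
setGeneric("predictProbabilities",
           function(object, newdata, ...) standardGeneric("predictProbabilities"))

setMethod("nPatterns", "SmileGANModel", function(object) object@M)
setMethod("nPatterns", "SmileGANEnsemble", function(object) object@M)
setMethod("roiNames", "SmileGANModel", function(object) object@roiNames)
setMethod("roiNames", "SmileGANEnsemble", function(object) object@roiNames)
setMethod("roiNames", "CovariateModel",
          function(object) rownames(object@coefficients))
setMethod("roiNames", "ROINormalizer", function(object) names(object@mu))
setMethod("lossHistory", "SmileGANModel", function(object) object@lossHistory)

setMethod("show", "CovariateModel", function(object) {
  cat("CovariateModel:", nrow(object@coefficients), "ROIs,",
      "fitted on", object@nFit, "CN scans\n")
  cat("  CN covariate means: age =", signif(object@covariateMeans["age"], 4),
      ", sex =", signif(object@covariateMeans["sex"], 4), "\n")
})

setMethod("show", "ROINormalizer", function(object) {
  cat("ROINormalizer:", length(object@mu), "ROIs -> CN mean",
      object@targetMean, ", SD", object@targetSd, "\n")
})

setMethod("show", "SmileGANModel", function(object) {
  cat("SmileGANModel: M =", object@M, "patterns,",
      length(object@roiNames), "ROIs\n")
  cat("  seed", object@seed, "|", nrow(object@lossHistory),
      "iterations |", if (object@converged) "converged" else "iteration cap",
      "|", object@restarts, "restart(s)\n")
  if (nrow(object@lossHistory)) {
    last <- object@lossHistory[nrow(object@lossHistory), ]
    cat("  final losses: adversarial", signif(last[1], 4),
        "change", signif(last[2], 4), "cluster", signif(last[3], 4), "\n")
  }
})

setMethod("show", "SmileGANEnsemble", function(object) {
  cat("SmileGANEnsemble:", length(object@models), "models, M =", object@M,
      ", template = model", object@templateIndex, "\n")
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport (repeated holdout CV):\n")
  print(object@stats, row.names = FALSE)
  cat("chosen M =", object@chosenM, "\n")
})

#' Accessor: stability statistics table
#' @param object a [StabilityReport-class].
#' @return data.frame of per-M stability statistics.
#' @export
stabilityStats <- function(object) object@stats

#' Accessor: chosen number of patterns
#' @param object a [StabilityReport-class].
#' @return integer.
#' @export
chosenM <- function(object) object@chosenM
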