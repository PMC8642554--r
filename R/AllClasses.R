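#' @import methods
NULL

#' Per-ROI age/sex covariate model
#'
#' Ordinary least squares coefficients of volume on (intercept, age, sex),
#' one triple per ROI, fitted exclusively on the cognitively normal (CN)
#' reference group. Residualization subtracts covariate deviations from the
#' CN covariate means, so the CN-referenced intercept is preserved.
#'
#' @slot coefficients numeric matrix, ROIs x c(intercept, age, sex).
#' @slot covariateMeans numeric, CN means of c(age, sex).
#' @slot nFit integer, number of CN scans used in the fit.
#' @exportClass CovariateModel
setClass("CovariateModel",
  representation(coefficients = "matrix", covariateMeans = "numeric",
                 nFit = "integer"),
  validity = function(object) {
    if (!identical(colnames(object@coefficients), c("intercept", "age", "sex")))
      return("coefficients must have columns intercept, age, sex")
    if (object@nFit < 10L) return("covariate model must be fitted on >= 10 CN scans")
    if (anyNA(object@coefficients)) return("coefficients contain NA")
    TRUE
  })

#' CN-referenced ROI normalizer
#'
#' Stores the per-ROI mean and standard deviation of the residualized CN
#' reference group, and maps each ROI affinely so that the CN group has
#' mean \code{targetMean} (1) and SD \code{targetSd} (0.1).
#'
#' @slot mu named numeric, per-ROI CN mean.
#' @slot sigma named numeric, per-ROI CN SD (sample, n-1 denominator), > 0.
#' @slot targetMean,targetSd numeric scalars (1 and 0.1).
#' @exportClass ROINormalizer
setClass("ROINormalizer",
  representation(mu = "numeric", sigma = "numeric",
                 targetMean = "numeric", targetSd = "numeric"),
  prototype(targetMean = 1, targetSd = 0.1),
  validity = function(object) {
    if (length(object@mu) != length(object@sigma))
      return("mu and sigma must have equal length")
    if (any(object@sigma <= 0)) return("sigma must be > 0 for every ROI")
    if (is.null(names(object@mu))) return("mu must be named by ROI")
    TRUE
  })

#' A trained Smile-GAN model
#'
#' One draw of the stochastic adversarial training procedure: the mapping
#' network f (CN features + one-hot subtype code -> synthetic patient
#' features), the clustering network g (patient features -> M-simplex), the
#' discriminator D, hyperparameters, seed, and the per-iteration loss
#' history.
#'
#' @slot M integer, number of patterns.
#' @slot roiNames character, feature names in training order.
#' @slot mapping,clustering,discriminator internal network parameter lists.
#' @slot control the [smileGANControl()] list used.
#' @slot seed integer seed of the successful attempt.
#' @slot lossHistory numeric matrix with columns adversarial, change,
#'   cluster (one row per generator iteration actually run).
#' @slot converged logical, plateau stopping rule fired before the
#'   iteration cap.
#' @slot collapsed logical, final model failed the minimum-cluster-size
#'   check.
#' @slot restarts integer, number of collapse restarts consumed.
#' @slot trainLabels integer, argmax pattern labels of the training patient
#'   rows under the final model.
#' @exportClass SmileGANModel
setClass("SmileGANModel",
  representation(M = "integer", roiNames = "character", mapping = "list",
                 clustering = "list", discriminator = "list",
                 control = "list", seed = "integer", lossHistory = "matrix",
                 converged = "logical", collapsed = "logical",
                 restarts = "integer", trainLabels = "integer"),
  validity = function(object) {
    if (object@M < 2L) return("M must be >= 2")
    if (length(object@lossHistory) && any(!is.finite(object@lossHistory)))
      return("loss history must be finite")
    TRUE
  })

#' Consensus ensemble of Smile-GAN models
#'
#' A set of independently trained models aligned to a template by
#' ARI-optimal label permutation; pattern probabilities are averaged across
#' the aligned models.
#'
#' @slot models list of [SmileGANModel-class] objects sharing M and
#'   roiNames.
#' @slot templateIndex integer, the model with the highest mean pairwise
#'   ARI against the others on the reference cohort.
#' @slot permutations list of integer bijections on 1..M; entry k maps
#'   model k's pattern labels onto the template's (identity for the
#'   template).
#' @slot M integer; @slot roiNames character.
#' @exportClass SmileGANEnsemble
setClass("SmileGANEnsemble",
  representation(models = "list", templateIndex = "integer",
                 permutations = "list", M = "integer",
                 roiNames = "character"),
  validity = function(object) {
    if (length(object@models) < 1L) return("ensemble needs >= 1 model")
    if (length(object@permutations) != length(object@models))
      return("one permutation per model required")
    for (p in object@permutations)
      if (!identical(sort(p), seq_len(object@M)))
        return("permutations must be bijections on 1..M")
    if (!identical(object@permutations[[object@templateIndex]],
                   seq_len(object@M)))
      return("template permutation must be the identity")
    TRUE
  })

#' Clustering-stability report for choosing M
#'
#' Per candidate number of patterns M: the per-fold dominant-pattern
#' labelings from repeated holdout cross-validation, all pairwise adjusted
#' Rand indices, and their mean and SD; plus the chosen M (argmax of the
#' mean pairwise ARI, ties toward smaller M).
#'
#' @slot stats data.frame with columns M, meanARI, sdARI, nPairs, nFolds.
#' @slot labelings list (one matrix per M, folds x n patient rows).
#' @slot pairwise list (one numeric vector per M).
#' @slot chosenM integer.
#' @exportClass StabilityReport
setClass("StabilityReport",
  representation(stats = "data.frame", labelings = "list",
                 pairwise = "list", chosenM = "integer"),
  validity = function(object) {
    if (!all(c("M", "meanARI", "sdARI", "nPairs", "nFolds") %in%
             colnames(object@stats)))
      return("stats must have columns M, meanARI, sdARI, nPairs, nFolds")
    ok <- vapply(object@pairwise,
                 function(p) !length(p) || all(p >= -1 - 1e-9 & p <= 1 + 1e-9),
                 logical(1))
    if (!all(ok)) return("pairwise ARI values must lie in [-1, 1]")
    TRUE
  })
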