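#' Fit the per-ROI age/sex covariate model on the CN reference group
#'
#' Ordinary least squares of each ROI volume on age and sex, fitted only on
#' cognitively normal (CN) scans. The fitted coefficients are later used to
#' residualize all data (CN and patient, cross-sectional and longitudinal)
#' so that non-disease covariate effects estimated in the reference group
#' are removed everywhere.
#'
#' @param cn ROI \code{SummarizedExperiment} containing only CN scans
#'   (diagnosis \code{"CN"} or \code{NA} treated as an error / accepted
#'   respectively is strict: all non-NA diagnoses must be CN).
#' @return a [CovariateModel-class].
#' @details A collinear covariate (e.g. constant sex) gets coefficient 0
#'   with a warning. Fewer than 10 CN scans is refused.
#' @export
fitCovariateModel <- function(cn) {
  validateROIExperiment(cn)
  dx <- SummarizedExperiment::colData(cn)$diagnosis
  if (any(!is.na(dx) & dx != "CN"))
    stop("covariate model must be fitted on CN scans only")
  X <- .sampleMatrix(cn)                      # n x R
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 CN scans to fit the covariate model, got ", n)
  age <- SummarizedExperiment::colData(cn)$age
  sex <- SummarizedExperiment::colData(cn)$sex
  fit <- stats::lm(X ~ age + sex)
  co <- t(stats::coef(fit))                   # R x 3
  colnames(co) <- c("intercept", "age", "sex")
  if (anyNA(co)) {
    bad <- colnames(co)[apply(co, 2, anyNA)]
    warning("collinear covariate(s) dropped (coefficient set to 0): ",
            paste(bad, collapse = ", "))
    co[is.na(co)] <- 0
  }
  rownames(co) <- colnames(X)
  methods::new("CovariateModel", coefficients = co,
               covariateMeans = c(age = mean(age), sex = mean(sex)),
               nFit = as.integer(n))
}

#' Residualize ROI volumes by CN-estimated age/sex effects
#'
#' Subtracts covariate deviations from the CN covariate means:
#' \code{v' = v - beta_age (age - meanAge) - beta_sex (sex - meanSex)}.
#' The CN-referenced intercept is kept, so the CN per-ROI mean is unchanged
#' and a value of "typical CN volume" stays interpretable. Applied
#' identically to CN and patient scans, cross-sectional and longitudinal,
#' using each scan's actual age.
#'
#' @param se ROI \code{SummarizedExperiment}.
#' @param model a [CovariateModel-class] fitted with [fitCovariateModel()].
#' @return the experiment with the \code{volumes} assay residualized.
#' @export
residualize <- function(se, model) {
  validateROIExperiment(se)
  v <- SummarizedExperiment::assay(se, "volumes")
  if (!identical(rownames(v), roiNames(model)))
    stop("ROI names of the data do not match the covariate model")
  cd <- SummarizedExperiment::colData(se)
  dAge <- cd$age - model@covariateMeans["age"]
  dSex <- cd$sex - model@covariateMeans["sex"]
  adj <- outer(model@coefficients[, "age"], dAge) +
         outer(model@coefficients[, "sex"], dSex)
  SummarizedExperiment::assay(se, "volumes") <- v - adj
  se
}

#' Fit the CN-referenced normalizer
#'
#' Records the per-ROI mean and sample SD (n-1 denominator) of the
#' residualized CN reference group.
#'
#' @param cn residualized CN ROI \code{SummarizedExperiment}.
#' @return a [ROINormalizer-class] targeting CN mean 1, SD 0.1.
#' @export
fitNormalizer <- function(cn) {
  validateROIExperiment(cn)
  dx <- SummarizedExperiment::colData(cn)$diagnosis
  if (any(!is.na(dx) & dx != "CN"))
    stop("normalizer must be fitted on CN scans only")
  v <- SummarizedExperiment::assay(cn, "volumes")
  mu <- rowMeans(v)
  sigma <- apply(v, 1, stats::sd)
  if (any(sigma <= 0))
    stop("zero-variance ROI(s): ",
         paste(rownames(v)[sigma <= 0], collapse = ", "))
  methods::new("ROINormalizer", mu = mu, sigma = sigma,
               targetMean = 1, targetSd = 0.1)
}

#' Apply the CN-referenced normalization
#'
#' Maps every ROI affinely, \code{v' = 1 + 0.1 (v - mu) / sigma}, so the CN
#' reference group has per-ROI mean 1 and SD 0.1. Applied to all scans (CN,
#' patients, longitudinal) with the CN-fitted parameters.
#'
#' @param se ROI \code{SummarizedExperiment} (residualized).
#' @param norm a [ROINormalizer-class].
#' @return the experiment on the normalized scale.
#' @export
normalizeROIs <- function(se, norm) {
  validateROIExperiment(se)
  v <- SummarizedExperiment::assay(se, "volumes")
  if (!identical(rownames(v), roiNames(norm)))
    stop("ROI names of the data do not match the normalizer")
  SummarizedExperiment::assay(se, "volumes") <-
    norm@targetMean + norm@targetSd * (v - norm@mu) / norm@sigma
  se
}

#' Residualize and normalize a whole cohort against its CN scans
#'
#' Convenience wrapper for the full preprocessing contract: fits the
#' covariate model and the normalizer on the CN scans only, then applies
#' both to every scan in the cohort.
#'
#' @param se ROI \code{SummarizedExperiment} with a \code{diagnosis}
#'   column containing at least 10 CN scans.
#' @return list with elements \code{data} (preprocessed experiment),
#'   \code{covariateModel}, \code{normalizer}.
#' @export
preprocessCohort <- function(se) {
  cn <- .diagnosisSubset(se, "CN")
  model <- fitCovariateModel(cn)
  norm <- fitNormalizer(residualize(cn, model))
  list(data = normalizeROIs(residualize(se, model), norm),
       covariateModel = model, normalizer = norm)
}

#' Serialize / restore preprocessing parameters as versioned JSON
#'
#' @param object a [CovariateModel-class] or [ROINormalizer-class].
#' @param path output JSON file.
#' @return \code{path} invisibly; readers return the restored object.
#' @export
writeCovariateModel <- function(object, path) {
  doc <- list(format = "smilegan-covariate-model", version = 1L,
              roi = rownames(object@coefficients),
              intercept = unname(object@coefficients[, "intercept"]),
              beta_age = unname(object@coefficients[, "age"]),
              beta_sex = unname(object@coefficients[, "sex"]),
              mean_age = unname(object@covariateMeans["age"]),
              mean_sex = unname(object@covariateMeans["sex"]),
              n_fit = object@nFit)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCovariateModel
#' @export
readCovariateModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "smilegan-covariate-model"))
    stop("not a covariate-model document: ", path)
  co <- cbind(intercept = doc$intercept, age = doc$beta_age, sex = doc$beta_sex)
  rownames(co) <- doc$roi
  methods::new("CovariateModel", coefficients = co,
               covariateMeans = c(age = doc$mean_age, sex = doc$mean_sex),
               nFit = as.integer(doc$n_fit))
}

#' @rdname writeCovariateModel
#' @export
writeNormalizer <- function(object, path) {
  doc <- list(format = "smilegan-normalizer", version = 1L,
              roi = names(object@mu), mu = unname(object@mu),
              sigma = unname(object@sigma),
              target_mean = object@targetMean, target_sd = object@targetSd)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCovariateModel
#' @export
readNormalizer <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "smilegan-normalizer"))
    stop("not a normalizer document: ", path)
  mu <- doc$mu; names(mu) <- doc$roi
  sigma <- doc$sigma; names(sigma) <- doc$roi
  methods::new("ROINormalizer", mu = mu, sigma = sigma,
               targetMean = doc$target_mean, targetSd = doc$target_sd)
}
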