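# Versioned JSON archives for trained models and ensembles. JSON keeps the
# archives portable and text-only; numbers are written at full double
# precision, so reloaded models reproduce predictions to ~1e-15 relative.

.netToList <- function(net) {
  list(W = lapply(net$W, function(w) unclass(as.matrix(w))),
       b = net$b, head = net$head, slope = net$slope, sizes = net$sizes)
}

.netFromList <- function(x) {
  list(W = lapply(x$W, as.matrix), b = lapply(x$b, as.numeric),
       head = x$head, slope = x$slope, sizes = as.integer(x$sizes))
}

#' Save / load a trained model as a versioned JSON archive
#'
#' The archive stores the three networks, hyperparameters, seed, loss
#' history and ROI names. Loading refuses when the stored ROI names do not
#' match \code{expectedRoiNames} (when given).
#'
#' @param model a [SmileGANModel-class].
#' @param path JSON file path.
#' @return \code{path} invisibly; the reader returns the restored model.
#' @export
saveSmileGANModel <- function(model, path) {
  doc <- list(format = "smilegan-model", version = 1L, M = model@M,
              roi = model@roiNames, seed = model@seed,
              control = model@control,
              mapping = .netToList(model@mapping),
              clustering = .netToList(model@clustering),
              discriminator = .netToList(model@discriminator),
              lossHistory = unclass(model@lossHistory),
              converged = model@converged, collapsed = model@collapsed,
              restarts = model@restarts, trainLabels = model@trainLabels)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSmileGANModel
#' @param expectedRoiNames optional ROI names the archive must match.
#' @export
readSmileGANModel <- function(path, expectedRoiNames = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "smilegan-model"))
    stop("not a model archive: ", path)
  if (!is.null(expectedRoiNames) && !identical(doc$roi, expectedRoiNames))
    stop("ROI names of the archive do not match the expected features")
  lh <- as.matrix(doc$lossHistory)
  colnames(lh) <- c("adversarial", "change", "cluster")
  ctrl <- doc$control
  methods::new("SmileGANModel", M = as.integer(doc$M),
               roiNames = doc$roi,
               mapping = .netFromList(doc$mapping),
               clustering = .netFromList(doc$clustering),
               discriminator = .netFromList(doc$discriminator),
               control = ctrl, seed = as.integer(doc$seed),
               lossHistory = lh, converged = doc$converged,
               collapsed = doc$collapsed,
               restarts = as.integer(doc$restarts),
               trainLabels = as.integer(doc$trainLabels))
}

#' Save / load a consensus ensemble
#'
#' Writes one archive per member model plus an index file with the
#' template and label permutations.
#'
#' @param ensemble a [SmileGANEnsemble-class].
#' @param dir output directory (created if needed).
#' @return \code{dir} invisibly; the reader returns the restored ensemble.
#' @export
saveSmileGANEnsemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble@models))
    saveSmileGANModel(ensemble@models[[i]],
                      file.path(dir, sprintf("model_%03d.json", i)))
  idx <- list(format = "smilegan-ensemble", version = 1L,
              n = length(ensemble@models),
              templateIndex = ensemble@templateIndex,
              permutations = ensemble@permutations,
              M = ensemble@M, roi = ensemble@roiNames)
  jsonlite::write_json(idx, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveSmileGANEnsemble
#' @export
readSmileGANEnsemble <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                             simplifyVector = TRUE)
  if (!identical(idx$format, "smilegan-ensemble"))
    stop("not an ensemble archive: ", dir)
  models <- lapply(seq_len(idx$n), function(i)
    readSmileGANModel(file.path(dir, sprintf("model_%03d.json", i)), idx$roi))
  perms <- if (is.matrix(idx$permutations))
    lapply(seq_len(nrow(idx$permutations)),
           function(i) as.integer(idx$permutations[i, ]))
  else lapply(idx$permutations, as.integer)
  methods::new("SmileGANEnsemble", models = models,
               templateIndex = as.integer(idx$templateIndex),
               permutations = perms, M = as.integer(idx$M), roiNames = idx$roi)
}
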