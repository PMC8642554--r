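#' Training hyperparameters for Smile-GAN
#'
#' All knobs of the alternating minimax loop. Defaults were calibrated on
#' the bundled synthetic-cohort harness so that disjoint-mask subtypes are
#' recovered reliably at desk scale; every value can be overridden.
#'
#' @param mu weight of the L1 change loss (sparsity of the transformation).
#' @param lambda weight of the cross-entropy cluster loss.
#' @param lrG,lrD Adam learning rates for the generator pair (f, g) and the
#'   discriminator D.
#' @param batchSize minibatch size per group.
#' @param maxIter maximum number of generator iterations.
#' @param dSteps discriminator updates per generator update.
#' @param dWarmup discriminator-only updates run before the joint loop, so
#'   the adversarial signal points at the real patient modes before the
#'   mapping starts moving.
#' @param leakySlope negative-side slope of the leaky rectifier.
#' @param clipRadius Lipschitz control: every discriminator weight and bias
#'   is clamped to \code{[-clipRadius, clipRadius]} after each update.
#' @param clipAll also clamp f and g (off by default).
#' @param plateauWindow,plateauTol stopping rule: a plateau is declared
#'   when the moving averages of the change loss and the cluster loss over
#'   the last \code{plateauWindow} iterations each differ from the
#'   previous window by less than \code{plateauTol}.
#' @param labelStabilityARI corroboration required to stop at a plateau:
#'   the dominant-pattern labels of the training patient rows must agree
#'   across two consecutive checks at least this well (ARI) while every
#'   pattern keeps at least \code{collapseThreshold} of the rows. A
#'   plateau without stable labels keeps training (the run is still
#'   aligning); stable labels with a collapsed pattern end in a restart.
#' @param collapseThreshold minimum fraction of patient rows a pattern must
#'   dominate; below it the run is marked collapsed and restarted with
#'   seed + 1.
#' @param maxRestarts collapse restart budget.
#' @param ganForm \code{"standard"} conventional GAN value with
#'   non-saturating generator loss (default) or \code{"printed"} published
#'   variant (see [adversarialLosses()]).
#' @param residual parameterize the mapping as f(x, z) = x + MLP(\[x, z\]),
#'   so the sparse-transformation prior starts at the identity. With
#'   \code{FALSE} the mapping is the plain MLP output.
#' @param hiddenF,hiddenG,hiddenD hidden-layer widths as fractions of the
#'   feature count R (defaults R/2, R/4, R/2 for f; R/2, R/4 for g; R/2,
#'   R/8 for D).
#' @param eps probability clipping floor before logarithms.
#' @param checkEvery how often (iterations) the plateau rule is evaluated.
#' @param engine \code{"cpp"} (compiled loop, default) or \code{"R"}
#'   (reference implementation in plain R; identical mechanics, kept for
#'   inspection and cross-checking). Each engine is deterministic given
#'   (data, control, seed).
#' @return a named list of class \code{smileGANControl}.
#' @export
smileGANControl <- function(mu = 0.5, lambda = 2, lrG = 1e-3, lrD = 1e-3,
                            batchSize = 25L, maxIter = 8000L, dSteps = 3L,
                            dWarmup = 300L,
                            leakySlope = 0.2, clipRadius = 0.5,
                            clipAll = FALSE, plateauWindow = 1000L,
                            plateauTol = 0.05, collapseThreshold = 0.05,
                            labelStabilityARI = 0.995,
                            maxRestarts = 3L,
                            ganForm = c("standard", "printed"),
                            residual = TRUE,
                            hiddenF = c(0.5, 0.25, 0.5),
                            hiddenG = c(0.5, 0.25),
                            hiddenD = c(0.5, 0.125),
                            eps = 1e-12, checkEvery = 250L,
                            engine = c("cpp", "R")) {
  ganForm <- match.arg(ganForm)
  engine <- match.arg(engine)
  stopifnot(mu >= 0, lambda >= 0, clipRadius > 0, batchSize >= 2,
            maxIter >= 1, dSteps >= 1, collapseThreshold >= 0,
            maxRestarts >= 0)
  structure(list(mu = mu, lambda = lambda, lrG = lrG, lrD = lrD,
                 batchSize = as.integer(batchSize),
                 maxIter = as.integer(maxIter), dSteps = as.integer(dSteps),
                 dWarmup = as.integer(dWarmup),
                 leakySlope = leakySlope, clipRadius = clipRadius,
                 clipAll = clipAll,
                 plateauWindow = as.integer(plateauWindow),
                 plateauTol = plateauTol,
                 collapseThreshold = collapseThreshold,
                 labelStabilityARI = labelStabilityARI,
                 maxRestarts = as.integer(maxRestarts), ganForm = ganForm,
                 residual = residual, hiddenF = hiddenF, hiddenG = hiddenG,
                 hiddenD = hiddenD, eps = eps,
                 checkEvery = as.integer(checkEvery), engine = engine),
            class = "smileGANControl")
}

.width <- function(R, fracs) pmax(2L, as.integer(round(R * fracs)))

.initNetworks <- function(R, M, ctrl) {
  list(
    f = .mlpInit(c(R + M, .width(R, ctrl$hiddenF), R), "linear",
                 ctrl$leakySlope, zeroHead = ctrl$residual),
    g = .mlpInit(c(R, .width(R, ctrl$hiddenG), M), "softmax",
                 ctrl$leakySlope),
    d = .mlpInit(c(R, .width(R, ctrl$hiddenD), 1L), "sigmoid",
                 ctrl$leakySlope))
}

.fForward <- function(f, X, Z, residual, cache = FALSE) {
  fw <- .mlpForward(f, cbind(X, Z), cache = cache)
  if (residual) fw$out <- fw$out + X
  fw
}

# one full seeded training run; returns nets + history + flags
.trainOnce <- function(Xcn, Xpt, M, ctrl, seed) {
  .withSeed(seed, {
    nets <- .initNetworks(ncol(Xcn), M, ctrl)
    if (identical(ctrl$engine, "R")) {
      .trainLoopR(Xcn, Xpt, M, ctrl, nets)
    } else {
      res <- .cppTrainLoop(Xcn, Xpt, as.integer(M), nets$f, nets$g, nets$d,
                           ctrl)
      colnames(res$hist) <- c("adversarial", "change", "cluster")
      list(nets = list(f = res$f, g = res$g, d = res$d), hist = res$hist,
           converged = res$converged)
    }
  })
}

# plain-R reference engine: the readable mirror of the compiled loop
.trainLoopR <- function(Xcn, Xpt, M, ctrl, nets) {
    stF <- .adamInit(nets$f); stG <- .adamInit(nets$g); stD <- .adamInit(nets$d)
    B <- ctrl$batchSize
    hist <- matrix(NA_real_, ctrl$maxIter, 3,
                   dimnames = list(NULL, c("adversarial", "change", "cluster")))
    converged <- FALSE
    lastLabs <- NULL; wasStable <- FALSE
    nCN <- nrow(Xcn); nPT <- nrow(Xpt)
    # one discriminator ascent step on a fresh real/fake minibatch,
    # mutating nets$d and its Adam state in the enclosing frame
    dStep <- function() {
      xb <- Xcn[sample.int(nCN, B, replace = TRUE), , drop = FALSE]
      yb <- Xpt[sample.int(nPT, B, replace = TRUE), , drop = FALSE]
      zb <- sampleSubtypes(M, B)
      fake <- .fForward(nets$f, xb, zb, ctrl$residual)$out
      fwR <- .mlpForward(nets$d, yb, cache = TRUE)
      fwF <- .mlpForward(nets$d, fake, cache = TRUE)
      pR <- fwR$out; pF <- fwF$out
      dzR <- (pR - 1) / B
      dzF <- if (ctrl$ganForm == "standard") pF / B else (1 - pF) / B
      gR <- .mlpBackward(nets$d, fwR, dzR)
      gF <- .mlpBackward(nets$d, fwF, dzF)
      grads <- list(dW = Map(`+`, gR$dW, gF$dW), db = Map(`+`, gR$db, gF$db))
      up <- .adamStep(nets$d, grads, stD, ctrl$lrD)
      nets$d <<- .clipNet(up$net, ctrl$clipRadius); stD <<- up$state
      adversarialLosses(pR, pF, ctrl$ganForm)$discriminator
    }
    nWarm <- if (is.null(ctrl$dWarmup)) 0L else ctrl$dWarmup
    for (w in seq_len(nWarm)) dStep()
    for (t in seq_len(ctrl$maxIter)) {
      advVal <- NA_real_
      for (s in seq_len(ctrl$dSteps)) advVal <- dStep()
      ## ---- generator step (f and g jointly)
      xb <- Xcn[sample.int(nCN, B, replace = TRUE), , drop = FALSE]
      zb <- sampleSubtypes(M, B)
      fwf <- .fForward(nets$f, xb, zb, ctrl$residual, cache = TRUE)
      fake <- fwf$out
      fwD <- .mlpForward(nets$d, fake, cache = TRUE)
      fwG <- .mlpForward(nets$g, fake, cache = TRUE)
      pF <- fwD$out; q <- fwG$out
      dAdv <- .mlpBackward(nets$d, fwD, -(1 - pF) / B)$dInput
      dChg <- ctrl$mu * sign(fake - xb) / B
      gG <- .mlpBackward(nets$g, fwG, ctrl$lambda * (q - zb) / B)
      dY <- dAdv + dChg + gG$dInput
      gFnet <- .mlpBackward(nets$f, fwf, dY)
      upF <- .adamStep(nets$f, gFnet, stF, ctrl$lrG)
      nets$f <- upF$net; stF <- upF$state
      upG <- .adamStep(nets$g, gG, stG, ctrl$lrG)
      nets$g <- upG$net; stG <- upG$state
      if (ctrl$clipAll) {
        nets$f <- .clipNet(nets$f, ctrl$clipRadius)
        nets$g <- .clipNet(nets$g, ctrl$clipRadius)
      }
      hist[t, ] <- c(advVal, mean(rowSums(abs(fake - xb))),
                     mean(-rowSums(zb * log(pmin(pmax(q, ctrl$eps), 1)))))
      if (any(!is.finite(hist[t, ])))
        stop("non-finite loss at iteration ", t,
             " (adversarial/change/cluster = ",
             paste(signif(hist[t, ], 4), collapse = "/"), ")")
      ## ---- stopping rule: loss plateau + stable, non-degenerate labels.
      ## The loss moving averages alone cannot separate "converged" from
      ## "stalled before alignment" (minibatch noise floors the window
      ## deltas), so the plateau must be corroborated by the patient-row
      ## assignments holding still across two consecutive snapshots while
      ## every pattern keeps a non-collapsed share.
      W <- ctrl$plateauWindow
      if (t >= 2L * W && t %% ctrl$checkEvery == 0L) {
        cur <- colMeans(hist[(t - W + 1L):t, c("change", "cluster"), drop = FALSE])
        prev <- colMeans(hist[(t - 2L * W + 1L):(t - W), c("change", "cluster"),
                              drop = FALSE])
        if (all(abs(cur - prev) < ctrl$plateauTol)) {
          labs <- max.col(.fwdClustering(nets$g, Xpt), ties.method = "first")
          stable <- !is.null(lastLabs) &&
            adjustedRandIndex(labs, lastLabs) >= ctrl$labelStabilityARI &&
            min(tabulate(labs, nbins = M)) / nPT >= ctrl$collapseThreshold
          lastLabs <- labs
          if (stable && wasStable) {
            converged <- TRUE
            hist <- hist[seq_len(t), , drop = FALSE]
            break
          }
          wasStable <- stable
        } else {
          wasStable <- FALSE
        }
      }
    }
    if (!converged) hist <- hist[!is.na(hist[, 1]), , drop = FALSE]
    list(nets = nets, hist = hist, converged = converged)
}

#' Train a Smile-GAN model
#'
#' Alternating minimax training of the mapping f, clustering function g and
#' discriminator D on preprocessed CN and patient feature matrices (CN mean
#' 1 / SD 0.1 scale, see [preprocessCohort()]). Per generator iteration the
#' discriminator ascends the adversarial value (with weight clipping for
#' Lipschitz control) and (f, g) descend the full objective
#' \code{L_GAN + mu L_change + lambda L_cluster}. Training stops at the
#' iteration cap, or when the change- and cluster-loss moving averages
#' plateau while the patient-row assignments are stable and non-degenerate
#' (see [smileGANControl()]). If any learned pattern dominates fewer than
#' \code{collapseThreshold} of the patient rows, the run counts as
#' collapsed and is restarted with seed + 1 up to \code{maxRestarts} times.
#'
#' @param cn,pt CN and patient data: ROI \code{SummarizedExperiment}s or
#'   scans x ROI matrices with identical ROI columns.
#' @param M number of patterns (>= 2). Patient rows must number >= 5 M.
#' @param control a [smileGANControl()] list.
#' @param seed integer seed; the full run is a deterministic function of
#'   (data, control, seed).
#' @return a [SmileGANModel-class].
#' @seealso [predictProbabilities()], [buildConsensus()], [selectM()]
#' @export
smileGAN <- function(cn, pt, M, control = smileGANControl(), seed = 1L) {
  Xcn <- .sampleMatrix(cn); Xpt <- .sampleMatrix(pt)
  if (!identical(colnames(Xcn), colnames(Xpt)))
    stop("CN and patient data must share the same ROI columns")
  M <- as.integer(M)
  stopifnot(M >= 2L)
  if (nrow(Xpt) < 5L * M)
    stop("need at least 5*M patient rows, got ", nrow(Xpt))
  best <- NULL; bestFrac <- -Inf; restarts <- 0L
  for (attempt in 0:control$maxRestarts) {
    s <- as.integer(seed) + attempt
    run <- .trainOnce(Xcn, Xpt, M, control, s)
    q <- .fwdClustering(run$nets$g, Xpt)
    labs <- patternLabels(q)
    frac <- min(tabulate(labs, nbins = M)) / nrow(Xpt)
    collapsed <- frac < control$collapseThreshold
    if (frac > bestFrac) {
      bestFrac <- frac
      best <- list(run = run, labs = labs, seed = s, collapsed = collapsed)
    }
    if (!collapsed) break
    restarts <- attempt + 1L
  }
  if (best$collapsed)
    stop("all ", control$maxRestarts + 1L, " training attempts collapsed ",
         "(smallest pattern fraction ", signif(bestFrac, 3), " < ",
         control$collapseThreshold, ")")
  methods::new("SmileGANModel", M = M, roiNames = colnames(Xcn),
               mapping = best$run$nets$f, clustering = best$run$nets$g,
               discriminator = best$run$nets$d,
               control = unclass(control), seed = best$seed,
               lossHistory = best$run$hist,
               converged = best$run$converged, collapsed = FALSE,
               restarts = restarts, trainLabels = best$labs)
}

.fwdClustering <- function(g, X) .mlpForward(g, X)$out

#' Synthesize patient-like features from CN features and subtype codes
#'
#' Deterministic forward pass of the mapping function: y' = f(x, z).
#'
#' @param model a [SmileGANModel-class].
#' @param x scans x ROI matrix on the training scale.
#' @param z matching one-hot subtype batch (rows = scans, M columns).
#' @return scans x ROI matrix of synthesized features.
#' @export
synthesize <- function(model, x, z) {
  x <- as.matrix(x); z <- as.matrix(z)
  if (ncol(x) != length(model@roiNames)) stop("feature count mismatch")
  if (ncol(z) != model@M) stop("subtype code dimension mismatch")
  if (nrow(x) != nrow(z)) stop("batch sizes of x and z differ")
  .fForward(model@mapping, x, z, model@control$residual)$out
}

#' @describeIn predictProbabilities single trained model: rows are g(y_i).
#' @export
setMethod("predictProbabilities", "SmileGANModel", function(object, newdata, ...) {
  X <- .sampleMatrix(newdata)
  if (!identical(colnames(X), object@roiNames))
    stop("ROI columns do not match the model's training features")
  q <- .fwdClustering(object@clustering, X)
  rownames(q) <- rownames(X)
  colnames(q) <- paste0("P", seq_len(object@M))
  q
})

#' Dominant-pattern labels (argmax)
#'
#' Argmax pattern index per row; exact ties go to the lowest index.
#'
#' @param probs n x M probability matrix.
#' @return integer vector of labels in 1..M.
#' @export
patternLabels <- function(probs) max.col(as.matrix(probs), ties.method = "first")
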