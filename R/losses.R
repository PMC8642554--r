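#' Sample one-hot subtype codes
#'
#' Draws n independent one-hot vectors of dimension M, the 1 placed at each
#' position with equal probability 1/M, independently of the imaging data.
#'
#' @param M number of patterns (>= 2).
#' @param n number of draws (>= 1).
#' @param seed optional integer; when given, sampling uses a local RNG
#'   stream and the caller's stream is untouched.
#' @return n x M binary matrix, one 1 per row.
#' @export
sampleSubtypes <- function(M, n, seed = NULL) {
  stopifnot(M >= 2, n >= 1)
  draw <- function() sample.int(M, n, replace = TRUE)
  k <- if (is.null(seed)) draw() else .withSeed(seed, draw())
  z <- matrix(0, n, M)
  z[cbind(seq_len(n), k)] <- 1
  z
}

#' Change loss: mean L1 displacement of the mapping
#'
#' \code{mean_i || f(x_i, z_i) - x_i ||_1}, the sparsity-encouraging
#' penalty on the synthetic transformation away from the source features.
#'
#' @param x,yPrime matching numeric matrices (batch x features).
#' @return non-negative scalar.
#' @export
changeLoss <- function(x, yPrime) {
  x <- as.matrix(x); yPrime <- as.matrix(yPrime)
  if (!all(dim(x) == dim(yPrime))) stop("shape mismatch in changeLoss")
  mean(rowSums(abs(yPrime - x)))
}

#' Cluster loss: cross-entropy of the recovered subtype code
#'
#' \code{mean_i -sum_k z_ik log q_ik} with probabilities clipped to
#' \code{[eps, 1]} before the logarithm. Rows of \code{q} must lie on the
#' simplex (within 1e-6).
#'
#' @param z one-hot (or simplex) target batch.
#' @param q simplex batch from the clustering network.
#' @param eps clipping floor, default 1e-12.
#' @return non-negative scalar.
#' @export
clusterLoss <- function(z, q, eps = 1e-12) {
  z <- as.matrix(z); q <- as.matrix(q)
  if (!all(dim(z) == dim(q))) stop("shape mismatch in clusterLoss")
  if (any(abs(rowSums(q) - 1) > 1e-6) || any(q < -1e-9))
    stop("q rows must lie on the probability simplex")
  q <- pmin(pmax(q, eps), 1)
  mean(-rowSums(z * log(q)))
}

#' Adversarial objectives from discriminator outputs
#'
#' Given discriminator probabilities on real patient data and on
#' synthesized data, returns the discriminator objective (to be maximized)
#' and the generator objective (to be minimized). The default
#' \code{"standard"} form is the conventional GAN value
#' \code{E[log D(y)] + E[log(1 - D(y'))]} with the non-saturating generator
#' loss \code{-E[log D(y')]}; \code{"printed"} keeps the published variant
#' \code{E[log D(y)] + E[1 - log D(y')]} (generator gradient identical to
#' the non-saturating form).
#'
#' @param dReal,dFake numeric vectors of discriminator outputs in (0,1).
#' @param form \code{"standard"} or \code{"printed"}.
#' @param eps clipping floor for the logarithms.
#' @return list with elements \code{discriminator} and \code{generator}.
#' @export
adversarialLosses <- function(dReal, dFake, form = c("standard", "printed"),
                              eps = 1e-12) {
  form <- match.arg(form)
  if (!length(dReal) || !length(dFake)) stop("empty batch in adversarialLosses")
  dReal <- pmin(pmax(dReal, eps), 1 - eps)
  dFake <- pmin(pmax(dFake, eps), 1 - eps)
  disc <- if (form == "standard")
    mean(log(dReal)) + mean(log(1 - dFake))
  else
    mean(log(dReal)) + mean(1 - log(dFake))
  gen <- if (form == "standard") -mean(log(dFake)) else mean(1 - log(dFake))
  list(discriminator = disc, generator = gen)
}

#' Full training objective
#'
#' \code{L = L_GAN + mu * L_change + lambda * L_cluster}: the weighted sum
#' minimized over (f, g) and maximized over D.
#'
#' @param adversarial,change,cluster the three loss values.
#' @param mu,lambda non-negative weights of the change and cluster losses.
#' @return scalar.
#' @export
totalObjective <- function(adversarial, change, cluster, mu, lambda) {
  stopifnot(is.finite(adversarial), is.finite(change), is.finite(cluster),
            mu >= 0, lambda >= 0)
  adversarial + mu * change + lambda * cluster
}
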