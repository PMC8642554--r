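#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table under the permutation model:
#' \deqn{ARI = (\sum_{ij} C(n_{ij},2) - E) / (\tfrac12 (\sum_i C(a_i,2) +
#' \sum_j C(b_j,2)) - E)} with \eqn{E = \sum_i C(a_i,2) \sum_j C(b_j,2) /
#' C(n,2)}. Equals 1 for identical partitions up to relabeling and has
#' expectation 0 for independent random partitions. The degenerate case in
#' which the index is undefined (both partitions a single cluster, or both
#' all singletons) returns 1.
#'
#' @param a,b label vectors of equal length >= 2 (any atomic type).
#' @return numeric in [-1, 1].
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 items")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sumnij <- sum(ch2(tab))
  sa <- sum(ch2(rowSums(tab)))
  sb <- sum(ch2(colSums(tab)))
  expected <- sa * sb / ch2(n)
  maxIndex <- (sa + sb) / 2
  denom <- maxIndex - expected
  if (abs(denom) < .Machine$double.eps * 4) return(1)
  (sumnij - expected) / denom
}

# all permutations of 1..m in lexicographic order (m x m! matrix columns)
.permutationsLex <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- .permutationsLex(m - 1L)
  out <- matrix(0L, m, m * ncol(sub))
  col <- 0L
  for (first in seq_len(m)) {
    rest <- setdiff(seq_len(m), first)
    for (j in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- c(first, rest[sub[, j]])
    }
  }
  out
}

#' Match cluster labels to a template by optimal relabeling
#'
#' Finds the bijection on 1..M that, applied to \code{other}'s labels,
#' maximizes the diagonal of the M x M contingency table against
#' \code{template} — i.e. the relabeling with the highest overlap. The
#' search enumerates all M! permutations exactly (M <= 8), taking the
#' lexicographically first permutation on ties.
#'
#' @param template,other integer label vectors with values in 1..M.
#' @param M number of clusters.
#' @return integer permutation p of 1..M: label j of \code{other}
#'   becomes \code{p[j]}.
#' @export
matchLabels <- function(template, other, M) {
  if (length(template) != length(other)) stop("labelings must have equal length")
  M <- as.integer(M)
  if (M > 8L) stop("exact label matching is limited to M <= 8")
  stopifnot(all(template %in% seq_len(M)), all(other %in% seq_len(M)))
  C <- matrix(0, M, M)  # template x other
  tab <- table(factor(template, levels = seq_len(M)),
               factor(other, levels = seq_len(M)))
  C[] <- tab
  perms <- .permutationsLex(M)
  best <- -Inf; bestPerm <- perms[, 1]
  for (j in seq_len(ncol(perms))) {
    p <- perms[, j]  # other label k -> template label p[k]
    ov <- sum(C[cbind(p, seq_len(M))])
    if (ov > best) { best <- ov; bestPerm <- p }
  }
  as.integer(bestPerm)
}

#' Apply a label permutation
#' @param labels integer labels in 1..M.
#' @param perm permutation from [matchLabels()].
#' @return relabeled vector.
#' @export
applyLabelPermutation <- function(labels, perm) as.integer(perm[labels])
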