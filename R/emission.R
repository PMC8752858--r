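# Emission model for one PCR amplification of one locus.
#
# Given a true diploid genotype (u, v), each allele copy independently:
#   * drops out with probability d (allelic dropout),
#   * otherwise is read correctly with probability 1 - e, or read as one of
#     the other k - 1 alleles of the locus uniformly with probability e.
# The whole locus additionally fails to amplify with probability f.  The
# observation is the set of surviving calls: a pair {x, y}, an apparent
# homozygote {x} (one or both copies read x), or no amplification.

# probability that a copy with true allele t is read as allele a
.copyShow <- function(t, a, d, e, k) {
  (1 - d) * ifelse(a == t, 1 - e, e / (k - 1))
}

#' Probability of one PCR observation given a true genotype
#'
#' The per-replicate emission probability of the dropout/false-allele error
#' process, used by consensus reliability scoring and the trio likelihood.
#'
#' @param obs observed allele pair: integer vector of length 2 (an apparent
#'   homozygote is \code{c(a, a)}), or \code{NULL}/\code{NA} for amplification
#'   failure.
#' @param g true genotype: integer vector of length 2.
#' @param error an [ErrorModel-class].
#' @param k number of alleles at the locus.
#' @return the probability of the observation.
#' @examples
#' em <- ErrorModel(dropout = 0.1, falseAllele = 0, failure = 0)
#' # heterozygote (1,2) seen complete: both copies retained
#' emissionProb(c(1, 2), c(1, 2), em, k = 4)  # 0.81
#' @export
emissionProb <- function(obs, g, error, k) {
  d <- error@dropout; e <- error@falseAllele; f <- error@failure
  u <- g[1]; v <- g[2]
  if (is.null(obs) || anyNA(obs)) return(f + (1 - f) * d * d)
  x <- min(obs); y <- max(obs)
  if (x == y) {
    p <- .copyShow(u, x, d, e, k) * d + d * .copyShow(v, x, d, e, k) +
      .copyShow(u, x, d, e, k) * .copyShow(v, x, d, e, k)
  } else {
    p <- .copyShow(u, x, d, e, k) * .copyShow(v, y, d, e, k) +
      .copyShow(u, y, d, e, k) * .copyShow(v, x, d, e, k)
  }
  (1 - f) * p
}

# vectorized emission probability of one observation over a genotype matrix
.emissionVec <- function(obs, genos, error, k) {
  d <- error@dropout; e <- error@falseAllele; f <- error@failure
  n <- nrow(genos)
  if (is.null(obs) || anyNA(obs)) return(rep(f + (1 - f) * d * d, n))
  u <- genos[, 1]; v <- genos[, 2]
  x <- min(obs); y <- max(obs)
  if (x == y) {
    su <- .copyShow(u, x, d, e, k); sv <- .copyShow(v, x, d, e, k)
    p <- su * d + d * sv + su * sv
  } else {
    p <- .copyShow(u, x, d, e, k) * .copyShow(v, y, d, e, k) +
      .copyShow(u, y, d, e, k) * .copyShow(v, x, d, e, k)
  }
  (1 - f) * p
}

# all unordered genotypes over allele labels `labels`: matrix with 2 columns
.allGenotypes <- function(labels) {
  k <- length(labels)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cbind(labels[idx[, 1]], labels[idx[, 2]])
}

# Hardy-Weinberg prior over unordered genotypes, freqs p named by label
.hwPrior <- function(genos, p) {
  pa <- p[as.character(genos[, 1])]
  pb <- p[as.character(genos[, 2])]
  ifelse(genos[, 1] == genos[, 2], pa * pb, 2 * pa * pb)
}

# Posterior over true genotypes at one locus given a single observed pair
# (or a list of replicate observations) under HW priors.  Returns
# list(genos, post); `obs` may be a 2-vector or a list of 2-vectors/NULL.
.locusPosterior <- function(obs, p, error) {
  labels <- as.integer(names(p))
  genos <- .allGenotypes(labels)
  prior <- .hwPrior(genos, p)
  if (!is.list(obs)) obs <- list(obs)
  lik <- rep(1, nrow(genos))
  for (o in obs) lik <- lik * .emissionVec(o, genos, error, length(labels))
  w <- prior * lik
  s <- sum(w)
  if (s <= 0) return(list(genos = genos, post = rep(0, nrow(genos))))
  list(genos = genos, post = w / s)
}

# Transmission marginal tau(x): probability that an individual with genotype
# posterior `post` over `genos` transmits allele x; returns vector named by
# allele label.
.transmissionMarginal <- function(genos, post, labels) {
  acc <- rowsum(c(post / 2, post / 2), group = c(genos[, 1], genos[, 2]))
  tau <- stats::setNames(numeric(length(labels)), as.character(labels))
  tau[rownames(acc)] <- acc[, 1]
  tau
}
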