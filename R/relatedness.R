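#' Queller-Goodnight moment estimator of pairwise relatedness
#'
#' Symmetrized multilocus Queller-Goodnight estimator: per locus and
#' direction, the numerator is the average allele-sharing of the reference
#' individual's alleles with the partner minus the reference allele
#' frequencies, the denominator the maximal such quantity; numerators and
#' denominators are summed over both directions and all usable loci before
#' dividing. Unbiased for true relatedness under random mating but not
#' confined to [0, 1]. Loci untyped in either individual, or with an
#' undefined weight (denominator contribution zero, e.g. monomorphic), are
#' skipped.
#'
#' @param g1,g2 `L x 2` genotype matrices with loci rownames
#' @param freqs an [AlleleFreqTable-class]
#' @return estimated relatedness coefficient r (scalar)
#' @export
qgRelatedness <- function(g1, g2, freqs) {
  num <- 0; den <- 0
  for (l in rownames(g1)) {
    p <- freqs@freqs[[l]]
    if (is.null(p) || length(p) < 2L) next
    x <- g1[l, ]; y <- g2[l, ]
    if (anyNA(x) || anyNA(y)) next
    contrib <- .qgLocus(x, y, p)
    if (is.null(contrib)) next
    num <- num + contrib[1]; den <- den + contrib[2]
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

.qgLocus <- function(x, y, p) {
  pa <- p[as.character(x[1])]; pb <- p[as.character(x[2])]
  pc <- p[as.character(y[1])]; pd <- p[as.character(y[2])]
  if (anyNA(c(pa, pb, pc, pd)))
    stop("unknown allele: not present in the frequency table")
  s <- 0.5 * (sum(x[1] == y) + sum(x[2] == y))
  numX <- s - pa - pb
  denX <- 1 + (x[1] == x[2]) - pa - pb
  numY <- s - pc - pd
  denY <- 1 + (y[1] == y[2]) - pc - pd
  if (denX + denY == 0) return(NULL)
  c(numX + numY, denX + denY)
}

# IBD-mode probabilities of an ordered pair of unordered genotypes:
# returns c(P0, P1, P2) = P(g1, g2 | dyad shares 0/1/2 alleles IBD)
.ibdModeProbs <- function(g1, g2, p) {
  hw <- function(g) {
    pa <- p[as.character(g[1])]; pb <- p[as.character(g[2])]
    if (g[1] == g[2]) pa * pb else 2 * pa * pb
  }
  P0 <- hw(g1) * hw(g2)
  P2 <- if (all(sort(g1) == sort(g2))) hw(g1) else 0
  # one shared IBD allele x: p_x * p_(rest of g1) * p_(rest of g2),
  # summed over distinct shared allele values
  sharedVals <- intersect(g1, g2)
  P1 <- 0
  for (x in sharedVals) {
    restA <- if (g1[1] == x) g1[2] else g1[1]
    restB <- if (g2[1] == x) g2[2] else g2[1]
    P1 <- P1 + p[as.character(x)] * p[as.character(restA)] *
      p[as.character(restB)]
  }
  c(P0 = unname(P0), P1 = unname(P1), P2 = unname(P2))
}

#' Dyadic maximum-likelihood relatedness over IBD modes
#'
#' Maximizes the multilocus likelihood sum(log(k0*P0 + k1*P1 + k2*P2)) over
#' the non-inbred IBD-coefficient simplex (k0, k1, k2), where the per-locus
#' mode probabilities P_i follow from the allele frequencies. Because each
#' locus likelihood is linear in k, the log-likelihood is concave on the
#' simplex and the EM iteration converges to the global maximum; a dense
#' grid search backs it up if EM ever fails to improve. Returns the
#' coefficients and r = k2 + k1/2. Optionally the genotyping error model is
#' folded into the per-locus mode probabilities by summing over true
#' genotype pairs.
#'
#' @param g1,g2 `L x 2` genotype matrices with loci rownames
#' @param freqs an [AlleleFreqTable-class]
#' @param error optional [ErrorModel-class]; `NULL` (default) treats the
#'   genotypes as known
#' @param ids identifiers recorded on the estimate
#' @param tol EM convergence tolerance on the log-likelihood
#' @param maxIter EM iteration cap
#' @return a [RelatednessEstimate-class]
#' @export
mlRelatedness <- function(g1, g2, freqs, error = NULL,
                          ids = c("g1", "g2"), tol = 1e-12,
                          maxIter = 5000L) {
  P <- .dyadModeMatrix(g1, g2, freqs, error)
  if (nrow(P) == 0L) stop("no jointly typed loci")
  k <- c(1, 1, 1) / 3
  llOld <- -Inf
  flag <- "ok"
  for (it in seq_len(maxIter)) {
    mix <- as.vector(P %*% k)
    ll <- sum(log(mix))
    if (is.finite(ll) && ll - llOld < tol && it > 1L) break
    llOld <- ll
    resp <- P * rep(k, each = nrow(P)) / mix
    k <- colMeans(resp)
  }
  if (!is.finite(llOld)) {
    # grid fallback
    flag <- "grid"
    grid <- .simplexGrid(0.01)
    lls <- apply(grid, 1, function(kk) sum(log(as.vector(P %*% kk))))
    k <- grid[which.max(lls), ]
  }
  k <- pmax(k, 0); k <- k / sum(k)
  # EM approaches simplex boundaries only asymptotically; because the
  # log-likelihood is concave, comparing the EM point against the exactly
  # maximized edges and vertices recovers boundary MLEs.
  k <- .refineSimplexMax(P, k)
  new("RelatednessEstimate", ids = as.character(ids), estimator = "ml",
      r = unname(k[3] + k[2] / 2), k = unname(k), nLoci = nrow(P),
      flag = flag)
}

# per-locus (P0, P1, P2) matrix for a dyad; folds in the error model when
# supplied by summing over true genotype pairs
.dyadModeMatrix <- function(g1, g2, freqs, error = NULL) {
  rows <- list()
  noErr <- is.null(error) ||
    (error@dropout == 0 && error@falseAllele == 0 && error@failure == 0)
  for (l in rownames(g1)) {
    p <- freqs@freqs[[l]]
    if (is.null(p)) next
    x <- g1[l, ]; y <- g2[l, ]
    if (anyNA(x) || anyNA(y)) next
    if (noErr) {
      rows[[l]] <- .ibdModeProbs(x, y, p)
    } else {
      labels <- as.integer(names(p))
      genos <- .allGenotypes(labels)
      k <- length(labels)
      e1 <- vapply(seq_len(nrow(genos)), function(i)
        emissionProb(x, genos[i, ], error, k), 0)
      e2 <- vapply(seq_len(nrow(genos)), function(i)
        emissionProb(y, genos[i, ], error, k), 0)
      acc <- c(P0 = 0, P1 = 0, P2 = 0)
      for (i in seq_len(nrow(genos))) for (j in seq_len(nrow(genos))) {
        if (e1[i] == 0 || e2[j] == 0) next
        acc <- acc + e1[i] * e2[j] * .ibdModeProbs(genos[i, ], genos[j, ], p)
      }
      rows[[l]] <- acc
    }
  }
  do.call(rbind, rows) %||% matrix(0, 0, 3)
}

# compare a candidate interior point against the three maximized simplex
# edges and the vertices; return the argmax of the log-likelihood
.refineSimplexMax <- function(P, k) {
  ll <- function(kk) {
    mix <- as.vector(P %*% kk)
    if (any(mix <= 0)) return(-1e300)  # finite penalty keeps optimize() quiet
    sum(log(mix))
  }
  cand <- list(k, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  edges <- list(function(t) c(0, t, 1 - t),     # k0 = 0
                function(t) c(t, 0, 1 - t),     # k1 = 0
                function(t) c(t, 1 - t, 0))     # k2 = 0
  for (ed in edges) {
    op <- stats::optimize(function(t) ll(ed(t)), c(0, 1), maximum = TRUE,
                          tol = 1e-10)
    cand[[length(cand) + 1L]] <- ed(op$maximum)
  }
  lls <- vapply(cand, ll, 0)
  best <- cand[[which.max(lls)]]
  best <- pmax(best, 0)
  best / sum(best)
}

.simplexGrid <- function(step = 0.01) {
  k0 <- seq(0, 1, by = step)
  grid <- expand.grid(k0 = k0, k1 = k0)
  grid <- grid[grid$k0 + grid$k1 <= 1 + 1e-12, ]
  cbind(grid$k0, grid$k1, pmax(1 - grid$k0 - grid$k1, 0))
}
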