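#' Generate a random allele frequency table
#'
#' Draws per-locus allele frequencies from a symmetric Dirichlet distribution.
#' With the default concentration (`alpha = 1`) loci vary realistically in
#' evenness; frequencies are floored at 1e-3 (then renormalized) so every
#' allele remains observable.
#'
#' @param L number of loci (default 18).
#' @param k alleles per locus; a scalar or length-`L` vector, each >= 2.
#' @param alpha Dirichlet concentration parameter.
#' @param seed optional RNG seed for a reproducible table.
#' @return an [AlleleFreqTable-class]; allele labels are `1:k`.
#' @examples
#' ft <- generateAlleleFrequencies(L = 18, k = 8, seed = 7)
#' expectedHeterozygosity(ft)
#' @export
generateAlleleFrequencies <- function(L = 18L, k = 8L, alpha = 1,
                                      seed = NULL) {
  L <- checkCount(L, "L", 1L)
  if (any(k < 2)) stop("k must be >= 2 alleles per locus")
  k <- rep_len(as.integer(k), L)
  withSeed(seed, {
    freqs <- lapply(seq_len(L), function(l) {
      g <- stats::rgamma(k[l], shape = alpha)
      p <- pmax(g / sum(g), 1e-3)
      p <- p / sum(p)
      stats::setNames(p, seq_len(k[l]))
    })
    names(freqs) <- sprintf("L%02d", seq_len(L))
    AlleleFreqTable(freqs)
  })
}

#' Expected heterozygosity per locus
#'
#' Computes 1 - sum(p^2) for each locus of a frequency table.
#'
#' @param freqs an [AlleleFreqTable-class]
#' @return named numeric vector, one value per locus
#' @export
expectedHeterozygosity <- function(freqs) {
  vapply(freqs@freqs, function(p) 1 - sum(p^2), 0)
}

#' Draw genotypes in Hardy-Weinberg proportions
#'
#' Samples `n` unrelated diploid genotypes, each allele drawn independently
#' from the locus frequencies.
#'
#' @param freqs an [AlleleFreqTable-class]
#' @param n number of individuals
#' @param ids optional identifiers (default \code{"G1"..."Gn"})
#' @param seed optional RNG seed
#' @return a [GenotypeTable-class]
#' @export
drawGenotypes <- function(freqs, n, ids = NULL, seed = NULL) {
  n <- checkCount(n, "n", 1L)
  if (is.null(ids)) ids <- sprintf("G%d", seq_len(n))
  L <- nLoci(freqs)
  withSeed(seed, {
    a1 <- a2 <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) {
      p <- freqs@freqs[[l]]
      lab <- as.integer(names(p))
      a1[, l] <- sample(lab, n, replace = TRUE, prob = p)
      a2[, l] <- sample(lab, n, replace = TRUE, prob = p)
    }
    GenotypeTable(ids, loci(freqs), a1, a2)
  })
}

# one Mendelian offspring genotype from two parent rows (L x 2 matrices)
.mendelianOffspring <- function(gDam, gSire) {
  L <- nrow(gDam)
  pickD <- gDam[cbind(seq_len(L), sample(c(1L, 2L), L, replace = TRUE))]
  pickS <- gSire[cbind(seq_len(L), sample(c(1L, 2L), L, replace = TRUE))]
  orderPair(pickD, pickS)
}
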