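#' Random-mating resampling null for mated-pair relatedness
#'
#' Builds the reference distribution for mean mated-pair relatedness under
#' random mating: per iteration, `nPairs` (male, female) pairs are drawn
#' uniformly with replacement from the potential-breeder pools, relatedness
#' is estimated for each pair, and the iteration mean is recorded. Use the
#' moment estimator (`"qg"`, default, unbiased so the null mean is
#' well-defined) or dyadic maximum likelihood (`"ml"`).
#'
#' @param males,females [GenotypeTable-class] pools of potential breeders
#' @param freqs an [AlleleFreqTable-class]; when `NULL`, allele frequencies
#'   are estimated from the combined pools
#' @param nPairs pairs drawn per iteration
#' @param nIter number of iterations
#' @param estimator `"qg"` or `"ml"`
#' @param observed optional observed mean pair relatedness to place on the
#'   null
#' @param storeDraws keep the full iterations x pairs draw matrix
#' @param seed optional RNG seed (identical seeds give identical draws)
#' @return a [NullDistribution-class]
#' @examples
#' ft <- generateAlleleFrequencies(6, 4, seed = 2)
#' males <- drawGenotypes(ft, 30, seed = 3)
#' females <- drawGenotypes(ft, 35, seed = 4)
#' randomMatingNull(males, females, nPairs = 30, nIter = 50, seed = 5)
#' @export
randomMatingNull <- function(males, females, nPairs, nIter,
                             estimator = c("qg", "ml"), freqs = NULL,
                             observed = NA_real_, storeDraws = TRUE,
                             seed = NULL) {
  estimator <- match.arg(estimator)
  nPairs <- checkCount(nPairs, "nPairs", 1L)
  nIter <- checkCount(nIter, "nIter", 1L)
  if (nIndividuals(males) < 1L || nIndividuals(females) < 1L)
    stop("pools must be non-empty")
  if (is.null(freqs)) freqs <- .poolFrequencies(males, females)

  withSeed(seed, {
    m <- nIter * nPairs
    iM <- sample.int(nIndividuals(males), m, replace = TRUE)
    iF <- sample.int(nIndividuals(females), m, replace = TRUE)
    r <- if (estimator == "qg") {
      .qgPairsVec(males, iM, females, iF, freqs)
    } else {
      vapply(seq_len(m), function(t)
        mlRelatedness(genotypeOf(males, iM[t]), genotypeOf(females, iF[t]),
                      freqs)@r, 0)
    }
    draws <- matrix(r, nIter, nPairs, byrow = TRUE)
    means <- rowMeans(draws, na.rm = TRUE)
    pct <- if (is.na(observed)) NA_real_ else mean(means <= observed)
    new("NullDistribution", nIter = nIter, nPairs = nPairs,
        estimator = estimator, iterationMeans = means,
        draws = if (storeDraws) draws else matrix(0, 0, 0),
        observed = observed, percentile = pct)
  })
}

# allele frequencies counted over two pooled genotype tables
.poolFrequencies <- function(...) {
  tabs <- list(...)
  lociN <- loci(tabs[[1]])
  freqs <- lapply(seq_along(lociN), function(l) {
    alle <- unlist(lapply(tabs, function(tb) c(tb@a1[, l], tb@a2[, l])))
    alle <- alle[!is.na(alle)]
    tab <- table(alle)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(freqs) <- lociN
  poly <- vapply(freqs, length, 1L) >= 2L
  if (!all(poly))
    warning("dropping monomorphic loci from pool frequencies: ",
            paste(lociN[!poly], collapse = ", "))
  if (!any(poly)) stop("all loci monomorphic in the pools")
  AlleleFreqTable(freqs[poly])
}

# vectorized symmetrized Queller-Goodnight over index pairs
.qgPairsVec <- function(tab1, i1, tab2, i2, freqs) {
  m <- length(i1)
  num <- den <- numeric(m)
  for (l in seq_along(tab1@loci)) {
    p <- freqs@freqs[[tab1@loci[l]]]
    if (is.null(p) || length(p) < 2L) next
    lab <- as.integer(names(p)); pv <- as.numeric(p)
    a <- tab1@a1[i1, l]; b <- tab1@a2[i1, l]
    cc <- tab2@a1[i2, l]; d <- tab2@a2[i2, l]
    ok <- !(is.na(a) | is.na(cc))
    pa <- pv[match(a, lab)]; pb <- pv[match(b, lab)]
    pc_ <- pv[match(cc, lab)]; pd <- pv[match(d, lab)]
    s <- 0.5 * ((a == cc) + (a == d) + (b == cc) + (b == d))
    numX <- s - pa - pb;  denX <- 1 + (a == b) - pa - pb
    numY <- s - pc_ - pd; denY <- 1 + (cc == d) - pc_ - pd
    use <- ok & (denX + denY != 0)
    use[is.na(use)] <- FALSE
    num[use] <- num[use] + (numX + numY)[use]
    den[use] <- den[use] + (denX + denY)[use]
  }
  out <- rep(NA_real_, m)
  out[den != 0] <- num[den != 0] / den[den != 0]
  out
}

#' Summarize relatedness among observed mated pairs
#'
#' Median and range of pair relatedness, plus the count, fraction and mean of
#' pairs at or above the related-pair threshold (default r >= 0.25,
#' capturing first- and second-degree relatives).
#'
#' @param r numeric vector of pair relatedness estimates
#' @param threshold related-pair cutoff
#' @return list: n, median, range, nRelated, fracRelated, meanRelated
#' @export
breederRelatednessSummary <- function(r, threshold = 0.25) {
  r <- r[!is.na(r)]
  if (!length(r)) stop("empty input: no pair estimates")
  rel <- r[r >= threshold]
  list(n = length(r), median = stats::median(r), range = range(r),
       nRelated = length(rel), fracRelated = length(rel) / length(r),
       meanRelated = if (length(rel)) mean(rel) else NA_real_)
}
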