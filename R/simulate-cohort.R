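#' Simulate a pup-survival cohort directly from model coefficients
#'
#' Parameter-recovery harness: draws pair-year covariates from realistic
#' marginal distributions, z-scores the realized pup table (sample SD, n - 1),
#' and generates each pup's 15-month survival from a logistic model with the
#' supplied standardized coefficients, optionally with a pair-level Gaussian
#' random intercept. Defaults reproduce the scale of the motivating study:
#' ~83 pair-years and ~357 pups.
#'
#' @param nPairs number of pair-years
#' @param meanPups mean pups per pair-year (Poisson, conditioned >= 1)
#' @param coefs named coefficients on z-scored covariates (plus `intercept`);
#'   names as in [SimulationConfig()]
#' @param reSD SD of the pair-level random intercept (0 for a purely fixed
#'   effects generating model)
#' @param seed optional RNG seed
#' @return data.frame with pup-level covariates (raw), `alive`, and `pair_id`
#' @examples
#' d <- simulatePupCohort(seed = 1)
#' fit <- pupSurvivalAnalysis(d)
#' coef(fit$fixed)
#' @export
simulatePupCohort <- function(nPairs = 83L, meanPups = 357 / 83,
                              coefs = c(intercept = 0.02,
                                        harvest_rate = -0.56,
                                        n_adults = 0.19, pair_ho = -0.12,
                                        density = -0.18, years_paired = 0.28),
                              reSD = 0, seed = NULL) {
  nPairs <- checkCount(nPairs, "nPairs", 2L)
  withSeed(seed, {
    # pair-year covariates on their natural scales
    yearsPaired <- 1L + stats::rpois(nPairs, 1.2)
    covs <- data.frame(
      harvest_rate = stats::rbeta(nPairs, 2, 12),
      n_adults = 2L + stats::rpois(nPairs, 3),
      pair_ho = stats::rbeta(nPairs, 20, 7),
      density = stats::rlnorm(nPairs, log(12), 0.25),
      years_paired = yearsPaired)
    litter <- 1L + stats::rpois(nPairs, max(meanPups - 1, 0.1))
    pairId <- sprintf("pair%03d", seq_len(nPairs))
    u <- stats::rnorm(nPairs, 0, reSD)

    rows <- rep(seq_len(nPairs), times = litter)
    d <- covs[rows, , drop = FALSE]
    d$pair_id <- pairId[rows]
    cn <- setdiff(names(coefs), "intercept")
    z <- scale(as.matrix(d[cn]))
    eta <- coefs["intercept"] + as.vector(z %*% coefs[cn]) + u[rows]
    d$alive <- stats::rbinom(nrow(d), 1L, stats::plogis(eta))
    rownames(d) <- NULL
    d
  })
}

#' Parameter-recovery harness for the pup-survival models
#'
#' Repeatedly simulates pup cohorts from known standardized coefficients
#' ([simulatePupCohort()]), refits the corresponding model (fixed logistic,
#' or mixed with the pair random intercept when `reSD > 0` and
#' `mixed = TRUE`), and collects the fitted coefficients, so that the mean
#' estimate can be compared with the generating truth.
#'
#' @param nReplicates number of simulate-and-refit replicates
#' @param coefs generating coefficients (see [simulatePupCohort()])
#' @param reSD generating pair random-intercept SD
#' @param mixed fit the mixed model (otherwise the fixed-effects model)
#' @param nPairs pair-years per replicate
#' @param nAGQ quadrature nodes for mixed fits
#' @param seed RNG seed governing all replicates
#' @return matrix (replicates x coefficients) of fitted values, with an
#'   `re_sd` column for mixed fits
#' @export
survivalRecoveryHarness <- function(nReplicates = 200L,
                                    coefs = c(intercept = 0.02,
                                              harvest_rate = -0.56,
                                              n_adults = 0.19,
                                              pair_ho = -0.12,
                                              density = -0.18,
                                              years_paired = 0.28),
                                    reSD = 0, mixed = FALSE, nPairs = 83L,
                                    nAGQ = 15L, seed = NULL) {
  nReplicates <- checkCount(nReplicates, "nReplicates", 1L)
  cn <- setdiff(names(coefs), "intercept")
  withSeed(seed, {
    out <- matrix(NA_real_, nReplicates, length(cn) + 1L + mixed,
                  dimnames = list(NULL, c("intercept", cn,
                                          if (mixed) "re_sd")))
    for (b in seq_len(nReplicates)) {
      d <- simulatePupCohort(nPairs = nPairs, coefs = coefs, reSD = reSD)
      Z <- zTransform(d[cn])
      fit <- if (mixed) fitMixedLogistic(d$alive, Z, d$pair_id, nAGQ = nAGQ)
             else fitLogistic(d$alive, Z)
      out[b, seq_len(length(cn) + 1L)] <- coef(fit)[c("(Intercept)", cn)]
      if (mixed) out[b, "re_sd"] <- fit@reSD
    }
    out
  })
}

#' Simulate genotype dyads of known relationship
#'
#' Draws pairs of multilocus genotypes from Hardy-Weinberg founders with a
#' specified true relationship, for estimator calibration: unrelated,
#' parent-offspring (`"po"`), full siblings (`"fs"`), or half siblings
#' (`"hs"`).
#'
#' @param n number of dyads
#' @param freqs an [AlleleFreqTable-class]
#' @param type relationship of each dyad
#' @param seed optional RNG seed
#' @return list of two aligned [GenotypeTable-class] objects (`first`,
#'   `second`); dyad i is row i of each
#' @export
simulateDyads <- function(n, freqs, type = c("unrelated", "po", "fs", "hs"),
                          seed = NULL) {
  type <- match.arg(type)
  n <- checkCount(n, "n", 1L)
  L <- nLoci(freqs)
  withSeed(seed, {
    g1 <- array(NA_integer_, c(n, L, 2))
    g2 <- array(NA_integer_, c(n, L, 2))
    for (i in seq_len(n)) {
      a <- .hwGenotype(freqs); b <- .hwGenotype(freqs)
      pair <- switch(type,
        unrelated = list(a, b),
        po = list(a, .mendelianOffspring(a, b)),
        fs = list(.mendelianOffspring(a, b), .mendelianOffspring(a, b)),
        hs = {
          c2 <- .hwGenotype(freqs)
          list(.mendelianOffspring(a, b), .mendelianOffspring(a, c2))
        })
      g1[i, , ] <- pair[[1]]; g2[i, , ] <- pair[[2]]
    }
    ids <- sprintf("D%04d", seq_len(n))
    list(first = GenotypeTable(paste0(ids, "a"), loci(freqs),
                               g1[, , 1], g1[, , 2]),
         second = GenotypeTable(paste0(ids, "b"), loci(freqs),
                                g2[, , 1], g2[, , 2]))
  })
}
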