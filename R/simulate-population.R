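#' Configure the synthetic pack-population generator
#'
#' Builds a [SimulationConfig-class] with defaults matching the monitoring
#' design the package emulates: 16 packs followed for 10 years, 18 loci with 8
#' alleles each, litters of mean size ~4.3, extra-pair "sneaker" sires on ~12%
#' of breeding events, occasional polygyny, annual fall/winter harvest, and
#' pup survival generated from a logistic model on standardized covariates
#' (harvest rate, group adults, pair heterozygosity, density, years paired)
#' with a pair-level random intercept.
#'
#' @param nGroups number of packs.
#' @param nYears number of simulated years.
#' @param startYear first calendar year.
#' @param nLoci,nAlleles loci and alleles per locus for the genotypes.
#' @param meanLitter mean litter size (Poisson).
#' @param sneakerProb probability a breeding event is sired by an unsampled
#'   sneaker male rather than the pack male.
#' @param polygynyProb probability a second female in the pack also breeds in
#'   a given year.
#' @param immigrantProb probability a replacement breeder is an immigrant
#'   (fresh genotype from the frequency table) rather than a resident adult.
#' @param adultMortality annual non-harvest mortality of members >= 1 year.
#' @param dispersalProb probability a 2-year-old non-breeder leaves the study
#'   population.
#' @param sneakerHomOffset per-locus probability a sneaker genotype is forced
#'   homozygous, lowering sneaker heterozygosity below the population mean.
#' @param harvestSchedule per-year harvest probability (recycled/truncated to
#'   `nYears`); the default has no harvest in year 1, a brief opening, a pause,
#'   then sustained harvest.
#' @param pupHarvestRecovery probability a pup death is a recorded harvest.
#' @param areaSize study-area size in km^2 (for the density covariate,
#'   animals per 1000 km^2).
#' @param survivalCoefs named coefficients of the generating survival model on
#'   z-scored covariates (plus `intercept`).
#' @param pairRESD SD of the pair-level Gaussian random intercept.
#' @param covariateRef 2 x 5 matrix (rows `mean`, `sd`) of reference moments
#'   used to standardize covariates during sequential simulation.
#' @param samplesPerIndividual,replicatesPerSample,detectionProb fecal
#'   sampling design knobs.
#' @param seed RNG seed stored with the configuration.
#' @return a validated [SimulationConfig-class]
#' @export
SimulationConfig <- function(nGroups = 16L, nYears = 10L, startYear = 2008L,
                             nLoci = 18L, nAlleles = 8L, meanLitter = 4.3,
                             sneakerProb = 0.12, polygynyProb = 0.08,
                             immigrantProb = 0.5, adultMortality = 0.12,
                             dispersalProb = 0.4, sneakerHomOffset = 0,
                             harvestSchedule = NULL,
                             pupHarvestRecovery = 0.5, areaSize = 10000,
                             survivalCoefs = c(intercept = 0.02,
                                               harvest_rate = -0.56,
                                               n_adults = 0.19,
                                               pair_ho = -0.12,
                                               density = -0.18,
                                               years_paired = 0.28),
                             pairRESD = 0.85,
                             covariateRef = NULL,
                             samplesPerIndividual = 2L,
                             replicatesPerSample = 4L,
                             detectionProb = 1,
                             seed = 1L) {
  if (is.null(harvestSchedule)) {
    harvestSchedule <- c(0, 0.10, 0, rep(0.18, max(0L, nYears - 3L)))
  }
  harvestSchedule <- rep_len(harvestSchedule, nYears)
  if (is.null(covariateRef)) {
    covariateRef <- rbind(
      mean = c(harvest_rate = 0.12, n_adults = 5, pair_ho = 0.75,
               density = 12, years_paired = 2.2),
      sd = c(harvest_rate = 0.08, n_adults = 2, pair_ho = 0.07,
             density = 3, years_paired = 1.5))
  }
  new("SimulationConfig",
      nGroups = checkCount(nGroups, "nGroups"),
      nYears = checkCount(nYears, "nYears"),
      startYear = as.integer(startYear),
      nLoci = checkCount(nLoci, "nLoci"),
      nAlleles = checkCount(nAlleles, "nAlleles", 2L),
      meanLitter = meanLitter, sneakerProb = sneakerProb,
      polygynyProb = polygynyProb, immigrantProb = immigrantProb,
      adultMortality = adultMortality, dispersalProb = dispersalProb,
      sneakerHomOffset = sneakerHomOffset,
      harvestSchedule = as.numeric(harvestSchedule),
      pupHarvestRecovery = pupHarvestRecovery, areaSize = areaSize,
      survivalCoefs = survivalCoefs, pairRESD = pairRESD,
      covariateRef = covariateRef,
      samplesPerIndividual = checkCount(samplesPerIndividual,
                                        "samplesPerIndividual"),
      replicatesPerSample = checkCount(replicatesPerSample,
                                       "replicatesPerSample"),
      detectionProb = detectionProb,
      seed = as.integer(seed))
}

# single HW genotype draw (L x 2), with optional per-locus forced homozygosity
.hwGenotype <- function(freqs, homOffset = 0) {
  L <- nLoci(freqs)
  a1 <- a2 <- integer(L)
  for (l in seq_len(L)) {
    p <- freqs@freqs[[l]]
    lab <- as.integer(names(p))
    if (homOffset > 0 && stats::runif(1) < homOffset) {
      a1[l] <- a2[l] <- sample(lab, 1L, prob = p)
    } else {
      a1[l] <- sample(lab, 1L, prob = p)
      a2[l] <- sample(lab, 1L, prob = p)
    }
  }
  orderPair(a1, a2)
}

#' Simulate a multi-year pack population with known pedigree
#'
#' Generates founders in Hardy-Weinberg proportions, maintains one breeding
#' pair per pack with turnover on breeder death (replacements drawn from
#' unrelated resident adults or, with `immigrantProb`, immigrants carrying a
#' fresh genotype), sires litters by the pack male or a sneaker male, draws
#' pup survival to 15 months from the configured logistic model (covariates
#' standardized against the configured reference moments, plus a pair-level
#' random intercept), and applies the harvest schedule each fall/winter.
#'
#' @param config a [SimulationConfig-class]
#' @param freqs optional [AlleleFreqTable-class]; generated from the config
#'   when missing.
#' @return a [TruePopulation-class]
#' @examples
#' cfg <- SimulationConfig(nGroups = 4L, nYears = 3L, seed = 11)
#' pop <- simulatePopulation(cfg)
#' pop
#' @export
simulatePopulation <- function(config, freqs = NULL) {
  validObject(config)
  withSeed(config@seed, .simulatePopulationImpl(config, freqs))
}

.simulatePopulationImpl <- function(cfg, freqs) {
  if (is.null(freqs))
    freqs <- generateAlleleFrequencies(cfg@nLoci, cfg@nAlleles)

  # individual state, grown in parallel vectors
  e <- new.env()
  e$id <- character(0); e$sex <- character(0)
  e$birth <- integer(0); e$death <- integer(0)
  e$group <- character(0); e$dam <- character(0); e$sire <- character(0)
  e$sneaker <- logical(0); e$immigrant <- logical(0)
  e$dispersed <- logical(0)
  e$geno <- list()
  e$n <- 0L

  newInd <- function(sex, birth, group, dam = NA_character_,
                     sire = NA_character_, sneaker = FALSE,
                     immigrant = FALSE, geno = NULL) {
    e$n <- e$n + 1L
    id <- sprintf("W%04d", e$n)
    e$id[e$n] <- id; e$sex[e$n] <- sex
    e$birth[e$n] <- birth; e$death[e$n] <- NA_integer_
    e$group[e$n] <- group; e$dam[e$n] <- dam; e$sire[e$n] <- sire
    e$sneaker[e$n] <- sneaker; e$immigrant[e$n] <- immigrant
    e$dispersed[e$n] <- FALSE
    if (is.null(geno))
      geno <- .hwGenotype(freqs, if (sneaker) cfg@sneakerHomOffset else 0)
    e$geno[[e$n]] <- geno
    id
  }
  idx <- function(id) match(id, e$id[seq_len(e$n)])
  alive <- function(i, y) e$birth[i] <= y &
    (is.na(e$death[i]) | e$death[i] >= y)
  trueHo <- function(i) {
    g <- e$geno[[i]]; mean(g[, 1] != g[, 2])
  }
  related <- function(i, j) {
    # parent/offspring or shared parent; sufficient for breeder replacement
    pi <- c(e$dam[i], e$sire[i]); pj <- c(e$dam[j], e$sire[j])
    any(stats::na.omit(c(e$id[i] %in% pj, e$id[j] %in% pi,
                         intersect(stats::na.omit(pi),
                                   stats::na.omit(pj)) > "")))
  }

  groups <- sprintf("P%02d", seq_len(cfg@nGroups))
  breederM <- breederF <- stats::setNames(character(cfg@nGroups), groups)
  for (g in groups) {
    breederM[g] <- newInd("M", cfg@startYear - 3L, g)
    breederF[g] <- newInd("F", cfg@startYear - 3L, g)
  }

  yearsPaired <- new.env(); pairRE <- new.env()
  pairRows <- list(); pupRows <- list(); harvRows <- list()
  cn <- colnames(cfg@covariateRef)
  b <- cfg@survivalCoefs

  for (t in seq_len(cfg@nYears)) {
    y <- cfg@startYear + t - 1L

    # breeder turnover at the start of the breeding season
    for (g in groups) {
      for (sx in c("M", "F")) {
        cur <- if (sx == "M") breederM[g] else breederF[g]
        i <- idx(cur)
        if (alive(i, y) && !e$dispersed[i]) next
        mate <- idx(if (sx == "M") breederF[g] else breederM[g])
        pool <- which(alive(seq_len(e$n), y) & e$sex[seq_len(e$n)] == sx &
                        (y - e$birth[seq_len(e$n)]) >= 2L &
                        !e$dispersed[seq_len(e$n)] &
                        !e$sneaker[seq_len(e$n)] &
                        e$group[seq_len(e$n)] != g)
        pool <- pool[!(e$id[pool] %in% c(breederM, breederF))]
        if (length(pool) && alive(mate, y))
          pool <- pool[!vapply(pool, related, TRUE, j = mate)]
        if (!length(pool) || stats::runif(1) < cfg@immigrantProb) {
          rep_id <- newInd(sx, y - 3L, g, immigrant = TRUE)
        } else {
          pick <- pool[sample.int(length(pool), 1L)]
          e$group[pick] <- g
          rep_id <- e$id[pick]
        }
        if (sx == "M") breederM[g] <- rep_id else breederF[g] <- rep_id
      }
    }

    nAliveSummer <- sum(alive(seq_len(e$n), y) & !e$dispersed[seq_len(e$n)] &
                          !e$sneaker[seq_len(e$n)])
    density <- nAliveSummer / (cfg@areaSize / 1000)

    # breeding events per group
    for (g in groups) {
      males <- breederM[g]; fem <- breederF[g]
      members <- which(e$group[seq_len(e$n)] == g &
                         alive(seq_len(e$n), y) & !e$dispersed[seq_len(e$n)])
      nAdults <- sum((y - e$birth[members]) >= 1L)
      dams <- fem
      extraF <- members[e$sex[members] == "F" &
                          (y - e$birth[members]) >= 2L &
                          !(e$id[members] %in% c(fem, males))]
      if (length(extraF) && stats::runif(1) < cfg@polygynyProb)
        dams <- c(dams, e$id[extraF[sample.int(length(extraF), 1L)]])

      grpRows <- list()
      for (damId in dams) {
        litter <- stats::rpois(1L, cfg@meanLitter)
        if (litter == 0L) next
        sneak <- stats::runif(1) < cfg@sneakerProb
        sireId <- if (sneak) newInd("M", y - 3L, NA_character_,
                                    sneaker = TRUE) else males
        pairKey <- paste(damId, males, sep = ":")
        ypNow <- (if (exists(pairKey, yearsPaired))
          get(pairKey, yearsPaired) else 0L) + 1L
        assign(pairKey, ypNow, yearsPaired)
        if (!exists(pairKey, pairRE))
          assign(pairKey, stats::rnorm(1L, 0, cfg@pairRESD), pairRE)
        u <- get(pairKey, pairRE)

        pairHo <- mean(c(trueHo(idx(damId)), trueHo(idx(males))))
        x <- c(harvest_rate = cfg@harvestSchedule[t], n_adults = nAdults,
               pair_ho = pairHo, density = density, years_paired = ypNow)
        z <- (x - cfg@covariateRef["mean", cn]) / cfg@covariateRef["sd", cn]
        eta <- b["intercept"] + sum(b[cn] * z[cn]) + u
        pSurv <- stats::plogis(eta)

        gDam <- e$geno[[idx(damId)]]; gSire <- e$geno[[idx(sireId)]]
        for (k in seq_len(litter)) {
          pupGeno <- .mendelianOffspring(gDam, gSire)
          pupId <- newInd(sample(c("M", "F"), 1L), y, g, dam = damId,
                          sire = sireId, geno = pupGeno)
          survived <- stats::rbinom(1L, 1L, pSurv)
          if (!survived) {
            e$death[idx(pupId)] <- y
            if (stats::runif(1) < cfg@pupHarvestRecovery)
              harvRows[[length(harvRows) + 1L]] <-
                data.frame(id = pupId, year = y, group = g)
          }
          pupRows[[length(pupRows) + 1L]] <- data.frame(
            pup_id = pupId, pair_id = pairKey, dam_id = damId,
            sire_id = sireId, group = g, birth_year = y,
            harvest_rate = unname(x["harvest_rate"]),
            n_adults = unname(x["n_adults"]),
            pair_ho = unname(x["pair_ho"]),
            density = unname(x["density"]),
            years_paired = unname(x["years_paired"]),
            survived = survived, sneaker_sired = sneak)
        }
        grpRows[[length(grpRows) + 1L]] <- data.frame(
          pair_id = pairKey, dam_id = damId, sire_id = males, group = g,
          year = y, years_paired = ypNow, polygamy = FALSE,
          pair_ho = pairHo, n_adults = nAdults,
          harvest_rate = cfg@harvestSchedule[t], density = density)
      }
      if (length(grpRows)) {
        gr <- do.call(rbind, grpRows)
        gr$polygamy <- length(unique(gr$dam_id)) > 1L
        pairRows[[length(pairRows) + 1L]] <- gr
      }
    }

    # fall/winter harvest and background mortality of members >= 1 year
    older <- which(alive(seq_len(e$n), y) & !e$dispersed[seq_len(e$n)] &
                     (y - e$birth[seq_len(e$n)]) >= 1L)
    for (i in older) {
      if (stats::runif(1) < cfg@harvestSchedule[t]) {
        e$death[i] <- y
        harvRows[[length(harvRows) + 1L]] <-
          data.frame(id = e$id[i], year = y, group = e$group[i])
      } else if (stats::runif(1) < cfg@adultMortality) {
        e$death[i] <- y
      }
    }
    # dispersal of surviving 2-year-old non-breeders
    two <- which(alive(seq_len(e$n), y + 1L) & !e$dispersed[seq_len(e$n)] &
                   (y - e$birth[seq_len(e$n)]) == 2L &
                   !e$sneaker[seq_len(e$n)] &
                   !(e$id[seq_len(e$n)] %in% c(breederM, breederF)))
    for (i in two) if (stats::runif(1) < cfg@dispersalProb) {
      e$dispersed[i] <- TRUE
      e$death[i] <- y
    }
  }

  n <- e$n
  ind <- data.frame(
    id = e$id[1:n], sex = e$sex[1:n], birth_year = e$birth[1:n],
    death_year = e$death[1:n], group = e$group[1:n], dam_id = e$dam[1:n],
    sire_id = e$sire[1:n], is_sneaker = e$sneaker[1:n],
    is_immigrant = e$immigrant[1:n], dispersed = e$dispersed[1:n])
  a1 <- t(vapply(e$geno[1:n], function(g) g[, 1], integer(cfg@nLoci)))
  a2 <- t(vapply(e$geno[1:n], function(g) g[, 2], integer(cfg@nLoci)))
  gt <- GenotypeTable(ind$id, loci(freqs), a1, a2)

  emptyHarv <- data.frame(id = character(0), year = integer(0),
                          group = character(0))
  new("TruePopulation", individuals = ind, genotypes = gt, freqs = freqs,
      pairYears = if (length(pairRows)) do.call(rbind, pairRows)
                  else data.frame(),
      pups = if (length(pupRows)) do.call(rbind, pupRows) else data.frame(),
      harvest = if (length(harvRows)) do.call(rbind, harvRows)
                else emptyHarv,
      config = cfg)
}
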