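#' @import methods
NULL

#' Per-locus allele frequency table
#'
#' Holds, for each microsatellite locus, a named vector of allele frequencies.
#' Allele labels are integer-valued (stored as the names of each vector);
#' frequencies at every locus sum to one and are strictly positive, and every
#' locus carries at least two alleles.
#'
#' @slot freqs named list; one named numeric vector per locus.
#' @export
setClass("AlleleFreqTable", representation(freqs = "list"))

setValidity("AlleleFreqTable", function(object) {
  f <- object@freqs
  if (length(f) < 1L) return("at least one locus is required")
  if (is.null(names(f)) || anyDuplicated(names(f)))
    return("loci must be uniquely named")
  for (l in names(f)) {
    p <- f[[l]]
    if (!is.numeric(p) || length(p) < 2L)
      return(sprintf("locus %s needs >= 2 alleles", l))
    if (is.null(names(p)) || anyNA(suppressWarnings(as.integer(names(p)))))
      return(sprintf("locus %s: allele labels must be integer-valued", l))
    if (any(p <= 0)) return(sprintf("locus %s: frequencies must be > 0", l))
    if (abs(sum(p) - 1) > 1e-9)
      return(sprintf("locus %s: frequencies must sum to 1", l))
  }
  TRUE
})

#' Diploid multilocus genotypes for a set of individuals
#'
#' The central genotype container: two integer allele matrices (individuals x
#' loci), unordered within a locus (allele1 <= allele2), with \code{NA} marking
#' untyped loci. Single genotypes extracted from the table are plain
#' \code{L x 2} integer matrices with loci as rownames, the representation all
#' statistical operations in the package accept.
#'
#' @slot ids character vector of individual/sample identifiers.
#' @slot loci character vector of locus names.
#' @slot a1,a2 integer matrices, \code{length(ids)} rows by
#'   \code{length(loci)} columns.
#' @export
setClass("GenotypeTable",
  representation(ids = "character", loci = "character",
                 a1 = "matrix", a2 = "matrix"))

setValidity("GenotypeTable", function(object) {
  n <- length(object@ids); L <- length(object@loci)
  if (anyDuplicated(object@ids)) return("ids must be unique")
  for (s in c("a1", "a2")) {
    m <- slot(object, s)
    if (!is.integer(m)) return(sprintf("%s must be an integer matrix", s))
    if (!all(dim(m) == c(n, L))) return(sprintf("%s has wrong dimensions", s))
  }
  if (any(xor(is.na(object@a1), is.na(object@a2))))
    return("a1/a2 must be NA together (a locus is typed with both alleles or not at all)")
  ok <- is.na(object@a1) | object@a1 <= object@a2
  if (!all(ok)) return("allele pairs must be ordered (a1 <= a2)")
  TRUE
})

#' PCR error process for replicate amplifications
#'
#' Rates of the three error events acting on each replicate PCR of a locus:
#' whole-locus amplification failure, per-allele allelic dropout, and
#' per-allele false-allele substitution (the amplified copy is read as a
#' uniformly chosen different allele of the locus).
#'
#' @slot dropout per-allele, per-PCR allelic dropout probability.
#' @slot falseAllele per-allele, per-PCR substitution probability.
#' @slot failure per-locus, per-PCR amplification failure probability.
#' @export
setClass("ErrorModel",
  representation(dropout = "numeric", falseAllele = "numeric",
                 failure = "numeric"),
  prototype(dropout = 0.01, falseAllele = 0.01, failure = 0))

setValidity("ErrorModel", function(object) {
  for (s in c("dropout", "falseAllele", "failure")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      return(sprintf("%s must be a single probability in [0, 1]", s))
  }
  TRUE
})

#' Consensus genotype of one noninvasive sample
#'
#' Per-locus consensus calls derived from replicate PCRs: heterozygote calls
#' confirmed by >= 2 independent PCRs showing the pair together, homozygote
#' calls by >= 3 PCRs showing the single allele with no confirmed second
#' allele; loci failing both rules are missing.
#'
#' @slot sampleId sample identifier.
#' @slot loci locus names.
#' @slot status per-locus status, one of \code{"het"}, \code{"hom"},
#'   \code{"missing"}.
#' @slot a1,a2 confirmed allele pair (ordered; \code{NA} when missing).
#' @export
setClass("ConsensusGenotype",
  representation(sampleId = "character", loci = "character",
                 status = "character", a1 = "integer", a2 = "integer"))

setValidity("ConsensusGenotype", function(object) {
  L <- length(object@loci)
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  if (length(object@status) != L || length(object@a1) != L ||
      length(object@a2) != L) return("per-locus slots must align with loci")
  if (!all(object@status %in% c("het", "hom", "missing")))
    return("status must be het/hom/missing")
  bad <- (object@status == "missing" & !is.na(object@a1)) |
         (object@status == "het" & (is.na(object@a1) | object@a1 == object@a2)) |
         (object@status == "hom" & (is.na(object@a1) | object@a1 != object@a2))
  if (any(bad, na.rm = TRUE)) return("alleles inconsistent with status")
  TRUE
})

#' Catalog of unique individuals identified from noninvasive samples
#'
#' Result of dropout-tolerant clustering of sample consensus genotypes: one
#' entry per distinct individual, with a representative genotype (per-locus
#' consensus of the member samples, heterozygote evidence overriding
#' dropout homozygotes), the member sample ids, and the detection count.
#'
#' @slot ids individual identifiers.
#' @slot representatives list of [ConsensusGenotype-class] objects.
#' @slot members list of character vectors of member sample ids.
#' @slot meta data.frame of optional per-individual metadata.
#' @export
setClass("IndividualCatalog",
  representation(ids = "character", representatives = "list",
                 members = "list", meta = "data.frame"))

setValidity("IndividualCatalog", function(object) {
  n <- length(object@ids)
  if (length(object@representatives) != n || length(object@members) != n)
    return("slots must have one entry per individual")
  if (anyDuplicated(object@ids)) return("individual ids must be unique")
  if (anyDuplicated(unlist(object@members)))
    return("a sample may belong to only one individual")
  TRUE
})

#' Configuration of the synthetic pack-population generator
#'
#' Defaults emulate the monitoring design the package targets: 16 packs
#' resampled over 10 summers, 18 microsatellite loci with ~8 alleles each,
#' replicate PCRs with dropout and false-allele rates of 0.01, pack breeding
#' pairs with occasional polygyny and extra-pair "sneaker" sires, fall/winter
#' harvest, and pup survival to 15 months generated from a logistic model on
#' standardized covariates with a pair-level random intercept.
#'
#' @export
setClass("SimulationConfig",
  representation(
    nGroups = "integer", nYears = "integer", startYear = "integer",
    nLoci = "integer", nAlleles = "integer",
    meanLitter = "numeric", sneakerProb = "numeric", polygynyProb = "numeric",
    immigrantProb = "numeric", adultMortality = "numeric",
    dispersalProb = "numeric", sneakerHomOffset = "numeric",
    harvestSchedule = "numeric", pupHarvestRecovery = "numeric",
    areaSize = "numeric",
    survivalCoefs = "numeric", pairRESD = "numeric",
    covariateRef = "matrix",
    samplesPerIndividual = "integer", replicatesPerSample = "integer",
    detectionProb = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  cnt <- c(nGroups = object@nGroups, nYears = object@nYears,
           nLoci = object@nLoci, nAlleles = object@nAlleles,
           samplesPerIndividual = object@samplesPerIndividual,
           replicatesPerSample = object@replicatesPerSample)
  if (any(cnt < 1L)) return("all counts must be positive")
  if (object@nAlleles < 2L) return("nAlleles must be >= 2")
  pr <- c(object@sneakerProb, object@polygynyProb, object@immigrantProb,
          object@adultMortality, object@dispersalProb, object@detectionProb,
          object@pupHarvestRecovery, object@sneakerHomOffset,
          object@harvestSchedule)
  if (anyNA(pr) || any(pr < 0) || any(pr > 1))
    return("all probabilities must lie in [0, 1]")
  if (length(object@harvestSchedule) != object@nYears)
    return("harvestSchedule must have one rate per simulated year")
  if (object@meanLitter <= 0) return("meanLitter must be positive")
  if (object@pairRESD < 0) return("pairRESD must be >= 0")
  need <- c("intercept", "harvest_rate", "n_adults", "pair_ho", "density",
            "years_paired")
  if (!all(need %in% names(object@survivalCoefs)))
    return(paste("survivalCoefs must name:", paste(need, collapse = ", ")))
  if (!all(c("mean", "sd") %in% rownames(object@covariateRef)))
    return("covariateRef needs 'mean' and 'sd' rows")
  TRUE
})

#' Ground-truth synthetic population
#'
#' Output of [simulatePopulation()]: the full individual table with pedigree
#' edges, true genotypes, pack composition and breeder histories, per-pup true
#' survival with its generating covariates, and the harvest record. Every
#' downstream stage of the pipeline can be validated against this object.
#'
#' @slot individuals data.frame: id, sex, birth_year, death_year, group,
#'   dam_id, sire_id, is_sneaker, is_immigrant.
#' @slot genotypes [GenotypeTable-class] of true genotypes for all individuals.
#' @slot freqs generating [AlleleFreqTable-class].
#' @slot pairYears data.frame of true pair-year records.
#' @slot pups data.frame of per-pup truth (covariates, survival).
#' @slot harvest data.frame of harvest events (id, year, group).
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("TruePopulation",
  representation(individuals = "data.frame", genotypes = "GenotypeTable",
                 freqs = "AlleleFreqTable", pairYears = "data.frame",
                 pups = "data.frame", harvest = "data.frame",
                 config = "SimulationConfig"))

setValidity("TruePopulation", function(object) {
  ind <- object@individuals
  founders <- is.na(ind$dam_id) & is.na(ind$sire_id)
  half <- xor(is.na(ind$dam_id), is.na(ind$sire_id))
  if (any(half)) return("every non-founder must have both a dam and a sire")
  if (!all(ind$id %in% object@genotypes@ids))
    return("every individual needs a true genotype")
  dy <- ind$death_year[!is.na(ind$death_year)]
  by <- ind$birth_year[!is.na(ind$death_year)]
  if (any(dy < by)) return("death year must be >= birth year")
  TRUE
})

#' Pairwise relatedness estimate
#'
#' A dyad's estimated relatedness coefficient r, with the estimator used and,
#' for likelihood estimates, the IBD-mode coefficients (k0, k1, k2) with
#' r = k2 + k1/2.
#'
#' @export
setClass("RelatednessEstimate",
  representation(ids = "character", estimator = "character", r = "numeric",
                 k = "numeric", nLoci = "integer", flag = "character"))

setValidity("RelatednessEstimate", function(object) {
  if (length(object@ids) != 2L) return("ids must name the two individuals")
  if (length(object@k) == 3L && !anyNA(object@k)) {
    if (abs(sum(object@k) - 1) > 1e-9) return("k0+k1+k2 must equal 1")
    if (any(object@k < -1e-12 | object@k > 1 + 1e-12))
      return("each k must lie in [0, 1]")
  }
  TRUE
})

#' Random-mating resampling null for mated-pair relatedness
#'
#' Distribution of mean pair relatedness when mates are drawn at random (with
#' replacement) from the potential-breeder pools, as produced by
#' [randomMatingNull()].
#'
#' @slot iterationMeans per-iteration mean relatedness across the resampled
#'   pairs.
#' @slot draws matrix of pair-level relatedness draws (iterations x pairs),
#'   possibly 0-row when draws were not stored.
#' @slot observed observed mean pair relatedness supplied for comparison
#'   (\code{NA} when none).
#' @slot percentile fraction of iteration means <= observed.
#' @export
setClass("NullDistribution",
  representation(nIter = "integer", nPairs = "integer", estimator = "character",
                 iterationMeans = "numeric", draws = "matrix",
                 observed = "numeric", percentile = "numeric"))

setValidity("NullDistribution", function(object) {
  if (length(object@iterationMeans) != object@nIter)
    return("iterationMeans must have one entry per iteration")
  if (nrow(object@draws) > 0 &&
      !all(dim(object@draws) == c(object@nIter, object@nPairs)))
    return("draws must be nIter x nPairs when stored")
  TRUE
})

#' Fitted logistic (or mixed logistic) model
#'
#' Uniform container for the package's fixed and mixed-effects logistic fits:
#' coefficient table with asymptotic Wald tests, log-likelihood, AIC
#' (2*npar - 2*logLik), and for mixed fits the random-intercept SD and
#' grouping factor.
#'
#' @export
setClass("ModelFit",
  representation(label = "character", coef = "numeric", se = "numeric",
                 z = "numeric", p = "numeric", logLik = "numeric",
                 npar = "integer", nobs = "integer", aic = "numeric",
                 reSD = "numeric", groupVar = "character",
                 converged = "logical", separation = "logical"))

setValidity("ModelFit", function(object) {
  if (length(object@logLik) != 1L) return("logLik must be a scalar")
  if (abs(object@aic - (2 * object@npar - 2 * object@logLik)) > 1e-6)
    return("AIC must equal 2*npar - 2*logLik")
  if (!anyNA(object@se) && any(object@se <= 0))
    return("standard errors must be positive")
  TRUE
})

#' Genotype of an unsampled sire reconstructed from mother-offspring data
#'
#' Per-locus paternal allele constraints deduced from a dam and her assigned
#' offspring: a fixed allele wherever some offspring carries an allele the dam
#' cannot have transmitted, otherwise a candidate set; completeness records
#' how much of the diploid genotype is pinned down (0, 0.5 or 1 per locus).
#'
#' @export
setClass("ReconstructedSire",
  representation(id = "character", loci = "character", a1 = "integer",
                 a2 = "integer", candidates = "list", completeness = "numeric",
                 offspring = "character"))
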