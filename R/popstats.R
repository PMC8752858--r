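#' Observed heterozygosity of a multilocus genotype
#'
#' Fraction of typed loci at which the individual carries two distinct
#' alleles; untyped loci are excluded from both numerator and denominator.
#'
#' @param g an `L x 2` genotype matrix, a [ConsensusGenotype-class], or a
#'   [GenotypeTable-class] (then one record per individual is returned)
#' @return for a single genotype, a list (typed, het, ho); for a table, a
#'   data.frame of per-individual records
#' @export
observedHeterozygosity <- function(g) {
  if (is(g, "GenotypeTable")) {
    typed <- rowSums(!is.na(g@a1))
    het <- rowSums(g@a1 != g@a2, na.rm = TRUE)
    if (any(typed == 0))
      stop("undefined H_o: individual(s) with no typed loci")
    return(data.frame(id = g@ids, typed = typed, het = het,
                      ho = het / typed, row.names = NULL))
  }
  if (is(g, "ConsensusGenotype")) g <- genotypeOf(g)
  typed <- sum(!is.na(g[, 1]))
  if (typed == 0) stop("undefined H_o: no typed loci")
  het <- sum(g[, 1] != g[, 2], na.rm = TRUE)
  list(typed = typed, het = het, ho = het / typed)
}

#' Allele frequencies counted over a set of individuals
#'
#' Counts alleles over the individuals of a genotype table (e.g. the catalog
#' subset detected in one year); frequencies sum to one per locus. Loci with
#' no typed individual are dropped with a warning.
#'
#' @param tab a [GenotypeTable-class]
#' @return an [AlleleFreqTable-class]
#' @export
yearlyAlleleFrequencies <- function(tab) {
  freqs <- list()
  dropped <- character(0)
  for (l in seq_along(tab@loci)) {
    alle <- c(tab@a1[, l], tab@a2[, l])
    alle <- alle[!is.na(alle)]
    if (!length(alle)) { dropped <- c(dropped, tab@loci[l]); next }
    cnt <- table(alle)
    freqs[[tab@loci[l]]] <- stats::setNames(as.numeric(cnt) / sum(cnt),
                                            names(cnt))
  }
  if (length(dropped))
    warning("dropping loci with no typed individuals: ",
            paste(dropped, collapse = ", "))
  if (!length(freqs)) stop("no typed loci")
  AlleleFreqTable(freqs)
}

#' Genotype-recapture harvest rate
#'
#' Annual harvest rate as the number of summer-detected genotypes re-detected
#' among harvested-animal tissues, divided by the number of genotypes
#' detected the previous summer. Matching uses the dropout-tolerant rule, so
#' tissue genotypes from outside the study population simply never match.
#'
#' @param summer list of [ConsensusGenotype-class] (or an
#'   [IndividualCatalog-class]) for the summer catalog
#' @param harvest a [GenotypeTable-class] of harvest tissue genotypes
#' @param minSharedLoci passed to [matchGenotypes()]
#' @return list: rate, matched (summer ids re-detected), summerSize
#' @export
harvestRate <- function(summer, harvest, minSharedLoci = 10L) {
  if (is(summer, "IndividualCatalog")) summer <- summer@representatives
  if (!length(summer)) stop("undefined rate: empty summer catalog")
  hcons <- lapply(seq_len(nIndividuals(harvest)), function(i)
    asConsensus(harvest, harvest@ids[i]))
  matched <- character(0)
  for (s in summer) {
    hit <- any(vapply(hcons, function(h)
      matchGenotypes(s, h, minSharedLoci) == "same-individual", TRUE))
    if (hit) matched <- c(matched, s@sampleId)
  }
  list(rate = length(matched) / length(summer), matched = matched,
       summerSize = length(summer))
}

#' Pair-bond histories from multi-year pedigrees
#'
#' Builds pair-year records from pedigree output: pair-bond duration equals 1
#' in the first breeding year of a dam-sire pair and increments with each
#' later breeding year (the counter continues across gap years), and
#' polygamy is flagged whenever more than one female in a group gave birth in
#' the same year.
#'
#' @param pedigree data.frame with columns offspring_id, dam_id, sire_id,
#'   year, group (one row per pup)
#' @return data.frame: pair_id, dam_id, sire_id, group, year, years_paired,
#'   polygamy, n_pups
#' @export
buildPairHistories <- function(pedigree) {
  ped <- pedigree[!is.na(pedigree$dam_id) & !is.na(pedigree$sire_id), ,
                  drop = FALSE]
  if (!nrow(ped)) return(data.frame())
  ped$pair_id <- paste(ped$dam_id, ped$sire_id, sep = ":")
  key <- paste(ped$pair_id, ped$year)
  agg <- ped[!duplicated(key), c("pair_id", "dam_id", "sire_id", "group",
                                 "year")]
  agg$n_pups <- as.integer(table(key)[paste(agg$pair_id, agg$year)])
  agg <- agg[order(agg$pair_id, agg$year), ]
  agg$years_paired <- stats::ave(agg$year, agg$pair_id,
                                 FUN = seq_along)
  gy <- paste(agg$group, agg$year)
  damsPerGY <- tapply(agg$dam_id, gy, function(d) length(unique(d)))
  agg$polygamy <- unname(damsPerGY[gy] > 1L)
  rownames(agg) <- NULL
  agg
}

#' Apparent pup survival at 15 months
#'
#' Labels each pup of a birth-year cohort alive when its genotype is
#' re-detected in the following summer's catalog (dropout-tolerant match);
#' pups matched only among harvested tissues during their first year, or not
#' detected at all, are labelled dead (absence at 15 months is treated as
#' death).
#'
#' @param pups named list of `L x 2` genotype matrices (or a
#'   [GenotypeTable-class]) for the pup cohort
#' @param nextSummer list of [ConsensusGenotype-class] (or an
#'   [IndividualCatalog-class]) for the following summer
#' @param harvest optional [GenotypeTable-class] of first-year harvest
#'   tissues
#' @param minSharedLoci passed to [matchGenotypes()]
#' @return data.frame: pup_id, alive, detected_summer, detected_harvest
#' @export
apparentSurvival <- function(pups, nextSummer, harvest = NULL,
                             minSharedLoci = 10L) {
  if (is(pups, "GenotypeTable"))
    pups <- stats::setNames(lapply(pups@ids, function(i)
      genotypeOf(pups, i)), pups@ids)
  if (is(nextSummer, "IndividualCatalog"))
    nextSummer <- nextSummer@representatives
  hcons <- if (!is.null(harvest) && nIndividuals(harvest) > 0)
    lapply(seq_len(nIndividuals(harvest)), function(i)
      asConsensus(harvest, harvest@ids[i])) else list()
  rows <- lapply(names(pups), function(pid) {
    pc <- asConsensus(pups[[pid]], pid)
    inSummer <- any(vapply(nextSummer, function(s)
      matchGenotypes(pc, s, minSharedLoci) == "same-individual", TRUE))
    inHarvest <- length(hcons) > 0 && any(vapply(hcons, function(h)
      matchGenotypes(pc, h, minSharedLoci) == "same-individual", TRUE))
    data.frame(pup_id = pid, alive = as.integer(inSummer),
               detected_summer = inSummer, detected_harvest = inHarvest)
  })
  do.call(rbind, rows)
}
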