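# Plain-CSV interfaces.  All alleles are integer labels; 0 denotes no
# amplification in replicate files.

#' Read and write replicate PCR tables
#'
#' Replicate files have columns sample_id, locus, replicate, allele1,
#' allele2 and optionally individual_id/year/group; `blind = TRUE` strips the
#' truth column on write.
#'
#' @param path CSV path
#' @param replicates data.frame as produced by
#'   [simulateNoninvasiveSamples()]
#' @param blind drop the `individual_id` truth column
#' @return `readReplicates` returns the data.frame
#' @export
readReplicates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readReplicates
#' @export
writeReplicates <- function(replicates, path, blind = FALSE) {
  if (blind) replicates$individual_id <- NULL
  utils::write.csv(replicates, path, row.names = FALSE)
  invisible(path)
}

#' Read/write multilocus genotypes in long CSV form
#'
#' Long format: one row per individual and locus with columns id, locus,
#' allele1, allele2 (`NA` for untyped loci).
#'
#' @param path CSV path
#' @param tab a [GenotypeTable-class]
#' @export
readGenotypesCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(d$id)
  lociN <- unique(d$locus)
  a1 <- a2 <- matrix(NA_integer_, length(ids), length(lociN))
  i <- match(d$id, ids); j <- match(d$locus, lociN)
  a1[cbind(i, j)] <- d$allele1
  a2[cbind(i, j)] <- d$allele2
  GenotypeTable(ids, lociN, a1, a2)
}

#' @rdname readGenotypesCSV
#' @export
writeGenotypesCSV <- function(tab, path) {
  d <- data.frame(
    id = rep(tab@ids, times = length(tab@loci)),
    locus = rep(tab@loci, each = length(tab@ids)),
    allele1 = as.vector(tab@a1), allele2 = as.vector(tab@a2))
  utils::write.csv(d[order(d$id, d$locus), ], path, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth to a directory
#'
#' Emits `truth_individuals.csv`, `truth_genotypes.csv`, `harvest.csv`,
#' `pair_years.csv`, `pup_truth.csv` and a `config.yaml` echo of the
#' generator settings.
#'
#' @param pop a [TruePopulation-class]
#' @param dir output directory (created if needed)
#' @export
writeTruth <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pop@individuals, file.path(dir, "truth_individuals.csv"),
                   row.names = FALSE)
  writeGenotypesCSV(pop@genotypes, file.path(dir, "truth_genotypes.csv"))
  utils::write.csv(pop@harvest, file.path(dir, "harvest.csv"),
                   row.names = FALSE)
  utils::write.csv(pop@pairYears, file.path(dir, "pair_years.csv"),
                   row.names = FALSE)
  utils::write.csv(pop@pups, file.path(dir, "pup_truth.csv"),
                   row.names = FALSE)
  cfg <- pop@config
  yaml::write_yaml(list(
    nGroups = cfg@nGroups, nYears = cfg@nYears, startYear = cfg@startYear,
    nLoci = cfg@nLoci, nAlleles = cfg@nAlleles, meanLitter = cfg@meanLitter,
    sneakerProb = cfg@sneakerProb, polygynyProb = cfg@polygynyProb,
    immigrantProb = cfg@immigrantProb, adultMortality = cfg@adultMortality,
    harvestSchedule = cfg@harvestSchedule, pairRESD = cfg@pairRESD,
    survivalCoefs = as.list(cfg@survivalCoefs), seed = cfg@seed),
    file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write consensus genotypes and a catalog to CSV
#'
#' @param genotypes list of [ConsensusGenotype-class]
#' @param catalog an [IndividualCatalog-class]
#' @param path CSV path
#' @export
writeConsensusCSV <- function(genotypes, path) {
  rows <- lapply(genotypes, function(g)
    data.frame(sample_id = g@sampleId, locus = g@loci, allele1 = g@a1,
               allele2 = g@a2, status = g@status))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConsensusCSV
#' @export
writeCatalogCSV <- function(catalog, path) {
  d <- data.frame(individual_id = catalog@ids,
                  detections = lengths(catalog@members),
                  samples = vapply(catalog@members, paste, "",
                                   collapse = ";"))
  extra <- catalog@meta[setdiff(names(catalog@meta),
                                c("individual_id", "detections"))]
  if (ncol(extra)) d <- cbind(d, extra)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a null-distribution summary as JSON
#'
#' @param nd a [NullDistribution-class]
#' @param path output path
#' @export
writeNullSummary <- function(nd, path) {
  q <- stats::quantile(nd@iterationMeans, c(0.025, 0.5, 0.975))
  jsonlite::write_json(list(
    estimator = nd@estimator, iterations = nd@nIter, pairs = nd@nPairs,
    mean = mean(nd@iterationMeans), median = unname(q[2]),
    q025 = unname(q[1]), q975 = unname(q[3]),
    observed = nd@observed, percentile = nd@percentile),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
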