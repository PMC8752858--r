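#' Compare two consensus genotypes under the dropout-tolerant rule
#'
#' Two genotypes are the same individual when, over jointly confirmed loci,
#' they are identical except at most one locus where one genotype is
#' homozygous for an allele contained in the other's heterozygote (a
#' dropout-compatible mismatch, e.g. 102/102 vs 102/106). Any
#' dropout-incompatible locus, or two or more dropout-compatible mismatches,
#' makes them different; fewer than `minSharedLoci` jointly confirmed loci is
#' indeterminate. The comparison is symmetric.
#'
#' @param g1,g2 [ConsensusGenotype-class] objects on the same locus universe
#' @param minSharedLoci minimum jointly confirmed loci for a verdict
#' @return one of `"same-individual"`, `"different"`, `"indeterminate"`
#' @export
matchGenotypes <- function(g1, g2, minSharedLoci = 10L) {
  shared <- which(g1@status != "missing" & g2@status != "missing")
  if (length(shared) < minSharedLoci) return("indeterminate")
  dropoutOk <- 0L
  for (li in shared) {
    x <- c(g1@a1[li], g1@a2[li]); y <- c(g2@a1[li], g2@a2[li])
    if (x[1] == y[1] && x[2] == y[2]) next
    homHet <- (g1@status[li] == "hom" && g2@status[li] == "het" &&
                 x[1] %in% y) ||
              (g2@status[li] == "hom" && g1@status[li] == "het" &&
                 y[1] %in% x)
    if (homHet) dropoutOk <- dropoutOk + 1L else return("different")
    if (dropoutOk >= 2L) return("different")
  }
  "same-individual"
}

#' Cluster samples into unique individuals
#'
#' Greedy agglomeration of consensus genotypes: samples are processed in
#' order of decreasing confirmed-locus count (ties by sample id), and each
#' joins the first existing catalog entry whose representative genotype it
#' matches under [matchGenotypes()]; otherwise it founds a new entry. The
#' representative is the per-locus consensus of the members, heterozygote
#' evidence overriding dropout homozygotes.
#'
#' @param genotypes list of [ConsensusGenotype-class] objects
#' @param minSharedLoci passed to [matchGenotypes()]
#' @param meta optional data.frame keyed by `sample_id` (e.g. year, group);
#'   summarized per individual (first detection's values, plus year range)
#' @return an [IndividualCatalog-class]
#' @export
clusterSamples <- function(genotypes, minSharedLoci = 10L, meta = NULL) {
  if (!length(genotypes))
    return(new("IndividualCatalog", ids = character(0),
               representatives = list(), members = list(),
               meta = data.frame()))
  nconf <- vapply(genotypes, nConfirmed, 1L)
  sid <- vapply(genotypes, function(g) g@sampleId, "")
  ord <- order(-nconf, sid)
  reps <- list(); members <- list()
  for (i in ord) {
    g <- genotypes[[i]]
    joined <- FALSE
    for (j in seq_along(reps)) {
      if (matchGenotypes(g, reps[[j]], minSharedLoci) == "same-individual") {
        reps[[j]] <- .mergeRepresentative(reps[[j]], g)
        members[[j]] <- c(members[[j]], g@sampleId)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps[[length(reps) + 1L]] <- g
      members[[length(members) + 1L]] <- g@sampleId
    }
  }
  ids <- sprintf("IND%04d", seq_along(reps))
  reps <- lapply(seq_along(reps), function(j) {
    r <- reps[[j]]; r@sampleId <- ids[j]; r
  })
  mdf <- data.frame(individual_id = ids, detections = lengths(members))
  if (!is.null(meta)) {
    first <- vapply(members, function(m) m[1], "")
    mrow <- meta[match(first, meta$sample_id), , drop = FALSE]
    mrow$sample_id <- NULL
    mdf <- cbind(mdf, mrow)
    if ("year" %in% names(meta)) {
      yrs <- lapply(members, function(m)
        meta$year[match(m, meta$sample_id)])
      mdf$first_year <- vapply(yrs, function(v) min(v, na.rm = TRUE), 1)
      mdf$last_year <- vapply(yrs, function(v) max(v, na.rm = TRUE), 1)
    }
  }
  rownames(mdf) <- NULL
  new("IndividualCatalog", ids = ids, representatives = reps,
      members = members, meta = mdf)
}

# merge a newly joined sample into a representative: het overrides dropout
# homozygote, confirmed fills missing
.mergeRepresentative <- function(rep, g) {
  for (li in seq_along(rep@loci)) {
    rs <- rep@status[li]; gs <- g@status[li]
    if (gs == "missing") next
    if (rs == "missing" ||
        (rs == "hom" && gs == "het" && rep@a1[li] %in% c(g@a1[li], g@a2[li]))) {
      rep@status[li] <- gs
      rep@a1[li] <- g@a1[li]; rep@a2[li] <- g@a2[li]
    }
  }
  rep
}

#' Wrap plain genotypes as consensus objects
#'
#' Adapter used when matching error-free genotypes (e.g. harvest tissues)
#' against a catalog: heterozygous loci become het-confirmed, homozygous loci
#' hom-confirmed, untyped loci missing.
#'
#' @param g an `L x 2` genotype matrix with loci rownames, or a
#'   [GenotypeTable-class] (then `id` selects the row)
#' @param id sample identifier for the wrapper
#' @return a [ConsensusGenotype-class]
#' @export
asConsensus <- function(g, id = "g") {
  if (is(g, "GenotypeTable")) { gm <- genotypeOf(g, id) } else gm <- g
  status <- ifelse(is.na(gm[, 1]), "missing",
                   ifelse(gm[, 1] == gm[, 2], "hom", "het"))
  new("ConsensusGenotype", sampleId = as.character(id),
      loci = rownames(gm), status = unname(status),
      a1 = as.integer(ifelse(status == "missing", NA, gm[, 1])),
      a2 = as.integer(ifelse(status == "missing", NA, gm[, 2])))
}
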