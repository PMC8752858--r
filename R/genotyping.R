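#' Screen a sample on its first two replicate PCRs
#'
#' A sample is kept for further amplification only if alleles amplified at
#' >= `minLoci` loci (default 5) in the first two PCRs; samples amplifying at
#' fewer loci are discarded.
#'
#' @param reps data.frame of replicate observations for one sample: columns
#'   `locus`, `replicate`, `allele1`, `allele2` (0 = no amplification)
#' @param minLoci screening threshold
#' @return `TRUE` (keep) or `FALSE` (discard)
#' @export
screenSample <- function(reps, minLoci = 5L) {
  if (is.null(reps) || nrow(reps) == 0L)
    stop("malformed input: sample has no replicates")
  first2 <- reps[reps$replicate <= 2L, , drop = FALSE]
  amp <- first2$allele1 > 0 | first2$allele2 > 0
  length(unique(first2$locus[amp])) >= minLoci
}

#' Call a consensus genotype from replicate PCRs
#'
#' Per locus: a heterozygote is confirmed when the same two distinct alleles
#' are seen together in >= 2 independent PCRs (the most frequently observed
#' such pair wins, ties broken by smallest alleles); a homozygote is confirmed
#' when >= 3 PCRs show the single allele and no second allele reaches
#' confirmation support (a second allele seen in >= 2 PCRs vetoes the
#' homozygote). Loci failing both rules are missing. Amplification failures
#' never count toward consensus.
#'
#' @param reps data.frame of all replicates for one kept sample (columns as
#'   in [screenSample()])
#' @param sampleId identifier recorded on the result (defaults to a
#'   `sample_id` column when present)
#' @param loci locus universe; defaults to the loci present in `reps`
#' @return a [ConsensusGenotype-class]
#' @export
callConsensus <- function(reps, sampleId = NULL, loci = NULL) {
  if (is.null(sampleId))
    sampleId <- if ("sample_id" %in% names(reps))
      as.character(reps$sample_id[1]) else "sample"
  if (is.null(loci)) loci <- sort(unique(as.character(reps$locus)))
  L <- length(loci)
  status <- rep("missing", L)
  a1 <- a2 <- rep(NA_integer_, L)
  for (li in seq_len(L)) {
    r <- reps[reps$locus == loci[li] & (reps$allele1 > 0 | reps$allele2 > 0),
              , drop = FALSE]
    if (nrow(r) == 0L) next
    p <- orderPair(r$allele1, r$allele2)
    het <- p[, 1] != p[, 2]
    if (any(het)) {
      key <- paste(p[het, 1], p[het, 2], sep = "/")
      cnt <- sort(table(key), decreasing = TRUE)
      top <- names(cnt)[cnt == max(cnt)]
      top <- sort(top)[1]                      # deterministic tie-break
      if (max(cnt) >= 2L) {
        ab <- as.integer(strsplit(top, "/")[[1]])
        status[li] <- "het"; a1[li] <- ab[1]; a2[li] <- ab[2]
        next
      }
    }
    # homozygote path: count replicates showing exactly one allele
    homAllele <- p[!het, 1]
    if (length(homAllele)) {
      cnt <- sort(table(homAllele), decreasing = TRUE)
      cand <- as.integer(names(cnt)[1])
      support <- cnt[1]
      # veto: any different allele appearing in >= 2 replicates
      seen <- table(c(p[, 1], p[het, 2]))
      other <- seen[names(seen) != as.character(cand)]
      if (support >= 3L && (!length(other) || max(other) < 2L)) {
        status[li] <- "hom"; a1[li] <- cand; a2[li] <- cand
      }
    }
  }
  new("ConsensusGenotype", sampleId = as.character(sampleId),
      loci = loci, status = status, a1 = a1, a2 = a2)
}

#' Screen and call consensus genotypes for a batch of samples
#'
#' Applies [screenSample()] then [callConsensus()] to every sample in a
#' replicate table, fixing a common locus universe.
#'
#' @param replicates data.frame with columns sample_id, locus, replicate,
#'   allele1, allele2
#' @param minLociScreen screening threshold passed to [screenSample()]
#' @return list with `genotypes` (list of [ConsensusGenotype-class] for kept
#'   samples) and `screened` (data.frame: sample_id, kept, nLociFirst2)
#' @export
genotypeSamples <- function(replicates, minLociScreen = 5L) {
  lociAll <- sort(unique(as.character(replicates$locus)))
  bySample <- split(replicates, replicates$sample_id)
  kept <- vapply(bySample, screenSample, TRUE, minLoci = minLociScreen)
  genos <- lapply(bySample[kept], function(r)
    callConsensus(r, sampleId = r$sample_id[1], loci = lociAll))
  names(genos) <- names(bySample)[kept]
  list(genotypes = genos,
       screened = data.frame(sample_id = names(bySample),
                             kept = unname(kept)))
}
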