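#' Reliability score of a single-sample consensus genotype
#'
#' Bayesian accuracy check for unique genotypes represented by only one
#' noninvasive sample. Per confirmed locus, the posterior probability that
#' the consensus call is the true genotype is computed by enumerating all
#' candidate true genotypes at the locus under Hardy-Weinberg priors (from
#' the allele frequency table) and the replicate-PCR emission model
#' (dropout, false allele, amplification failure). The sample score is the
#' product over confirmed loci; genotypes scoring >= `threshold` (default
#' 0.95) are flagged reliable.
#'
#' @param g a [ConsensusGenotype-class] from a single sample
#' @param reps data.frame of that sample's replicates (columns locus,
#'   replicate, allele1, allele2; 0 = no amplification)
#' @param freqs an [AlleleFreqTable-class]
#' @param error an [ErrorModel-class]
#' @param threshold reliability flag threshold
#' @return list: `score` (product over confirmed loci), `perLocus` (named
#'   posterior per confirmed locus), `reliable` (score >= threshold)
#' @export
reliabilityScore <- function(g, reps, freqs, error, threshold = 0.95) {
  conf <- which(g@status != "missing")
  if (!length(conf))
    return(list(score = NA_real_, perLocus = numeric(0), reliable = FALSE))
  per <- stats::setNames(numeric(length(conf)), g@loci[conf])
  for (m in seq_along(conf)) {
    li <- conf[m]
    locName <- g@loci[li]
    p <- freqs@freqs[[locName]]
    if (is.null(p)) stop("locus absent from frequency table: ", locName)
    r <- reps[reps$locus == locName, , drop = FALSE]
    obs <- lapply(seq_len(nrow(r)), function(j) {
      if (r$allele1[j] <= 0 && r$allele2[j] <= 0) return(NULL)
      c(r$allele1[j], r$allele2[j])
    })
    lab <- as.integer(names(p))
    if (!all(c(g@a1[li], g@a2[li]) %in% lab))
      stop("unknown allele at locus ", locName,
           ": not present in the frequency table")
    post <- .locusPosterior(obs, p, error)
    hit <- post$genos[, 1] == g@a1[li] & post$genos[, 2] == g@a2[li]
    per[m] <- sum(post$post[hit])
  }
  score <- prod(per)
  list(score = score, perLocus = per, reliable = score >= threshold)
}
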