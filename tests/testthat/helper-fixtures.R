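# shared fixtures built in code

# fixed two-locus, three-allele frequency table for exhaustive small cases
smallFreqs <- function() {
  AlleleFreqTable(list(
    L01 = c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
    L02 = c(`1` = 0.6, `2` = 0.25, `3` = 0.15)))
}

# constant-genotype matrix helper: same allele pair at every locus
mkGeno <- function(a, b, freqs) {
  L <- nLoci(freqs)
  g <- cbind(rep(as.integer(a), L), rep(as.integer(b), L))
  g <- t(apply(g, 1, sort))
  rownames(g) <- loci(freqs)
  colnames(g) <- c("a1", "a2")
  g
}

# genotype matrix from explicit per-locus pairs: list of c(a, b)
mkGenoList <- function(pairs, freqs) {
  g <- t(vapply(pairs, function(p) sort(as.integer(p), na.last = TRUE),
                integer(2)))
  rownames(g) <- loci(freqs)[seq_len(nrow(g))]
  colnames(g) <- c("a1", "a2")
  g
}

# replicate data.frame for one sample from a list of per-replicate calls;
# each element of `calls` is a named list locus -> c(a, b) (0,0 = failure)
mkReps <- function(calls, sampleId = "s1") {
  rows <- list()
  for (r in seq_along(calls)) {
    for (l in names(calls[[r]])) {
      p <- calls[[r]][[l]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sampleId, locus = l, replicate = r,
        allele1 = min(p), allele2 = max(p))
    }
  }
  do.call(rbind, rows)
}
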