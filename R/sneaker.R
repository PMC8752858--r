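#' Reconstruct an unsampled sire from mother-offspring genotypes
#'
#' For a dam and her assigned offspring (sire unknown), deduces the paternal
#' allele of each offspring at each locus: the allele not attributable to the
#' dam is paternal; when both offspring alleles could be maternal the
#' contribution is an ambiguous candidate set. Constraints are combined
#' across the full siblings: alleles paternal in some offspring become fixed
#' sire alleles (at most two per locus), remaining ambiguity is reported as
#' candidate sets, and per-locus completeness is 1, 0.5 or 0 as both, one or
#' neither sire allele is pinned down.
#'
#' @param dam `L x 2` genotype matrix of the dam (loci rownames)
#' @param offspring named list of `L x 2` genotype matrices of her offspring
#' @param id identifier for the reconstructed sire
#' @param maxIncompatible per-offspring tolerance: more than this many
#'   offspring alleles unexplainable by the dam raises an inconsistent-input
#'   error
#' @return a [ReconstructedSire-class]
#' @export
reconstructSneaker <- function(dam, offspring, id = "SNEAK1",
                               maxIncompatible = 2L) {
  lociN <- rownames(dam)
  L <- length(lociN)
  # per-offspring dam compatibility
  for (oid in names(offspring)) {
    off <- offspring[[oid]]
    bad <- 0L
    for (l in lociN) {
      oo <- off[l, ]; dd <- dam[l, ]
      if (anyNA(oo) || anyNA(dd)) next
      if (!any(oo %in% dd)) bad <- bad + 1L   # neither allele maternal
    }
    if (bad > maxIncompatible)
      stop("inconsistent input: offspring ", oid, " incompatible with dam at ",
           bad, " alleles (> ", maxIncompatible, ")")
  }

  fixed <- vector("list", L); cand <- vector("list", L)
  names(fixed) <- names(cand) <- lociN
  for (l in lociN) {
    dd <- dam[l, ]
    fx <- integer(0); sets <- list()
    for (oid in names(offspring)) {
      oo <- offspring[[oid]][l, ]
      if (anyNA(oo) || anyNA(dd)) next
      inDam <- oo %in% dd
      if (all(inDam)) {
        sets[[length(sets) + 1L]] <- unique(oo)   # ambiguous: either could be paternal
      } else if (any(inDam)) {
        fx <- c(fx, oo[!inDam])
      } else {
        # dropout-tolerated incompatibility: skip the locus for this offspring
        next
      }
    }
    fx <- sort(unique(fx))
    if (length(fx) > 2L)
      stop("inconsistent input: >2 distinct obligate paternal alleles at ", l)
    # an ambiguous set shared by all informative offspring narrows candidates
    cset <- if (length(sets)) sort(Reduce(intersect, sets)) else integer(0)
    fixed[[l]] <- fx
    cand[[l]] <- setdiff(cset, fx)
  }

  a1 <- a2 <- rep(NA_integer_, L)
  compl <- numeric(L)
  for (li in seq_len(L)) {
    fx <- fixed[[li]]
    if (length(fx) == 2L) {
      a1[li] <- fx[1]; a2[li] <- fx[2]; compl[li] <- 1
    } else if (length(fx) == 1L) {
      a1[li] <- fx[1]; compl[li] <- 0.5
    }
  }
  new("ReconstructedSire", id = id, loci = lociN, a1 = a1, a2 = a2,
      candidates = cand, completeness = compl,
      offspring = names(offspring))
}
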