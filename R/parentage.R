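# Trio likelihood machinery.
#
# The likelihood of an observed offspring genotype given observed parent
# genotypes integrates over the true genotypes of all three individuals:
# Hardy-Weinberg priors on the parents, the replicate-PCR emission model on
# every observed genotype, and Mendelian transmission in between.  Because
# transmission depends on the parents only through the allele each one
# passes, the parental integrals collapse into per-parent transmission
# marginals, which keeps the computation exact and O(k^2) per locus.

# per-locus P(obs offspring | parent info); tauD/tauS are transmission
# marginals over allele labels (NULL -> integrate the parent over HW, i.e.
# tau = allele frequencies)
.offspringObsLik <- function(obsOff, p, error, tauD = NULL, tauS = NULL) {
  labels <- as.integer(names(p))
  if (is.null(tauD)) tauD <- stats::setNames(as.numeric(p), names(p))
  if (is.null(tauS)) tauS <- stats::setNames(as.numeric(p), names(p))
  genos <- .allGenotypes(labels)
  c1 <- as.character(genos[, 1]); c2 <- as.character(genos[, 2])
  pGo <- ifelse(genos[, 1] == genos[, 2],
                tauD[c1] * tauS[c1],
                tauD[c1] * tauS[c2] + tauD[c2] * tauS[c1])
  em <- vapply(seq_len(nrow(genos)), function(i)
    emissionProb(obsOff, genos[i, ], error, length(labels)), 0)
  sum(pGo * em)
}

# transmission marginal of an observed parent at one locus
.parentTau <- function(obsPar, p, error) {
  post <- .locusPosterior(obsPar, p, error)
  .transmissionMarginal(post$genos, post$post, as.integer(names(p)))
}

#' Trio log-likelihood of an offspring given two candidate parents
#'
#' Per jointly typed locus, computes P(observed offspring genotype | observed
#' dam and sire genotypes) by summing over true-genotype states weighted by
#' dropout/false-allele emission probabilities and Mendelian transmission,
#' with Hardy-Weinberg priors on the parents' true genotypes; log-likelihoods
#' accumulate across loci. Loci missing in any member are skipped. A `NULL`
#' parent is integrated over Hardy-Weinberg genotype frequencies (the
#' unknown-parent hypothesis).
#'
#' @param off,dam,sire `L x 2` genotype matrices with loci rownames (`NA`
#'   rows untyped); `dam`/`sire` may be `NULL` for an unknown parent
#' @param freqs an [AlleleFreqTable-class]
#' @param error an [ErrorModel-class]
#' @return the summed log-likelihood (`-Inf` for a Mendelian impossibility at
#'   zero error rates)
#' @export
trioLoglik <- function(off, dam, sire, freqs, error = ErrorModel()) {
  lociN <- rownames(off)
  ll <- 0
  used <- 0L
  for (l in lociN) {
    p <- freqs@freqs[[l]]
    if (is.null(p)) next
    oo <- off[l, ]
    if (anyNA(oo)) next
    od <- if (!is.null(dam)) dam[l, ] else NULL
    os <- if (!is.null(sire)) sire[l, ] else NULL
    if (!is.null(dam) && anyNA(od)) next
    if (!is.null(sire) && anyNA(os)) next
    tauD <- if (is.null(od)) NULL else .parentTau(od, p, error)
    tauS <- if (is.null(os)) NULL else .parentTau(os, p, error)
    lik <- .offspringObsLik(oo, p, error, tauD, tauS)
    ll <- ll + log(lik)
    used <- used + 1L
  }
  if (used == 0L) stop("undefined likelihood: no jointly typed loci")
  ll
}

#' Count Mendelian mismatches between an offspring and a candidate pair
#'
#' Per locus, the minimum number of offspring alleles (0, 1 or 2) that cannot
#' be explained by any consistent transmission from the proposed parents,
#' summed across loci; parents untyped at a locus explain anything there.
#' The pair is accepted when the total is at most `maxMismatch` (default 2,
#' tolerating allelic dropout).
#'
#' @param off,dam,sire `L x 2` genotype matrices with loci rownames
#' @param maxMismatch acceptance tolerance in alleles
#' @param minSharedLoci minimum loci jointly typed in all three members
#' @return list: `mismatches`, `accept`, `sharedLoci`
#' @export
exclusionCheck <- function(off, dam, sire, maxMismatch = 2L,
                           minSharedLoci = 10L) {
  lociN <- rownames(off)
  mm <- 0L; shared <- 0L
  for (l in lociN) {
    oo <- off[l, ]
    if (anyNA(oo)) next
    dd <- dam[l, ]; ss <- sire[l, ]
    if (!anyNA(dd) && !anyNA(ss)) shared <- shared + 1L
    dHas <- function(a) anyNA(dd) || a %in% dd
    sHas <- function(a) anyNA(ss) || a %in% ss
    m1 <- (!dHas(oo[1])) + (!sHas(oo[2]))
    m2 <- (!dHas(oo[2])) + (!sHas(oo[1]))
    mm <- mm + min(m1, m2)
  }
  if (shared < minSharedLoci)
    return(list(mismatches = NA_integer_, accept = FALSE,
                sharedLoci = shared))
  list(mismatches = as.integer(mm), accept = mm <= maxMismatch,
       sharedLoci = shared)
}

#' Assign a dam and sire to an offspring
#'
#' Evaluates all dam x sire pairs among the candidates plus dam-only,
#' sire-only and no-parent hypotheses (unknown parents integrated over
#' Hardy-Weinberg genotype frequencies) with [trioLoglik()]. The
#' maximum-likelihood hypothesis is accepted when its log-likelihood exceeds
#' the runner-up's by at least `deltaLL`; otherwise the top-ranked full pair
#' is accepted by mismatch-tolerant exclusion ([exclusionCheck()]) when it
#' passes, and the offspring is left unassigned when neither route decides.
#'
#' @param off `L x 2` genotype matrix of the offspring
#' @param dams,sires named lists of candidate genotype matrices (use the
#'   candidates of reproductive age, >= 2 years old in the birth year)
#' @param freqs an [AlleleFreqTable-class]
#' @param error an [ErrorModel-class]
#' @param deltaLL confidence margin over the runner-up hypothesis
#' @param maxMismatch,minSharedLoci exclusion-fallback settings
#' @return data.frame row: dam, sire (NA when unknown), method
#'   (likelihood/exclusion/unassigned), score (log-likelihood ratio vs the
#'   no-parent hypothesis), deltaLL margin, mismatches
#' @export
assignParentage <- function(off, dams, sires, freqs, error = ErrorModel(),
                            deltaLL = 3, maxMismatch = 2L,
                            minSharedLoci = 10L) {
  unassigned <- data.frame(dam = NA_character_, sire = NA_character_,
                           method = "unassigned", score = NA_real_,
                           deltaLL = NA_real_, mismatches = NA_integer_)
  eng <- .parentageEngine(off, dams, sires, freqs, error)
  ll0 <- eng(NA_character_, NA_character_)
  hyp <- list(list(dam = NA_character_, sire = NA_character_, ll = ll0))
  for (dn in names(dams)) {
    hyp[[length(hyp) + 1L]] <- list(dam = dn, sire = NA_character_,
                                    ll = eng(dn, NA_character_))
    for (sn in names(sires))
      hyp[[length(hyp) + 1L]] <- list(dam = dn, sire = sn, ll = eng(dn, sn))
  }
  for (sn in names(sires))
    hyp[[length(hyp) + 1L]] <- list(dam = NA_character_, sire = sn,
                                    ll = eng(NA_character_, sn))
  lls <- vapply(hyp, function(h) h$ll, 0)
  ord <- order(lls, decreasing = TRUE)
  best <- hyp[[ord[1]]]
  margin <- if (length(ord) > 1L) lls[ord[1]] - lls[ord[2]] else Inf
  if (is.finite(lls[ord[1]]) && margin >= deltaLL &&
      !(is.na(best$dam) && is.na(best$sire))) {
    return(data.frame(dam = best$dam, sire = best$sire,
                      method = "likelihood", score = best$ll - ll0,
                      deltaLL = margin, mismatches = NA_integer_))
  }
  # exclusion fallback on the top-ranked full pair
  full <- ord[vapply(hyp[ord], function(h)
    !is.na(h$dam) && !is.na(h$sire), TRUE)]
  if (length(full)) {
    top <- hyp[[full[1]]]
    ex <- exclusionCheck(off, dams[[top$dam]], sires[[top$sire]],
                         maxMismatch, minSharedLoci)
    if (isTRUE(ex$accept)) {
      return(data.frame(dam = top$dam, sire = top$sire,
                        method = "exclusion", score = top$ll - ll0,
                        deltaLL = margin, mismatches = ex$mismatches))
    }
  }
  unassigned
}

# Cached trio-likelihood engine: precomputes, per offspring-typed locus, the
# genotype grid, the offspring emission vector, and each candidate parent's
# transmission marginal, then evaluates any (dam, sire) hypothesis cheaply.
# The arithmetic is identical to trioLoglik(); loci missing in a named
# parent are skipped for that hypothesis.
.parentageEngine <- function(off, dams, sires, freqs, error) {
  lociN <- rownames(off)
  keep <- lociN[!is.na(off[, 1]) & lociN %in% loci(freqs)]
  if (!length(keep)) stop("undefined likelihood: no typed loci in offspring")
  prep <- lapply(keep, function(l) {
    p <- freqs@freqs[[l]]
    labels <- as.integer(names(p))
    genos <- .allGenotypes(labels)
    c1 <- as.character(genos[, 1]); c2 <- as.character(genos[, 2])
    list(p = p, genos = genos, c1 = c1, c2 = c2, hom = c1 == c2,
         em = .emissionVec(off[l, ], genos, error, length(labels)))
  })
  names(prep) <- keep
  tauOf <- function(g) {
    lapply(keep, function(l) {
      if (anyNA(g[l, ])) return(NULL)
      .parentTau(g[l, ], prep[[l]]$p, error)
    })
  }
  dTau <- lapply(dams, tauOf)
  sTau <- lapply(sires, tauOf)
  hwLik <- vapply(seq_along(keep), function(li) {
    pr <- prep[[li]]
    sum(.hwPrior(pr$genos, pr$p) * pr$em)
  }, 0)
  function(dn, sn) {
    ll <- 0
    for (li in seq_along(keep)) {
      pr <- prep[[li]]
      tD <- if (is.na(dn)) NULL else dTau[[dn]][[li]]
      tS <- if (is.na(sn)) NULL else sTau[[sn]][[li]]
      if (!is.na(dn) && is.null(tD)) next   # dam untyped here: skip locus
      if (!is.na(sn) && is.null(tS)) next
      if (is.null(tD) && is.null(tS)) { ll <- ll + log(hwLik[li]); next }
      if (is.null(tD)) tD <- stats::setNames(as.numeric(pr$p), names(pr$p))
      if (is.null(tS)) tS <- stats::setNames(as.numeric(pr$p), names(pr$p))
      pGo <- ifelse(pr$hom, tD[pr$c1] * tS[pr$c1],
                    tD[pr$c1] * tS[pr$c2] + tD[pr$c2] * tS[pr$c1])
      ll <- ll + log(sum(pGo * pr$em))
    }
    ll
  }
}

#' Assign parentage across a pup cohort
#'
#' Convenience wrapper applying [assignParentage()] to every offspring,
#' returning the pedigree table the downstream pair-history and survival
#' operations consume.
#'
#' @param offspring named list of offspring genotype matrices
#' @param dams,sires named lists of candidate parent genotype matrices
#' @param freqs,error,... passed to [assignParentage()]
#' @return data.frame: offspring_id, dam_id, sire_id, method, score,
#'   mismatches
#' @export
buildPedigree <- function(offspring, dams, sires, freqs,
                          error = ErrorModel(), ...) {
  rows <- lapply(names(offspring), function(oid) {
    a <- assignParentage(offspring[[oid]], dams, sires, freqs, error, ...)
    data.frame(offspring_id = oid, dam_id = a$dam, sire_id = a$sire,
               method = a$method, score = a$score, mismatches = a$mismatches)
  })
  do.call(rbind, rows)
}
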