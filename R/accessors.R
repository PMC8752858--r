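# ---- constructors ------------------------------------------------------

#' Construct an allele frequency table
#'
#' @param freqs named list of named numeric vectors (allele label -> frequency)
#' @return an [AlleleFreqTable-class]
#' @export
AlleleFreqTable <- function(freqs) {
  new("AlleleFreqTable", freqs = lapply(freqs, function(p) {
    p <- p[order(as.integer(names(p)))]
    p / sum(p)
  }))
}

#' Construct a genotype table
#'
#' @param ids individual/sample identifiers
#' @param loci locus names
#' @param a1,a2 integer matrices of alleles (ids x loci); pairs are reordered
#'   so that a1 <= a2
#' @export
GenotypeTable <- function(ids, loci, a1, a2) {
  a1 <- matrix(as.integer(a1), length(ids), length(loci))
  a2 <- matrix(as.integer(a2), length(ids), length(loci))
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  new("GenotypeTable", ids = as.character(ids), loci = as.character(loci),
      a1 = a1, a2 = a2)
}

#' Construct a PCR error model
#'
#' @param dropout per-allele allelic dropout rate per PCR
#' @param falseAllele per-allele false-allele substitution rate per PCR
#' @param failure per-locus amplification failure rate per PCR
#' @export
ErrorModel <- function(dropout = 0.01, falseAllele = 0.01, failure = 0) {
  new("ErrorModel", dropout = dropout, falseAllele = falseAllele,
      failure = failure)
}

# ---- accessors ---------------------------------------------------------

#' @rdname GenotypeTable-class
#' @export
setMethod("nLoci", "GenotypeTable", function(x) length(x@loci))
#' @rdname GenotypeTable-class
#' @export
setMethod("nLoci", "AlleleFreqTable", function(x) length(x@freqs))
#' @rdname GenotypeTable-class
#' @export
setMethod("nLoci", "ConsensusGenotype", function(x) length(x@loci))

#' @rdname GenotypeTable-class
#' @export
setMethod("loci", "GenotypeTable", function(x) x@loci)
#' @rdname GenotypeTable-class
#' @export
setMethod("loci", "AlleleFreqTable", function(x) names(x@freqs))
#' @rdname GenotypeTable-class
#' @export
setMethod("loci", "ConsensusGenotype", function(x) x@loci)

#' @rdname GenotypeTable-class
#' @export
setMethod("nIndividuals", "GenotypeTable", function(x) length(x@ids))
#' @rdname GenotypeTable-class
#' @export
setMethod("nIndividuals", "IndividualCatalog", function(x) length(x@ids))

#' @rdname GenotypeTable-class
#' @export
setMethod("individualIds", "GenotypeTable", function(x) x@ids)
#' @rdname GenotypeTable-class
#' @export
setMethod("individualIds", "IndividualCatalog", function(x) x@ids)

#' @rdname genotypeOf
#' @export
setMethod("genotypeOf", "GenotypeTable", function(x, i) {
  if (is.character(i)) i <- match(i, x@ids)
  if (anyNA(i)) stop("unknown individual id")
  g <- cbind(x@a1[i, ], x@a2[i, ])
  rownames(g) <- x@loci
  colnames(g) <- c("a1", "a2")
  g
})

#' @rdname genotypeOf
#' @export
setMethod("genotypeOf", "ConsensusGenotype", function(x, i) {
  g <- cbind(a1 = x@a1, a2 = x@a2)
  rownames(g) <- x@loci
  g
})

#' @rdname genotypeOf
#' @export
setMethod("genotypeOf", "ReconstructedSire", function(x, i) {
  g <- cbind(a1 = x@a1, a2 = x@a2)
  rownames(g) <- x@loci
  g
})

#' @rdname nConfirmed
#' @export
setMethod("nConfirmed", "ConsensusGenotype",
          function(x) sum(x@status != "missing"))

#' Subset a genotype table by individual
#'
#' @param x a [GenotypeTable-class]
#' @param i ids or indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  GenotypeTable(x@ids[i], x@loci, x@a1[i, , drop = FALSE],
                x@a2[i, , drop = FALSE])
})

# ---- show methods ------------------------------------------------------

setMethod("show", "AlleleFreqTable", function(object) {
  k <- vapply(object@freqs, length, 1L)
  cat(sprintf("AlleleFreqTable: %d loci, %d-%d alleles per locus\n",
              length(k), min(k), max(k)))
})

setMethod("show", "GenotypeTable", function(object) {
  typed <- mean(!is.na(object@a1))
  cat(sprintf("GenotypeTable: %d individuals x %d loci (%.1f%% typed)\n",
              length(object@ids), length(object@loci), 100 * typed))
})

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf(
    "ErrorModel: dropout %.3g, false allele %.3g, amplification failure %.3g per PCR\n",
    object@dropout, object@falseAllele, object@failure))
})

setMethod("show", "ConsensusGenotype", function(object) {
  cat(sprintf("ConsensusGenotype '%s': %d/%d loci confirmed (%d het, %d hom)\n",
              object@sampleId, nConfirmed(object), length(object@loci),
              sum(object@status == "het"), sum(object@status == "hom")))
})

setMethod("show", "IndividualCatalog", function(object) {
  det <- lengths(object@members)
  cat(sprintf("IndividualCatalog: %d individuals from %d samples (detections %d-%d)\n",
              length(object@ids), sum(det),
              if (length(det)) min(det) else 0L,
              if (length(det)) max(det) else 0L))
})

setMethod("show", "TruePopulation", function(object) {
  ind <- object@individuals
  cat(sprintf(
    "TruePopulation: %d individuals (%d sneakers), %d packs x %d years, %d pups, %d harvest records\n",
    nrow(ind), sum(ind$is_sneaker), object@config@nGroups,
    object@config@nYears, nrow(object@pups), nrow(object@harvest)))
})

setMethod("show", "RelatednessEstimate", function(object) {
  cat(sprintf("RelatednessEstimate [%s]: r = %.3f (%s, %d loci)\n",
              paste(object@ids, collapse = " x "), object@r, object@estimator,
              object@nLoci))
  if (length(object@k) == 3L && !anyNA(object@k))
    cat(sprintf("  k0 = %.3f, k1 = %.3f, k2 = %.3f\n",
                object@k[1], object@k[2], object@k[3]))
})

setMethod("show", "NullDistribution", function(object) {
  q <- stats::quantile(object@iterationMeans, c(.025, .5, .975))
  cat(sprintf(
    "NullDistribution (%s): %d iterations x %d pairs\n  mean %.4f, median %.4f, 95%% interval [%.4f, %.4f]\n",
    object@estimator, object@nIter, object@nPairs,
    mean(object@iterationMeans), q[2], q[1], q[3]))
  if (!is.na(object@observed))
    cat(sprintf("  observed %.4f at percentile %.3f\n", object@observed,
                object@percentile))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit '%s': n = %d, logLik = %.2f, AIC = %.2f\n",
              object@label, object@nobs, object@logLik, object@aic))
  tab <- data.frame(beta = round(object@coef, 3), se = round(object@se, 3),
                    p = signif(object@p, 3))
  print(tab)
  if (!is.na(object@reSD))
    cat(sprintf("  random intercept (%s) SD = %.3f\n", object@groupVar,
                object@reSD))
  if (object@separation) cat("  WARNING: separation detected; fit unreliable\n")
})

setMethod("show", "ReconstructedSire", function(object) {
  cat(sprintf(
    "ReconstructedSire '%s': %d loci, mean completeness %.2f, %d supporting offspring\n",
    object@id, length(object@loci), mean(object@completeness),
    length(object@offspring)))
})

#' Coefficient and model-summary extractors for ModelFit
#' @param object a [ModelFit-class]
#' @param ... ignored
#' @export
setMethod("coef", "ModelFit", function(object, ...) object@coef)

#' @rdname coef-ModelFit-method
#' @export
setMethod("logLik", "ModelFit", function(object, ...)
  structure(object@logLik, df = object@npar, class = "logLik"))
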