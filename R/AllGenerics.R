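#' @rdname GenotypeTable-class
#' @param x an object with loci
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' Extract one genotype as a loci x 2 integer matrix
#'
#' @param x a [GenotypeTable-class], [ConsensusGenotype-class] or
#'   [ReconstructedSire-class]
#' @param i individual id or index (ignored for single-genotype objects)
#' @return integer matrix with \code{nLoci(x)} rows, two columns and loci as
#'   rownames; \code{NA} rows are untyped loci.
#' @export
setGeneric("genotypeOf", function(x, i) standardGeneric("genotypeOf"))

#' Number of confirmed (non-missing) loci
#' @param x a [ConsensusGenotype-class]
#' @export
setGeneric("nConfirmed", function(x) standardGeneric("nConfirmed"))
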