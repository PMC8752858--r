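#' Simulate noninvasive fecal samples with replicate PCRs
#'
#' Emulates summer scat sampling: each detected pack member contributes one or
#' more samples, each amplified in several replicate PCRs. Per replicate and
#' locus, the whole locus fails with the failure rate; otherwise each true
#' allele independently drops out at the dropout rate, and amplified copies
#' are mis-read as a uniformly chosen different allele at the false-allele
#' rate. A replicate retaining a single distinct allele is recorded as an
#' apparent homozygote; `0` denotes no amplification.
#'
#' @param pop a [TruePopulation-class]
#' @param error an [ErrorModel-class]
#' @param years calendar years to sample (default: all simulated years)
#' @param samplesPerIndividual,replicatesPerSample,detectionProb overrides of
#'   the population's configured sampling design
#' @param seed optional RNG seed
#' @return data.frame with columns sample_id, individual_id, year, group,
#'   locus, replicate, allele1, allele2
#' @export
simulateNoninvasiveSamples <- function(pop, error = ErrorModel(),
                                       years = NULL,
                                       samplesPerIndividual = NULL,
                                       replicatesPerSample = NULL,
                                       detectionProb = NULL, seed = NULL) {
  validObject(error)
  cfg <- pop@config
  nS <- samplesPerIndividual %||% cfg@samplesPerIndividual
  nR <- replicatesPerSample %||% cfg@replicatesPerSample
  pDet <- detectionProb %||% cfg@detectionProb
  checkProb(pDet, "detectionProb")
  if (is.null(years))
    years <- cfg@startYear + seq_len(cfg@nYears) - 1L
  ind <- pop@individuals

  withSeed(seed, {
    det <- list()
    for (y in years) {
      here <- ind$birth_year <= y &
        (is.na(ind$death_year) | ind$death_year >= y) &
        !ind$is_sneaker & !is.na(ind$group)
      ids <- ind$id[here]
      if (pDet < 1) ids <- ids[stats::runif(length(ids)) < pDet]
      if (length(ids))
        det[[length(det) + 1L]] <- data.frame(individual_id = ids, year = y)
    }
    if (!length(det)) stop("no individuals detected in the requested years")
    det <- do.call(rbind, det)
    det <- det[rep(seq_len(nrow(det)), each = nS), ]
    det$sample_id <- sprintf("S%05d", seq_len(nrow(det)))

    lociN <- loci(pop@freqs)
    L <- length(lociN)
    truth <- pop@genotypes
    rows <- match(det$individual_id, truth@ids)
    # expand to (samples x replicates) x loci
    m <- nrow(det) * nR
    rIdx <- rep(rows, each = nR)
    t1 <- truth@a1[rIdx, , drop = FALSE]
    t2 <- truth@a2[rIdx, , drop = FALSE]
    o1 <- .amplifyCopies(t1, error, pop@freqs)
    o2 <- .amplifyCopies(t2, error, pop@freqs)
    fail <- matrix(stats::runif(m * L) < error@failure, m, L)
    o1[fail] <- 0L; o2[fail] <- 0L
    # single survivor -> apparent homozygote
    only2 <- o1 == 0L & o2 > 0L
    o1[only2] <- o2[only2]
    only1 <- o2 == 0L & o1 > 0L
    o2[only1] <- o1[only1]
    swap <- o1 > o2
    tmp <- o1[swap]; o1[swap] <- o2[swap]; o2[swap] <- tmp

    out <- data.frame(
      sample_id = rep(det$sample_id, each = nR * L),
      individual_id = rep(det$individual_id, each = nR * L),
      year = rep(det$year, each = nR * L),
      group = rep(ind$group[rows], each = nR * L),
      locus = rep(rep(lociN, times = nR), times = nrow(det)),
      replicate = rep(rep(seq_len(nR), each = L), times = nrow(det)),
      allele1 = as.vector(t(o1)), allele2 = as.vector(t(o2)))
    rownames(out) <- NULL
    out
  })
}

# apply dropout + false-allele substitution to one allele-copy matrix
.amplifyCopies <- function(a, error, freqs) {
  m <- nrow(a); L <- ncol(a)
  out <- a
  drop <- matrix(stats::runif(m * L) < error@dropout, m, L)
  out[drop] <- 0L
  if (error@falseAllele > 0) {
    sub <- matrix(stats::runif(m * L) < error@falseAllele, m, L) & !drop
    for (l in seq_len(L)) {
      s <- which(sub[, l])
      if (!length(s)) next
      lab <- as.integer(names(freqs@freqs[[l]]))
      k <- length(lab)
      # uniform over the k-1 other alleles of the locus
      shift <- sample.int(k - 1L, length(s), replace = TRUE)
      pos <- match(out[s, l], lab)
      out[s, l] <- lab[((pos - 1L + shift) %% k) + 1L]
    }
  }
  out
}

#' Error-free tissue genotypes of harvested animals
#'
#' Returns one complete multilocus genotype per harvest record (tissue DNA is
#' treated as error-free), tagged with harvest year and study-area membership
#' (sneaker males harvested outside any sampled pack are flagged out-of-area).
#'
#' @param pop a [TruePopulation-class]
#' @param year optional calendar year filter
#' @return list with elements `genotypes` (a [GenotypeTable-class]) and
#'   `meta` (data.frame: id, year, group, in_study_area)
#' @export
simulateHarvestTissues <- function(pop, year = NULL) {
  h <- pop@harvest
  if (!is.null(year)) h <- h[h$year %in% year, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(list(genotypes = GenotypeTable(character(0), loci(pop@freqs),
                                          matrix(integer(0), 0, nLoci(pop@freqs)),
                                          matrix(integer(0), 0, nLoci(pop@freqs))),
                meta = data.frame(id = character(0), year = integer(0),
                                  group = character(0),
                                  in_study_area = logical(0))))
  }
  list(genotypes = pop@genotypes[h$id],
       meta = data.frame(id = h$id, year = h$year, group = h$group,
                         in_study_area = !is.na(h$group)))
}
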