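test_that("allele frequency tables are valid, deterministic, and give the
           right expected heterozygosity", {
  ft <- generateAlleleFrequencies(L = 18, k = 8, seed = 7)
  expect_s4_class(ft, "AlleleFreqTable")
  sums <- vapply(ft@freqs, sum, 0)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(unlist(ft@freqs) > 0))
  ft2 <- generateAlleleFrequencies(L = 18, k = 8, seed = 7)
  expect_identical(ft@freqs, ft2@freqs)

  expect_error(generateAlleleFrequencies(L = 3, k = 1), "k must be >= 2")

  # uniform frequencies at k = 4 give He = 1 - 4 * 0.25^2 = 0.75
  unif <- AlleleFreqTable(list(L01 = c(`1` = .25, `2` = .25, `3` = .25,
                                       `4` = .25)))
  expect_equal(unname(expectedHeterozygosity(unif)), 0.75)
})

test_that("simulated populations satisfy pedigree and Mendelian invariants", {
  cfg <- SimulationConfig(nGroups = 5L, nYears = 4L, seed = 42)
  pop <- simulatePopulation(cfg)
  ind <- pop@individuals

  # non-founders have both parents; death >= birth
  nonf <- !is.na(ind$dam_id)
  expect_true(all(!is.na(ind$sire_id[nonf])))
  dy <- ind$death_year; by <- ind$birth_year
  expect_true(all(dy[!is.na(dy)] >= by[!is.na(dy)]))

  # exhaustive Mendelian check on every trio and locus
  for (i in which(nonf)) {
    off <- genotypeOf(pop@genotypes, ind$id[i])
    dam <- genotypeOf(pop@genotypes, ind$dam_id[i])
    sire <- genotypeOf(pop@genotypes, ind$sire_id[i])
    ok <- vapply(seq_len(nrow(off)), function(l) {
      any(c(off[l, 1] %in% dam[l, ] & off[l, 2] %in% sire[l, ],
            off[l, 2] %in% dam[l, ] & off[l, 1] %in% sire[l, ]))
    }, TRUE)
    expect_true(all(ok))
  }

  # bit-identical reruns under the same seed
  pop2 <- simulatePopulation(cfg)
  expect_identical(pop@individuals, pop2@individuals)
  expect_identical(pop@genotypes@a1, pop2@genotypes@a1)
  expect_identical(pop@pups, pop2@pups)
})

test_that("founder heterozygosity matches Hardy-Weinberg expectation", {
  ft <- generateAlleleFrequencies(18, 8, seed = 3)
  tab <- drawGenotypes(ft, 400, seed = 4)
  hoMean <- mean(observedHeterozygosity(tab)$ho)
  he <- mean(expectedHeterozygosity(ft))
  # per-individual H_o averages n*L binomial-ish draws; 3 SE bound
  se <- sqrt(he * (1 - he) / (400 * 18))
  expect_lt(abs(hoMean - he), 3 * se)
})

test_that("forced monogamy makes the pack male sire every pup", {
  cfg <- SimulationConfig(nGroups = 4L, nYears = 3L, sneakerProb = 0,
                          polygynyProb = 0, seed = 9)
  pop <- simulatePopulation(cfg)
  expect_false(any(pop@pups$sneaker_sired))
  expect_false(any(pop@individuals$is_sneaker))
  # every pup's sire is the social male of its pair record
  expect_true(all(pop@pups$sire_id ==
                    sub("^.*:", "", pop@pups$pair_id)))
})

test_that("neutral survival coefficients yield ~50% pup survival", {
  cfg <- SimulationConfig(nGroups = 25L, nYears = 20L,
                          survivalCoefs = c(intercept = 0,
                                            harvest_rate = 0, n_adults = 0,
                                            pair_ho = 0, density = 0,
                                            years_paired = 0),
                          pairRESD = 0, seed = 15)
  pop <- simulatePopulation(cfg)
  n <- nrow(pop@pups)
  expect_gte(n, 2000)
  phat <- mean(pop@pups$survived)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("replicate samples reproduce the error process", {
  cfg <- SimulationConfig(nGroups = 3L, nYears = 2L, seed = 5)
  pop <- simulatePopulation(cfg)

  # noise-free limit: every replicate equals the true genotype
  reps0 <- simulateNoninvasiveSamples(pop, ErrorModel(0, 0, 0), seed = 1)
  tr <- pop@genotypes
  i <- match(reps0$individual_id, tr@ids)
  j <- match(reps0$locus, tr@loci)
  expect_true(all(reps0$allele1 == tr@a1[cbind(i, j)]))
  expect_true(all(reps0$allele2 == tr@a2[cbind(i, j)]))

  # dropout 0.5 on heterozygous loci: ~25% apparent homozygote of each allele
  repsD <- simulateNoninvasiveSamples(pop, ErrorModel(0.5, 0, 0),
                                      replicatesPerSample = 12L, seed = 2)
  i <- match(repsD$individual_id, tr@ids); j <- match(repsD$locus, tr@loci)
  hetTrue <- tr@a1[cbind(i, j)] != tr@a2[cbind(i, j)]
  amp <- repsD$allele1 > 0
  hh <- repsD[hetTrue & amp, ]; ii <- i[hetTrue & amp]; jj <- j[hetTrue & amp]
  apparentHom1 <- hh$allele1 == hh$allele2 & hh$allele1 == tr@a1[cbind(ii, jj)]
  # P(apparent hom of allele1 | amplified) = .25 / (1 - .25)
  expect_lt(abs(mean(apparentHom1) - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / nrow(hh)))

  # dropout 0.01: empirical dropout frequency within binomial CI over >= 1e5
  # heterozygote-locus-replicate allele copies
  cfgBig <- SimulationConfig(nGroups = 10L, nYears = 4L, seed = 6)
  popB <- simulatePopulation(cfgBig)
  repsE <- simulateNoninvasiveSamples(popB, ErrorModel(0.01, 0, 0),
                                      replicatesPerSample = 6L, seed = 3)
  trB <- popB@genotypes
  i <- match(repsE$individual_id, trB@ids); j <- match(repsE$locus, trB@loci)
  hetTrue <- trB@a1[cbind(i, j)] != trB@a2[cbind(i, j)]
  he <- repsE[hetTrue, ]
  expect_gte(2 * nrow(he), 1e5)
  # a dropout shows as an apparent homozygote (one copy lost)
  dropped <- he$allele1 == he$allele2 | he$allele1 == 0
  nCopies <- 2 * nrow(he)
  phat <- sum(dropped + (he$allele1 == 0)) / nCopies   # 0,0 = both dropped
  expect_lt(abs(phat - 0.01), 3 * sqrt(0.01 * 0.99 / nCopies))
})

test_that("harvest tissues conserve the harvest record and match fecal truth", {
  cfg <- SimulationConfig(nGroups = 4L, nYears = 3L, seed = 8)
  pop <- simulatePopulation(cfg)
  ht <- simulateHarvestTissues(pop)
  expect_equal(nIndividuals(ht$genotypes), nrow(pop@harvest))

  # a year with no harvest gives empty output
  noHarv <- SimulationConfig(nGroups = 3L, nYears = 2L,
                             harvestSchedule = c(0, 0),
                             pupHarvestRecovery = 0, seed = 8)
  popN <- simulatePopulation(noHarv)
  expect_equal(nrow(popN@harvest), 0L)
  expect_equal(nIndividuals(simulateHarvestTissues(popN)$genotypes), 0L)

  # harvested + fecal-sampled individual: identical genotype in both outputs
  reps <- simulateNoninvasiveSamples(pop, ErrorModel(0, 0, 0), seed = 2)
  both <- intersect(ht$meta$id, reps$individual_id)
  expect_gt(length(both), 0)
  id1 <- both[1]
  fecal <- reps[reps$individual_id == id1 & reps$replicate == 1 &
                  reps$sample_id == reps$sample_id[reps$individual_id == id1][1], ]
  g <- genotypeOf(ht$genotypes, id1)
  expect_equal(fecal$allele1[match(rownames(g), fecal$locus)],
               unname(g[, 1]))
})

test_that("error model and config validation reject bad rates", {
  expect_error(ErrorModel(dropout = 1.2), "probability")
  expect_error(SimulationConfig(sneakerProb = -0.1), "probabilities")
  expect_error(SimulationConfig(nGroups = 0L), ">=")
})
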