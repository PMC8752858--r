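ft18 <- generateAlleleFrequencies(18, 8, seed = 71)

test_that("sample screening applies the >= 5 amplified loci rule", {
  # 5 loci amplified in the first two PCRs, 13 failed -> keep
  calls <- lapply(1:2, function(r) {
    c(setNames(lapply(1:5, function(l) c(1, 2)), sprintf("L%02d", 1:5)),
      setNames(lapply(6:18, function(l) c(0, 0)), sprintf("L%02d", 6:18)))
  })
  expect_true(screenSample(mkReps(calls)))

  # 4 loci amplified -> discard
  calls4 <- lapply(1:2, function(r) {
    c(setNames(lapply(1:4, function(l) c(1, 2)), sprintf("L%02d", 1:4)),
      setNames(lapply(5:18, function(l) c(0, 0)), sprintf("L%02d", 5:18)))
  })
  expect_false(screenSample(mkReps(calls4)))

  # all 18 amplified -> keep
  callsAll <- lapply(1:2, function(r)
    setNames(lapply(1:18, function(l) c(1, 2)), sprintf("L%02d", 1:18)))
  expect_true(screenSample(mkReps(callsAll)))

  expect_error(screenSample(data.frame()), "malformed")
})

test_that("consensus calls follow the het >= 2 / hom >= 3 PCR rules", {
  # {a, b} in two replicates -> het-confirmed
  g <- callConsensus(mkReps(list(list(L01 = c(1, 3)), list(L01 = c(1, 3)))))
  expect_equal(g@status, "het")
  expect_equal(c(g@a1, g@a2), c(1L, 3L))

  # {a} in three replicates, never a second allele -> hom-confirmed
  g <- callConsensus(mkReps(list(list(L01 = c(2, 2)), list(L01 = c(2, 2)),
                                 list(L01 = c(2, 2)))))
  expect_equal(g@status, "hom")
  expect_equal(c(g@a1, g@a2), c(2L, 2L))

  # {a} in only two replicates -> fails both thresholds, missing
  g <- callConsensus(mkReps(list(list(L01 = c(2, 2)), list(L01 = c(2, 2)))))
  expect_equal(g@status, "missing")
  expect_true(is.na(g@a1))

  # a second allele seen in >= 2 PCRs vetoes the homozygote
  g <- callConsensus(mkReps(list(list(L01 = c(2, 2)), list(L01 = c(2, 2)),
                                 list(L01 = c(2, 2)), list(L01 = c(3, 3)),
                                 list(L01 = c(3, 3)))))
  expect_equal(g@status, "missing")
})

test_that("consensus matches its rule restatement on all replicate patterns", {
  # exhaustive: 3 replicates, every observed pair over alleles {1,2,3} or
  # failure, at one locus (the rule is per-locus)
  obsSpace <- list(NULL, c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (i in seq_along(obsSpace)) for (j in seq_along(obsSpace))
    for (k in seq_along(obsSpace)) {
      pattern <- list(obsSpace[[i]], obsSpace[[j]], obsSpace[[k]])
      calls <- lapply(pattern, function(p)
        list(L01 = if (is.null(p)) c(0, 0) else p))
      got <- callConsensus(mkReps(calls))
      want <- oracleConsensusLocus(pattern)
      expect_equal(got@status, want$status,
                   info = paste("pattern", i, j, k))
      if (want$status != "missing")
        expect_equal(c(got@a1, got@a2), c(want$a, want$b))
    }
})

test_that("consensus is monotone: extra replicates never demote a het call", {
  base <- list(list(L01 = c(1, 2)), list(L01 = c(1, 2)))
  extras <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 3), c(0, 0))
  for (ex in extras) {
    g <- callConsensus(mkReps(c(base, list(list(L01 = ex)))))
    expect_equal(g@status, "het")
  }
})

test_that("dropout-tolerant matching follows the one-locus rule and is
           symmetric", {
  ft <- ft18
  gA <- asConsensus(mkGeno(2, 5, ft), "A")        # het at all loci
  expect_equal(matchGenotypes(gA, gA), "same-individual")

  # (102,102) vs (102,106) pattern at one locus, identical elsewhere
  gB <- gA
  gB@status[4] <- "hom"; gB@a2[4] <- gB@a1[4]
  expect_equal(matchGenotypes(gA, gB), "same-individual")
  expect_equal(matchGenotypes(gB, gA), "same-individual")

  # dropout-compatible mismatches at two loci -> different
  gC <- gB
  gC@status[9] <- "hom"; gC@a2[9] <- gC@a1[9]
  expect_equal(matchGenotypes(gA, gC), "different")

  # dropout-incompatible locus -> different
  gD <- gA
  gD@a1[4] <- 7L; gD@a2[4] <- 8L
  expect_equal(matchGenotypes(gA, gD), "different")

  # too few shared loci -> indeterminate
  gE <- gA
  gE@status[1:10] <- "missing"; gE@a1[1:10] <- NA; gE@a2[1:10] <- NA
  expect_equal(matchGenotypes(gA, gE), "indeterminate")
})

test_that("matching agrees with its restatement on exhaustive small cases", {
  # all status/allele combinations at 2 loci over 3 alleles
  perLocus <- list(
    list(status = "missing", a1 = NA_integer_, a2 = NA_integer_),
    list(status = "hom", a1 = 1L, a2 = 1L),
    list(status = "hom", a1 = 2L, a2 = 2L),
    list(status = "het", a1 = 1L, a2 = 2L),
    list(status = "het", a1 = 1L, a2 = 3L),
    list(status = "het", a1 = 2L, a2 = 3L))
  combos <- expand.grid(l1 = seq_along(perLocus), l2 = seq_along(perLocus))
  build <- function(row) {
    s <- perLocus[c(row[1], row[2])]
    new("ConsensusGenotype", sampleId = "x", loci = c("L01", "L02"),
        status = vapply(s, `[[`, "", "status"),
        a1 = vapply(s, `[[`, 1L, "a1"), a2 = vapply(s, `[[`, 1L, "a2"))
  }
  for (i in seq_len(nrow(combos))) for (j in seq_len(nrow(combos))) {
    g1 <- build(unlist(combos[i, ])); g2 <- build(unlist(combos[j, ]))
    got <- matchGenotypes(g1, g2, minSharedLoci = 1L)
    want <- oracleMatch(
      data.frame(status = g1@status, a1 = g1@a1, a2 = g1@a2),
      data.frame(status = g2@status, a1 = g2@a1, a2 = g2@a2), 1L)
    expect_equal(got, want, info = paste(i, j))
    # symmetry
    expect_equal(got, matchGenotypes(g2, g1, minSharedLoci = 1L))
  }
})

test_that("clustering recovers individuals and is deterministic", {
  ft <- ft18
  # n identical noise-free samples -> one individual with n detections
  g <- mkGeno(1, 4, ft)
  gs <- lapply(1:5, function(i) asConsensus(g, sprintf("s%d", i)))
  cat1 <- clusterSamples(gs)
  expect_equal(nIndividuals(cat1), 1L)
  expect_equal(lengths(cat1@members), 5L)

  # 30 individuals, >= 2 error-free samples each -> exactly 30 entries
  tab <- drawGenotypes(ft, 30, seed = 5)
  gs2 <- unlist(lapply(1:30, function(i) {
    lapply(1:2, function(s)
      asConsensus(genotypeOf(tab, i), sprintf("i%02d_s%d", i, s)))
  }), recursive = FALSE)
  cat2 <- clusterSamples(gs2)
  expect_equal(nIndividuals(cat2), 30L)

  # permuting input order of equal-rank samples leaves the partition fixed
  perm <- sample(seq_along(gs2))
  cat3 <- clusterSamples(gs2[perm])
  part <- function(ct) {
    sets <- lapply(ct@members, sort)
    sets[order(vapply(sets, `[`, "", 1))]
  }
  expect_identical(part(cat2), part(cat3))

  # heterozygote evidence overrides a dropout homozygote in the representative
  full <- asConsensus(mkGeno(2, 6, ft), "full")
  dropped <- full
  dropped@sampleId <- "dropped"
  dropped@status[3] <- "hom"; dropped@a2[3] <- dropped@a1[3]
  cat4 <- clusterSamples(list(dropped, full))
  expect_equal(cat4@representatives[[1]]@status[3], "het")
})

test_that("reliability scores behave like posterior probabilities", {
  ft <- smallFreqs()
  em0 <- ErrorModel(0, 0, 0)
  reps <- mkReps(list(list(L01 = c(1, 2), L02 = c(1, 1)),
                      list(L01 = c(1, 2), L02 = c(1, 1)),
                      list(L01 = c(1, 2), L02 = c(1, 1))))
  g <- callConsensus(reps)
  r0 <- reliabilityScore(g, reps, ft, em0)
  expect_equal(r0$score, 1)
  expect_true(r0$reliable)

  # hand enumeration: homozygote seen in 3 PCRs at dropout 0.01, p(a) = 0.5
  ftH <- AlleleFreqTable(list(L01 = c(`1` = 0.5, `2` = 0.3, `3` = 0.2)))
  emD <- ErrorModel(0.01, 0, 0)
  repsH <- mkReps(list(list(L01 = c(1, 1)), list(L01 = c(1, 1)),
                       list(L01 = c(1, 1))))
  gH <- callConsensus(repsH)
  rH <- reliabilityScore(gH, repsH, ftH, emD)
  want <- oracleReliabilityLocus(c(1, 1), list(c(1, 1), c(1, 1), c(1, 1)),
                                 ftH@freqs$L01, emD)
  expect_equal(unname(rH$perLocus["L01"]), want, tolerance = 1e-12)

  # reliability decreases with the dropout rate for an apparent homozygote
  scores <- vapply(c(0.01, 0.05, 0.2), function(d)
    reliabilityScore(gH, repsH, ftH, ErrorModel(d, 0, 0))$score, 0)
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores >= 0 & scores <= 1))

  # unknown allele -> error
  repsU <- mkReps(list(list(L01 = c(9, 9)), list(L01 = c(9, 9)),
                       list(L01 = c(9, 9))))
  gU <- callConsensus(repsU)
  expect_error(reliabilityScore(gU, repsU, ftH, emD), "unknown allele")
})

test_that("emission probabilities match per-copy event enumeration", {
  labels <- 1:3
  p <- c(`1` = 0.5, `2` = 0.3, `3` = 0.2)
  cases <- expand.grid(d = c(0, 0.01, 0.3), e = c(0, 0.01, 0.1),
                       f = c(0, 0.05))
  genos <- list(c(1L, 1L), c(1L, 2L), c(2L, 3L))
  obsList <- list(NULL, c(1, 1), c(2, 2), c(1, 2), c(1, 3), c(2, 3))
  for (ci in seq_len(nrow(cases))) {
    em <- ErrorModel(cases$d[ci], cases$e[ci], cases$f[ci])
    for (g in genos) {
      tot <- 0
      for (obs in obsList) {
        got <- emissionProb(obs, g, em, k = 3)
        want <- oracleEmission(obs, g, em, labels)
        expect_equal(got, want, tolerance = 1e-12)
        tot <- tot + got
      }
      # obs space is exhaustive up to the missing (3,3) pair
      tot <- tot + emissionProb(c(3, 3), g, em, k = 3)
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})
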