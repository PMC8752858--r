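ftP <- generateAlleleFrequencies(18, 8, seed = 81)
em0 <- ErrorModel(0, 0, 0)
emStd <- ErrorModel(0.01, 0.01, 0)

test_that("trio log-likelihood reduces to Mendelian transmission at zero
           error", {
  ft <- smallFreqs()
  # forced transmission: everyone homozygous for the same allele
  expect_equal(trioLoglik(mkGeno(1, 1, ft), mkGeno(1, 1, ft),
                          mkGeno(1, 1, ft), ft, em0), 0)
  # Mendelian impossibility
  expect_equal(trioLoglik(mkGeno(3, 3, ft), mkGeno(1, 1, ft),
                          mkGeno(2, 2, ft), ft, em0), -Inf)
  # closed-form checks over all offspring genotypes for het x het parents:
  # (1,2) x (1,3) -> offspring {1,1}:1/4 {1,3}:1/4 {1,2}:1/4 {2,3}:1/4
  dam <- mkGeno(1, 2, ft); sire <- mkGeno(1, 3, ft)
  L <- nLoci(ft)
  for (case in list(list(c(1, 1), 0.25), list(c(1, 3), 0.25),
                    list(c(1, 2), 0.25), list(c(2, 3), 0.25),
                    list(c(2, 2), 0), list(c(3, 3), 0))) {
    off <- mkGeno(case[[1]][1], case[[1]][2], ft)
    want <- if (case[[2]] == 0) -Inf else L * log(case[[2]])
    expect_equal(trioLoglik(off, dam, sire, ft, em0), want)
  }
})

test_that("trio likelihood equals exhaustive enumeration with errors", {
  ft1 <- AlleleFreqTable(list(L01 = c(`1` = 0.4, `2` = 0.3, `3` = 0.2,
                                      `4` = 0.1)))
  obsSets <- list(c(1L, 2L), c(2L, 2L), c(3L, 4L), c(1L, 1L))
  g <- function(p) mkGenoList(list(p), ft1)
  for (err in list(emStd, ErrorModel(0.05, 0.02, 0.1))) {
    for (oo in obsSets) for (od in obsSets) for (os in obsSets) {
      got <- trioLoglik(g(oo), g(od), g(os), ft1, err)
      want <- log(oracleTrioLikLocus(oo, od, os, ft1@freqs$L01, err))
      expect_equal(got, want, tolerance = 1e-10)
    }
    # unknown-parent hypotheses against the same oracle
    for (oo in obsSets) for (od in obsSets) {
      gotD <- trioLoglik(g(oo), g(od), NULL, ft1, err)
      wantD <- log(oracleTrioLikLocus(oo, od, NULL, ft1@freqs$L01, err))
      expect_equal(gotD, wantD, tolerance = 1e-10)
      got0 <- trioLoglik(g(oo), NULL, NULL, ft1, err)
      want0 <- log(oracleTrioLikLocus(oo, NULL, NULL, ft1@freqs$L01, err))
      expect_equal(got0, want0, tolerance = 1e-10)
    }
  }
  expect_error(trioLoglik(mkGenoList(list(c(NA, NA)), ft1),
                          g(c(1L, 2L)), g(c(1L, 2L)), ft1, emStd),
               "undefined likelihood")
})

test_that("exclusion counts unexplainable alleles and tolerates two", {
  ft <- ftP
  dam <- mkGeno(1, 2, ft); sire <- mkGeno(3, 4, ft)
  # true trio: 0 mismatches, accept
  off <- mkGeno(1, 3, ft)
  ex <- exclusionCheck(off, dam, sire)
  expect_equal(ex$mismatches, 0L)
  expect_true(ex$accept)

  # two mismatching alleles -> accept at the tolerance boundary
  off2 <- off
  off2[1, ] <- c(5L, 5L)   # neither allele from either parent: min over
                           # assignments = 2 at this locus
  ex2 <- exclusionCheck(off2, dam, sire)
  expect_equal(ex2$mismatches, 2L)
  expect_true(ex2$accept)

  # three mismatching alleles -> reject
  off3 <- off2
  off3[2, ] <- c(5L, 3L)   # 5 unexplainable by dam under best assignment
  ex3 <- exclusionCheck(off3, dam, sire)
  expect_equal(ex3$mismatches, 3L)
  expect_false(ex3$accept)

  # untyped parent locus explains anything
  damNA <- dam; damNA[1, ] <- NA
  exNA <- exclusionCheck(off2, damNA, sire)
  expect_equal(exNA$mismatches, 1L)
})

test_that("likelihood and exclusion agree on noise-free data", {
  ft <- ftP
  set.seed(91)
  tab <- drawGenotypes(ft, 40)
  dams <- setNames(lapply(1:10, function(i) genotypeOf(tab, i)),
                   sprintf("D%02d", 1:10))
  sires <- setNames(lapply(11:20, function(i) genotypeOf(tab, i)),
                    sprintf("S%02d", 11:20))
  for (rep in 1:10) {
    di <- sample(10, 1); si <- sample(10, 1)
    off <- packped:::.mendelianOffspring(dams[[di]], sires[[si]])
    rownames(off) <- loci(ft)
    for (dn in names(dams)) for (sn in names(sires)) {
      ll <- trioLoglik(off, dams[[dn]], sires[[sn]], ft, em0)
      ex <- exclusionCheck(off, dams[[dn]], sires[[sn]], maxMismatch = 0L)
      expect_equal(is.finite(ll), ex$accept)
    }
  }
})

test_that("parentage assignment recovers true parents and sneaker dams", {
  ft <- ftP
  set.seed(101)
  tab <- drawGenotypes(ft, 60)
  dams <- setNames(lapply(1:30, function(i) genotypeOf(tab, i)),
                   sprintf("D%02d", 1:30))
  sires <- setNames(lapply(31:60, function(i) genotypeOf(tab, i)),
                    sprintf("S%02d", 1:30))

  # noise-free trio among 30 x 30 candidates
  off <- packped:::.mendelianOffspring(dams[["D07"]], sires[["S12"]])
  rownames(off) <- loci(ft)
  a <- assignParentage(off, dams, sires, ft, em0)
  expect_equal(a$method, "likelihood")
  expect_equal(c(a$dam, a$sire), c("D07", "S12"))

  # pup of an unsampled sneaker sire: dam assigned, sire unknown
  sneaker <- packped:::.hwGenotype(ft)
  rownames(sneaker) <- loci(ft)
  offS <- packped:::.mendelianOffspring(dams[["D03"]], sneaker)
  rownames(offS) <- loci(ft)
  aS <- assignParentage(offS, dams, sires, ft, emStd)
  expect_equal(aS$dam, "D03")
  expect_true(is.na(aS$sire))

  # empty candidate sets -> unassigned
  aE <- assignParentage(off, list(), list(), ft, emStd)
  expect_equal(aE$method, "unassigned")
})

test_that("parentage recovery exceeds 95% at study error rates and degrades
           monotonically with dropout", {
  ft <- ftP
  set.seed(111)
  tab <- drawGenotypes(ft, 30)
  dams <- setNames(lapply(1:15, function(i) genotypeOf(tab, i)),
                   sprintf("D%02d", 1:15))
  sires <- setNames(lapply(16:30, function(i) genotypeOf(tab, i)),
                    sprintf("S%02d", 1:15))
  nPup <- 24L
  truth <- cbind(sample(15, nPup, replace = TRUE),
                 sample(15, nPup, replace = TRUE))
  offs <- lapply(seq_len(nPup), function(i) {
    g <- packped:::.mendelianOffspring(dams[[truth[i, 1]]],
                                       sires[[truth[i, 2]]])
    rownames(g) <- loci(ft)
    g
  })
  # observed genotypes pass through one noisy PCR read per dropout level
  noisy <- function(g, d) {
    out <- g
    for (l in seq_len(nrow(g))) {
      drop <- runif(2) < d
      if (all(drop)) { out[l, ] <- NA }
      else if (drop[1]) out[l, ] <- c(g[l, 2], g[l, 2])
      else if (drop[2]) out[l, ] <- c(g[l, 1], g[l, 1])
    }
    out
  }
  rates <- c(0, 0.01, 0.05, 0.2)
  rec <- vapply(rates, function(d) {
    hits <- vapply(seq_len(nPup), function(i) {
      obs <- noisy(offs[[i]], d)
      a <- assignParentage(obs, dams, sires, ft,
                           ErrorModel(max(d, 0.01), 0.01, 0))
      identical(c(a$dam, a$sire),
                c(sprintf("D%02d", truth[i, 1]), sprintf("S%02d", truth[i, 2])))
    }, TRUE)
    mean(hits)
  }, 0)
  expect_gte(rec[2], 0.95)          # study error rates
  expect_true(all(diff(rec) <= 0))  # monotone non-increasing in dropout
})

test_that("sneaker genotypes are reconstructed from mother-offspring data", {
  ft <- smallFreqs()
  dam <- mkGenoList(list(c(1, 2), c(1, 2)), ft)

  # offspring (a, c): paternal allele c fixed
  off1 <- mkGenoList(list(c(1, 3), c(1, 1)), ft)
  rs <- reconstructSneaker(dam, list(o1 = off1))
  expect_equal(rs@a1[1], 3L)
  expect_equal(rs@completeness[1], 0.5)

  # offspring (a, b): ambiguous, both maternally explainable
  off2 <- mkGenoList(list(c(1, 2), c(1, 2)), ft)
  rs2 <- reconstructSneaker(dam, list(o1 = off2))
  expect_true(is.na(rs2@a1[1]))
  expect_equal(rs2@candidates[[1]], c(1L, 2L))
  expect_equal(rs2@completeness[1], 0)

  # two offspring (a,c), (b,c): sire carries c
  offA <- mkGenoList(list(c(1, 3), c(1, 1)), ft)
  offB <- mkGenoList(list(c(2, 3), c(1, 2)), ft)
  rs3 <- reconstructSneaker(dam, list(oA = offA, oB = offB))
  expect_equal(rs3@a1[1], 3L)

  # offspring incompatible with the dam at too many alleles -> error
  offBad <- mkGenoList(list(c(3, 3), c(3, 3)), ft)
  damHom <- mkGenoList(list(c(1, 1), c(1, 1)), ft)
  expect_error(reconstructSneaker(damHom, list(o = offBad), maxIncompatible = 1L),
               "inconsistent input")
})

test_that("reconstructed sneakers match simulated truth at fixed loci", {
  cfg <- SimulationConfig(nGroups = 6L, nYears = 4L, sneakerProb = 0.35,
                          meanLitter = 5, seed = 77)
  pop <- simulatePopulation(cfg)
  ind <- pop@individuals
  sneakers <- ind$id[ind$is_sneaker]
  expect_gt(length(sneakers), 2)
  checked <- 0L
  for (sn in sneakers) {
    kids <- ind$id[!is.na(ind$sire_id) & ind$sire_id == sn]
    if (length(kids) < 2) next
    damId <- unique(ind$dam_id[ind$id %in% kids])
    dam <- genotypeOf(pop@genotypes, damId)
    offs <- setNames(lapply(kids, function(k) genotypeOf(pop@genotypes, k)),
                     kids)
    rs <- reconstructSneaker(dam, offs, id = sn)
    truthG <- genotypeOf(pop@genotypes, sn)
    for (li in seq_along(rs@loci)) {
      if (!is.na(rs@a1[li]))
        expect_true(rs@a1[li] %in% truthG[li, ])
      if (!is.na(rs@a2[li]))
        expect_setequal(c(rs@a1[li], rs@a2[li]), unique(truthG[li, ]))
    }
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})
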