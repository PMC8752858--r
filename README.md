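# packped

Pedigree, relatedness and mate-choice inference from noninvasive
microsatellite genotypes in socially structured (pack-living) populations.

## The problem

Monitoring programs for pack-living carnivores often rest on fecal DNA:
scats collected at summer pup-rearing sites are genotyped in replicate PCRs
at a panel of microsatellite loci, harvested animals contribute tissue
genotypes in fall and winter, and everything downstream — who is who, who
bred with whom, whether mates are chosen for genetic diversity, and what
drives pup survival — must be inferred through the noise of allelic dropout
and false alleles. `packped` implements that full inference chain as
tested, reusable R functions, together with a synthetic-data generator that
emulates the sampling and error processes so every stage can be verified
against known truth.

The chain, stage by stage:

1. **Consensus genotyping** — screen samples (≥ 5 loci amplifying in the
   first two PCRs), confirm heterozygotes seen together in ≥ 2 PCRs and
   homozygotes seen in ≥ 3, and score single-sample genotypes with a
   Bayesian accuracy check against a 0.95 threshold
   (`screenSample()`, `callConsensus()`, `reliabilityScore()`).
2. **Individual identification** — merge samples whose genotypes mismatch
   only by allelic dropout at ≤ 1 locus into unique individuals
   (`matchGenotypes()`, `clusterSamples()`).
3. **Parentage** — per-offspring trio maximum likelihood under an explicit
   dropout/false-allele emission model (rates 0.01/0.01), with a
   two-allele-mismatch exclusion fallback and reconstruction of unsampled
   "sneaker" sires from mother–offspring genotypes
   (`trioLoglik()`, `assignParentage()`, `reconstructSneaker()`).
4. **Relatedness** — symmetrized Queller–Goodnight moment estimates and
   dyadic maximum likelihood over IBD coefficients
   (r = k2 + k1/2), plus the random-mating resampling null for mated-pair
   relatedness (`qgRelatedness()`, `mlRelatedness()`, `randomMatingNull()`).
5. **Population statistics** — observed heterozygosity, yearly allele
   frequencies, genotype-recapture harvest rates, pair-bond histories and
   apparent pup survival at 15 months (`observedHeterozygosity()`,
   `harvestRate()`, `buildPairHistories()`, `apparentSurvival()`).
6. **Models** — z-scored fixed and mixed-effects (pair random intercept,
   adaptive Gauss–Hermite quadrature) logistic regressions for mate choice
   and pup survival, AIC comparisons, Wald tests, and the
   sneaker-vs-mated-male t test (`mateChoiceAnalysis()`,
   `pupSurvivalAnalysis()`, `twoSampleT()`).

See `vignettes/packped-methods.Rmd` for the models, assumptions, defaults
and design decisions.

## Worked example

```r
library(packped)

# a small synthetic population with known pedigree
cfg <- SimulationConfig(nGroups = 5L, nYears = 4L, seed = 42)
pop <- simulatePopulation(cfg)
pop
#> TruePopulation: 88 individuals (3 sneakers), 5 packs x 4 years, 72 pups, 21 harvest records

# noninvasive sampling at the working error rates, then identification
reps <- simulateNoninvasiveSamples(pop, ErrorModel(dropout = 0.01, falseAllele = 0.01), seed = 1)
catl <- clusterSamples(genotypeSamples(reps)$genotypes)
catl
#> IndividualCatalog: 85 individuals from 322 samples (detections 2-8)
length(unique(reps$individual_id))   # truth: 85 individuals were sampled
#> [1] 85

# the random-mating null at study scale: unrelated pools average r = 0
ft <- generateAlleleFrequencies(L = 18, k = 8, seed = 7)
males <- drawGenotypes(ft, 151, seed = 1); females <- drawGenotypes(ft, 167, seed = 2)
randomMatingNull(males, females, nPairs = 151, nIter = 1000, seed = 3)
#> NullDistribution (qg): 1000 iterations x 151 pairs
#>   mean -0.0042, median -0.0042, 95% interval [-0.0217, 0.0139]

# parameter recovery: cohorts of ~357 pups in ~83 pair-years simulated from
# known standardized survival coefficients, refit 50 times
est <- survivalRecoveryHarness(nReplicates = 50, seed = 1)
round(colMeans(est), 3)
#>    intercept harvest_rate     n_adults      pair_ho      density years_paired
#>        0.025       -0.562        0.221       -0.127       -0.168        0.268
```

The catalog size matching the number of sampled individuals shows the
dropout-tolerant identification working at realistic error rates; the null
mean near zero is the reference against which observed mated-pair
relatedness is judged; and the recovered coefficients sitting on the
generating values (−0.56 for harvest rate, 0.28 for years paired, …) show
the survival-model pipeline — covariate z-scoring included — is unbiased at
study scale.

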