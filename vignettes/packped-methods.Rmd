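---
title: "Methods: from replicate PCRs to pedigrees, relatedness nulls and survival models"
author: "packped"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from replicate PCRs to pedigrees, relatedness nulls and survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(packped)
```

# Scope

`packped` implements the inference chain used in noninvasive genetic
monitoring of pack-living carnivores: fecal samples genotyped in replicate
PCRs at codominant microsatellite loci are turned into consensus genotypes,
merged into unique individuals, assembled into pedigrees, and summarized as
relatedness patterns, pair-bond histories, genotype-recapture harvest rates,
apparent pup survival, and the logistic-regression models that act on those
summaries. A configurable simulator generates populations with known
pedigree, sampling and error processes so that every stage can be validated
against truth. This vignette documents the models, the defaults, and the
numerical and design choices.

# The PCR error model

All genotype-level likelihoods share one emission model for a single PCR
amplification of one locus, acting on a true diploid genotype $(u, v)$:

* with probability $f$ the locus fails to amplify entirely (default 0);
* otherwise each allele copy independently *drops out* with probability $d$;
* each surviving copy is mis-read as one of the other $k - 1$ alleles of the
  locus with probability $e$, uniformly.

A replicate retaining two calls shows the unordered pair; a replicate
retaining one distinct call is an *apparent homozygote* — the signature of
allelic dropout; retaining none is a failure. The working rates are
$d = e = 0.01$ per copy per PCR, the standard assumption for this kind of
fecal-DNA data, exposed through `ErrorModel()`. `emissionProb()` is the
closed form; the test suite checks it against exhaustive enumeration of the
per-copy events and verifies that probabilities over the observation space
sum to one.

# Consensus genotyping and individual identification

Samples are screened on their first two PCRs: fewer than 5 amplifying loci
discards the sample (`screenSample()`). Consensus calls per locus
(`callConsensus()`) require two independent PCRs showing a heterozygote's
two alleles together, or three PCRs showing a single allele for a
homozygote. Two resolution rules are ours, because the screening rules alone
do not determine them: when several heterozygote pairs reach support, the
best-supported pair wins with ties broken toward the smallest alleles; and a
second allele seen in two or more PCRs vetoes a homozygote call. Both are
deterministic and exercised by an exhaustive small-case enumeration (all
3-replicate observation patterns over 3 alleles).

Two consensus genotypes are the *same individual* (`matchGenotypes()`) when
they agree at every jointly confirmed locus except at most one locus that is
dropout-compatible: one genotype homozygous for an allele contained in the
other's heterozygote. Two dropout-compatible mismatches, or any
dropout-incompatible locus, separate the genotypes. Because this relation is
not transitive, clustering (`clusterSamples()`) is defined procedurally:
samples are processed by decreasing confirmed-locus count (ties by sample
id) and join the first existing entry they match, so complete genotypes seed
the clusters and the partition is reproducible under permutation of
equal-rank input. The representative genotype is the per-locus consensus of
members, with heterozygote evidence overriding dropout homozygotes — our
documented resolution of a question the matching rule leaves open. The
minimum overlap to compare two partial genotypes defaults to 10 of 18 loci,
balancing discriminating power against data loss; it is configurable
everywhere it appears.

Single-sample genotypes are scored by `reliabilityScore()`: per confirmed
locus, the posterior probability that the consensus call is the true
genotype, enumerating all candidate genotypes under Hardy–Weinberg priors
and the emission model; the product over loci is compared with the 0.95
accuracy threshold. This is a simplified Bayesian counterpart of the
published single-sample accuracy test, whose internal algorithm is not
described in the literature we reimplement from.

# Parentage

`trioLoglik()` computes $\log P(\text{obs offspring} \mid \text{obs dam},
\text{obs sire})$ per locus, integrating over the true genotypes of all
three individuals: Hardy–Weinberg priors on parents, Mendelian transmission,
and the emission model applied to each observed (consensus) genotype as a
single observation. Because transmission depends on a parent only through
the allele it passes, the parental sums collapse into per-parent
transmission marginals — an exact factorization that keeps candidate scans
$O(k^2)$ per locus; the test suite verifies exact agreement (to $10^{-10}$)
with brute-force enumeration over genotype triples at a 4-allele locus.
An unknown parent is integrated over Hardy–Weinberg genotype frequencies.
Loci missing in any named member are skipped.

`assignParentage()` evaluates all dam × sire pairs plus dam-only, sire-only
and no-parent hypotheses and accepts the maximum-likelihood hypothesis when
it leads the runner-up by $\Delta\log L \ge 3$ (about LOD 1.3). The
published analyses state no acceptance criterion, so this gate is our
documented stand-in, chosen to be conservative at 18 loci and configurable.
When the gate is not met, the top-ranked full pair is accepted by exclusion
(`exclusionCheck()`) if its mismatch count — the per-locus minimum number of
offspring alleles unexplainable by any transmission assignment, summed over
loci — is at most 2 alleles across the 18 loci, the published dropout
tolerance. Unsampled "sneaker" sires are reconstructed from mother–offspring
genotypes (`reconstructSneaker()`): per locus, offspring alleles the dam
cannot have transmitted are obligate paternal alleles, ambiguous cases
contribute candidate sets intersected across full siblings. This per-family
reconstruction replaces the cited full-likelihood sibship program: it is a
deliberate simplification that is desk-scale, transparent, and sufficient
for breeder identity, sneaker counts and pair histories; it does not perform
joint sibship partitioning across families.

# Relatedness and the random-mating null

Two estimators are provided. The symmetrized Queller–Goodnight moment
estimator (`qgRelatedness()`) sums numerators and denominators over both
reference directions and loci; it is unbiased under random mating, which
makes the null's "mean 0.00" well-defined, so it is the default inside the
null. The dyadic maximum-likelihood estimator (`mlRelatedness()`) maximizes
$\sum_\ell \log(k_0 P_0 + k_1 P_1 + k_2 P_2)$ over the non-inbred
IBD-coefficient simplex and reports $r = k_2 + k_1/2$. The published
workflow uses a triadic ML estimator; the dyadic form is our documented
simplification — the quantities the analysis consumes (medians, ranges,
calibration of first-degree pairs) do not depend on the triadic refinement,
and the estimator name is recorded on every estimate. Inbred (Jacquard)
modes are out of scope because founders are outbred by design.

Numerically, each locus likelihood is linear in $(k_0, k_1, k_2)$, so the
log-likelihood is concave on the simplex; EM (to a $10^{-12}$ log-likelihood
tolerance) finds the global maximum but approaches boundaries only
asymptotically, so the EM point is compared against the exactly maximized
simplex edges (Brent's method) and vertices, and the best wins. A dense-grid
fallback guards degenerate inputs. Agreement with a dense simplex-grid
maximizer within 0.02 in $r$ is asserted in the tests. Genotyping error can
optionally be folded into the per-locus mode probabilities by summing over
true genotype pairs; it is off by default because error is handled upstream
at consensus calling.

`randomMatingNull()` draws `nPairs` male–female pairs uniformly with
replacement per iteration and records iteration means of pair relatedness;
the study-scale configuration is 151 males, 167 females, 151 pairs, and
1,000–10,000 iterations. Pool allele frequencies are estimated from the
pools themselves unless supplied.

# Population statistics

Observed heterozygosity is per individual (heterozygous / typed loci);
population summaries average over individuals, not loci — the reported
dispersion across individuals supports that reading, and the alternative is
one line of code away. Harvest rate divides summer-detected genotypes
re-detected among harvest tissues by the summer catalog size, using the same
dropout-tolerant matcher, which makes the rate invariant to out-of-area
tissues. Pair-bond duration equals 1 in a pair's first breeding year and
increments per breeding year; the counter *continues* across gap years (the
published definition fixes only the start; resetting is a configuration of
`buildPairHistories()` input rather than a second code path). Apparent
survival labels a pup alive if re-detected the following summer; detected
only in first-year harvest, or not at all, means dead. The harvest-rate
covariate attached to a pup cohort is the rate during the cohort's first
year of life — harvest occurring between the birth summer and the next
summer's resampling — which reconciles the two phrasings the source analyses
use for the same lag.

# Regression models

Covariates are z-scored (sample SD, $n-1$) for coefficient comparability;
`zTransform()` returns the transform constants for back-mapping.
`fitLogistic()` delegates to the standard IRLS GLM fitter and is
cross-checked against an independently hand-rolled IRLS oracle to $10^{-6}$;
Wald $p$-values are asymptotic, AIC is $2k - 2\log L$, and separation is
flagged rather than silently reported. `fitMixedLogistic()` uses adaptive
Gauss–Hermite quadrature with 15 nodes for the pair-level random intercept
(the tests show 15 vs 40 nodes agree in log-likelihood to $10^{-4}$);
$p$-values are asymptotic Wald $z$ with no small-sample correction, matching
the published analysis choice. The mate-choice model regresses an indicator
(male heterozygosity above the reference-pool mean) on continuous female
heterozygosity; the reference pool is all potential breeders (≥ 2 years old)
by default, configurable to breeding males only, since the source does not
name the pool. The sneaker-vs-mated-male comparison uses Welch's $t$ by
default (the samples differ in size and spread); the pooled variant is
available because the published variant is unstated.

# The synthetic-data generator

`simulatePopulation()` emulates the monitoring design: 16 packs followed for
10 years; 18 loci with ~8 alleles whose frequencies come from a symmetric
Dirichlet; founders in Hardy–Weinberg proportions; one breeding pair per
pack with turnover on death (replacements drawn from unrelated resident
adults or, with probability 0.5, immigrants carrying fresh genotypes — a
stand-in for the metapopulation exchange such populations sit in); litters
of mean size 4.3 (≈ 357 pups per 83 pair-years at study scale); sneaker
sires on 12% of breeding events (≈ 10 sneakers per 83 events); polygyny in
8% of pack-years; an annual harvest schedule with no harvest in year 1, a
brief opening, a pause, and sustained harvest thereafter (default rates
0.10/0.18); and summer fecal sampling in which each detected pack member
contributes 2 samples of 4 replicate PCRs. Pup survival to 15 months is
drawn from the logistic model with the published fixed-effects coefficients
as generating truth and a pair-level random intercept of SD 0.85. Litter
size, turnover and dispersal distributions are configuration knobs, not
claims of fidelity — the sources do not state them.

One sequencing constraint is worth flagging: the analysis z-scores
covariates on the realized data table, but a sequential simulation cannot
standardize against a table that does not exist yet, so the generator
standardizes against fixed reference moments (configured per covariate).
The parameter-recovery harness (`simulatePupCohort()`,
`survivalRecoveryHarness()`) instead z-scores each realized table exactly as
the analysis does, which is why acceptance-grade coefficient recovery runs
through the harness while the full generator serves the identification,
pedigree and survival-labelling checks.

What the generator does *not* emulate: spatial structure and territory
geometry, scat deposition and detection ecology, age-structured
reproduction beyond the pup/yearling/adult distinction, inbred matings
(founders are outbred and breeder replacement avoids close kin), locus
linkage, null alleles and stutter artifacts. Tests passing on synthetic
data therefore demonstrate the correctness of the inference chain under its
stated error model, not robustness to every artifact of real fragment data.

# Problem sizes and determinism

The test and acceptance configurations are sized for a desk run: 200
simulate-and-refit replicates for coefficient recovery (~83 pair-years and
~357 pups each), 1,000 null iterations of 151 pairs, 500 first-degree dyads
for ML calibration, and zero-error identity pipelines of 5 packs × 4 years.
Every stochastic entry point takes a seed; identical seeds give
bit-identical output (simulation state is restored afterwards, so seeded
calls do not perturb the caller's RNG stream). Known limitations: the
maximum-likelihood random-intercept SD is biased low at ~4 pups per pair
(a generic property of ML variance components with small clusters, visible
in the recovery harness); likelihood comparisons across hypotheses use each
hypothesis's jointly typed loci, so near-complete genotypes are assumed for
candidate scans; and the exclusion fallback examines the top-likelihood
pair only.
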