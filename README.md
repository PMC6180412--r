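# boaGBLUP

Breed-of-origin aware genomic evaluation for three-way crossbred
populations.

In commercial pig production a terminal crossbred animal is a mosaic of
chromosome segments from three purebred lines: a sire line S and two
dam lines LR and LW. The additive effect of a SNP allele on crossbred
performance can depend on the line it was inherited from — the allele
may tag different causal variants, the causal variant may segregate at
very different frequencies across lines, or its epistatic context may
differ. `boaGBLUP` implements the full analysis chain for studying this
question on phased genotype data, together with a synthetic-data
generator that provides complete ground truth for validation:

1. **Breed-of-origin assignment** (`buildHaplotypeLibrary()`,
   `assignBreedOfOrigin()`, `applyAssignmentFilters()`): each crossbred
   allele is voted on by up to 18 haplotype-window views against a
   purebred library (80% purity rule), with the published 90%/90%/5-copy
   quality filters.
2. **Partial genomic relationship matrices**
   (`buildPartialGRMSet()`): VanRaden method-1 matrices per
   breed-of-origin,

   `G_bb = (M^b − 2p^b)(M^b − 2p^b)' / F_b`,  haploid-centred
   crossbred blocks, missing origins contributing exactly zero, and
   `F_b = Σ_j 2 p_j^b (1 − p_j^b)`.
3. **The BOA model** (`boaModelData()`, `solveBoaMme()`,
   `remlEstimate()`): a 4-trait animal model (S, LR, LW purebred traits
   + crossbred trait) where line b's purebred and origin-b crossbred
   effects covary through `Σ_b ⊗ G^(b)`, with litter and
   population-specific residuals; dense Henderson equations and
   average-information REML with delta-method standard errors for
   `h²` and the purebred–crossbred correlation `r_pc`.
4. **Back-solved SNP effects** (`snpEffectsFromFit()`):
   `α̂ = F⁻¹ W' G⁻¹ â` per origin and performance type, with exact
   GEBV reconstruction on unblended systems.
5. **LD-block variance mapping** (`segmentLdBlocks()`,
   `blockVarianceExplained()`, `matchTopRegions()`): Fisher's exact
   test on gametic 2×2 counts (P < 0.01) defines block breakpoints;
   each block's share of genetic variance is
   `Var(Σ z_j α̂_j)/σ²_a × (x̄_n/n_i) × 100`; top-10 blocks are matched
   across origins within 1 Mb.
6. **Focal-locus dissection** (`focalLdBlock()`,
   `enumerateBlockHaplotypes()`, `weightedAlleleMeans()`,
   `fitFocalSnpModel()`): the haplotype block co-segregating with a
   known causal mutation, per-origin haplotype effects, and
   origin-specific allele-substitution effects from a pedigree-based
   fixed-regression mixed model.

`runPipeline()` chains all stages deterministically from one seed;
`simulateStudy()` / `buildFocalScenario()` generate the synthetic
three-way cross study (diverged lines with realistic within-line LD,
gene-dropped genomes with true origin labels, phenotypes whose
generating variance components are the exact REML estimands).

## Worked example

```r
library(boaGBLUP)

sim  <- simulateStudy(seed = 7, nFounders = c(S = 20, LR = 20, LW = 20),
                      nPurebred = c(S = 80, LR = 80, LW = 80), nF1 = 40,
                      nCrossbred = 150, nChrom = 2, snpsPerChrom = 200)
grms <- buildPartialGRMSet(sim$purebreds, sim$cb, sim$cbOrigins)
grms
#> PartialGRMSet over 400 SNPs
#>   G^(S): 100 purebred + 150 crossbred animals, F = 124.93
#>   G^(LR): 100 purebred + 150 crossbred animals, F = 118.82
#>   G^(LW): 100 purebred + 150 crossbred animals, F = 132.49

md  <- boaModelData(sim$records, grms, trait = "y")
fit <- solveBoaMme(md, varianceTargets())
fit
#> BoaFit: BOA 4-trait GBLUP
#>   S: var(PB) = 0.3100, var(CB) = 0.2050, cov = 0.2017
#>   LR: var(PB) = 0.3300, var(CB) = 0.1025, cov = 0.1306
#>   LW: var(PB) = 0.3400, var(CB) = 0.1025, cov = 0.1661

head(fit@gebv$crossbred[, "total"])  # crossbred GEBVs, sum of 3 partials
eff <- snpEffectsFromFit(fit, grms)  # per SNP x origin x performance
```

The variance components shown are the ones supplied to the solver
(generator targets); `remlEstimate(md)` estimates them from the data
instead. In this fitted example the crossbred total GEBVs correlate
about 0.72 with the simulated true genetic values, and the purebred
back-solve reconstructs the GEBVs to ~1e-14 (see
`attr(eff, "reconstruction")`).

A full deterministic run of every stage, including the focal-mutation
analysis:

```r
report <- runPipeline(runConfig(seed = 2, focalScenario = TRUE))
report$assignment$accuracy        # ~0.998 vs simulation truth
report$focal$substitution         # b_S, b_LR, b_LW with SEs
writeReport(report, "results/focal-run")
```

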