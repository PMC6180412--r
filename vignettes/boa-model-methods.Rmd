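---
title: "Breed-of-origin aware genomic prediction: models and methods"
author: "boaGBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed-of-origin aware genomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boaGBLUP)
```

## The problem

In a terminal three-way pig cross — an S-line sire mated to an F1
(Landrace-type LR x Large-White-type LW) dam — every crossbred animal is
a mosaic of chromosome segments inherited from three distinct purebred
lines. The additive effect of a marker allele on crossbred performance
may depend on which line it was inherited from: the allele can tag
different causal variants in different ancestral backgrounds, the causal
variant itself can segregate at very different frequencies across lines,
and epistatic context differs between lines. `boaGBLUP` implements the
complete analysis chain needed to study this question: tracing the
breed-of-origin of crossbred alleles, fitting a GBLUP model whose
genetic covariance is split into three breed-specific partial
relationship matrices (the BOA model), back-solving SNP-allele effects
per breed-of-origin, mapping the genetic variance onto linkage
disequilibrium (LD) blocks, and dissecting a known large-effect locus
through its haplotypes. A fully labelled synthetic-data generator
provides the ground truth against which every stage is validated.

## The synthetic study

`simulateStudy()` generates the study design all tests and examples run
on. Its defaults are fixed study conditions, not tuning knobs:

* **Three diverged lines.** Pairwise Weir–Cockerham $F_{ST}$ targets of
  0.17 (S, LR), 0.12 (S, LW) and 0.14 (LR, LW) — the differentiation of
  distantly related commercial lines. A star-shaped Balding–Nichols
  model is solved for per-line divergence levels
  ($F_S = 0.15$, $F_{LR} = 0.19$, $F_{LW} = 0.09$ before the
  haplotype-pool correction below), since the expected pairwise
  $F_{ST}$ is the mean of the two per-line levels.
* **Within-line LD.** Each line carries a pool of 20 ancestral
  haplotypes; founder gametes are recombinant mosaics of the pool with
  geometric segment lengths of mean 30 SNPs. This mimics the small
  long-term effective size of breeding lines and gives adjacent-SNP
  $r^2$ of roughly $1/20$ with distance decay. Because pool sampling is
  itself drift of about $1/20$, the Balding–Nichols levels are
  recalibrated so the realised $F_{ST}$ stays on target. Setting
  `ld = NULL` recovers a pure frequency model without LD (used for the
  no-divergence sanity check, where $F_{ST}$ must vanish).
* **Pedigree.** 40 founders per line (80 in the focal scenario), 300
  purebred offspring per line in full-sib litters of 6, 120 F1 dams
  bred from LR sires and LW dams, and 600 terminal crossbreds from S
  sires and F1 dams. Gene dropping uses 1 cM/Mb, Poisson crossover
  counts and no interference (Haldane), with the true breed-of-origin
  of every allele carried along.
* **Marker panel.** 2,000 SNPs on four 100-Mb chromosomes, evenly
  spaced. Desk scale: large enough that every estimator behaves, small
  enough that the whole test suite runs in minutes.
* **Phenotypes.** Per line b the simulator draws per-SNP bivariate
  (purebred, crossbred) effects with covariance
  $\Sigma_b / F_b$, where $F_b = \sum_j 2p_j^b(1-p_j^b)$ and
  $\Sigma_b$ holds the target variance components. Because breeding
  values are then exactly $\mathbf W \boldsymbol\alpha$ with
  $\mathrm{Var}(\mathbf a) = \Sigma_b \otimes \mathbf G^{(b)}$, the
  generator's inputs are the *exact estimands* of the REML fit — the
  recovery tests compare estimates against the numbers the generator
  consumed, not against approximations. Defaults follow back fat
  thickness: purebred heritabilities 0.31/0.33/0.34, crossbred
  heritability 0.41, purebred–crossbred correlations 0.80/0.71/0.89,
  common-litter ratio 0.10, phenotypic variance 1. The crossbred
  genetic variance is split 1/2 : 1/4 : 1/4 over S, LR and LW origins,
  mirroring genome shares in the cross. Fixed effects are farm-by-sex
  classes plus an on-test body-weight covariate, a desk-scale analogue
  of the farm-by-breed-by-sex structures of combined
  crossbred–purebred recording.

What the generator does **not** emulate: genotyping and imputation
error, phasing error (data are truth-phased), selection, non-additive
gene action, and genuine population history beyond the two-level
drift/pool model. Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to those
real-data complications.

## Breed-of-origin assignment

Crossbred alleles are assigned an origin from a purebred haplotype
library. Every chromosome is tiled with cores of nine lengths, each
anchored both at the chromosome start and shifted by half a core, so
every allele appears in 18 haplotype views. A window haplotype is
assigned to a line when at least 80% of its purebred copies come from
that line. Each crossbred allele then collects one vote per matching
assigned view; votes incompatible with the cross design (non-S paternal,
S maternal) are discarded and the majority decides, with ties and empty
vote sets left missing. The vote-aggregation rule is the package's own
choice of a simple, auditable policy; published pipelines defer to more
elaborate zygosity-aware rules, and the majority rule reproduces their
published completeness on the synthetic data (more than 90% of alleles
assigned, over 95% correct among assigned).

Quality filters follow the published thresholds and order: SNPs with
under 90% per-side assignment are dropped, then animals with under 90%
of their allele slots assigned (interpreted per allele slot, not per
bp), then SNPs whose counted allele appears fewer than 5 times within
any origin. Raising any threshold can only shrink the kept sets, and
all populations are analysed with one common SNP set.

The default core lengths for a 41k-style dense panel would be 25–400
SNPs; the desk-scale panel uses 10–150 so that cores cover comparable
genetic lengths at the lower marker density.

## Partial relationship matrices

For origin b with counted-allele frequency vector $\mathbf p^b$
(counted over purebred-b alleles plus crossbred alleles assigned origin
b) the blocks are VanRaden method 1:

$$
\mathbf G_{bb} = \frac{\mathbf W^b \mathbf W^{b\prime}}{F_b},\qquad
\mathbf G_{b,CB} = \frac{\mathbf W^b \mathbf W^{CB,b\prime}}{F_b},\qquad
\mathbf G_{CB,CB}^{(b)} = \frac{\mathbf W^{CB,b} \mathbf W^{CB,b\prime}}{F_b},
$$

with $\mathbf W^b$ the purebred dosages centred on $2\mathbf p^b$ and
$\mathbf W^{CB,b}$ the haploid origin-b allele content of crossbreds
centred on $\mathbf p^b$ — alleles without an assigned origin
contribute exactly zero. The diploid/haploid centring asymmetry is kept
exactly as the model defines it, and the zero convention biases
crossbred diagonals slightly downward; no correction is applied, the
behaviour is documented and tested instead. All three matrices share
one SNP set and one scaling $F_b$ per origin.

Numerics: partial matrices are rank-deficient whenever animals
duplicate or the SNP count is small, so the solver blends
$\mathbf G' = (1-\lambda)\mathbf G + \lambda \bar d \mathbf I$ with
$\lambda = 10^{-6}$ by default ($\bar d$ = mean diagonal, keeping the
trace); $\lambda = 0$ leaves the matrix untouched for exactness tests.

## The BOA mixed model and REML

Purebred performance of each line and crossbred performance are treated
as four traits on disjoint animals. For line b the purebred trait and
the origin-b partial crossbred trait share the genetic covariance
$\Sigma_b \otimes \mathbf G^{(b)}$, where $\Sigma_b$ is a 2x2 matrix
(variances and the covariance that defines $r_{pc}$); different lines'
effects are uncorrelated, litter effects are i.i.d. per record
population and residuals are population-specific. Crossbred total
breeding values are the sum of the three partials by construction.

`solveBoaMme()` builds Henderson's mixed-model equations and solves
them densely; `remlEstimate()` maximises the restricted likelihood by
average information with step halving whenever a step would decrease
the likelihood, variance floors at $10^{-8}\,\mathrm{var}(y)$ and
positive-semidefinite projection of each $\Sigma_b$ (the covariance is
shrunk to 0.999 of its bound). Standard errors come from the inverse
average-information matrix, and derived parameters
($h^2_{PB}$, $h^2_{CB}$, $r_{pc}$) carry delta-method standard errors.
The convergence criterion is a relative parameter change below `tol`
(default $10^{-8}$; the large simulation studies use $10^{-6}$, which
changes estimates well below their standard errors while keeping 20
replicate fits within minutes). Residual covariances between purebred
and crossbred traits are inestimable (disjoint animals) and fixed at
zero.

Two independent oracles guard this machinery: on instances of up to ~30
animals the MME solution must equal brute-force multivariate-normal
conditioning to $10^{-8}$, and the engine must match both the
closed-form REML solution of the i.i.d. model and an independent
numerical optimiser of the restricted likelihood.

## Back-solving SNP effects

GEBVs convert to allele effects through
$\hat{\boldsymbol\alpha} = F^{-1}\mathbf W' \mathbf G^{-1}\hat{\mathbf a}$,
the minimum-norm solution of
$\hat{\mathbf a} = \mathbf W\hat{\boldsymbol\alpha}$. With an unblended
full-rank $\mathbf G$ the reconstruction
$\mathbf W\hat{\boldsymbol\alpha}$ is exact; blending breaks the
identity by design and the reconstruction error is always computed and
reported rather than hidden. Singular matrices (detected by reciprocal
condition below $10^{-10}$) fall back to the Moore–Penrose inverse.
Purebred-performance effects invert the purebred block of
$\mathbf G^{(b)}$ and crossbred-performance effects the
crossbred block with the origin-content matrix; a flag switches to the
full assembled matrix, since the model description leaves the choice
open.

## LD blocks and variance decomposition

Within one breed-of-origin, gametic 2x2 tables of consecutive kept SNPs
are tested with a two-sided Fisher's exact test (sum of hypergeometric
point probabilities not exceeding the observed one, with the customary
$1+10^{-7}$ tie guard); a breakpoint falls wherever the
disequilibrium coefficient $D$ is not significantly different from zero
at raw $P < 0.01$ — deliberately with no multiplicity correction.
Blocks partition the kept SNPs. The percentage of genetic variance of
block i is

$$
\frac{\mathrm{Var}(\sum_{j} z_j \hat\alpha_j)}{\sigma^2_a}\times
\frac{\bar n}{n_i} \times 100,
$$

with $z_j$ the genotypes of all purebred individuals of the block's
breed (the literal convention; a flag allows crossbred origin-coded
genotypes instead), $\bar n$ the mean block size of the scenario and
$\sigma^2_a$ the total genetic variance of that trait/scenario from the
variance-component fit (a flag allows the empirical
$\mathrm{Var}(\mathbf Z\hat{\boldsymbol\alpha})$). Top-10 blocks are
compared across scenarios; two blocks match when they overlap or lie
less than 1 Mb apart on the same chromosome, with ties in the ranking
broken by genomic position.

Block lengths from significance-based segmentation depend on sample
size: with 600 crossbreds the synthetic study yields mean block lengths
around 2–3 SNPs (S longest, LR shortest, matching the lines' LD
ranking), shorter than the 5–7 SNPs reported for populations several
times larger.

## The focal-locus analysis

`buildFocalScenario()` adds one biallelic causal mutation with founder
mutant-allele frequencies 0.85 (S), 0.06 (LR) and 0.39 (LW), an
allele-substitution effect of +0.5 phenotypic SD on the growth trait
that is *identical* across origins, and `on_panel = FALSE` so the panel
sees it only through LD. Under the haplotype-pool model the mutation is
placed on `round(20 p)` ancestral haplotypes, so carriers share
flanking haplotype background — the mechanism that makes a panel tag a
mutation in the first place. Crossbred within-origin frequencies are
emergent (drift through the cross), not targeted; the focal scenario
uses 80 founders per line so the rare LR allele survives the cross at a
stable frequency.

The analysis then mirrors the published MC4R-style workflow: the focal
block collects all same-chromosome SNPs in significant LD with the
mutation per origin (not consecutive-pair segmentation), cross-origin
comparison uses the intersection block; block haplotypes are enumerated
with the focal allele each carries, copies carrying the minority allele
of their haplotype are excluded as presumed genotyping errors; the
effect of a haplotype is the centred sum
$\sum_j (x_j - p_j^b)\hat\alpha_j^b$ of back-solved
crossbred-performance effects (the centring keeps count-weighted means
near zero; an uncentred variant is a flag, as no formula is prescribed);
and frequency-weighted means of the m- and w-carrying classes give the
haplotype-based substitution approximation, reported in the
w-replacing-m direction. The direct estimate regresses fixed-effect
pre-corrected crossbred phenotypes on the three origin-specific centred
mutant-allele contents in a mixed model with litter, a pedigree
relationship matrix and the genetic variance fixed at the BOA-model
value; litter and residual variances are re-estimated. The gamete's
origin over the block is taken as the strict majority of its assigned
labels. Because BLUP shrinks the jointly estimated SNP effects while
the fixed regression does not, the haplotype-based substitution
estimate is expected to keep the sign of the fixed estimate at a much
smaller magnitude — one of the qualitative checks of the acceptance
suite, alongside equality of the fixed estimates across origins within
confidence intervals and the LR origin showing both the smallest
explained variance around the mutation and the tightest spread of
haplotype effects (its mutant allele is nearly absent).

## Design decisions worth knowing

* S4 classes with validity checks hold the central objects
  (`PhasedGenotypes`, `OriginMatrix`, `PartialGRMSet`, `BoaFit`);
  lighter tabular results stay data frames.
* One master seed drives every stage through `deriveSeeds()`; the full
  pipeline is byte-identical under a fixed config.
* The F1 dams are bred from founder and purebred-offspring parents of
  the two dam lines, so rare alleles have a realistic chance to reach
  the cross.
* `fisherExact2x2()` is implemented from the hypergeometric density and
  is tested for exact agreement with full enumeration over all tables
  with totals up to 30, and with `stats::fisher.test()`.
* The tabular pedigree relationship matrix is tested against an
  exhaustive enumeration of all transmission configurations on
  pedigrees of up to 8 animals (exact, including inbred diagonals).
* Degenerate inputs: monomorphic frequency models are rejected;
  zero-margin contingency tables return p = 1; an origin absent from
  the crossbreds makes its substitution coefficient `NA` rather than a
  silent zero; all-SNPs-removed filter configurations raise an error.

## Problem sizes

The packaged analyses run at: 2,000 SNPs / 1,500 records for REML
(20 replicates), 2,001 SNPs with 80 founders per line for the focal
scenario, toys of 20–40 animals for all exactness oracles, and 10,000
SNPs for the $F_{ST}$ calibration checks. These sizes were chosen so
each statistical property is measurable with comfortable margins while
the whole validation suite stays in the minutes range on one core.

## Limitations

Dense linear algebra throughout: the fit is meant for thousands, not
hundreds of thousands, of animals. The BOA assignment implements a
single published filter convention and a majority vote, not the full
zygosity-aware decision tables of dedicated phasing pipelines. REML
standard errors are asymptotic; near variance boundaries they are
optimistic. The generator's LD model is a two-parameter caricature of
breed history — adequate for validating estimators, not for studying
fine-scale LD phenomena.
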