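#' Simulate a complete three-way crossbred study
#'
#' End-to-end generator of the study design the package targets: three
#' diverged purebred lines genotyped on a medium-density panel, a
#' terminal S x (LR x LW) cross, gene-dropped phased genomes with true
#' breed-of-origin labels, and phenotypes under breed-of-origin specific
#' additive effects with common-litter and residual noise. Defaults are
#' desk-scale study conditions: 40 founders and 300 purebred offspring
#' per line, 120 F1 dams, 600 crossbreds, 2,000 panel SNPs on four
#' 100-Mb chromosomes (1 cM/Mb), pairwise F_ST targets 0.17/0.12/0.14,
#' and back-fat-like variance components (see [varianceTargets()]).
#'
#' @param seed integer master seed; all stages derive their own seeds
#'   from it.
#' @param nFounders,nPurebred,nF1,nCrossbred,litterSize pedigree design.
#' @param nChrom,snpsPerChrom,chromLengthMb marker panel design.
#' @param fst pairwise F_ST target matrix.
#' @param ld within-breed LD model of the founder lines (see
#'   [simulateFounderBreeds()]).
#' @param vc variance-component targets.
#' @param trait phenotype column name.
#' @param focal optional list describing a focal mutation:
#'   `freqs` (named founder allele frequencies of the mutant allele),
#'   `effect` (substitution effect, trait units), `chrom`, `posMb`,
#'   `onPanel` (default `FALSE`).
#' @param nQtl causal SNPs per breed (default: all panel SNPs).
#' @param cMperMb recombination map density.
#' @return list with `map`, `ped`, `geno`, `origins` (truth),
#'   `records`, `purebreds` (named list of per-breed purebred
#'   [PhasedGenotypes-class], founders included), `cb` (crossbred
#'   genotypes), `cbOrigins` (truth origins of crossbreds), `founders`,
#'   and the `seed`.
#' @export
simulateStudy <- function(seed = 1,
                          nFounders = c(S = 40, LR = 40, LW = 40),
                          nPurebred = c(S = 300, LR = 300, LW = 300),
                          nF1 = 120, nCrossbred = 600, litterSize = 6,
                          nChrom = 4, snpsPerChrom = 500,
                          chromLengthMb = 100,
                          fst = defaultFstTargets(),
                          ld = list(nAncestral = 20, segSnps = 30),
                          vc = varianceTargets(), trait = "y",
                          focal = NULL, nQtl = NULL, cMperMb = 1) {
  seeds <- deriveSeeds(seed, 4)
  spacing <- chromLengthMb * 1e6 / snpsPerChrom
  chrom <- rep(sprintf("chr%d", seq_len(nChrom)), each = snpsPerChrom)
  pos <- rep(round(seq(spacing, chromLengthMb * 1e6, length.out =
                         snpsPerChrom)), nChrom)
  map <- markerMap(chrom, pos)
  freqOverride <- NULL
  if (!is.null(focal)) {
    fchrom <- sprintf("chr%d", focal$chrom %||% 1)
    fpos <- round((focal$posMb %||% (chromLengthMb / 2)) * 1e6) + 1L
    sel <- map$chrom == fchrom
    ins <- which(sel & map$pos > fpos)[1]
    stopifnot_msg(!is.na(ins) && !any(map$pos[sel] == fpos),
                  "focal position collides with a panel SNP")
    row <- data.frame(chrom = fchrom, pos = fpos, id = "focal",
                      is_focal = TRUE, on_panel = isTRUE(focal$onPanel))
    map <- rbind(map[seq_len(ins - 1), ], row,
                 map[ins:nrow(map), ])
    rownames(map) <- NULL
    if (all(focal$freqs <= 0) || all(focal$freqs >= 1))
      stop("focal mutation must segregate in at least one breed",
           call. = FALSE)
    freqOverride <- setNames(list(focal$freqs), as.character(ins))
  }
  founders <- simulateFounderBreeds(map, nFounders, fst, seed = seeds[1],
                                    ld = ld, freqOverride = freqOverride)
  ped <- makeCrossPedigree(nFounders, nPurebred, nF1, nCrossbred,
                           litterSize, seed = seeds[2])
  gd <- geneDropPedigree(founders, ped, map, seed = seeds[3],
                         cMperMb = cMperMb)
  records <- simulatePhenotypes(gd$geno, gd$origins, ped, vc = vc,
                                trait = trait,
                                focalEffect = if (is.null(focal)) 0
                                              else focal$effect,
                                nQtl = nQtl, seed = seeds[4])
  cbIdx <- which(ped$group == "CB")
  purebreds <- lapply(setNames(BREEDS, BREEDS), function(b)
    subsetGenotypes(gd$geno, which(ped$group == b), NULL))
  list(map = map, ped = ped, geno = gd$geno, origins = gd$origins,
       records = records, purebreds = purebreds,
       cb = subsetGenotypes(gd$geno, cbIdx, NULL),
       cbOrigins = subsetOrigins(gd$origins, cbIdx, NULL),
       founders = founders, seed = seed)
}

#' Simulate the focal-mutation (major-gene) scenario
#'
#' Study conditions for the focal-locus analysis: the default study plus
#' one biallelic focal mutation with mutant-allele founder frequencies
#' 0.85 (S), 0.06 (LR) and 0.39 (LW), a large substitution effect that
#' is identical across breeds-of-origin, and the mutation withheld from
#' the analysis panel so the panel tags it only through linkage
#' disequilibrium. Crossbred within-origin frequencies are emergent, not
#' targeted.
#'
#' @param seed integer master seed.
#' @param focalFreqs founder mutant-allele frequencies per breed.
#' @param focalEffect substitution effect in trait units (phenotypic SD
#'   is 1 under the default variance targets).
#' @param nFounders founder animals per breed; the focal scenario uses a
#'   wider founder base than the baseline study so that the rare mutant
#'   allele of the LR line survives the cross at a stable frequency.
#' @param ... passed to [simulateStudy()].
#' @return see [simulateStudy()].
#' @export
buildFocalScenario <- function(seed = 1,
                               focalFreqs = c(S = 0.85, LR = 0.06,
                                              LW = 0.39),
                               focalEffect = 0.5,
                               nFounders = c(S = 80, LR = 80, LW = 80),
                               ...) {
  simulateStudy(seed = seed,
                nFounders = nFounders,
                focal = list(freqs = focalFreqs, effect = focalEffect,
                             chrom = 1, posMb = 50.05, onPanel = FALSE),
                vc = varianceTargets(h2PB = c(S = 0.09, LR = 0.22,
                                              LW = 0.20),
                                     h2CB = 0.29,
                                     rpc = c(S = 0.69, LR = 0.60,
                                             LW = 0.68)),
                trait = "ADG", ...)
}
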