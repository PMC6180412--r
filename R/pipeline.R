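#' Configuration for an end-to-end pipeline run
#'
#' Collects the thresholds of the breed-of-origin workflow (defaults are
#' the standard settings: 80% library purity, 90% SNP and animal
#' assignment rates, minimum 5 allele copies per origin, P < 0.01 for
#' linkage disequilibrium, top-10 blocks compared within 1 Mb) together
#' with the simulation design and the variance-component source.
#'
#' @param seed master seed.
#' @param purity,snpRate,animalRate,minCopies assignment thresholds.
#' @param alpha LD significance threshold.
#' @param topK,maxGapBp region-comparison settings.
#' @param ridge identity blending for matrix inversion in the solver.
#' @param vcSource `"fixed"` (use the generator targets) or `"reml"`.
#' @param windowLengths haplotype core lengths (SNPs).
#' @param focalScenario simulate the focal-mutation scenario instead of
#'   the baseline study.
#' @param sim list of overrides passed to [simulateStudy()] /
#'   [buildFocalScenario()].
#' @return config list.
#' @export
runConfig <- function(seed = 1, purity = 0.80, snpRate = 0.90,
                      animalRate = 0.90, minCopies = 5, alpha = 0.01,
                      topK = 10, maxGapBp = 1e6, ridge = 1e-6,
                      vcSource = c("fixed", "reml"),
                      windowLengths = c(10, 14, 20, 28, 39, 55, 77, 107,
                                        150),
                      focalScenario = FALSE, sim = list()) {
  stopifnot(purity > 0.5, purity <= 1, snpRate >= 0, snpRate <= 1,
            animalRate >= 0, animalRate <= 1, minCopies >= 0,
            alpha > 0, alpha <= 1, topK >= 1, maxGapBp >= 0)
  list(seed = seed, purity = purity, snpRate = snpRate,
       animalRate = animalRate, minCopies = minCopies, alpha = alpha,
       topK = topK, maxGapBp = maxGapBp, ridge = ridge,
       vcSource = match.arg(vcSource), windowLengths = windowLengths,
       focalScenario = focalScenario, sim = sim)
}

## fixed-effect-corrected phenotypes of one record population
precorrectPhenotypes <- function(md, fit, pop = "CB") {
  sel <- md$pop == pop
  resid <- md$y - as.vector(md$X %*% fit@fixef$beta)
  setNames(resid[sel], md$records$id[sel])
}

#' Run the full breed-of-origin analysis pipeline
#'
#' Simulates the study (baseline or focal scenario), assigns the
#' breed-of-origin of crossbred alleles from the purebred haplotype
#' library, applies the assignment filters, builds the three partial
#' relationship matrices, fits the BOA model, back-solves SNP-allele
#' effects per breed-of-origin, segments LD blocks and their explained
#' genetic variance, matches top regions across origins and — in the
#' focal scenario — runs the focal-locus haplotype and substitution
#' analysis. Fully deterministic given the config seed.
#'
#' @param config list from [runConfig()].
#' @return report list (thresholds used, per-stage counts, assignment
#'   accuracy against truth, variance components, block summaries, top
#'   regions, focal results) with data.frame outputs under `$tables`.
#' @export
runPipeline <- function(config = runConfig()) {
  sim <- do.call(if (config$focalScenario) buildFocalScenario
                 else simulateStudy,
                 c(list(seed = config$seed), config$sim))
  trait <- setdiff(names(sim$records),
                   c("id", "group", "litter", "sex", "farm", "BWon",
                     "BWoff", "gTrue"))[1]
  map <- sim$map
  hapLib <- buildHaplotypeLibrary(sim$purebreds,
                                   windowSpec(config$windowLengths),
                                   purity = config$purity)
  origins <- assignBreedOfOrigin(sim$cb, hapLib)
  filt <- applyAssignmentFilters(origins, sim$cb,
                                 snpRate = config$snpRate,
                                 animalRate = config$animalRate,
                                 minCopies = config$minCopies)
  keptSnps <- sort(union(filt$keptSnps, which(map$is_focal)))
  keptAnimals <- filt$keptAnimals
  cbK <- subsetGenotypes(sim$cb, keptAnimals, keptSnps)
  orK <- subsetOrigins(origins, match(keptAnimals, animalIds(sim$cb)),
                       keptSnps)
  truthK <- subsetOrigins(sim$cbOrigins,
                          match(keptAnimals, animalIds(sim$cb)), keptSnps)
  acc <- assignmentAccuracy(orK, truthK)
  mapK <- snpMap(cbK)
  panelK <- which(mapK$on_panel)
  grms <- buildPartialGRMSet(sim$purebreds, cbK, orK, snps = panelK)
  records <- sim$records[sim$records$group != "CB" |
                           sim$records$id %in% keptAnimals, ]
  md <- boaModelData(records, grms, trait = trait)
  vcTruth <- attr(sim$records, "truth")$vc
  vc <- if (config$vcSource == "reml") {
    remlEstimate(md, init = vcTruth, tol = 1e-6)
  } else vcTruth
  fit <- solveBoaMme(md, vc, ridge = config$ridge)
  effects <- snpEffectsFromFit(fit, grms)
  sigma2aCB <- sum(vapply(BREEDS, function(b) vc$genetic[[b]][2, 2], 0))
  blocks <- list(); blockSummary <- list(); blockVar <- list()
  for (b in BREEDS) {
    bl <- segmentLdBlocks(cbK, orK, b, snps = panelK,
                          alpha = config$alpha)
    Z <- genotypeDosage(sim$purebreds[[b]])[, keptSnps, drop = FALSE]
    Z <- Z[, panelK, drop = FALSE]
    colnames(Z) <- mapK$id[panelK]
    effCB <- effects[effects$origin == b &
                       effects$performance == "crossbred", ]
    bv <- blockVarianceExplained(bl, Z,
                                 setNames(effCB$effect, effCB$snp),
                                 sigma2a = sigma2aCB)
    blocks[[b]] <- bl
    blockSummary[[b]] <- attr(bl, "summary")
    blockVar[[b]] <- bv
  }
  matches <- list()
  for (pair in list(c("S", "LR"), c("S", "LW"), c("LR", "LW"))) {
    matches[[paste(pair, collapse = "_")]] <-
      matchTopRegions(blockVar[[pair[1]]], blockVar[[pair[2]]],
                      k = config$topK, maxGapBp = config$maxGapBp)
  }
  report <- list(
    config = config[c("seed", "purity", "snpRate", "animalRate",
                      "minCopies", "alpha", "topK", "maxGapBp", "ridge",
                      "vcSource", "focalScenario")],
    trait = trait,
    counts = list(
      snpsSimulated = nrow(map), snpsKept = length(panelK),
      crossbredsKept = length(keptAnimals),
      filterStats = as.list(filt$stats)),
    assignment = list(assigned = acc$assigned, accuracy = acc$accuracy,
                      perOrigin = as.list(acc$perOrigin)),
    varianceComponents = list(
      genetic = lapply(vc$genetic, function(S)
        list(varPB = S[1, 1], covPBCB = S[1, 2], varCB = S[2, 2])),
      litter = as.list(vc$litter), residual = as.list(vc$residual)),
    geneticParameters = geneticParameters(vc),
    blockSummary = do.call(rbind, blockSummary),
    topRegionMatches = lapply(matches, nrow))
  tables <- list(snpEffects = effects)
  for (b in BREEDS) tables[[paste0("blocks_", b)]] <- blockVar[[b]]
  for (nm in names(matches)) tables[[paste0("match_", nm)]] <- matches[[nm]]
  if (config$focalScenario) {
    fb <- focalLdBlock(cbK, orK, alpha = config$alpha)
    ## origins where the mutation shows no LD (e.g. lost by drift)
    ## contribute only the focal SNP; intersect over informative origins
    informative <- Filter(function(x) length(x) > 1, fb$perOrigin)
    if (length(informative) < length(fb$perOrigin))
      warning("focal mutation shows no LD for origin(s): ",
              paste(setdiff(names(fb$perOrigin), names(informative)),
                    collapse = ", "), call. = FALSE)
    fb$intersection <- sort(Reduce(intersect, informative))
    haps <- enumerateBlockHaplotypes(cbK, orK, fb$intersection)
    freqs <- lapply(setNames(BREEDS, BREEDS), function(b)
      list(p = grms@breeds[[b]]$p))
    haps <- haplotypeEffects(haps, effects, freqs, cbK)
    wam <- weightedAlleleMeans(haps)
    A <- pedigreeNumeratorMatrix(sim$ped)
    yCorr <- precorrectPhenotypes(md, fit, "CB")
    content <- focalAlleleContent(cbK, orK)[names(yCorr), , drop = FALSE]
    litters <- records$litter[match(names(yCorr), records$id)]
    sub <- fitFocalSnpModel(yCorr, content, litters, A,
                            sigma2u = sigma2aCB)
    ## percent of genetic variance of the block containing the focal SNP
    focalPos <- mapK$pos[fb$focal]
    focalPercent <- vapply(BREEDS, function(b) {
      bv <- blockVar[[b]]
      hit <- bv$chrom == mapK$chrom[fb$focal] &
        bv$startPos <= focalPos & bv$endPos >= focalPos
      if (!any(hit)) {
        near <- which(bv$chrom == mapK$chrom[fb$focal])
        hit <- near[which.min(pmin(abs(bv$startPos[near] - focalPos),
                                   abs(bv$endPos[near] - focalPos)))]
      }
      max(bv$percent[hit])
    }, 0)
    report$focal <- list(
      blockSizes = lapply(fb$perOrigin, length),
      intersectionSize = length(fb$intersection),
      nHaplotypes = nrow(haps),
      excludedCopies = attr(haps, "excludedCopies"),
      weightedAlleleMeans = wam,
      substitution = sub,
      focalBlockPercent = as.list(focalPercent))
    tables$focalHaplotypes <- haps
  }
  report$tables <- tables
  report
}
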