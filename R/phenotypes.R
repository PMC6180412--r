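#' Variance-component targets for the simulator
#'
#' Builds the full set of variance components of the breed-of-origin model
#' from heritabilities and purebred--crossbred genetic correlations, on a
#' phenotypic-variance scale of `phenVar` per trait. The crossbred genetic
#' variance is split over breeds-of-origin by `cbSplit`; the default
#' (1/2, 1/4, 1/4) mirrors the genome shares of the sire and the two dam
#' lines in a terminal three-way cross. Default heritabilities and
#' correlations are those of back fat thickness in the populations the
#' simulator emulates (h2 purebred 0.31/0.33/0.34, h2 crossbred 0.41,
#' r_pc 0.80/0.71/0.89).
#'
#' @param h2PB named per-breed purebred heritabilities.
#' @param h2CB crossbred heritability (total across origins).
#' @param rpc named per-breed purebred--crossbred genetic correlations.
#' @param litter common-litter variance ratios (purebred, crossbred).
#' @param phenVar phenotypic variance (trait units squared).
#' @param cbSplit share of the crossbred genetic variance per
#'   breed-of-origin.
#' @return list with `genetic` (per breed a 2x2 covariance matrix with
#'   rows/cols `PB`, `CB`), `litter` and `residual` (named vectors over
#'   populations S, LR, LW, CB).
#' @export
varianceTargets <- function(h2PB = c(S = 0.31, LR = 0.33, LW = 0.34),
                            h2CB = 0.41,
                            rpc = c(S = 0.80, LR = 0.71, LW = 0.89),
                            litter = c(purebred = 0.10, crossbred = 0.10),
                            phenVar = 1,
                            cbSplit = c(S = 0.5, LR = 0.25, LW = 0.25)) {
  if (any(h2PB < 0 | h2PB > 1) || h2CB < 0 || h2CB > 1 ||
      any(litter < 0 | litter > 1))
    stop("variance ratios must lie in [0, 1]", call. = FALSE)
  if (any(abs(rpc) > 1)) stop("r_pc must lie in [-1, 1]", call. = FALSE)
  gen <- list()
  for (b in BREEDS) {
    s11 <- h2PB[[b]] * phenVar
    s22 <- h2CB * phenVar * cbSplit[[b]] / sum(cbSplit)
    s12 <- rpc[[b]] * sqrt(s11 * s22)
    gen[[b]] <- matrix(c(s11, s12, s12, s22), 2, 2,
                       dimnames = list(c("PB", "CB"), c("PB", "CB")))
  }
  lit <- c(rep(litter[["purebred"]], 3), litter[["crossbred"]]) * phenVar
  names(lit) <- c(BREEDS, "CB")
  resid <- c(phenVar - h2PB[BREEDS] * phenVar - lit[BREEDS],
             CB = phenVar - h2CB * phenVar - lit[["CB"]])
  names(resid) <- c(BREEDS, "CB")
  if (any(resid <= 0))
    stop("heritability plus litter ratio must stay below 1", call. = FALSE)
  list(genetic = gen, litter = lit, residual = resid)
}

## bivariate (purebred, crossbred) SNP effects per breed, scaled so that
## the variance of breeding values matches the target components exactly
## under the partial-GRM model: alpha ~ N(0, Sigma_b / F_b)
drawSnpEffects <- function(freqs, vc, nQtl = NULL, seed = 1) {
  set.seed(seed)
  out <- list()
  for (b in BREEDS) {
    p <- freqs[[b]]$p
    m <- length(p)
    qtl <- if (is.null(nQtl)) seq_len(m) else sort(sample.int(m, nQtl))
    Fq <- sum(2 * p[qtl] * (1 - p[qtl]))
    S <- vc$genetic[[b]] / Fq
    L <- chol(S + diag(1e-12, 2))
    z <- matrix(rnorm(2 * length(qtl)), ncol = 2) %*% L
    aPB <- numeric(m); aCB <- numeric(m)
    aPB[qtl] <- z[, 1]; aCB[qtl] <- z[, 2]
    out[[b]] <- list(PB = aPB, CB = aCB, qtl = qtl)
  }
  out
}

#' Simulate phenotypes under the breed-of-origin model
#'
#' Phenotype = fixed part (farm x sex classes plus one covariate) +
#' additive genetic value + common-litter effect + residual. Purebred
#' animals express the purebred-performance SNP effects of their own
#' breed; crossbred animals express breed-of-origin specific
#' crossbred-performance effects summed over their allele origins. Per
#' breed, the (purebred, crossbred) effect pairs are drawn bivariate
#' normal with covariance `vc$genetic[[b]] / F_b`, which makes the input
#' variance components the exact estimands of the REML fit on the same
#' data. Founder and F1 animals receive no records.
#'
#' @param geno [PhasedGenotypes-class] for all pedigree animals.
#' @param origins [OriginMatrix-class] truth (or assigned) origins.
#' @param ped pedigree data.frame.
#' @param vc variance-component targets ([varianceTargets()]).
#' @param trait name of the phenotype column.
#' @param nFarms number of farm levels.
#' @param farmSd SD of the farm-by-sex fixed effects.
#' @param covEffect regression coefficient on the on-test body-weight
#'   covariate.
#' @param focalEffect additive allele-substitution effect of the focal
#'   SNP (trait units per counted allele), equal across origins; 0 if
#'   there is no focal SNP.
#' @param nQtl number of causal SNPs per breed (default: every panel SNP,
#'   the polygenic limit).
#' @param seed integer seed.
#' @return TraitRecords data.frame (`id`, `group`, `litter`, `farm`,
#'   `sex`, `BWon`, `BWoff`, trait value, `gTrue`) with the simulation
#'   truth attached as attribute `"truth"`.
#' @export
simulatePhenotypes <- function(geno, origins, ped, vc = varianceTargets(),
                               trait = "y", nFarms = 3, farmSd = 0.5,
                               covEffect = 0.3, focalEffect = 0,
                               nQtl = NULL, seed = 1) {
  seeds <- deriveSeeds(seed, 3)
  map <- snpMap(geno)
  panel <- which(map$on_panel)
  recIdx <- which(ped$group %in% c(BREEDS, "CB") & !is.na(ped$litter))
  cbIdx <- which(ped$group == "CB")
  pbIdx <- lapply(BREEDS, function(b) which(ped$group == b))
  names(pbIdx) <- BREEDS
  cbOr <- subsetOrigins(origins, cbIdx, NULL)
  freqs <- list()
  for (b in BREEDS) {
    freqs[[b]] <- breedAlleleFrequencies(
      subsetGenotypes(geno, pbIdx[[b]], panel),
      subsetGenotypes(geno, cbIdx, panel),
      subsetOrigins(cbOr, NULL, panel), b)
  }
  eff <- drawSnpEffects(freqs, vc, nQtl = nQtl, seed = seeds[1])

  set.seed(seeds[2])
  n <- nrow(ped)
  g <- numeric(n)
  dosage <- genotypeDosage(geno)[, panel, drop = FALSE]
  for (b in BREEDS) {
    idx <- pbIdx[[b]]
    W <- sweep(dosage[idx, , drop = FALSE], 2, 2 * freqs[[b]]$p)
    g[idx] <- as.vector(W %*% eff[[b]]$PB)
  }
  for (b in BREEDS) {
    Wcb <- originContent(subsetGenotypes(geno, cbIdx, panel),
                         subsetOrigins(cbOr, NULL, panel),
                         b, freqs[[b]]$p)
    g[cbIdx] <- g[cbIdx] + as.vector(Wcb %*% eff[[b]]$CB)
  }
  if (focalEffect != 0 && any(map$is_focal)) {
    fj <- which(map$is_focal)
    g <- g + focalEffect * (geno@pat[, fj] + geno@mat[, fj])
  }

  rec <- ped[recIdx, c("id", "group", "litter", "sex")]
  pop <- ifelse(rec$group == "CB", "CB", rec$group)
  rec$farm <- sprintf("farm%d", sample.int(nFarms, nrow(rec), replace = TRUE))
  rec$BWon <- rnorm(nrow(rec))
  rec$BWoff <- rnorm(nrow(rec))
  fsLev <- as.vector(outer(seq_len(nFarms), c("M", "F"), paste0))
  fsEff <- setNames(rnorm(length(fsLev), 0, farmSd), fsLev)
  lits <- unique(rec$litter)
  litPop <- pop[match(lits, rec$litter)]
  litEff <- setNames(rnorm(length(lits), 0, sqrt(vc$litter[litPop])), lits)
  e <- rnorm(nrow(rec), 0, sqrt(vc$residual[pop]))
  y <- fsEff[paste0(sub("farm", "", rec$farm), rec$sex)] +
    covEffect * rec$BWon + g[recIdx] + litEff[rec$litter] + e
  rec[[trait]] <- as.vector(y)
  rec$gTrue <- g[recIdx]
  rownames(rec) <- NULL
  attr(rec, "truth") <- list(effects = eff, freqs = freqs, vc = vc,
                             focalEffect = focalEffect, seed = seed)
  rec
}

#' Derive residual feed intake
#'
#' Regresses average daily feed intake on on-test and off-test body
#' weight, back fat and average daily gain by least squares, separately
#' within the purebred and the crossbred population (whose feed-intake
#' recording regimes differ), and stores the residual as RFI. Residuals
#' are mean-zero and orthogonal to all four covariates within each
#' population by construction.
#'
#' @param records data.frame with columns `ADFI`, `BWon`, `BWoff`, `BF`,
#'   `ADG` and `group`.
#' @return `records` with an `RFI` column (NA where ADFI is missing) and
#'   the fitted coefficients as attribute `"rfi_fit"`.
#' @export
deriveRfi <- function(records) {
  need <- c("ADFI", "BWon", "BWoff", "BF", "ADG")
  if (!all(need %in% names(records)))
    stop("records must contain ", paste(need, collapse = ", "), call. = FALSE)
  records$RFI <- NA_real_
  pop <- ifelse(records$group == "CB", "crossbred", "purebred")
  fits <- list()
  for (pp in unique(pop)) {
    sel <- which(pop == pp & complete.cases(records[, need]))
    if (!length(sel)) next
    X <- cbind(1, as.matrix(records[sel, c("BWon", "BWoff", "BF", "ADG")]))
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient covariate matrix in RFI regression (",
           pp, ")", call. = FALSE)
    fit <- lm.fit(X, records$ADFI[sel])
    records$RFI[sel] <- fit$residuals
    fits[[pp]] <- fit$coefficients
  }
  attr(records, "rfi_fit") <- fits
  records
}
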