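#' LD block around a focal SNP, per breed-of-origin
#'
#' Unlike consecutive-pair segmentation, the focal block collects every
#' SNP on the focal SNP's chromosome whose alleles are in significant
#' gametic disequilibrium with the focal SNP itself (Fisher's exact test
#' on same-origin gametes, p < alpha), separately per breed-of-origin,
#' plus the cross-origin intersection used for comparisons.
#'
#' @param geno crossbred [PhasedGenotypes-class] including the focal SNP
#'   column (the focal SNP may be off-panel).
#' @param origins crossbred [OriginMatrix-class] covering the same SNPs.
#' @param alpha significance threshold.
#' @param breeds origins to build blocks for.
#' @return list with `focal` (index), `perOrigin` (named list of sorted
#'   SNP indices, focal included), `intersection` (common indices).
#' @export
focalLdBlock <- function(geno, origins, alpha = 0.01, breeds = BREEDS) {
  map <- snpMap(geno)
  fj <- which(map$is_focal)
  stopifnot_msg(length(fj) == 1L, "exactly one focal SNP is required")
  cand <- setdiff(which(map$chrom == map$chrom[fj]), fj)
  perOrigin <- list()
  for (b in breeds) {
    inLd <- vapply(cand, function(j) {
      if (alpha >= 1) return(TRUE)  # degenerate threshold: keep all
      gt <- gameticTable(geno, origins, b, fj, j)
      fisherExact2x2(gt$table) < alpha
    }, TRUE)
    perOrigin[[b]] <- sort(c(fj, cand[inLd]))
  }
  list(focal = fj, perOrigin = perOrigin,
       intersection = sort(Reduce(intersect, perOrigin)))
}

#' Enumerate haplotypes of a focal LD block
#'
#' Lists the distinct haplotypes over the block's panel SNPs among
#' crossbred gametes, with copy counts per breed-of-origin and the focal
#' allele each haplotype carries. A gamete's origin is the strict
#' majority of its assigned origin labels over the block; gametes without
#' a majority are excluded. Haplotypes seen with both focal alleles have
#' their minority-allele copies excluded (treated as genotyping errors)
#' and are flagged inconsistent.
#'
#' @param geno crossbred [PhasedGenotypes-class] (with the focal SNP).
#' @param origins crossbred [OriginMatrix-class].
#' @param blockSnps SNP indices of the block (the focal SNP, if present,
#'   is separated out automatically).
#' @param alleleLabels labels for focal allele 1 and 0 (mutant m, wild w).
#' @return data.frame with `hap`, `allele`, one count column per origin,
#'   `consistent`; excluded copy count in attribute `"excludedCopies"`.
#' @export
enumerateBlockHaplotypes <- function(geno, origins, blockSnps,
                                     alleleLabels = c("m", "w")) {
  map <- snpMap(geno)
  fj <- which(map$is_focal)
  cols <- setdiff(blockSnps, fj)
  if (!length(cols))
    stop("the focal block holds no SNPs besides the focal mutation; ",
         "no haplotypes can be enumerated (is the mutation segregating ",
         "in every origin?)", call. = FALSE)
  n <- nAnimals(geno)
  str <- c(hapStrings(geno@pat, cols), hapStrings(geno@mat, cols))
  focal <- c(geno@pat[, fj], geno@mat[, fj])
  orLab <- rbind(origins@pat[, cols, drop = FALSE],
                 origins@mat[, cols, drop = FALSE])
  gamOrigin <- apply(orLab, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tb <- tabulate(v, nbins = 3)
    top <- which(tb == max(tb))
    if (length(top) > 1 || max(tb) <= sum(tb) / 2) NA_integer_ else top
  })
  keep <- !is.na(gamOrigin)
  str <- str[keep]; focal <- focal[keep]; gamOrigin <- gamOrigin[keep]
  keys <- unique(str)
  ki <- match(str, keys)
  excluded <- 0L
  rows <- list()
  for (k in seq_along(keys)) {
    sel <- ki == k
    nm <- sum(focal[sel] == 1L); nw <- sum(focal[sel] == 0L)
    if (nm == nw && nm > 0) { excluded <- excluded + nm + nw; next }
    carried <- if (nm >= nw) 1L else 0L
    drop <- sel & focal != carried
    excluded <- excluded + sum(drop)
    use <- sel & !drop
    cnt <- tabulate(gamOrigin[use], nbins = 3)
    rows[[length(rows) + 1L]] <- data.frame(
      hap = keys[k],
      allele = alleleLabels[ifelse(carried == 1L, 1L, 2L)],
      count_S = cnt[1], count_LR = cnt[2], count_LW = cnt[3],
      consistent = !any(drop), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "excludedCopies") <- excluded
  attr(out, "blockCols") <- cols
  out
}

#' Effects of block haplotypes per breed-of-origin
#'
#' The effect of a haplotype is the centred sum of the back-solved
#' crossbred-performance SNP effects of its origin over the block SNPs:
#' `sum_j (allele_j - p_j^origin) alphaHat_j^origin`. Centring keeps the
#' frequency-weighted mean haplotype effect near zero within each origin.
#' The uncentred plain sum is available with `center = FALSE`.
#'
#' @param hapTable result of [enumerateBlockHaplotypes()].
#' @param effects data.frame from [snpEffectsFromFit()] (crossbred
#'   performance rows are used).
#' @param freqs named list per breed with element `p` (breed-specific
#'   allele frequencies, named by SNP id).
#' @param geno the crossbred genotypes (for the SNP id map).
#' @param center subtract origin allele frequencies before summing.
#' @return `hapTable` with columns `effect_S`, `effect_LR`, `effect_LW`.
#' @export
haplotypeEffects <- function(hapTable, effects, freqs, geno, center = TRUE) {
  cols <- attr(hapTable, "blockCols")
  ids <- snpMap(geno)$id[cols]
  codes <- matrix(as.integer(unlist(strsplit(hapTable$hap, ""))),
                  nrow = nrow(hapTable), byrow = TRUE)
  for (b in BREEDS) {
    eff <- effects[effects$origin == b & effects$performance == "crossbred", ]
    alpha <- setNames(eff$effect, eff$snp)[ids]
    p <- freqs[[b]]$p[ids]
    X <- if (center) sweep(codes, 2, p) else codes
    hapTable[[paste0("effect_", b)]] <- as.vector(X %*% alpha)
  }
  hapTable
}

#' Frequency-weighted mean effects of the focal alleles
#'
#' Per breed-of-origin, the mean effect of the haplotypes carrying the
#' mutant (m) allele and of those carrying the wild-type (w) allele,
#' weighted by haplotype copy counts within each allele class. Their
#' difference (w minus m: the effect of substituting an m allele by a w
#' allele) approximates the allele-substitution effect.
#'
#' @param hapTable output of [haplotypeEffects()].
#' @return data.frame per origin: `mMean`, `wMean`, `wForM`, `spread`
#'   (max - min haplotype effect among observed haplotypes), `nHap`.
#' @export
weightedAlleleMeans <- function(hapTable) {
  out <- list()
  for (b in BREEDS) {
    cnt <- hapTable[[paste0("count_", b)]]
    eff <- hapTable[[paste0("effect_", b)]]
    obs <- cnt > 0
    wm <- function(cls) {
      sel <- obs & hapTable$allele == cls
      if (!any(sel)) return(NA_real_)
      sum(eff[sel] * cnt[sel]) / sum(cnt[sel])
    }
    mMean <- wm("m"); wMean <- wm("w")
    out[[b]] <- data.frame(
      origin = b, mMean = mMean, wMean = wMean, wForM = wMean - mMean,
      spread = if (any(obs)) max(eff[obs]) - min(eff[obs]) else NA_real_,
      nHap = sum(obs))
  }
  do.call(rbind, out)
}

#' Origin-specific allele content of the focal SNP
#'
#' Per crossbred animal and breed-of-origin, the number of mutant (m,
#' code-1) focal alleles inherited from that origin.
#'
#' @param geno crossbred [PhasedGenotypes-class] with the focal SNP.
#' @param origins crossbred [OriginMatrix-class] covering the focal SNP.
#' @return matrix animals x origins.
#' @export
focalAlleleContent <- function(geno, origins) {
  fj <- which(snpMap(geno)$is_focal)
  stopifnot_msg(length(fj) == 1L, "exactly one focal SNP is required")
  X <- matrix(0, nAnimals(geno), 3,
              dimnames = list(animalIds(geno), BREEDS))
  for (bc in 1:3) {
    X[, bc] <- (!is.na(origins@pat[, fj]) & origins@pat[, fj] == bc) *
      geno@pat[, fj] +
      (!is.na(origins@mat[, fj]) & origins@mat[, fj] == bc) *
      geno@mat[, fj]
  }
  X
}

#' Fixed-regression substitution effect of the focal SNP
#'
#' Mixed model for pre-corrected crossbred phenotypes: an overall mean,
#' one fixed regression per breed-of-origin on the centred mutant-allele
#' content, a random common-litter effect, a random additive genetic
#' effect with pedigree relationship matrix `A` and variance fixed at
#' `sigma2u` (taken from the BOA-model fit), and a residual. Litter and
#' residual variances are estimated by AI-REML; the regressions are then
#' the GLS solutions at the estimated covariance.
#'
#' @param y pre-corrected phenotypes of the crossbred animals.
#' @param content animals x origins mutant-allele content
#'   ([focalAlleleContent()]).
#' @param litter litter labels per animal.
#' @param A pedigree numerator relationship matrix over (at least) the
#'   crossbred animals, dimnames by id.
#' @param sigma2u additive genetic variance (fixed, from the BOA model).
#' @param tol,maxIter REML controls.
#' @return data.frame per origin: `b` (effect of one m allele), `se`,
#'   `wForM` (= -b, the w-for-m substitution effect), plus the estimated
#'   `sigma2c`, `sigma2e` as attributes.
#' @export
fitFocalSnpModel <- function(y, content, litter, A, sigma2u,
                             tol = 1e-6, maxIter = 100) {
  ids <- rownames(content)
  A <- A[ids, ids]
  n <- length(y)
  lev <- unique(litter)
  Zl <- matrix(0, n, length(lev))
  Zl[cbind(seq_len(n), match(litter, lev))] <- 1
  est <- apply(content, 2, function(x) var(x) > 0)
  Xc <- sweep(content[, est, drop = FALSE], 2,
              colMeans(content[, est, drop = FALSE]))
  X <- cbind(`(Intercept)` = 1, Xc)
  fit <- aiRemlCore(y, X, list(tcrossprod(Zl), diag(n)),
                    offset = sigma2u * A, tol = tol, maxIter = maxIter)
  V <- sigma2u * A + fit$theta[1] * tcrossprod(Zl) + fit$theta[2] * diag(n)
  Vi <- chol2inv(chol(V))
  XtViX <- crossprod(X, Vi %*% X)
  bcov <- solve(XtViX)
  beta <- drop(bcov %*% crossprod(X, Vi %*% y))
  b <- se <- setNames(rep(NA_real_, 3), BREEDS)
  b[colnames(Xc)] <- beta[-1]
  se[colnames(Xc)] <- sqrt(diag(bcov))[-1]
  out <- data.frame(origin = BREEDS, b = b, se = se, wForM = -b,
                    row.names = NULL)
  attr(out, "sigma2c") <- fit$theta[1]
  attr(out, "sigma2e") <- fit$theta[2]
  attr(out, "sigma2u") <- sigma2u
  out
}
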