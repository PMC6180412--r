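## gametes (haplotype strands) of one breed-of-origin: rows are gamete
## copies over the selected SNP columns, NA where the origin is not b
originGametes <- function(haps, origins, breed, cols) {
  code <- match(breed, origins@levels)
  hp <- haps@pat[, cols, drop = FALSE]
  hm <- haps@mat[, cols, drop = FALSE]
  op <- origins@pat[, cols, drop = FALSE]
  om <- origins@mat[, cols, drop = FALSE]
  hp[is.na(op) | op != code] <- NA_integer_
  hm[is.na(om) | om != code] <- NA_integer_
  rbind(hp, hm)
}

#' Gametic 2x2 table and disequilibrium coefficient for two loci
#'
#' Counts the four gametic types at two loci over the crossbred gametes
#' assigned to one breed-of-origin; gametes missing the origin or allele
#' at either locus are excluded. `D = p11 - p1. * p.1` over gamete
#' frequencies (counted allele = 1).
#'
#' @param haps crossbred [PhasedGenotypes-class].
#' @param origins crossbred [OriginMatrix-class].
#' @param breed breed-of-origin label.
#' @param i,j SNP indices (or ids).
#' @return list with `table` (2x2 counts, rows = allele at i, cols =
#'   allele at j, in order 0, 1), `D`, `n`.
#' @export
gameticTable <- function(haps, origins, breed, i, j) {
  map <- snpMap(haps)
  if (is.character(i)) i <- match(i, map$id)
  if (is.character(j)) j <- match(j, map$id)
  g <- originGametes(haps, origins, breed, c(i, j))
  keep <- !is.na(g[, 1]) & !is.na(g[, 2])
  a <- g[keep, 1]; b <- g[keep, 2]
  tab <- matrix(c(sum(a == 0 & b == 0), sum(a == 0 & b == 1),
                  sum(a == 1 & b == 0), sum(a == 1 & b == 1)),
                2, 2, byrow = TRUE, dimnames = list(c("0", "1"), c("0", "1")))
  n <- sum(tab)
  D <- if (n > 0) tab["1", "1"] / n - sum(tab["1", ]) / n * sum(tab[, "1"]) / n
       else NA_real_
  list(table = tab, D = D, n = n)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summation over the hypergeometric support:
#' the probability of every table with the observed margins whose point
#' probability does not exceed that of the observed table (with the usual
#' 1 + 1e-7 relative tolerance against floating-point ties). Degenerate
#' margins give p = 1.
#'
#' @param tab 2x2 count matrix.
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(tab) {
  stopifnot_msg(all(dim(tab) == c(2, 2)) && all(tab >= 0),
                "need a 2x2 table of non-negative counts")
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || nn == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  pObs <- dhyper(tab[1, 1], m, nn, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Segment a breed-of-origin's genome into LD blocks
#'
#' Within one breed-of-origin, every pair of consecutive kept SNPs on a
#' chromosome is tested for gametic disequilibrium with Fisher's exact
#' test; a breakpoint falls between two consecutive SNPs whenever D is
#' not significantly different from zero (p >= alpha). Blocks partition
#' the kept SNPs of each chromosome; single-SNP blocks are allowed.
#'
#' @param haps crossbred [PhasedGenotypes-class].
#' @param origins crossbred [OriginMatrix-class].
#' @param breed breed-of-origin.
#' @param snps kept SNP ids or indices (default: all panel SNPs).
#' @param alpha significance threshold on the raw per-pair p-value (no
#'   multiplicity correction, by design).
#' @return data.frame of blocks (`chrom`, `startSnp`, `endSnp`,
#'   `startPos`, `endPos`, `nSnps`, `origin`) with per-origin summary
#'   statistics (count, mean/min/max length) as attribute `"summary"`.
#' @export
segmentLdBlocks <- function(haps, origins, breed, snps = NULL, alpha = 0.01) {
  map <- snpMap(haps)
  if (is.null(snps)) snps <- which(map$on_panel)
  si <- if (is.character(snps)) match(snps, map$id) else snps
  blocks <- list()
  for (ch in unique(map$chrom[si])) {
    idx <- si[map$chrom[si] == ch]
    breakAfter <- logical(length(idx))
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1)) {
        gt <- gameticTable(haps, origins, breed, idx[k], idx[k + 1])
        breakAfter[k] <- fisherExact2x2(gt$table) >= alpha
      }
    }
    blockId <- cumsum(c(0, head(breakAfter, -1)))
    for (bk in unique(blockId)) {
      jj <- idx[blockId == bk]
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = ch, startSnp = map$id[jj[1]], endSnp = map$id[jj[length(jj)]],
        startPos = map$pos[jj[1]], endPos = map$pos[jj[length(jj)]],
        nSnps = length(jj), origin = breed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  attr(out, "summary") <- data.frame(
    origin = breed, nBlocks = nrow(out), meanLen = mean(out$nSnps),
    minLen = min(out$nSnps), maxLen = max(out$nSnps))
  out
}

#' Percentage of genetic variance explained by each LD block
#'
#' For block i containing SNPs j with effects `alpha_j`, the block genetic
#' value of individual k is `a_ik = sum_j z_kj alpha_j`; the percentage of
#' genetic variance is `Var(a_i) / sigma2a * (xn / n_i) * 100` with `xn`
#' the mean SNP count over the blocks of the scenario — so that block
#' percentages are comparable across blocks of different size.
#'
#' @param blocks block table from [segmentLdBlocks()].
#' @param Z genotype matrix (individuals x kept SNPs, columns named by
#'   SNP id) over which the variance is taken; conventionally the diploid
#'   dosages of all purebred individuals of the block's breed.
#' @param effects named SNP-effect vector (same SNP set).
#' @param sigma2a total additive genetic variance of the scenario
#'   (denominator); typically the REML estimate. If `NULL`, the variance
#'   of the total genomic value `Z alpha` is used.
#' @return `blocks` with columns `varA` (unscaled `Var(a_i)`), `percent`
#'   and `rank` (1 = most variance) added.
#' @export
blockVarianceExplained <- function(blocks, Z, effects, sigma2a = NULL) {
  snpIds <- colnames(Z)
  stopifnot_msg(!is.null(snpIds) && !is.null(names(effects)),
                "Z columns and effects must be named by SNP id")
  if (is.null(sigma2a))
    sigma2a <- var(as.vector(Z %*% effects[snpIds]))
  xn <- mean(blocks$nSnps)
  varA <- numeric(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    j1 <- match(blocks$startSnp[i], snpIds)
    j2 <- match(blocks$endSnp[i], snpIds)
    cols <- j1:j2
    varA[i] <- var(as.vector(Z[, cols, drop = FALSE] %*%
                             effects[snpIds[cols]]))
  }
  blocks$varA <- varA
  blocks$percent <- varA / sigma2a * (xn / blocks$nSnps) * 100
  blocks$rank <- rank(-blocks$percent, ties.method = "first")
  blocks
}

#' Match top LD blocks between two scenarios
#'
#' Takes the `k` blocks with the largest percentage of genetic variance
#' from each table (ties broken by genomic position) and reports pairs on
#' the same chromosome that overlap or lie less than `maxGapBp` apart —
#' the criterion used to compare regions across breeds-of-origin whose
#' block boundaries differ.
#'
#' @param tableA,tableB block tables with `percent` columns.
#' @param k number of top blocks per table.
#' @param maxGapBp maximum separation (exclusive) between non-overlapping
#'   blocks, in bp.
#' @return data.frame of matched pairs with positions and percentages
#'   from both scenarios.
#' @export
matchTopRegions <- function(tableA, tableB, k = 10, maxGapBp = 1e6) {
  topk <- function(tb) {
    ord <- order(-tb$percent, tb$chrom, tb$startPos)
    tb[ord[seq_len(min(k, nrow(tb)))], , drop = FALSE]
  }
  A <- topk(tableA); B <- topk(tableB)
  out <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (A$chrom[i] != B$chrom[j]) next
    gap <- max(B$startPos[j] - A$endPos[i], A$startPos[i] - B$endPos[j])
    if (gap < maxGapBp) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = A$chrom[i],
        startA = A$startPos[i], endA = A$endPos[i], percentA = A$percent[i],
        startB = B$startPos[j], endB = B$endPos[j], percentB = B$percent[j])
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), startA = numeric(),
                      endA = numeric(), percentA = numeric(),
                      startB = numeric(), endB = numeric(),
                      percentB = numeric()))
  }
  do.call(rbind, out)
}
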