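#' Default pairwise allelic differentiation between the three lines
#'
#' Weir–Cockerham F_ST targets between the sire line S and the two dam
#' lines: 0.17 (S, LR), 0.12 (S, LW), 0.14 (LR, LW) — the level of
#' divergence typical of distantly related commercial pig lines.
#' @export
defaultFstTargets <- function() {
  m <- matrix(0, 3, 3, dimnames = list(BREEDS, BREEDS))
  m["S", "LR"] <- m["LR", "S"] <- 0.17
  m["S", "LW"] <- m["LW", "S"] <- 0.12
  m["LR", "LW"] <- m["LW", "LR"] <- 0.14
  m
}

#' Solve per-breed divergence levels from pairwise F_ST targets
#'
#' Under a star-shaped divergence model (each breed drifts independently
#' from a common ancestral population, breed b with Balding–Nichols
#' parameter F_b), the expected pairwise F_ST between breeds a and b is
#' approximately (F_a + F_b) / 2. Given a symmetric matrix of pairwise
#' targets this solves the (least-squares, exact for three breeds) linear
#' system for the per-breed F_b.
#'
#' @param fst symmetric matrix of pairwise F_ST targets with breed
#'   dimnames.
#' @return named vector of per-breed divergence levels, each in `[0, 1)`.
#' @export
solveDivergence <- function(fst = defaultFstTargets()) {
  br <- rownames(fst)
  pairs <- utils::combn(seq_along(br), 2)
  A <- matrix(0, ncol(pairs), length(br))
  y <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    A[k, c(i, j)] <- 0.5
    y[k] <- fst[i, j]
  }
  Fb <- as.vector(qr.solve(A, y))
  names(Fb) <- br
  if (any(Fb < 0) || any(Fb >= 1))
    stop("pairwise F_ST targets are not representable by a star-shaped ",
         "divergence model", call. = FALSE)
  Fb
}

#' Simulate founder haplotypes for diverged purebred lines
#'
#' Two-level model. Allele frequencies: an ancestral frequency per SNP
#' drawn from Uniform(`ancestral[1]`, `ancestral[2]`), and breed
#' frequencies from the Balding–Nichols Beta distribution. Haplotypes:
#' each breed carries a finite pool of `ld$nAncestral` ancestral
#' haplotypes drawn from its frequencies, and every founder gamete is a
#' recombinant mosaic of that pool with geometric segment lengths of
#' mean `ld$segSnps` SNPs — which produces the within-breed linkage
#' disequilibrium of a line with a small long-term effective size, as in
#' commercial livestock. The haplotype-pool drift itself differentiates
#' breeds by about `1/nAncestral`, so the Balding–Nichols divergence is
#' calibrated downwards to keep the realised pairwise Weir–Cockerham
#' F_ST at its targets. With `ld = NULL` founder gametes are sampled
#' independently per SNP (a pure frequency model, no within-breed LD)
#' and realised F_ST converges to the raw targets, including zero.
#'
#' @param map marker map ([markerMap()]).
#' @param nFounders named integer vector: founder animals per breed.
#' @param fst symmetric matrix of pairwise F_ST targets.
#' @param seed integer seed.
#' @param ancestral range of the ancestral allele-frequency distribution;
#'   must exclude 0 and 1 (monomorphic-everywhere models are rejected).
#' @param ld list with `nAncestral` (haplotype-pool size per breed) and
#'   `segSnps` (mean mosaic segment length, SNPs), or `NULL` for the
#'   LD-free frequency model.
#' @param freqOverride optional list `list(snp_index = c(S=, LR=, LW=))`
#'   forcing the founder allele frequency of selected SNPs (a focal
#'   mutation at prescribed breed frequencies). Under the haplotype-pool
#'   model the counted allele is placed on `round(nAncestral * p)`
#'   ancestral haplotypes, so its carriers share flanking background and
#'   the panel tags it through linkage disequilibrium; without the pool
#'   model it is allocated to `round(2 * nFounders * p)` gametes at
#'   random.
#' @return named list of [PhasedGenotypes-class] objects, one per breed;
#'   breed frequencies as attribute `"freqs"`.
#' @export
simulateFounderBreeds <- function(map, nFounders = c(S = 40, LR = 40, LW = 40),
                                  fst = defaultFstTargets(), seed = 1,
                                  ancestral = c(0.1, 0.9),
                                  ld = list(nAncestral = 20, segSnps = 30),
                                  freqOverride = NULL) {
  if (anyDuplicated(names(nFounders)))
    stop("duplicate breed ids", call. = FALSE)
  if (any(nFounders < 2)) stop("need at least 2 founders per breed")
  if (ancestral[1] <= 0 || ancestral[2] >= 1 || ancestral[1] >= ancestral[2])
    stop("ancestral frequency range must lie strictly inside (0,1)",
         call. = FALSE)
  breeds <- names(nFounders)
  Fb <- solveDivergence(fst[breeds, breeds, drop = FALSE])
  if (!is.null(ld)) {
    ## pool sampling adds ~1/nAncestral of drift per breed
    poolF <- 1 / ld$nAncestral
    Fb <- pmax((Fb - poolF) / (1 - poolF), 0)
  }
  m <- nrow(map)
  set.seed(seed)
  pAnc <- runif(m, ancestral[1], ancestral[2])
  freqs <- matrix(NA_real_, m, length(breeds), dimnames = list(map$id, breeds))
  for (b in breeds) {
    if (Fb[b] < 1e-12) {
      freqs[, b] <- pAnc
    } else {
      shape <- (1 - Fb[b]) / Fb[b]
      freqs[, b] <- rbeta(m, pAnc * shape, (1 - pAnc) * shape)
    }
  }
  out <- list()
  for (b in breeds) {
    n <- nFounders[[b]]
    if (is.null(ld)) {
      pat <- matrix(rbinom(n * m, 1L, rep(freqs[, b], each = n)), n, m)
      mat <- matrix(rbinom(n * m, 1L, rep(freqs[, b], each = n)), n, m)
      if (!is.null(freqOverride)) {
        for (j in names(freqOverride)) {
          jj <- as.integer(j)
          k <- round(2 * n * freqOverride[[j]][[b]])
          alle <- integer(2 * n)
          alle[sample.int(2 * n, k)] <- 1L
          pat[, jj] <- alle[seq_len(n)]
          mat[, jj] <- alle[n + seq_len(n)]
          freqs[jj, b] <- k / (2 * n)
        }
      }
    } else {
      pool <- matrix(rbinom(ld$nAncestral * m, 1L,
                            rep(freqs[, b], each = ld$nAncestral)),
                     ld$nAncestral, m)
      if (!is.null(freqOverride)) {
        for (j in names(freqOverride)) {
          jj <- as.integer(j)
          k <- round(ld$nAncestral * freqOverride[[j]][[b]])
          alle <- integer(ld$nAncestral)
          if (k > 0) alle[sample.int(ld$nAncestral, k)] <- 1L
          pool[, jj] <- alle
        }
      }
      gam <- matrix(0L, 2L * n, m)
      for (g in seq_len(2L * n)) {
        for (ch in unique(map$chrom)) {
          idx <- which(map$chrom == ch)
          newSeg <- c(TRUE, runif(length(idx) - 1) < 1 / ld$segSnps)
          segId <- cumsum(newSeg)
          anc <- sample.int(ld$nAncestral, max(segId), replace = TRUE)
          gam[g, idx] <- pool[cbind(anc[segId], idx)]
        }
      }
      pat <- gam[seq_len(n), , drop = FALSE]
      mat <- gam[n + seq_len(n), , drop = FALSE]
    }
    rownames(pat) <- rownames(mat) <- sprintf("%s_f%d", b, seq_len(n))
    out[[b]] <- phasedGenotypes(pat, mat, map)
  }
  attr(out, "freqs") <- freqs
  attr(out, "divergence") <- Fb
  out
}

#' Pairwise Weir–Cockerham F_ST between two samples
#'
#' Standard two-population Weir & Cockerham (1984) estimator (ratio of
#' averages over loci) from diploid genotypes.
#'
#' @param genoA,genoB [PhasedGenotypes-class] objects on the same map.
#' @return single numeric F_ST estimate.
#' @export
weirFst <- function(genoA, genoB) {
  dA <- genotypeDosage(genoA); dB <- genotypeDosage(genoB)
  n1 <- nrow(dA); n2 <- nrow(dB); r <- 2
  p1 <- colMeans(dA) / 2; p2 <- colMeans(dB) / 2
  h1 <- colMeans(dA == 1L); h2 <- colMeans(dB == 1L)
  nbar <- (n1 + n2) / 2
  nC <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nC *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  keep <- is.finite(a) & is.finite(b) & is.finite(cc)
  sum(a[keep]) / sum((a + b + cc)[keep])
}
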