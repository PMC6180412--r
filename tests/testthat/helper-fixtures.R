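## small constructed fixtures shared across tests

## phased genotypes from explicit haplotype matrices
pg <- function(pat, mat, chrom = "chr1", pos = NULL, ids = NULL,
               is_focal = FALSE, on_panel = TRUE) {
  pat <- rbind(pat); mat <- rbind(mat)
  m <- ncol(pat)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("a%d", seq_len(nrow(pat)))
  rownames(pat) <- rownames(mat) <- ids
  phasedGenotypes(pat, mat, markerMap(chrom, pos, is_focal = is_focal,
                                      on_panel = on_panel))
}

## origin matrix from character labels, recycled
om <- function(pat, mat) originMatrix(rbind(pat), rbind(mat))

## a tiny deterministic study used by several oracle tests
tinyStudy <- function(seed = 42, nFounders = 10, nPurebred = 12, nF1 = 6,
                      nCrossbred = 8, snps = 60, litterSize = 3) {
  simulateStudy(seed = seed,
                nFounders = c(S = nFounders, LR = nFounders,
                              LW = nFounders),
                nPurebred = c(S = nPurebred, LR = nPurebred,
                              LW = nPurebred),
                nF1 = nF1, nCrossbred = nCrossbred,
                litterSize = litterSize,
                nChrom = 1, snpsPerChrom = snps, chromLengthMb = 50)
}

## exhaustive gene-transmission oracle for the numerator relationship
## matrix: enumerates every equally likely inheritance configuration of a
## pedigree (feasible up to ~8 non-founders) and computes expected IBD
pathCountingA <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  nf <- which(!is.na(si) | !is.na(di))
  nbits <- 2L * length(nf)
  stopifnot(nbits <= 16L)
  Asum <- matrix(0, n, n)
  configs <- 2L^nbits
  for (cfg in 0:(configs - 1L)) {
    bits <- as.integer(intToBits(cfg))[seq_len(nbits)]
    ## allele labels: founder alleles unique; offspring copy from parents
    pat <- integer(n); mat <- integer(n)
    nxt <- 1L
    for (i in seq_len(n)) {
      k <- match(i, nf)
      if (is.na(k)) {
        pat[i] <- nxt; mat[i] <- nxt + 1L; nxt <- nxt + 2L
      } else {
        s <- si[i]; d <- di[i]
        pat[i] <- if (bits[2 * k - 1] == 0L) pat[s] else mat[s]
        mat[i] <- if (bits[2 * k] == 0L) pat[d] else mat[d]
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      Asum[i, j] <- Asum[i, j] +
        ((pat[i] == pat[j]) + (pat[i] == mat[j]) +
         (mat[i] == pat[j]) + (mat[i] == mat[j])) / 2
    }
  }
  Asum / configs
}

## blend each partial matrix towards the identity so both solution routes
## work with the same (positive-definite) covariance
blendGrms <- function(grms, ridge = 1e-6) {
  for (b in names(grms@breeds))
    grms@breeds[[b]]$G <- regularizePsd(grms@breeds[[b]]$G, ridge)
  grms
}

## independent oracle: joint BLUP by direct multivariate-normal
## conditioning, built with explicit covariance blocks (no MME)
conditionOracle <- function(md, vc) {
  n <- length(md$y)
  V <- matrix(0, n, n)
  covUy <- list()   # per breed: Cov([aPB; aCB], y)
  for (b in BREEDS) {
    G <- md$grms@breeds[[b]]$G
    gm <- md$genetic[[b]]
    q <- gm$q
    S <- vc$genetic[[b]]
    ## incidence of records on the two effect vectors
    Zpb <- matrix(0, n, q); Zpb[cbind(gm$rowsPB, gm$posPB)] <- 1
    Zcb <- matrix(0, n, q); Zcb[cbind(gm$rowsCB, gm$posCB)] <- 1
    V <- V + S[1, 1] * Zpb %*% G %*% t(Zpb) +
      S[2, 2] * Zcb %*% G %*% t(Zcb) +
      S[1, 2] * (Zpb %*% G %*% t(Zcb) + Zcb %*% G %*% t(Zpb))
    covUy[[b]] <- rbind(S[1, 1] * G %*% t(Zpb) + S[1, 2] * G %*% t(Zcb),
                        S[1, 2] * G %*% t(Zpb) + S[2, 2] * G %*% t(Zcb))
  }
  for (pp in names(md$litter))
    V <- V + vc$litter[[pp]] * tcrossprod(md$litter[[pp]])
  V <- V + diag(vc$residual[md$pop])
  Vi <- solve(V)
  X <- md$X
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% md$y)
  r <- md$y - X %*% beta
  u <- lapply(covUy, function(C) as.vector(C %*% Vi %*% r))
  list(beta = as.vector(beta), u = u)
}

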