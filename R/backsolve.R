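#' Back-solve SNP-allele effects from genomic breeding values
#'
#' Converts GEBVs to per-SNP allele effects through the identity
#' `alpha = F^-1 W' G^-1 a`, where `W` is the centred genotype matrix
#' that built the (partial) relationship matrix `G = W W' / F`. With an
#' unblended full-rank `G` this is the minimum-norm solution of
#' `a = W alpha`, so `W alpha` reproduces the GEBVs exactly.
#'
#' @param W centred genotype matrix (animals x SNPs).
#' @param G relationship (sub)matrix over the same animals; if `NULL`,
#'   rebuilt as `W W' / F`.
#' @param Fscale scaling factor `sum_j 2 p_j (1 - p_j)`.
#' @param gebv vector of breeding values, one per row of `W`.
#' @param pseudoInverse use a Moore–Penrose pseudo-inverse when `G` is
#'   singular (otherwise singular `G` is an error).
#' @return numeric vector of allele effects (one per SNP column) with the
#'   maximum absolute GEBV reconstruction deviation as attribute
#'   `"reconstruction_error"`.
#' @export
backsolveSnpEffects <- function(W, G = NULL, Fscale, gebv,
                                pseudoInverse = TRUE) {
  if (is.null(G)) G <- tcrossprod(W) / Fscale
  stopifnot_msg(nrow(W) == nrow(G) && length(gebv) == nrow(G),
                "W, G and gebv dimensions do not match")
  ## a numerically successful Cholesky on a near-singular G can still
  ## produce a useless inverse, so guard with the reciprocal condition
  singular <- rcond(symmpart(G)) < 1e-10
  Ginv <- if (singular) NULL
          else tryCatch(chol2inv(chol(symmpart(G))),
                        error = function(e) NULL)
  alpha <- NULL
  if (!is.null(Ginv))
    alpha <- as.vector(crossprod(W, Ginv %*% gebv)) / Fscale
  if (is.null(alpha)) {
    if (!pseudoInverse)
      stop("G is singular; set pseudoInverse = TRUE to use the ",
           "Moore-Penrose inverse", call. = FALSE)
    alpha <- as.vector(crossprod(W, MASS::ginv(symmpart(G)) %*% gebv)) /
      Fscale
  }
  names(alpha) <- colnames(W)
  attr(alpha, "reconstruction_error") <-
    max(abs(as.vector(W %*% alpha) - gebv))
  alpha
}

#' Reconstruct GEBVs from back-solved SNP effects
#'
#' @param W centred genotype matrix.
#' @param alpha SNP-effect vector.
#' @param gebv original GEBVs to compare against (optional).
#' @return list with `gebv` (reconstructed values) and `maxDeviation`
#'   (NA when no reference is given).
#' @export
reconstructGebv <- function(W, alpha, gebv = NULL) {
  rec <- as.vector(W %*% alpha)
  names(rec) <- rownames(W)
  list(gebv = rec,
       maxDeviation = if (is.null(gebv)) NA_real_ else max(abs(rec - gebv)))
}

#' Back-solve all breed-of-origin SNP effects from a fitted BOA model
#'
#' For each breed-of-origin: purebred-performance effects from the
#' purebred GEBVs with the purebred block of `G^(b)` and the diploid
#' centred matrix `W^b`, and crossbred-performance effects from the
#' origin-b partial GEBVs of the crossbred animals with the
#' crossbred-crossbred block and the haploid origin-content matrix.
#' The full assembled `G^(b)` (joint purebred + crossbred back-solve) is
#' available with `block = "assembled"`.
#'
#' @param fit [BoaFit-class] from [solveBoaMme()].
#' @param grms [PartialGRMSet-class] used for the fit.
#' @param block `"separate"` (default; purebred and crossbred blocks
#'   inverted separately, as printed) or `"assembled"`.
#' @return data.frame with columns `snp`, `origin`, `performance`,
#'   `effect`; reconstruction errors as attribute `"reconstruction"`.
#' @export
snpEffectsFromFit <- function(fit, grms, block = c("separate", "assembled")) {
  block <- match.arg(block)
  out <- list(); recon <- list()
  for (b in BREEDS) {
    el <- grms@breeds[[b]]
    npb <- length(el$purebredIds)
    if (block == "separate") {
      Gpp <- el$G[seq_len(npb), seq_len(npb)]
      Gcc <- el$G[npb + seq_along(el$crossbredIds),
                  npb + seq_along(el$crossbredIds)]
      aPB <- backsolveSnpEffects(el$W, Gpp, el$F, fit@gebv$purebred[[b]])
      aCB <- backsolveSnpEffects(el$Wcb, Gcc, el$F,
                                 fit@gebv$crossbred[el$crossbredIds, b])
    } else {
      Wfull <- rbind(el$W, el$Wcb)
      aPB <- backsolveSnpEffects(Wfull, el$G, el$F, fit@gebv$full[[b]]$PB)
      aCB <- backsolveSnpEffects(Wfull, el$G, el$F, fit@gebv$full[[b]]$CB)
    }
    out[[length(out) + 1L]] <- data.frame(
      snp = grms@snps, origin = b, performance = "purebred",
      effect = as.vector(aPB), stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      snp = grms@snps, origin = b, performance = "crossbred",
      effect = as.vector(aCB), stringsAsFactors = FALSE)
    recon[[b]] <- c(purebred = attr(aPB, "reconstruction_error"),
                    crossbred = attr(aCB, "reconstruction_error"))
  }
  res <- do.call(rbind, out)
  attr(res, "reconstruction") <- recon
  res
}
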