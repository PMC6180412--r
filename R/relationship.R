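#' Breed-specific allele frequencies of the counted allele
#'
#' For breed b, the frequency at SNP j is the number of counted (code-1)
#' alleles of breed-b origin — purebred breed-b alleles plus crossbred
#' alleles assigned origin b — divided by the total number of breed-b
#' alleles at that SNP. Crossbred alleles without an assigned origin enter
#' neither numerator nor denominator.
#'
#' @param purebred [PhasedGenotypes-class] of the breed's purebred animals.
#' @param cb [PhasedGenotypes-class] of the crossbred animals.
#' @param origins [OriginMatrix-class] for the crossbred animals.
#' @param breed breed label.
#' @return list with `p` (named frequency vector), `F` (scaling factor
#'   `sum_j 2 p_j (1 - p_j)`), `nAlleles` (denominators).
#' @export
breedAlleleFrequencies <- function(purebred, cb, origins, breed) {
  code <- match(breed, origins@levels)
  pbOnes <- colSums(purebred@pat) + colSums(purebred@mat)
  pbTot <- 2 * nAnimals(purebred)
  cbP <- !is.na(origins@pat) & origins@pat == code
  cbM <- !is.na(origins@mat) & origins@mat == code
  cbOnes <- colSums(cb@pat * cbP) + colSums(cb@mat * cbM)
  cbTot <- colSums(cbP) + colSums(cbM)
  denom <- pbTot + cbTot
  if (any(denom == 0))
    stop("zero breed-", breed, "-allele count at SNPs: ",
         paste(head(snpMap(cb)$id[denom == 0]), collapse = ", "),
         " (filter these upstream)", call. = FALSE)
  p <- (pbOnes + cbOnes) / denom
  list(p = setNames(p, snpMap(cb)$id), F = sum(2 * p * (1 - p)),
       nAlleles = denom)
}

## centred crossbred origin-b allele content: (allele - p) summed over the
## gametes assigned origin b; alleles with missing origin contribute 0.
## In the S x (LR x LW) design at most one gamete per animal has origin b,
## so the uncentred content is the 0/1 coding of the model.
originContent <- function(cb, origins, breed, p) {
  code <- match(breed, origins@levels)
  cp <- !is.na(origins@pat) & origins@pat == code
  cm <- !is.na(origins@mat) & origins@mat == code
  W <- cp * sweep(cb@pat, 2, p) + cm * sweep(cb@mat, 2, p)
  rownames(W) <- animalIds(cb)
  W
}

#' Build the three breed-specific partial genomic relationship matrices
#'
#' VanRaden method-1 partial relationship matrices per breed-of-origin.
#' For breed b, purebred rows are centred diploid dosages
#' `M^b - 2 p^b` and crossbred rows are centred haploid origin-b allele
#' content `M^CB,b - p^b` with alleles of missing origin contributing
#' exactly zero; every block is scaled by `F_b = sum_j 2 p_j (1 - p_j)`.
#' All three matrices are built on one common SNP set.
#'
#' @param purebreds named list of purebred [PhasedGenotypes-class] per
#'   breed.
#' @param cb crossbred [PhasedGenotypes-class].
#' @param origins crossbred [OriginMatrix-class].
#' @param snps SNP ids (or index) of the common kept SNP set; default all
#'   panel SNPs of the crossbred map.
#' @return A [PartialGRMSet-class].
#' @export
buildPartialGRMSet <- function(purebreds, cb, origins, snps = NULL) {
  map <- snpMap(cb)
  if (is.null(snps)) snps <- map$id[map$on_panel]
  si <- if (is.character(snps)) match(snps, map$id) else snps
  cbS <- subsetGenotypes(cb, NULL, si)
  orS <- subsetOrigins(origins, NULL, si)
  breeds <- list()
  for (b in BREEDS) {
    pbS <- subsetGenotypes(purebreds[[b]], NULL, si)
    fr <- breedAlleleFrequencies(pbS, cbS, orS, b)
    W <- sweep(genotypeDosage(pbS), 2, 2 * fr$p)
    Wcb <- originContent(cbS, orS, b, fr$p)
    Gpp <- tcrossprod(W) / fr$F
    Gpc <- tcrossprod(W, Wcb) / fr$F
    Gcc <- tcrossprod(Wcb) / fr$F
    G <- rbind(cbind(Gpp, Gpc), cbind(t(Gpc), Gcc))
    ids <- c(animalIds(pbS), animalIds(cbS))
    dimnames(G) <- list(ids, ids)
    breeds[[b]] <- list(G = symmpart(G), W = W, Wcb = Wcb, p = fr$p,
                        F = fr$F, purebredIds = animalIds(pbS),
                        crossbredIds = animalIds(cbS))
  }
  new("PartialGRMSet", breeds = breeds, snps = map$id[si])
}

#' Blend a relationship matrix towards the identity
#'
#' `G' = (1 - ridge) G + ridge * mean(diag(G)) I`, which bounds the
#' smallest eigenvalue below by `ridge * mean(diag(G))` and leaves the
#' average diagonal unchanged. `ridge = 0` returns `G` untouched.
#'
#' @param G symmetric matrix.
#' @param ridge blending weight in `[0, 1]`.
#' @return blended matrix.
#' @export
regularizePsd <- function(G, ridge = 1e-6) {
  if (ridge == 0) return(G)
  d <- mean(diag(G))
  (1 - ridge) * G + diag(ridge * d, nrow(G))
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Recursive (tabular) construction of Wright's numerator relationship
#' matrix A with inbreeding: `A[i,i] = 1 + 0.5 A[sire, dam]` and
#' `A[i,j] = 0.5 (A[j, sire] + A[j, dam])`, unknown parents contributing
#' zero.
#'
#' @param ped pedigree data.frame with `id`, `sire`, `dam`, parents before
#'   offspring.
#' @return numeric matrix with animal ids as dimnames.
#' @export
pedigreeNumeratorMatrix <- function(ped) {
  validatePedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (is.na(s)) 0 else A[j, s]) +
                   (if (is.na(d)) 0 else A[j, d]))
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + 0.5 * (if (is.na(s) || is.na(d)) 0 else A[s, d])
  }
  A
}
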