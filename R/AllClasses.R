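#' Class "PhasedGenotypes": phased biallelic genotypes
#'
#' Holds the two gametes of every animal at every SNP as 0/1 allele codes
#' (1 = counted allele), together with the marker map. The paternal gamete
#' is the one inherited from the sire. Phase is consumed, not estimated:
#' simulated data carry truth phase and real data must arrive phased.
#'
#' @slot pat integer matrix, animals x SNPs, paternal allele codes (0/1).
#' @slot mat integer matrix, animals x SNPs, maternal allele codes (0/1).
#' @slot map data.frame marker map with columns `chrom`, `pos`, `id`,
#'   `is_focal`, `on_panel`; positions are 1-based bp, strictly increasing
#'   within chromosome.
#' @export
setClass("PhasedGenotypes",
  representation(pat = "matrix", mat = "matrix", map = "data.frame"))

setValidity("PhasedGenotypes", function(object) {
  msg <- character()
  if (!identical(dim(object@pat), dim(object@mat)))
    msg <- c(msg, "paternal and maternal matrices differ in dimension")
  if (ncol(object@pat) != nrow(object@map))
    msg <- c(msg, "number of SNP columns does not match the marker map")
  vals <- c(object@pat, object@mat)
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "allele codes must be 0 or 1")
  if (is.null(rownames(object@pat)))
    msg <- c(msg, "animal ids (rownames) are required")
  mm <- validateMarkerMap(object@map)
  if (!isTRUE(mm)) msg <- c(msg, mm)
  if (length(msg)) msg else TRUE
})

#' Class "OriginMatrix": breed-of-origin labels per allele
#'
#' For each crossbred animal, SNP and gamete, the parental breed the allele
#' was inherited from, coded as an integer index into `levels(x)`
#' (`S`, `LR`, `LW`), with `NA` for alleles without an assigned origin.
#'
#' @slot pat integer matrix (animals x SNPs) of origin codes, paternal side.
#' @slot mat integer matrix, maternal side.
#' @slot levels character vector of origin labels the codes index.
#' @export
setClass("OriginMatrix",
  representation(pat = "matrix", mat = "matrix", levels = "character"))

setValidity("OriginMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@pat), dim(object@mat)))
    msg <- c(msg, "paternal and maternal matrices differ in dimension")
  k <- length(object@levels)
  vals <- c(object@pat, object@mat)
  vals <- vals[!is.na(vals)]
  if (length(vals) && (any(vals < 1L) || any(vals > k)))
    msg <- c(msg, "origin codes outside the level set")
  if (length(msg)) msg else TRUE
})

#' Class "PartialGRMSet": breed-specific partial genomic relationships
#'
#' One VanRaden-type partial relationship matrix per breed-of-origin,
#' assembled over that breed's purebred animals plus all crossbred animals,
#' with the centred genotype matrices, the breed-specific allele frequencies
#' and the scaling factor that built it. Purebred rows are centred on twice
#' the breed frequency (diploid 0/1/2 content); crossbred rows hold haploid
#' origin-coded content (0/1) centred on the frequency itself, and alleles
#' with no assigned origin contribute exactly zero.
#'
#' @slot breeds named list (one element per breed) with components `G`
#'   (assembled partial matrix), `W` (centred purebred matrix),
#'   `Wcb` (centred crossbred origin-content matrix), `p` (allele
#'   frequencies), `F` (scaling factor), `purebredIds`, `crossbredIds`.
#' @slot snps character vector of SNP ids common to all three matrices.
#' @export
setClass("PartialGRMSet", representation(breeds = "list", snps = "character"))

setValidity("PartialGRMSet", function(object) {
  msg <- character()
  for (b in names(object@breeds)) {
    el <- object@breeds[[b]]
    need <- c("G", "W", "Wcb", "p", "F", "purebredIds", "crossbredIds")
    if (!all(need %in% names(el))) {
      msg <- c(msg, sprintf("breed '%s' misses components", b)); next
    }
    if (el$F <= 0) msg <- c(msg, sprintf("scaling factor F for '%s' not > 0", b))
    if (max(abs(el$G - t(el$G))) > 1e-8)
      msg <- c(msg, sprintf("partial matrix for '%s' not symmetric", b))
  }
  if (length(msg)) msg else TRUE
})

#' Class "BoaFit": fitted breed-of-origin GBLUP model
#'
#' Result of fitting the multi-trait animal model with three partial
#' relationship matrices: variance components, genomic breeding values for
#' purebred performance (purebred animals) and the per-origin partial
#' breeding values for crossbred performance (crossbred animals), fixed
#' effect solutions and convergence diagnostics.
#'
#' @slot vc list of variance components (per-breed 2x2 genetic covariance,
#'   litter and residual variances) with standard errors where estimated.
#' @slot gebv list with `purebred` (named vectors per breed) and
#'   `crossbred` (matrix of per-origin partial GEBVs plus their total).
#' @slot fixef list of fixed-effect solutions per record population.
#' @slot details list: convergence info, problem sizes, ridge used.
#' @export
setClass("BoaFit",
  representation(vc = "list", gebv = "list", fixef = "list", details = "list"))

setMethod("show", "PhasedGenotypes", function(object) {
  cat(sprintf("PhasedGenotypes: %d animals x %d SNPs on %d chromosome(s)\n",
              nrow(object@pat), ncol(object@pat),
              length(unique(object@map$chrom))))
})

setMethod("show", "OriginMatrix", function(object) {
  tot <- 2L * length(object@pat)
  ass <- sum(!is.na(object@pat)) + sum(!is.na(object@mat))
  cat(sprintf("OriginMatrix: %d animals x %d SNPs; %.1f%% of alleles assigned\n",
              nrow(object@pat), ncol(object@pat),
              if (tot) 100 * ass / tot else NA_real_))
})

setMethod("show", "PartialGRMSet", function(object) {
  cat("PartialGRMSet over", length(object@snps), "SNPs\n")
  for (b in names(object@breeds)) {
    el <- object@breeds[[b]]
    cat(sprintf("  G^(%s): %d purebred + %d crossbred animals, F = %.2f\n",
                b, length(el$purebredIds), length(el$crossbredIds), el$F))
  }
})

setMethod("show", "BoaFit", function(object) {
  cat("BoaFit:", object@details$model %||% "BOA model", "\n")
  if (!is.null(object@vc$genetic)) {
    for (b in names(object@vc$genetic)) {
      S <- object@vc$genetic[[b]]
      cat(sprintf("  %s: var(PB) = %.4f, var(CB) = %.4f, cov = %.4f\n",
                  b, S[1, 1], S[2, 2], S[1, 2]))
    }
  }
  if (isTRUE(object@details$converged)) cat("  REML converged in",
      object@details$iterations, "iterations\n")
})
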