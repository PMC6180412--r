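#' Construct a marker map
#'
#' @param chrom chromosome labels.
#' @param pos 1-based bp positions, strictly increasing within chromosome.
#' @param id SNP ids (default `snp1..snpN`).
#' @param is_focal logical flag for the single focal causal mutation.
#' @param on_panel logical; `FALSE` for markers (such as the focal mutation)
#'   withheld from the analysis panel so that the panel tags them only
#'   through linkage disequilibrium.
#' @return data.frame with columns `chrom`, `pos`, `id`, `is_focal`,
#'   `on_panel`.
#' @export
markerMap <- function(chrom, pos, id = NULL,
                      is_focal = FALSE, on_panel = TRUE) {
  n <- length(pos)
  map <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    id = if (is.null(id)) paste0("snp", seq_len(n)) else as.character(id),
    is_focal = rep_len(is_focal, n),
    on_panel = rep_len(on_panel, n),
    stringsAsFactors = FALSE)
  v <- validateMarkerMap(map)
  if (!isTRUE(v)) stop(v, call. = FALSE)
  map
}

validateMarkerMap <- function(map) {
  need <- c("chrom", "pos", "id", "is_focal", "on_panel")
  if (!all(need %in% names(map))) return("marker map misses required columns")
  if (any(map$pos < 1L)) return("positions must be >= 1 (1-based)")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      return(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  if (sum(map$is_focal) > 1L) return("at most one focal SNP is allowed")
  TRUE
}

#' Construct a PhasedGenotypes object
#'
#' @param pat,mat integer matrices (animals x SNPs) of 0/1 allele codes for
#'   the paternal and maternal gamete; rownames are animal ids.
#' @param map marker map as returned by [markerMap()].
#' @return A [PhasedGenotypes-class] object.
#' @export
phasedGenotypes <- function(pat, mat, map) {
  storage.mode(pat) <- "integer"
  storage.mode(mat) <- "integer"
  colnames(pat) <- colnames(mat) <- map$id
  new("PhasedGenotypes", pat = pat, mat = mat, map = map)
}

#' Construct an OriginMatrix from character labels
#'
#' @param pat,mat character matrices of origin labels (`"S"`, `"LR"`,
#'   `"LW"`) or `NA` for missing; or integer code matrices.
#' @param levels origin label set.
#' @return An [OriginMatrix-class] object.
#' @export
originMatrix <- function(pat, mat, levels = BREEDS) {
  enc <- function(m) {
    if (is.character(m)) {
      out <- matrix(match(m, levels), nrow(m), ncol(m),
                    dimnames = dimnames(m))
      if (any(!is.na(m) & is.na(out)))
        stop("unknown origin label", call. = FALSE)
      out
    } else {
      storage.mode(m) <- "integer"
      m
    }
  }
  new("OriginMatrix", pat = enc(pat), mat = enc(mat), levels = levels)
}

#' @rdname phasedGenotypes
#' @param x object.
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
#' @rdname phasedGenotypes
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname phasedGenotypes
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @rdname phasedGenotypes
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' Extract one gamete matrix
#' @param x a PhasedGenotypes or OriginMatrix.
#' @param side `"pat"` or `"mat"`.
#' @export
setGeneric("gamete", function(x, side = c("pat", "mat"))
  standardGeneric("gamete"))

setMethod("nAnimals", "PhasedGenotypes", function(x) nrow(x@pat))
setMethod("nSnps", "PhasedGenotypes", function(x) ncol(x@pat))
setMethod("animalIds", "PhasedGenotypes", function(x) rownames(x@pat))
setMethod("snpMap", "PhasedGenotypes", function(x) x@map)
setMethod("gamete", "PhasedGenotypes", function(x, side = c("pat", "mat")) {
  side <- match.arg(side)
  slot(x, side)
})

setMethod("nAnimals", "OriginMatrix", function(x) nrow(x@pat))
setMethod("nSnps", "OriginMatrix", function(x) ncol(x@pat))
setMethod("animalIds", "OriginMatrix", function(x) rownames(x@pat))
setMethod("gamete", "OriginMatrix", function(x, side = c("pat", "mat")) {
  side <- match.arg(side)
  slot(x, side)
})

#' Origin labels as character matrices
#' @param x an OriginMatrix.
#' @return list with `pat` and `mat` character matrices.
#' @export
originLabels <- function(x) {
  dec <- function(m) {
    out <- matrix(x@levels[m], nrow(m), ncol(m), dimnames = dimnames(m))
    out
  }
  list(pat = dec(x@pat), mat = dec(x@mat))
}

#' Diploid genotype dosages (0/1/2 counted-allele counts)
#' @param x a PhasedGenotypes object.
#' @param panelOnly drop markers flagged `on_panel = FALSE`.
#' @return integer matrix animals x SNPs.
#' @export
genotypeDosage <- function(x, panelOnly = FALSE) {
  d <- x@pat + x@mat
  if (panelOnly) d <- d[, x@map$on_panel, drop = FALSE]
  d
}

#' Subset a PhasedGenotypes object
#' @param x PhasedGenotypes.
#' @param animals,snps index vectors (ids, logical or integer).
#' @return PhasedGenotypes.
#' @export
subsetGenotypes <- function(x, animals = NULL, snps = NULL) {
  ai <- if (is.null(animals)) seq_len(nrow(x@pat)) else animals
  si <- if (is.null(snps)) seq_len(ncol(x@pat)) else snps
  if (is.character(si)) si <- match(si, x@map$id)
  map <- x@map[si, , drop = FALSE]
  rownames(map) <- NULL
  phasedGenotypes(x@pat[ai, si, drop = FALSE],
                  x@mat[ai, si, drop = FALSE], map)
}

#' Subset an OriginMatrix
#' @param x OriginMatrix.
#' @param animals,snps index vectors.
#' @return OriginMatrix.
#' @export
subsetOrigins <- function(x, animals = NULL, snps = NULL) {
  ai <- if (is.null(animals)) seq_len(nrow(x@pat)) else animals
  si <- if (is.null(snps)) seq_len(ncol(x@pat)) else snps
  new("OriginMatrix", pat = x@pat[ai, si, drop = FALSE],
      mat = x@mat[ai, si, drop = FALSE], levels = x@levels)
}
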