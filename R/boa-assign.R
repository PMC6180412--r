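#' Window specification for the haplotype library
#'
#' Each chromosome is tiled by cores of every requested length, once
#' anchored at the chromosome start ("not offset") and once shifted by
#' half a core ("offset", creating 50% overlaps), so that every allele is
#' seen in `2 * length(lengths)` haplotype views of variable length. The
#' default of nine geometrically spaced lengths gives the 18 views used
#' for dense panels; desk-scale analyses pass shorter length sets
#' matched to their SNP density.
#'
#' @param lengths core lengths in SNPs (each >= 2).
#' @param offsets use both anchoring modes (fixed; kept for clarity).
#' @return object of class `"windowSpec"`.
#' @export
windowSpec <- function(lengths = round(exp(seq(log(25), log(400),
                                               length.out = 9)))) {
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 2)) stop("core lengths must be >= 2", call. = FALSE)
  structure(list(lengths = lengths, viewsPerAllele = 2L * length(lengths)),
            class = "windowSpec")
}

## core boundaries for one chromosome with nIdx SNPs: tail windows shorter
## than 2 SNPs are merged into the preceding core
coreStarts <- function(nIdx, L, offset) {
  starts <- if (offset) c(1L, seq.int(L %/% 2 + 1L, nIdx, by = L))
            else seq.int(1L, nIdx, by = L)
  starts <- starts[starts <= nIdx]
  ends <- c(starts[-1] - 1L, nIdx)
  keep <- ends >= starts
  starts <- starts[keep]; ends <- ends[keep]
  nlast <- length(starts)
  if (nlast > 1 && ends[nlast] - starts[nlast] < 1L) {
    ends[nlast - 1] <- ends[nlast]
    starts <- starts[-nlast]; ends <- ends[-nlast]
  }
  cbind(start = starts, end = ends)
}

hapStrings <- function(H, cols) {
  do.call(paste0, as.data.frame(H[, cols, drop = FALSE]))
}

#' Build the purebred haplotype library
#'
#' For every window view, every distinct haplotype observed among the
#' purebred gametes is counted per breed; a haplotype is assigned the
#' breed holding at least `purity` of its copies, otherwise it stays
#' unassigned.
#'
#' @param purebreds named list of purebred [PhasedGenotypes-class] per
#'   breed (typically including the founder animals).
#' @param windows [windowSpec()].
#' @param purity minimum breed share of copies for assignment.
#' @return object of class `"haplotypeLibrary"`: per view window the SNP
#'   columns, the distinct haplotype keys and their assigned breed code.
#' @export
buildHaplotypeLibrary <- function(purebreds, windows = windowSpec(),
                                  purity = 0.80) {
  map <- snpMap(purebreds[[1]])
  breeds <- names(purebreds)
  H <- do.call(rbind, lapply(breeds, function(b)
    rbind(purebreds[[b]]@pat, purebreds[[b]]@mat)))
  breedOf <- rep(match(breeds, BREEDS),
                 times = vapply(purebreds, function(g) 2L * nAnimals(g), 0L))
  entries <- list()
  for (L in windows$lengths) {
    for (off in c(FALSE, TRUE)) {
      for (ch in unique(map$chrom)) {
        idx <- which(map$chrom == ch)
        if (L > length(idx))
          stop("core length ", L, " exceeds chromosome ", ch,
               " (", length(idx), " SNPs)", call. = FALSE)
        cs <- coreStarts(length(idx), L, off)
        for (w in seq_len(nrow(cs))) {
          cols <- idx[cs[w, "start"]:cs[w, "end"]]
          str <- hapStrings(H, cols)
          keys <- unique(str)
          ki <- match(str, keys)
          cnt <- matrix(0L, length(keys), 3)
          for (bc in unique(breedOf)) {
            t <- tabulate(ki[breedOf == bc], nbins = length(keys))
            cnt[, bc] <- t
          }
          tot <- rowSums(cnt)
          share <- cnt / tot
          best <- max.col(share, ties.method = "first")
          assign <- ifelse(share[cbind(seq_along(best), best)] >= purity,
                           best, NA_integer_)
          entries[[length(entries) + 1L]] <-
            list(cols = cols, keys = keys, assign = assign)
        }
      }
    }
  }
  structure(list(entries = entries, windows = windows, purity = purity,
                 nSnps = nrow(map)), class = "haplotypeLibrary")
}

#' Assign a breed-of-origin to every crossbred allele
#'
#' Each allele of each crossbred gamete collects one vote per window view
#' whose library haplotype matches and carries a breed assignment. Votes
#' incompatible with the cross design (non-S on the paternal side of an
#' S x (LR x LW) cross; S on the maternal side) are discarded. The
#' majority of the remaining votes assigns the origin; no votes or a tie
#' leave the allele missing.
#'
#' @param cb crossbred [PhasedGenotypes-class].
#' @param library [buildHaplotypeLibrary()] result built on the same map.
#' @param crossDesign allowed origins per gamete side.
#' @return [OriginMatrix-class] for the crossbred animals.
#' @export
assignBreedOfOrigin <- function(cb, library,
                                crossDesign = list(pat = "S",
                                                   mat = c("LR", "LW"))) {
  stopifnot_msg(library$nSnps == nSnps(cb),
                "library and genotypes disagree on the SNP set")
  n <- nAnimals(cb); m <- nSnps(cb)
  out <- list()
  for (side in c("pat", "mat")) {
    H <- slot(cb, side)
    allowed <- match(crossDesign[[side]], BREEDS)
    votes <- lapply(1:3, function(i) matrix(0L, n, m))
    for (e in library$entries) {
      str <- hapStrings(H, e$cols)
      br <- e$assign[match(str, e$keys)]
      for (bc in allowed) {
        rows <- which(!is.na(br) & br == bc)
        if (length(rows))
          votes[[bc]][rows, e$cols] <- votes[[bc]][rows, e$cols] + 1L
      }
    }
    vmax <- pmax(votes[[1]], votes[[2]], votes[[3]])
    nbest <- (votes[[1]] == vmax) + (votes[[2]] == vmax) +
      (votes[[3]] == vmax)
    origin <- matrix(NA_integer_, n, m, dimnames = list(animalIds(cb), NULL))
    for (bc in 1:3) {
      sel <- vmax > 0L & nbest == 1L & votes[[bc]] == vmax
      origin[sel] <- bc
    }
    out[[side]] <- origin
  }
  new("OriginMatrix", pat = out$pat, mat = out$mat, levels = BREEDS)
}

#' Quality filters on breed-of-origin assignments
#'
#' Applies, in order: (1) remove SNPs whose paternal or maternal allele
#' was assigned an origin in less than `snpRate` of the crossbred
#' animals; (2) remove crossbred animals with less than `animalRate` of
#' their allele slots assigned over the kept SNPs; (3) remove SNPs where
#' the counted (code-1) allele is observed fewer than `minCopies` times
#' among the alleles of any breed-of-origin. Raising any threshold can
#' only shrink the kept sets.
#'
#' @param origins crossbred [OriginMatrix-class].
#' @param geno crossbred [PhasedGenotypes-class] (needed for the
#'   minimum-copies rule; skip the rule with `minCopies = 0`).
#' @param snpRate,animalRate,minCopies thresholds.
#' @param countedAllele allele whose copies are counted (default 1).
#' @return list with `origins` (filtered), `keptSnps` (column indices into
#'   the input SNP set), `keptAnimals` (ids), and per-filter removal
#'   counts in `stats`.
#' @export
applyAssignmentFilters <- function(origins, geno = NULL, snpRate = 0.90,
                                   animalRate = 0.90, minCopies = 5,
                                   countedAllele = 1L) {
  patRate <- colMeans(!is.na(origins@pat))
  matRate <- colMeans(!is.na(origins@mat))
  keepSnp <- patRate >= snpRate & matRate >= snpRate
  s1 <- sum(!keepSnp)
  sub1 <- subsetOrigins(origins, NULL, which(keepSnp))
  assignedFrac <- (rowSums(!is.na(sub1@pat)) + rowSums(!is.na(sub1@mat))) /
    (2 * ncol(sub1@pat))
  keepAnimal <- assignedFrac >= animalRate
  s2 <- sum(!keepAnimal)
  sub2 <- subsetOrigins(sub1, which(keepAnimal), NULL)
  keepIdx <- which(keepSnp)
  if (minCopies > 0) {
    stopifnot_msg(!is.null(geno), "minimum-copies rule needs genotypes")
    g2 <- subsetGenotypes(geno, which(keepAnimal), keepIdx)
    ok <- rep(TRUE, length(keepIdx))
    for (bc in seq_along(origins@levels)) {
      cp <- !is.na(sub2@pat) & sub2@pat == bc
      cm <- !is.na(sub2@mat) & sub2@mat == bc
      cnt <- colSums((g2@pat == countedAllele) * cp) +
        colSums((g2@mat == countedAllele) * cm)
      ok <- ok & cnt >= minCopies
    }
    s3 <- sum(!ok)
    sub2 <- subsetOrigins(sub2, NULL, which(ok))
    keepIdx <- keepIdx[ok]
  } else s3 <- 0L
  if (!length(keepIdx))
    stop("all SNPs removed by assignment filters; check thresholds and ",
         "assignment quality", call. = FALSE)
  list(origins = sub2,
       keptSnps = keepIdx,
       keptAnimals = animalIds(origins)[keepAnimal],
       stats = c(snpRateRemoved = s1, animalRemoved = s2,
                 minCopiesRemoved = s3, keptSnps = length(keepIdx)))
}

#' Accuracy of breed-of-origin assignment against simulation truth
#'
#' @param origins assigned [OriginMatrix-class].
#' @param truth true [OriginMatrix-class] on the same animals and SNPs.
#' @return list with `assigned` (fraction of alleles assigned),
#'   `accuracy` (fraction of assigned alleles whose origin matches the
#'   truth; `NULL` when nothing is assigned) and `perOrigin` accuracy by
#'   true origin.
#' @export
assignmentAccuracy <- function(origins, truth) {
  a <- c(origins@pat, origins@mat)
  t <- c(truth@pat, truth@mat)
  assigned <- mean(!is.na(a))
  if (!any(!is.na(a)))
    return(list(assigned = 0, accuracy = NULL, perOrigin = NULL))
  ok <- !is.na(a)
  acc <- mean(a[ok] == t[ok])
  per <- vapply(seq_along(origins@levels), function(bc) {
    sel <- ok & t == bc
    if (!any(sel)) NA_real_ else mean(a[sel] == bc)
  }, 0)
  names(per) <- origins@levels
  list(assigned = assigned, accuracy = acc, perOrigin = per)
}
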