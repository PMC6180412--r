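#' Build a three-way terminal-cross pedigree
#'
#' Founders of the S, LR and LW lines, one generation of purebred
#' offspring per line, F1 (LR sire x LW dam) females, and the terminal
#' crossbred generation (S sire x F1 dam). Offspring are produced in
#' full-sib litters of `litterSize` so that a common-litter environmental
#' effect is estimable.
#'
#' @param nFounders named vector of founders per breed (even; half used as
#'   sires, half as dams).
#' @param nPurebred named vector of purebred offspring per breed.
#' @param nF1 number of F1 dams.
#' @param nCrossbred number of terminal crossbred animals.
#' @param litterSize full-sib litter size.
#' @param seed integer seed for mate allocation.
#' @return data.frame with columns `id`, `sire`, `dam` (`NA` for
#'   founders), `group` in `{S, LR, LW, F1, CB}`, `litter`, `sex`;
#'   parents always precede offspring.
#' @export
makeCrossPedigree <- function(nFounders = c(S = 40, LR = 40, LW = 40),
                              nPurebred = c(S = 300, LR = 300, LW = 300),
                              nF1 = 120, nCrossbred = 600,
                              litterSize = 6, seed = 1) {
  set.seed(seed)
  ped <- list()
  founders <- list()
  for (b in BREEDS) {
    n <- nFounders[[b]]
    ids <- sprintf("%s_f%d", b, seq_len(n))
    founders[[b]] <- list(sires = ids[seq_len(n %/% 2)],
                          dams = ids[(n %/% 2 + 1):n])
    ped[[length(ped) + 1L]] <- data.frame(
      id = ids, sire = NA_character_, dam = NA_character_,
      group = b, litter = NA_character_,
      sex = rep(c("M", "F"), c(n %/% 2, n - n %/% 2)),
      stringsAsFactors = FALSE)
  }
  dropLitters <- function(n, sires, dams, prefix, group) {
    nlit <- ceiling(n / litterSize)
    sire <- sample(sires, nlit, replace = TRUE)
    dam <- sample(dams, nlit, replace = TRUE)
    lit <- rep(seq_len(nlit), each = litterSize)[seq_len(n)]
    data.frame(
      id = sprintf("%s%d", prefix, seq_len(n)),
      sire = sire[lit], dam = dam[lit], group = group,
      litter = sprintf("%s_lit%d", prefix, lit),
      sex = sample(c("M", "F"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  pb <- list()
  for (b in BREEDS) {
    pb[[b]] <- dropLitters(nPurebred[[b]], founders[[b]]$sires,
                           founders[[b]]$dams, paste0(b, "_p"), b)
    ped[[length(ped) + 1L]] <- pb[[b]]
  }
  f1 <- dropLitters(nF1,
                    c(founders$LR$sires, pb$LR$id[pb$LR$sex == "M"]),
                    c(founders$LW$dams, pb$LW$id[pb$LW$sex == "F"]),
                    "F1_", "F1")
  f1$sex <- "F"
  ped[[length(ped) + 1L]] <- f1
  sSires <- c(founders$S$sires, pb$S$id[pb$S$sex == "M"])
  cb <- dropLitters(nCrossbred, sSires, f1$id, "CB_", "CB")
  ped[[length(ped) + 1L]] <- cb
  out <- do.call(rbind, ped)
  rownames(out) <- NULL
  validatePedigree(out)
  out
}

validatePedigree <- function(ped) {
  stopifnot_msg(all(c("id", "sire", "dam", "group") %in% names(ped)),
                "pedigree misses required columns")
  stopifnot_msg(!anyDuplicated(ped$id), "duplicate animal ids in pedigree")
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  for (col in c("sire", "dam")) {
    par <- ped[[col]]
    known <- !is.na(par)
    if (any(!par[known] %in% ped$id))
      stop("pedigree refers to unknown ", col, call. = FALSE)
    if (any(pos[par[known]] >= which(known)))
      stop("parents must precede offspring", call. = FALSE)
  }
  invisible(TRUE)
}

## one meiosis: per SNP, which of the parent's two gametes (1 = paternal,
## 2 = maternal) transmits, with Poisson crossover counts under Haldane
meiose <- function(map, cMperMb) {
  pick <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    spanMb <- (max(pos) - min(pos)) / 1e6
    ncx <- if (cMperMb > 0) rpois(1L, spanMb * cMperMb / 100) else 0L
    start <- sample.int(2L, 1L)
    if (ncx == 0L) {
      pick[idx] <- start
    } else {
      cx <- sort(runif(ncx, min(pos), max(pos)))
      nBefore <- findInterval(pos, cx)
      pick[idx] <- 1L + (start - 1L + nBefore) %% 2L
    }
  }
  pick
}

#' Drop founder genomes through a pedigree
#'
#' Standard gene dropping: every non-founder gamete is a recombinant
#' mosaic of the parent's two gametes, with a Poisson number of crossovers
#' per chromosome under a Haldane (no-interference) map of `cMperMb`
#' cM/Mb. The true breed-of-origin of every allele is carried along from
#' the founder breed, providing truth labels for validating breed-of-origin
#' assignment.
#'
#' @param founders named list of founder [PhasedGenotypes-class] per breed
#'   (as from [simulateFounderBreeds()]).
#' @param ped pedigree data.frame ([makeCrossPedigree()]).
#' @param map marker map shared by all founders.
#' @param seed integer seed.
#' @param cMperMb genetic map density; 0 disables recombination.
#' @return list with `geno` ([PhasedGenotypes-class] over all pedigree
#'   animals) and `origins` ([OriginMatrix-class] of true breed-of-origin
#'   labels for every animal and gamete).
#' @export
geneDropPedigree <- function(founders, ped, map, seed = 1, cMperMb = 1) {
  set.seed(seed)
  n <- nrow(ped); m <- nrow(map)
  pat <- matrix(NA_integer_, n, m, dimnames = list(ped$id, map$id))
  mat <- pat
  oPat <- pat; oMat <- pat
  for (i in seq_len(n)) {
    id <- ped$id[i]
    if (is.na(ped$sire[i]) || is.na(ped$dam[i])) {
      b <- ped$group[i]
      fg <- founders[[b]]
      if (is.null(fg) || !(id %in% animalIds(fg)))
        stop("missing founder genotypes for ", id, call. = FALSE)
      k <- match(id, animalIds(fg))
      pat[i, ] <- fg@pat[k, ]; mat[i, ] <- fg@mat[k, ]
      oPat[i, ] <- match(b, BREEDS); oMat[i, ] <- match(b, BREEDS)
    } else {
      si <- match(ped$sire[i], ped$id); di <- match(ped$dam[i], ped$id)
      pk <- meiose(map, cMperMb)
      pat[i, ] <- ifelse(pk == 1L, pat[si, ], mat[si, ])
      oPat[i, ] <- ifelse(pk == 1L, oPat[si, ], oMat[si, ])
      mk <- meiose(map, cMperMb)
      mat[i, ] <- ifelse(mk == 1L, pat[di, ], mat[di, ])
      oMat[i, ] <- ifelse(mk == 1L, oPat[di, ], oMat[di, ])
    }
  }
  list(geno = phasedGenotypes(pat, mat, map),
       origins = new("OriginMatrix", pat = oPat, mat = oMat, levels = BREEDS))
}
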