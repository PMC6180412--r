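test_that("breed allele frequencies pool purebred and origin alleles", {
  ## two S purebreds with dosages {2, 1} plus one crossbred whose
  ## S-origin (paternal) allele is 1: p = (3 + 1) / (4 + 1) = 0.8
  pb <- pg(rbind(1L, 1L), rbind(1L, 0L), ids = c("p1", "p2"))
  cb <- pg(rbind(1L), rbind(0L), ids = "cb1")
  orr <- om(rbind("S"), rbind(NA_character_))
  fr <- breedAlleleFrequencies(pb, cb, orr, "S")
  expect_equal(unname(fr$p), 0.8)
  expect_equal(unname(fr$nAlleles), 5)
  ## a crossbred allele with missing origin enters neither side:
  ## maternal allele (0) excluded above; flipping it changes nothing
  cb2 <- pg(rbind(1L), rbind(1L), ids = "cb1")
  fr2 <- breedAlleleFrequencies(pb, cb2, orr, "S")
  expect_equal(unname(fr2$p), 0.8)
})

test_that("partial matrices match a brute-force double loop", {
  sim <- tinyStudy(nFounders = 4, nPurebred = 5, nF1 = 3, nCrossbred = 6,
                   snps = 20)
  grms <- buildPartialGRMSet(sim$purebreds, sim$cb, sim$cbOrigins)
  lab <- originLabels(sim$cbOrigins)
  for (b in BREEDS) {
    el <- grms@breeds[[b]]
    p <- el$p
    dosPB <- genotypeDosage(sim$purebreds[[b]])
    npb <- nrow(dosPB); ncb <- nAnimals(sim$cb)
    Fb <- sum(2 * p * (1 - p))
    cent <- function(i) {
      if (i <= npb) return(dosPB[i, ] - 2 * p)
      k <- i - npb
      w <- numeric(length(p))
      for (j in seq_along(p)) {
        if (!is.na(lab$pat[k, j]) && lab$pat[k, j] == b)
          w[j] <- w[j] + sim$cb@pat[k, j] - p[j]
        if (!is.na(lab$mat[k, j]) && lab$mat[k, j] == b)
          w[j] <- w[j] + sim$cb@mat[k, j] - p[j]
      }
      w
    }
    for (i in seq_len(npb + ncb)) for (k in seq_len(npb + ncb)) {
      expect_equal(el$G[i, k], sum(cent(i) * cent(k)) / Fb,
                   tolerance = 1e-12)
    }
  }
})

test_that("crossbreds with no origin-b alleles have zero partial rows", {
  pb <- pg(rbind(c(1L, 0L), c(0L, 1L)), rbind(c(1L, 0L), c(1L, 0L)),
           ids = c("p1", "p2"))
  cb <- pg(rbind(c(1L, 1L), c(0L, 1L)), rbind(c(0L, 0L), c(1L, 1L)),
           ids = c("cb1", "cb2"))
  ## cb2 has every origin missing
  orr <- om(rbind(c("S", "S"), c(NA, NA)), rbind(c(NA, NA), c(NA, NA)))
  rownames(orr@pat) <- rownames(orr@mat) <- c("cb1", "cb2")
  purebreds <- list(S = pb, LR = pb, LW = pb)
  grms <- buildPartialGRMSet(purebreds, cb, orr)
  G <- grms@breeds$S$G
  expect_true(all(G["cb2", ] == 0))
  expect_true(all(G[, "cb2"] == 0))
})

test_that("partial matrices are SNP-order invariant, symmetric, near-PSD", {
  sim <- tinyStudy(snps = 40)
  grms <- buildPartialGRMSet(sim$purebreds, sim$cb, sim$cbOrigins)
  set.seed(31)
  perm <- sample(seq_len(40))
  for (b in BREEDS) {
    el <- grms@breeds[[b]]
    G <- el$G
    ## the sum over SNPs is order-free: rebuilding every block from
    ## column-permuted centred matrices leaves G unchanged
    Wp <- el$W[, perm, drop = FALSE]
    Wcbp <- el$Wcb[, perm, drop = FALSE]
    Gp <- rbind(cbind(tcrossprod(Wp), tcrossprod(Wp, Wcbp)),
                cbind(tcrossprod(Wcbp, Wp), tcrossprod(Wcbp))) / el$F
    expect_equal(G, Gp, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(G, t(G), tolerance = 1e-10)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("purebred diagonal of the own-breed partial matrix is near one", {
  sim <- tinyStudy(nFounders = 15, nPurebred = 40, snps = 400)
  grms <- buildPartialGRMSet(sim$purebreds, sim$cb, sim$cbOrigins)
  for (b in BREEDS) {
    el <- grms@breeds[[b]]
    npb <- length(el$purebredIds)
    expect_equal(mean(diag(el$G)[seq_len(npb)]), 1, tolerance = 0.1)
  }
})

test_that("crossbred partial diagonals sum to roughly the VanRaden diagonal", {
  ## equal-frequency limit: same founder frequencies in all breeds
  sim <- simulateStudy(seed = 5, fst = defaultFstTargets() * 0,
                       nFounders = c(S = 15, LR = 15, LW = 15),
                       nPurebred = c(S = 30, LR = 30, LW = 30),
                       nF1 = 15, nCrossbred = 30, nChrom = 1,
                       snpsPerChrom = 300, chromLengthMb = 50)
  grms <- buildPartialGRMSet(sim$purebreds, sim$cb, sim$cbOrigins)
  partSum <- Reduce(`+`, lapply(BREEDS, function(b) {
    el <- grms@breeds[[b]]
    npb <- length(el$purebredIds)
    diag(el$G)[-seq_len(npb)] * el$F
  }))
  ## standard VanRaden diagonal of the crossbreds at pooled frequencies
  pool <- rowMeans(sapply(BREEDS, function(b) grms@breeds[[b]]$p))
  W <- sweep(genotypeDosage(sim$cb)[, snpMap(sim$cb)$on_panel], 2, 2 * pool)
  vr <- rowSums(W^2)
  ## per-locus, the two haploid squared deviations sum to the diploid
  ## squared deviation in expectation (origins partition the two gametes)
  expect_equal(mean(partSum / vr), 1, tolerance = 0.1)
})

test_that("identity blending behaves as documented", {
  set.seed(2)
  W <- matrix(rnorm(12), 3, 4)
  G <- tcrossprod(W) / 4
  expect_identical(regularizePsd(G, 0), G)
  expect_equal(regularizePsd(diag(3), 0.5), diag(3))
  Gs <- tcrossprod(matrix(rnorm(8), 4, 2))  # rank 2, singular
  Gr <- regularizePsd(Gs, 0.01)
  ev <- eigen(Gr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0.01 * mean(diag(Gs)) * (1 - 1e-12))
})

test_that("tabular numerator matrix matches classical cases", {
  ped <- data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
                    dam = c(NA, NA, "d"), group = "S")
  A <- pedigreeNumeratorMatrix(ped)
  expect_equal(A["s", "o"], 0.5)
  expect_equal(diag(A), c(s = 1, d = 1, o = 1))
  ## founders only -> identity
  pedF <- data.frame(id = letters[1:4], sire = NA, dam = NA, group = "S")
  expect_equal(pedigreeNumeratorMatrix(pedF), diag(4),
               ignore_attr = TRUE)
  ## full sibs a = 0.5; offspring of full-sib mating has diagonal 1.25
  ped2 <- data.frame(id = c("s", "d", "x", "y", "z"),
                     sire = c(NA, NA, "s", "s", "x"),
                     dam = c(NA, NA, "d", "d", "y"), group = "S")
  A2 <- pedigreeNumeratorMatrix(ped2)
  expect_equal(A2["x", "y"], 0.5)
  expect_equal(A2["z", "z"], 1.25)
})

test_that("tabular numerator matrix equals the exhaustive-transmission oracle", {
  ## a three-generation pedigree with inbreeding and half sibs
  ped <- data.frame(
    id = c("f1", "f2", "f3", "a", "b", "c", "d", "e"),
    sire = c(NA, NA, NA, "f1", "f1", "a", "a", "c"),
    dam = c(NA, NA, NA, "f2", "f3", "b", "b", "d"),
    group = "S")
  A <- pedigreeNumeratorMatrix(ped)
  expect_equal(A, pathCountingA(ped), ignore_attr = TRUE,
               tolerance = 1e-12)
})
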