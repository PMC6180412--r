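test_that("divergence solver reproduces pairwise F_ST targets", {
  Fb <- solveDivergence(defaultFstTargets())
  expect_equal(unname((Fb["S"] + Fb["LR"]) / 2), 0.17)
  expect_equal(unname((Fb["S"] + Fb["LW"]) / 2), 0.12)
  expect_equal(unname((Fb["LR"] + Fb["LW"]) / 2), 0.14)
  expect_true(all(Fb >= 0 & Fb < 1))
})

test_that("Weir-Cockerham estimator is exact on a fixed-difference locus", {
  ## two breeds, one SNP, alternate alleles fixed: F_ST must be 1
  a <- pg(matrix(1L, 6, 1), matrix(1L, 6, 1))
  b <- pg(matrix(0L, 6, 1), matrix(0L, 6, 1))
  expect_equal(weirFst(a, b), 1)
})

test_that("realized founder F_ST approaches its targets", {
  map <- markerMap("chr1", seq_len(10000) * 100L)
  fnd <- simulateFounderBreeds(map, c(S = 60, LR = 60, LW = 60), seed = 5)
  expect_equal(weirFst(fnd$S, fnd$LR), 0.17, tolerance = 0.03 / 0.17)
  expect_equal(weirFst(fnd$S, fnd$LW), 0.12, tolerance = 0.03 / 0.12)
  expect_equal(weirFst(fnd$LR, fnd$LW), 0.14, tolerance = 0.03 / 0.14)
  ## no divergence under the pure frequency model (no haplotype pool):
  ## common frequency distribution, F_ST near zero
  zero <- defaultFstTargets() * 0
  f0 <- simulateFounderBreeds(map, c(S = 60, LR = 60, LW = 60),
                              fst = zero, seed = 5, ld = NULL)
  expect_lt(abs(weirFst(f0$S, f0$LR)), 0.01)
  ## determinism and error paths
  f2 <- simulateFounderBreeds(map, c(S = 60, LR = 60, LW = 60), seed = 5)
  expect_identical(fnd$S@pat, f2$S@pat)
  expect_error(simulateFounderBreeds(map, c(S = 60, S = 60, LW = 60)),
               "duplicate")
  expect_error(simulateFounderBreeds(map, c(S = 60, LR = 60, LW = 60),
                                     ancestral = c(0, 1)), "strictly")
})

test_that("gene dropping transmits whole gametes when recombination is off", {
  sim <- tinyStudy()
  gd0 <- geneDropPedigree(sim$founders, sim$ped, sim$map, seed = 3,
                          cMperMb = 0)
  ped <- sim$ped
  off <- which(!is.na(ped$sire))[1:20]
  for (i in off) {
    s <- match(ped$sire[i], ped$id)
    child <- gd0$geno@pat[i, ]
    expect_true(identical(child, gd0$geno@pat[s, ]) ||
                  identical(child, gd0$geno@mat[s, ]))
  }
})

test_that("crossbred origins respect the terminal-cross design", {
  sim <- tinyStudy(nCrossbred = 30)
  cbo <- sim$cbOrigins
  expect_true(all(cbo@pat == match("S", BREEDS)))
  expect_true(all(cbo@mat %in% match(c("LR", "LW"), BREEDS)))
})

test_that("maternal crossbred alleles are half LR-origin on average", {
  sim <- simulateStudy(seed = 8, nFounders = c(S = 10, LR = 10, LW = 10),
                       nPurebred = c(S = 10, LR = 10, LW = 10),
                       nF1 = 200, nCrossbred = 1500, nChrom = 1,
                       snpsPerChrom = 50, chromLengthMb = 100)
  fracLR <- mean(sim$cbOrigins@mat == match("LR", BREEDS))
  expect_equal(fracLR, 0.5, tolerance = 0.02 / 0.5)
})

test_that("gene dropping conserves allele content per origin", {
  ## breed-monomorphic founders: every allele must match its origin's
  ## founder allele
  map <- markerMap("chr1", seq_len(40) * 1e6)
  mono <- function(val, n) matrix(val, n, 40)
  founders <- list(
    S = pg(mono(1L, 6), mono(1L, 6), pos = map$pos,
           ids = sprintf("S_f%d", 1:6)),
    LR = pg(mono(0L, 6), mono(0L, 6), pos = map$pos,
            ids = sprintf("LR_f%d", 1:6)),
    LW = pg(mono(1L, 6), mono(1L, 6), pos = map$pos,
            ids = sprintf("LW_f%d", 1:6)))
  ped <- makeCrossPedigree(c(S = 6, LR = 6, LW = 6),
                           c(S = 8, LR = 8, LW = 8), nF1 = 6,
                           nCrossbred = 12, litterSize = 3, seed = 2)
  gd <- geneDropPedigree(founders, ped, map, seed = 2)
  lab <- originLabels(gd$origins)
  for (side in c("pat", "mat")) {
    al <- gamete(gd$geno, side)
    orr <- lab[[side]]
    expect_true(all(al[orr == "S"] == 1L))
    expect_true(all(al[orr == "LR"] == 0L))
    expect_true(all(al[orr == "LW"] == 1L))
  }
})

test_that("phenotypes degenerate correctly without genetic signal", {
  sim <- tinyStudy()
  vc0 <- varianceTargets(h2PB = c(S = 0, LR = 0, LW = 0), h2CB = 0,
                         litter = c(purebred = 0.0001,
                                    crossbred = 0.0001))
  rec <- simulatePhenotypes(sim$geno, sim$origins, sim$ped, vc = vc0,
                            seed = 4)
  expect_lt(var(rec$gTrue), 1e-8)
})

test_that("unit cross-performance correlation yields r_pc near one", {
  sim <- tinyStudy(nPurebred = 40, nCrossbred = 30, snps = 150)
  vc1 <- varianceTargets(rpc = c(S = 1, LR = 1, LW = 1))
  rec <- simulatePhenotypes(sim$geno, sim$origins, sim$ped, vc = vc1,
                            seed = 9)
  eff <- attr(rec, "truth")$effects
  for (b in BREEDS) {
    r <- cor(eff[[b]]$PB, eff[[b]]$CB)
    expect_gt(r, 0.999)
  }
})

test_that("simulated phenotypes recover the target heritability at scale", {
  sim <- simulateStudy(seed = 21, nPurebred = c(S = 700, LR = 30, LW = 30),
                       nFounders = c(S = 60, LR = 10, LW = 10),
                       nF1 = 20, nCrossbred = 20, nChrom = 2,
                       snpsPerChrom = 300)
  rec <- sim$records
  pb <- rec[rec$group == "S", ]
  ## realized genetic variance against the 0.31 target (phenVar 1)
  expect_equal(var(pb$gTrue), 0.31, tolerance = 0.25)
  resid <- pb$y - pb$gTrue
  expect_gt(var(resid), 0.4)  # litter + farm + covariate + residual
})

test_that("RFI residuals are orthogonal to their covariates", {
  set.seed(10)
  n <- 120
  rec <- data.frame(group = rep(c("S", "CB"), each = n / 2),
                    BWon = rnorm(n), BWoff = rnorm(n), BF = rnorm(n),
                    ADG = rnorm(n))
  rec$ADFI <- 2 + 0.5 * rec$BWon - 0.2 * rec$BWoff + 0.1 * rec$BF +
    0.7 * rec$ADG + rnorm(n)
  out <- deriveRfi(rec)
  for (pp in c("S", "CB")) {
    sel <- out$group == pp
    expect_lt(abs(sum(out$RFI[sel])), 1e-8)
    for (cv in c("BWon", "BWoff", "BF", "ADG"))
      expect_lt(abs(sum(out$RFI[sel] * rec[[cv]][sel])), 1e-8)
  }
  ## exact linear combination leaves zero residuals
  rec2 <- rec
  rec2$ADFI <- 1 + rec2$BWon + 2 * rec2$BWoff - rec2$BF + 0.5 * rec2$ADG
  out2 <- deriveRfi(rec2)
  expect_lt(max(abs(out2$RFI)), 1e-10)
})

test_that("RFI equals independently solved normal equations on a toy table", {
  ## 6 records, 5 parameters: solve the normal equations directly
  toy <- data.frame(group = "S",
                    BWon = c(1, 2, 3, 4, 5, 6),
                    BWoff = c(2.5, 1, 4.2, 3, 6, 5.5),
                    BF = c(0.5, 1.5, 1, 2, 0, 1),
                    ADG = c(1.1, 0.2, 0.9, 0.3, 1.4, 0.8),
                    ADFI = c(3.2, 4.1, 6.3, 7.7, 8.1, 9.9))
  X <- cbind(1, toy$BWon, toy$BWoff, toy$BF, toy$ADG)
  betaHat <- solve(t(X) %*% X, t(X) %*% toy$ADFI)
  oracle <- toy$ADFI - as.vector(X %*% betaHat)
  out <- deriveRfi(toy)
  expect_equal(out$RFI, oracle, tolerance = 1e-10)
})
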