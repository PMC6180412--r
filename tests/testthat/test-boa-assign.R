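## helper: purebred set whose single-window haplotype counts are fully
## controlled; one chromosome, one core length covering all SNPs
libFromCounts <- function(hapsByBreed, L = NULL) {
  m <- nchar(hapsByBreed[[1]][1])
  toGeno <- function(strs, prefix) {
    h <- t(vapply(strs, function(s) as.integer(strsplit(s, "")[[1]]),
                  integer(m)))
    ## duplicate each string on both gametes of one animal
    pg(h, h, ids = sprintf("%s_%d", prefix, seq_along(strs)))
  }
  purebreds <- lapply(names(hapsByBreed), function(b)
    toGeno(hapsByBreed[[b]], b))
  names(purebreds) <- names(hapsByBreed)
  buildHaplotypeLibrary(purebreds, windowSpec(if (is.null(L)) m else L))
}

test_that("library assignment follows the 80% purity rule", {
  ## copies are per gamete; each animal carries the string twice
  lib <- libFromCounts(list(
    S = rep("0101", 3),
    LR = c(rep("1100", 9), rep("0011", 1)) , # 18 vs 2 copies: share 0.9
    LW = c(rep("0011", 4), "1100")))         # "1100": 18 LR + 2 LW = 0.9
  entry <- lib$entries[[1]]
  expect_equal(entry$assign[match("0101", entry$keys)], match("S", BREEDS))
  expect_equal(entry$assign[match("1100", entry$keys)], match("LR", BREEDS))
  ## 0011: 2 LR + 8 LW copies -> share 0.8 >= 0.8: assigned LW
  expect_equal(entry$assign[match("0011", entry$keys)], match("LW", BREEDS))
})

test_that("haplotypes below the purity threshold stay unassigned", {
  lib <- libFromCounts(list(
    S = rep("1111", 3),      # 6 copies
    LR = rep("1111", 1),     # 2 copies
    LW = c("1111", "0000"))) # 2 + 2: "1111" share 6/10 = 0.6 < 0.8
  entry <- lib$entries[[1]]
  expect_true(is.na(entry$assign[match("1111", entry$keys)]))
  expect_equal(entry$assign[match("0000", entry$keys)], match("LW", BREEDS))
})

test_that("vote aggregation is majority with ties set missing", {
  ## breed-private alleles at every SNP; 8 SNPs, cores of 2 and 4 give
  ## 2 * 2 = 4 views per allele plus offset partials
  m <- 12
  mk <- function(v) paste(rep(v, m), collapse = "")
  lib <- libFromCounts(list(S = rep(mk(1), 4), LR = rep(mk(0), 4),
                            LW = rep(substr(paste(rep("01", m),
                                                  collapse = ""), 1, m), 4)),
                       L = c(3, 4))
  ## crossbred: paternal gamete all-1 (S), maternal all-0 (LR)
  cbh <- pg(matrix(1L, 1, m), matrix(0L, 1, m), ids = "cb1")
  orr <- assignBreedOfOrigin(cbh, lib)
  expect_true(all(orr@pat == match("S", BREEDS)))
  expect_true(all(orr@mat == match("LR", BREEDS)))
})

test_that("incompatible votes are discarded by the cross design", {
  m <- 8
  mk <- function(v) paste(rep(v, m), collapse = "")
  lib <- libFromCounts(list(S = rep(mk(1), 4), LR = rep(mk(0), 4),
                            LW = rep("01010101", 4)), L = c(4))
  ## paternal gamete matches LR perfectly: votes discarded -> missing
  cbh <- pg(matrix(0L, 1, m), matrix(1L, 1, m), ids = "cb1")
  orr <- assignBreedOfOrigin(cbh, lib)
  expect_true(all(is.na(orr@pat)))   # LR votes not allowed paternally
  expect_true(all(is.na(orr@mat)))   # S votes not allowed maternally
})

test_that("assignment is complete and exact for breed-private haplotypes", {
  ## no recombination + fully breed-private founder haplotypes
  sim0 <- simulateStudy(seed = 13, nFounders = c(S = 8, LR = 8, LW = 8),
                        nPurebred = c(S = 20, LR = 20, LW = 20),
                        nF1 = 10, nCrossbred = 25, nChrom = 1,
                        snpsPerChrom = 60,
                        fst = (defaultFstTargets() > 0) * 0.9,
                        cMperMb = 0)
  lib <- buildHaplotypeLibrary(sim0$purebreds, windowSpec(c(10, 20)))
  orr <- assignBreedOfOrigin(sim0$cb, lib)
  acc <- assignmentAccuracy(orr, sim0$cbOrigins)
  expect_gt(acc$assigned, 0.99)
  expect_equal(acc$accuracy, 1.0)
})

test_that("assignment filters implement the published thresholds", {
  ## 3 crossbreds x 10 SNPs; craft per-SNP paternal assignment rates
  n <- 100; m <- 4
  patL <- matrix("S", n, m)
  matL <- matrix("LR", n, m)
  patL[1:11, 1] <- NA    # rate 0.89 -> removed
  patL[1:9, 2] <- NA     # rate 0.91 -> kept
  filt <- applyAssignmentFilters(om(patL, matL), minCopies = 0)
  expect_false(1 %in% filt$keptSnps)
  expect_true(2 %in% filt$keptSnps)

  ## animal rule: animal with 91% of slots assigned kept, below removed
  patL2 <- matrix("S", n, m); matL2 <- matrix("LR", n, m)
  patL2[1, ] <- NA            # animal 1: 4/8 slots missing
  matL2[2, 1] <- NA           # animal 2: 7/8 = 0.875 -> removed
  orr2 <- om(patL2, matL2)
  rownames(orr2@pat) <- rownames(orr2@mat) <- sprintf("cb%d", 1:n)
  filt2 <- applyAssignmentFilters(orr2, minCopies = 0, snpRate = 0)
  expect_false("cb1" %in% filt2$keptAnimals)
  expect_false("cb2" %in% filt2$keptAnimals)
  expect_true("cb3" %in% filt2$keptAnimals)

  ## minimum-copies rule: counted allele seen 4x in one origin -> removed
  n3 <- 50
  patA <- matrix(1L, n3, 2); matA <- matrix(0L, n3, 2)
  patA[, 2] <- c(rep(1L, 4), rep(0L, n3 - 4))  # 4 S-origin copies of "1"
  matA[, 1] <- 1L; matA[, 2] <- 1L             # plenty of LR/LW copies
  geno <- pg(patA, matA, ids = sprintf("cb%d", 1:n3))
  orr3 <- om(matrix("S", n3, 2),
             matrix(rep(c("LR", "LW"), each = n3 / 2), n3, 2))
  rownames(orr3@pat) <- rownames(orr3@mat) <- animalIds(geno)
  filt3 <- applyAssignmentFilters(orr3, geno, snpRate = 0, animalRate = 0,
                                  minCopies = 5)
  expect_equal(filt3$keptSnps, 1L)
  ## 5 copies is enough
  patA[, 2] <- c(rep(1L, 5), rep(0L, n3 - 5))
  geno5 <- pg(patA, matA, ids = sprintf("cb%d", 1:n3))
  filt5 <- applyAssignmentFilters(orr3, geno5, snpRate = 0,
                                  animalRate = 0, minCopies = 5)
  expect_equal(filt5$keptSnps, c(1L, 2L))
})

test_that("filters are monotone in their thresholds", {
  set.seed(77)
  n <- 40; m <- 30
  mkLab <- function() {
    x <- matrix(sample(c("S", NA), n * m, replace = TRUE,
                       prob = c(0.93, 0.07)), n, m)
    x
  }
  patL <- mkLab()
  matL <- matrix(sample(c("LR", "LW", NA), n * m, replace = TRUE,
                        prob = c(0.5, 0.43, 0.07)), n, m)
  orr <- om(patL, matL)
  rownames(orr@pat) <- rownames(orr@mat) <- sprintf("cb%d", 1:n)
  kept <- function(sr, ar) {
    f <- applyAssignmentFilters(orr, minCopies = 0, snpRate = sr,
                                animalRate = ar)
    list(s = f$keptSnps, a = f$keptAnimals)
  }
  loose <- kept(0.85, 0.85)
  tight <- kept(0.95, 0.95)
  expect_true(all(tight$s %in% loose$s))
  expect_true(all(tight$a %in% loose$a))
})

test_that("accuracy summary handles perfect and empty assignments", {
  lab <- matrix("S", 5, 6)
  matl <- matrix("LW", 5, 6)
  truth <- om(lab, matl)
  perfect <- assignmentAccuracy(om(lab, matl), truth)
  expect_equal(perfect$assigned, 1)
  expect_equal(perfect$accuracy, 1)
  empty <- assignmentAccuracy(om(matrix(NA_character_, 5, 6),
                                 matrix(NA_character_, 5, 6)), truth)
  expect_equal(empty$assigned, 0)
  expect_null(empty$accuracy)
})
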