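test_that("fixed designs count levels and drop inestimable columns", {
  rec <- expand.grid(farm = c("farm1", "farm2", "farm3"),
                     sex = c("M", "F"), rep = 1:4)
  rec$group <- "S"; rec$id <- sprintf("S_p%d", seq_len(nrow(rec)))
  rec$litter <- rep(c("l1", "l2"), 12)
  rec$BWon <- rnorm(24); rec$y <- rnorm(24)
  sim <- tinyStudy(nPurebred = 24)
  ## reuse the GRM machinery with matching ids
  rec$id <- sim$ped$id[sim$ped$group == "S"][seq_len(24)]
  grms <- buildPartialGRMSet(sim$purebreds, sim$cb, sim$cbOrigins)
  md <- boaModelData(rec, grms, trait = "y",
                     fixed = list(purebred = ~ farm * sex,
                                  crossbred = ~ 1))
  ## 3 x 2 fully crossed: intercept + 5 free interaction contrasts
  expect_equal(ncol(md$X), 6)
  ## constant covariate flagged inestimable
  rec$flat <- 1
  expect_warning(
    boaModelData(rec, grms, trait = "y",
                 fixed = list(purebred = ~ sex + flat, crossbred = ~ 1)),
    "inestimable")
})

test_that("MME solutions equal direct conditioning on toy instances", {
  for (seed in c(1, 2)) {
    sim <- tinyStudy(seed = seed, nFounders = 4, nPurebred = 6, nF1 = 4,
                     nCrossbred = 8, snps = 80, litterSize = 3)
    grms <- blendGrms(buildPartialGRMSet(sim$purebreds, sim$cb,
                                         sim$cbOrigins))
    md <- boaModelData(sim$records, grms, trait = "y",
                       fixed = list(purebred = ~ BWon,
                                    crossbred = ~ BWon))
    vc <- varianceTargets()
    fit <- solveBoaMme(md, vc, ridge = 0)
    oracle <- conditionOracle(md, vc)
    expect_equal(unname(fit@fixef$beta), oracle$beta, tolerance = 1e-8)
    for (b in BREEDS) {
      q <- md$genetic[[b]]$q
      expect_equal(unname(fit@gebv$full[[b]]$PB), oracle$u[[b]][1:q],
                   tolerance = 1e-8)
      expect_equal(unname(fit@gebv$full[[b]]$CB),
                   oracle$u[[b]][q + 1:q], tolerance = 1e-8)
    }
  }
})

test_that("crossbred GEBVs are exactly additive over origins", {
  sim <- tinyStudy(seed = 3)
  grms <- buildPartialGRMSet(sim$purebreds, sim$cb, sim$cbOrigins)
  md <- suppressWarnings(boaModelData(sim$records, grms, trait = "y",
                                      fixed = list(purebred = ~ sex,
                                                   crossbred = ~ sex)))
  fit <- solveBoaMme(md, varianceTargets())
  cbm <- fit@gebv$crossbred
  expect_identical(unname(rowSums(cbm[, BREEDS])), unname(cbm[, "total"]))
})

test_that("vanishing variances shrink GEBVs to zero and recover GLS", {
  sim <- tinyStudy(seed = 5)
  grms <- buildPartialGRMSet(sim$purebreds, sim$cb, sim$cbOrigins)
  md <- suppressWarnings(boaModelData(sim$records, grms, trait = "y",
                                      fixed = list(purebred = ~ sex,
                                                   crossbred = ~ sex)))
  vc <- varianceTargets()
  tiny <- 1e-6
  for (b in BREEDS) vc$genetic[[b]] <- diag(tiny, 2)
  vc$litter[] <- tiny
  fit <- solveBoaMme(md, vc)
  expect_lt(max(abs(fit@gebv$crossbred[, "total"])), 2e-3)
  ## fixed solutions -> per-population least squares
  for (pp in c("S", "CB")) {
    sel <- md$pop == pp
    Xp <- md$X[sel, colSums(abs(md$X[sel, , drop = FALSE])) > 0,
               drop = FALSE]
    ols <- qr.solve(Xp, md$y[sel])
    got <- fit@fixef$beta[colnames(Xp)]
    expect_equal(unname(got), unname(ols), tolerance = 1e-3)
  }
})

test_that("duplicated records behave like a GLS stacked system", {
  sim <- tinyStudy(seed = 9, nFounders = 4, nPurebred = 6, nF1 = 4,
                   nCrossbred = 6, snps = 60)
  rec <- sim$records
  grms <- blendGrms(buildPartialGRMSet(sim$purebreds, sim$cb,
                                       sim$cbOrigins))
  md1 <- boaModelData(rec, grms, trait = "y",
                      fixed = list(purebred = ~ 1, crossbred = ~ 1))
  vc <- varianceTargets()
  fit1 <- solveBoaMme(md1, vc, ridge = 0)
  ## duplicating one crossbred record must equal giving it half the
  ## residual variance in the conditioning oracle
  dup <- rec[rec$group == "CB", ][1, ]
  md2 <- boaModelData(rbind(rec, dup), grms, trait = "y",
                      fixed = list(purebred = ~ 1, crossbred = ~ 1))
  fit2 <- solveBoaMme(md2, vc, ridge = 0)
  oracle2 <- conditionOracle(md2, vc)
  expect_equal(unname(fit2@gebv$full$S$CB), oracle2$u$S[md2$genetic$S$q +
                seq_len(md2$genetic$S$q)], tolerance = 1e-8)
  ## and the duplicated animal's GEBV moves towards its records
  id <- dup$id
  expect_false(isTRUE(all.equal(fit1@gebv$crossbred[id, "total"],
                                fit2@gebv$crossbred[id, "total"])))
})

test_that("derived genetic parameters follow their definitions", {
  vc <- varianceTargets()
  vc$genetic$S <- matrix(c(0.2, 0.147, 0.147, 0.3), 2)
  gp <- geneticParameters(vc)
  expect_equal(gp$rpc[gp$breed == "S"], 0.147 / sqrt(0.2 * 0.3))
  expect_equal(round(gp$rpc[gp$breed == "S"], 2), 0.60)
  ## h2CB from components 0.4 total genetic, 0.1 litter, 0.5 residual
  vc2 <- varianceTargets()
  for (b in BREEDS) vc2$genetic[[b]][2, 2] <- 0.4 / 3
  vc2$litter["CB"] <- 0.1; vc2$residual["CB"] <- 0.5
  expect_equal(unique(geneticParameters(vc2)$h2CB), 0.4)
  ## perfect correlation
  vc3 <- varianceTargets()
  vc3$genetic$LW <- matrix(c(0.2, sqrt(0.2 * 0.1), sqrt(0.2 * 0.1), 0.1), 2)
  expect_equal(geneticParameters(vc3)$rpc[3], 1)
})

test_that("REML engine matches closed forms and finds boundaries", {
  ## single-variance model: REML variance equals the sample variance
  set.seed(12)
  y <- rnorm(40, 5, 2)
  f <- aiRemlCore(y, matrix(1, 40, 1), list(diag(40)), tol = 1e-10)
  expect_equal(f$theta, var(y), tolerance = 1e-6)
  ## zero-signal data: genetic components head to the boundary
  sim <- tinyStudy(seed = 6, nFounders = 12, nPurebred = 80, nF1 = 30,
                   nCrossbred = 80, snps = 120)
  vc0 <- varianceTargets(h2PB = c(S = 0, LR = 0, LW = 0), h2CB = 0,
                         litter = c(purebred = 1e-4, crossbred = 1e-4))
  rec <- simulatePhenotypes(sim$geno, sim$origins, sim$ped, vc = vc0,
                            seed = 8)
  grms <- buildPartialGRMSet(sim$purebreds, sim$cb, sim$cbOrigins)
  md <- boaModelData(rec, grms, trait = "y")
  est <- remlEstimate(md, tol = 1e-4, maxIter = 60)
  ## effective genetic variance on the record scale: theta scaled by the
  ## mean partial diagonal (the crossbred partial diagonals are ~0.25-0.5,
  ## so theta itself is weakly identified when the signal is null)
  effCB <- 0
  for (b in BREEDS) {
    expect_lt(est$genetic[[b]][1, 1], 0.1)
    el <- grms@breeds[[b]]
    dcb <- mean(diag(el$G)[-seq_along(el$purebredIds)])
    effCB <- effCB + est$genetic[[b]][2, 2] * dcb
  }
  expect_lt(effCB, 0.15)
})

test_that("average-information REML matches an independent optimiser", {
  ## random-intercept model against the analytical profile optimum found
  ## by a grid-free optimizer on the REML likelihood
  set.seed(4)
  ng <- 25; per <- 4; n <- ng * per
  g <- rep(seq_len(ng), each = per)
  y <- 2 + rep(rnorm(ng, 0, 0.6), each = per) + rnorm(n, 0, 0.9)
  Z <- matrix(0, n, ng); Z[cbind(seq_len(n), g)] <- 1
  X <- matrix(1, n, 1)
  fit <- aiRemlCore(y, X, list(tcrossprod(Z), diag(n)), tol = 1e-10)
  ## independent check: numerical optimisation of the REML log-likelihood
  negll <- function(lt) {
    th <- exp(lt)
    V <- th[1] * tcrossprod(Z) + th[2] * diag(n)
    ch <- chol(V); Vi <- chol2inv(ch)
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    0.5 * (2 * sum(log(diag(ch))) + log(det(XtViX)) +
           t(r) %*% Vi %*% r)[1]
  }
  opt <- optim(log(c(0.3, 0.8)), negll, method = "BFGS")
  expect_equal(fit$theta, exp(opt$par), tolerance = 1e-4)
})
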