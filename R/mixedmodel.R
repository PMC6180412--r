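#' Assemble design matrices and covariance structures for the BOA model
#'
#' The breed-of-origin (BOA) animal model treats purebred performance of
#' each breed and crossbred performance as four traits recorded on
#' disjoint animals. Fixed effects are population-specific (farm-by-sex
#' classes and covariates, after the recording structure of combined
#' crossbred--purebred systems), litter is a random effect per record
#' population, and the genetic effects of breed b — the purebred trait
#' and the origin-b partial crossbred trait — covary through a 2x2
#' covariance matrix Kronecker the partial relationship matrix `G^(b)`.
#'
#' @param records TraitRecords data.frame; `group` identifies the record
#'   population (S, LR, LW or CB).
#' @param grms [PartialGRMSet-class].
#' @param trait name of the phenotype column.
#' @param fixed list with formulas `purebred` and `crossbred` for the
#'   fixed part (right-hand side only), evaluated within `records`.
#' @return an object of class `"boaModelData"`: record order, stacked
#'   response, block-diagonal fixed design (aliased columns dropped with
#'   a warning), litter and genetic incidence maps, and the record
#'   population index.
#' @export
boaModelData <- function(records, grms, trait = "y",
                         fixed = list(purebred = ~ farm * sex + BWon,
                                      crossbred = ~ farm * sex + BWon)) {
  pops <- c(BREEDS, "CB")
  records <- records[records$group %in% pops, , drop = FALSE]
  records <- records[order(match(records$group, pops)), , drop = FALSE]
  y <- records[[trait]]
  if (is.null(y)) stop("no column '", trait, "' in records", call. = FALSE)
  pop <- records$group
  Xblocks <- list()
  for (pp in pops) {
    sel <- pop == pp
    if (!any(sel)) { Xblocks[[pp]] <- NULL; next }
    f <- if (pp == "CB") fixed$crossbred else fixed$purebred
    Xp <- model.matrix(f, droplevels(records[sel, , drop = FALSE]))
    const <- apply(Xp, 2, function(col) all(col == col[1]))
    const[colnames(Xp) == "(Intercept)"] <- FALSE
    if (any(const)) {
      warning("inestimable (constant) fixed columns dropped in ", pp, ": ",
              paste(colnames(Xp)[const], collapse = ", "), call. = FALSE)
      Xp <- Xp[, !const, drop = FALSE]
    }
    q <- qr(Xp)
    if (q$rank < ncol(Xp)) {
      drop <- q$pivot[(q$rank + 1):ncol(Xp)]
      warning("aliased fixed columns dropped in ", pp, ": ",
              paste(colnames(Xp)[drop], collapse = ", "), call. = FALSE)
      Xp <- Xp[, -drop, drop = FALSE]
    }
    colnames(Xp) <- paste(pp, colnames(Xp), sep = ":")
    Xblocks[[pp]] <- Xp
  }
  n <- nrow(records)
  X <- matrix(0, n, sum(vapply(Xblocks, ncol, 0L)))
  colnames(X) <- unlist(lapply(Xblocks, colnames))
  at <- 0
  for (pp in pops) {
    if (is.null(Xblocks[[pp]])) next
    sel <- which(pop == pp)
    X[sel, at + seq_len(ncol(Xblocks[[pp]]))] <- Xblocks[[pp]]
    at <- at + ncol(Xblocks[[pp]])
  }
  ## litter incidence per population
  litter <- list()
  for (pp in pops) {
    sel <- which(pop == pp)
    if (!length(sel)) next
    lev <- unique(records$litter[sel])
    Z <- matrix(0, n, length(lev),
                dimnames = list(NULL, paste(pp, lev, sep = ":")))
    Z[cbind(sel, match(records$litter[sel], lev))] <- 1
    litter[[pp]] <- Z
  }
  ## genetic maps: for breed b, position of each record's animal in the
  ## order of G^(b) (purebred-b animals then crossbred animals)
  genetic <- list()
  for (b in BREEDS) {
    el <- grms@breeds[[b]]
    gAnimals <- c(el$purebredIds, el$crossbredIds)
    rowsPB <- which(pop == b)
    rowsCB <- which(pop == "CB")
    posPB <- match(records$id[rowsPB], gAnimals)
    posCB <- match(records$id[rowsCB], gAnimals)
    if (anyNA(posPB) || anyNA(posCB))
      stop("record animals absent from G^(", b, ")", call. = FALSE)
    genetic[[b]] <- list(rowsPB = rowsPB, posPB = posPB,
                         rowsCB = rowsCB, posCB = posCB,
                         q = length(gAnimals), ids = gAnimals)
  }
  structure(list(records = records, y = y, pop = pop, X = X,
                 litter = litter, genetic = genetic, grms = grms),
            class = "boaModelData")
}

## n x n covariance structure matrices, one per variance parameter, in the
## order: per breed (varPB_b, covPBCB_b, varCB_b), litter per population,
## residual per population
boaStructures <- function(md) {
  n <- length(md$y)
  Vlist <- list()
  labels <- character()
  covBlocks <- list()
  for (b in BREEDS) {
    G <- md$grms@breeds[[b]]$G
    gm <- md$genetic[[b]]
    Vpb <- matrix(0, n, n)
    Vpb[gm$rowsPB, gm$rowsPB] <- G[gm$posPB, gm$posPB]
    Vcb <- matrix(0, n, n)
    Vcb[gm$rowsCB, gm$rowsCB] <- G[gm$posCB, gm$posCB]
    Vx <- matrix(0, n, n)
    Vx[gm$rowsPB, gm$rowsCB] <- G[gm$posPB, gm$posCB]
    Vx <- Vx + t(Vx)
    k0 <- length(Vlist)
    Vlist <- c(Vlist, list(Vpb, Vx, Vcb))
    labels <- c(labels, paste0(c("varPB_", "covPBCB_", "varCB_"), b))
    covBlocks[[length(covBlocks) + 1L]] <- k0 + 1:3
  }
  for (pp in names(md$litter)) {
    Vlist <- c(Vlist, list(tcrossprod(md$litter[[pp]])))
    labels <- c(labels, paste0("litter_", pp))
  }
  for (pp in c(BREEDS, "CB")) {
    d <- as.numeric(md$pop == pp)
    Vlist <- c(Vlist, list(diag(d)))
    labels <- c(labels, paste0("resid_", pp))
  }
  list(Vlist = Vlist, labels = labels, covBlocks = covBlocks)
}

## flatten a variance-component list (as from varianceTargets) into the
## parameter vector of boaStructures, and back
vcToTheta <- function(vc) {
  th <- c()
  for (b in BREEDS) {
    S <- vc$genetic[[b]]
    th <- c(th, S[1, 1], S[1, 2], S[2, 2])
  }
  c(th, vc$litter[c(BREEDS, "CB")], vc$residual[c(BREEDS, "CB")])
}

thetaToVc <- function(theta) {
  gen <- list()
  for (i in seq_along(BREEDS)) {
    b <- BREEDS[i]
    k <- (i - 1) * 3
    gen[[b]] <- matrix(c(theta[k + 1], theta[k + 2],
                         theta[k + 2], theta[k + 3]), 2, 2,
                       dimnames = list(c("PB", "CB"), c("PB", "CB")))
  }
  list(genetic = gen,
       litter = setNames(theta[10:13], c(BREEDS, "CB")),
       residual = setNames(theta[14:17], c(BREEDS, "CB")))
}

#' Estimate variance components of the BOA model by AI-REML
#'
#' Average-information REML with step-halving safeguards, boundary
#' projection of variances and positive-semidefinite projection of the
#' per-breed 2x2 genetic covariance blocks. Standard errors come from the
#' inverse average-information matrix; heritabilities and the
#' purebred--crossbred genetic correlation are derived with delta-method
#' standard errors.
#'
#' @param md model data from [boaModelData()].
#' @param init optional starting values as a variance-component list.
#' @param tol relative parameter-change convergence tolerance.
#' @param maxIter maximum AI iterations.
#' @param verbose print the REML log-likelihood path.
#' @return variance-component list (`genetic`, `litter`, `residual`) with
#'   components `se` (same shape), `derived` (data.frame of h2 and r_pc
#'   with SEs), `logLik`, `converged`, `iterations`.
#' @export
remlEstimate <- function(md, init = NULL, tol = 1e-8, maxIter = 200,
                         verbose = FALSE) {
  st <- boaStructures(md)
  init2 <- if (!is.null(init)) vcToTheta(init) else NULL
  fit <- aiRemlCore(md$y, md$X, st$Vlist, init = init2,
                    covBlocks = st$covBlocks, tol = tol, maxIter = maxIter,
                    verbose = verbose)
  if (!fit$converged)
    warning("REML did not converge in ", maxIter, " iterations",
            call. = FALSE)
  vc <- thetaToVc(fit$theta)
  seList <- thetaToVc(fit$se)
  vc$se <- seList
  vc$derived <- derivedParameters(fit$theta, fit$thetaCov)
  vc$logLik <- fit$logLik
  vc$converged <- fit$converged
  vc$iterations <- fit$iterations
  vc
}

## h2 and r_pc with delta-method SEs from the AI covariance of theta
derivedParameters <- function(theta, thetaCov) {
  fns <- list()
  lbl <- c()
  for (i in seq_along(BREEDS)) {
    k <- (i - 1) * 3
    local({
      ii <- i; kk <- k
      fns[[length(fns) + 1L]] <<- function(th)
        th[kk + 1] / (th[kk + 1] + th[9 + ii] + th[13 + ii])
      fns[[length(fns) + 1L]] <<- function(th)
        th[kk + 2] / sqrt(th[kk + 1] * th[kk + 3])
    })
    lbl <- c(lbl, paste0("h2PB_", BREEDS[i]), paste0("rpc_", BREEDS[i]))
  }
  fns[[length(fns) + 1L]] <- function(th) {
    s <- th[3] + th[6] + th[9]
    s / (s + th[13] + th[17])
  }
  lbl <- c(lbl, "h2CB")
  est <- vapply(fns, function(f) f(theta), 0)
  se <- rep(NA_real_, length(fns))
  if (all(is.finite(thetaCov))) {
    for (j in seq_along(fns)) {
      g <- numeric(length(theta))
      for (k in seq_along(theta)) {
        h <- 1e-6 * max(abs(theta[k]), 1e-3)
        tp <- theta; tp[k] <- tp[k] + h
        tm <- theta; tm[k] <- tm[k] - h
        fp <- suppressWarnings(fns[[j]](tp))
        fm <- suppressWarnings(fns[[j]](tm))
        g[k] <- if (is.finite(fp) && is.finite(fm)) (fp - fm) / (2 * h)
                else 0
      }
      v <- drop(t(g) %*% thetaCov %*% g)
      se[j] <- if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
    }
  }
  data.frame(parameter = lbl, estimate = est, se = se)
}

#' Genetic parameters from variance components
#'
#' Heritability of crossbred performance pools the three partial genetic
#' variances: `h2_CB = sum_b varCB(b) / (sum_b varCB(b) + litter_CB +
#' resid_CB)`; purebred heritabilities are within-breed; `r_pc(b) =
#' covPBCB(b) / sqrt(varPB(b) varCB(b))`.
#'
#' @param vc variance-component list (`genetic`, `litter`, `residual`).
#' @return data.frame with one row per breed: `h2PB`, `rpc`, plus the
#'   common `h2CB`.
#' @export
geneticParameters <- function(vc) {
  s22 <- vapply(BREEDS, function(b) vc$genetic[[b]][2, 2], 0)
  h2CB <- sum(s22) / (sum(s22) + vc$litter[["CB"]] + vc$residual[["CB"]])
  data.frame(
    breed = BREEDS,
    h2PB = vapply(BREEDS, function(b) {
      s11 <- vc$genetic[[b]][1, 1]
      s11 / (s11 + vc$litter[[b]] + vc$residual[[b]])
    }, 0),
    rpc = vapply(BREEDS, function(b) {
      S <- vc$genetic[[b]]
      S[1, 2] / sqrt(S[1, 1] * S[2, 2])
    }, 0),
    h2CB = h2CB, row.names = NULL)
}

#' Solve the mixed-model equations of the BOA model
#'
#' Henderson's mixed-model equations for the four-trait model at given
#' variance components: fixed effects per record population, random
#' litter effects, and per breed b a bivariate genetic effect (purebred
#' trait, origin-b partial crossbred trait) with covariance
#' `Sigma_b (x) G^(b)`. Partial matrices are blended towards the identity
#' by `ridge` before inversion. The solution yields GEBVs for purebred
#' performance and, for every crossbred animal, the three origin partial
#' GEBVs for crossbred performance whose sum is its total GEBV.
#'
#' @param md model data from [boaModelData()].
#' @param vc variance components (targets or REML estimates).
#' @param ridge identity blending used to invert each `G^(b)`.
#' @return A [BoaFit-class] object.
#' @export
solveBoaMme <- function(md, vc, ridge = 1e-6) {
  n <- length(md$y)
  pops <- c(BREEDS, "CB")
  rinv <- 1 / vc$residual[md$pop]
  ## random-effect blocks: litter terms then genetic terms
  Zs <- list(); precs <- list(); info <- list()
  for (pp in names(md$litter)) {
    Zs[[length(Zs) + 1L]] <- md$litter[[pp]]
    precs[[length(precs) + 1L]] <-
      diag(1 / vc$litter[[pp]], ncol(md$litter[[pp]]))
    info[[length(info) + 1L]] <- list(type = "litter", pop = pp)
  }
  for (b in BREEDS) {
    gm <- md$genetic[[b]]
    q <- gm$q
    Z <- matrix(0, n, 2 * q)
    Z[cbind(gm$rowsPB, gm$posPB)] <- 1
    Z[cbind(gm$rowsCB, q + gm$posCB)] <- 1
    S <- vc$genetic[[b]]
    Sd <- S
    if (det(Sd) < 1e-12 * prod(diag(Sd)))
      Sd <- S + diag(1e-8 * mean(diag(S)), 2)
    Ginv <- chol2inv(chol(regularizePsd(md$grms@breeds[[b]]$G, ridge)))
    precs[[length(precs) + 1L]] <- kronecker(solve(Sd), Ginv)
    Zs[[length(Zs) + 1L]] <- Z
    info[[length(info) + 1L]] <- list(type = "genetic", breed = b, q = q,
                                      ids = gm$ids)
  }
  Z <- do.call(cbind, Zs)
  X <- md$X
  XtR <- t(X * rinv)
  ZtR <- t(Z * rinv)
  C <- rbind(cbind(XtR %*% X, XtR %*% Z),
             cbind(ZtR %*% X, ZtR %*% Z))
  at <- ncol(X)
  for (k in seq_along(precs)) {
    idx <- at + seq_len(ncol(Zs[[k]]))
    C[idx, idx] <- C[idx, idx] + precs[[k]]
    at <- at + ncol(Zs[[k]])
  }
  rhs <- c(XtR %*% md$y, ZtR %*% md$y)
  sol <- solve(symmpart(C), rhs)
  beta <- setNames(sol[seq_len(ncol(X))], colnames(X))
  at <- ncol(X)
  litterSol <- list(); gebvPB <- list(); partial <- list()
  pbPartial <- list(); fullSol <- list()
  for (k in seq_along(precs)) {
    uk <- sol[at + seq_len(ncol(Zs[[k]]))]
    at <- at + ncol(Zs[[k]])
    if (info[[k]]$type == "litter") {
      litterSol[[info[[k]]$pop]] <- setNames(uk, colnames(Zs[[k]]))
    } else {
      b <- info[[k]]$breed; q <- info[[k]]$q
      aPB <- setNames(uk[seq_len(q)], info[[k]]$ids)
      aCB <- setNames(uk[q + seq_len(q)], info[[k]]$ids)
      npb <- length(md$grms@breeds[[b]]$purebredIds)
      gebvPB[[b]] <- aPB[seq_len(npb)]
      pbPartial[[b]] <- aCB[seq_len(npb)]
      partial[[b]] <- aCB[npb + seq_len(q - npb)]
      fullSol[[b]] <- list(PB = aPB, CB = aCB)
    }
  }
  cbMat <- do.call(cbind, partial)
  cbMat <- cbind(cbMat, total = rowSums(cbMat))
  new("BoaFit",
      vc = vc,
      gebv = list(purebred = gebvPB, purebredCrossPartial = pbPartial,
                  crossbred = cbMat, full = fullSol),
      fixef = list(beta = beta, litter = litterSol),
      details = list(model = "BOA 4-trait GBLUP", ridge = ridge,
                     n = n, converged = NA, populations = table(md$pop)))
}

#' Select the purebred animals most related to the crossbreds
#'
#' Utility mirroring the practice of reducing a large purebred population
#' to the animals most closely related to the crossbred population before
#' variance-component estimation. Relatedness is the mean relationship of
#' a purebred animal to all crossbred animals in its breed's partial
#' matrix.
#'
#' @param grms [PartialGRMSet-class].
#' @param breed breed whose purebreds are ranked.
#' @param n number of animals to keep.
#' @return character vector of the `n` most related purebred ids.
#' @export
mostRelatedPurebreds <- function(grms, breed, n) {
  el <- grms@breeds[[breed]]
  npb <- length(el$purebredIds)
  cross <- el$G[seq_len(npb), npb + seq_along(el$crossbredIds),
                drop = FALSE]
  score <- rowMeans(cross)
  el$purebredIds[order(score, decreasing = TRUE)[seq_len(min(n, npb))]]
}
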