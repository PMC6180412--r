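## Generic average-information REML for linear variance models
##   y ~ N(X beta, V(theta)),  V(theta) = offset + sum_k theta_k * Vk
## Dense, desk scale. Used by the breed-of-origin model fit and by the
## focal-SNP substitution model.
##
## constraints: list of index vectors defining 2x2 covariance blocks as
## c(i_var1, i_cov, i_var2) kept positive semidefinite by shrinking the
## covariance; all other parameters are variances kept >= floor.

aiRemlCore <- function(y, X, Vlist, offset = NULL, init = NULL,
                       covBlocks = list(), tol = 1e-8, maxIter = 200,
                       verbose = FALSE) {
  n <- length(y)
  K <- length(Vlist)
  vy <- var(y)
  floorVal <- 1e-8 * vy
  covIdx <- unique(unlist(lapply(covBlocks, `[`, 2)))
  isCov <- seq_len(K) %in% covIdx
  theta <- if (is.null(init)) ifelse(isCov, 0, vy / K * 2) else init
  off <- if (is.null(offset)) matrix(0, n, n) else offset

  project <- function(th) {
    th[!isCov] <- pmax(th[!isCov], floorVal)
    for (blk in covBlocks) {
      bound <- sqrt(th[blk[1]] * th[blk[3]])
      th[blk[2]] <- sign(th[blk[2]]) * min(abs(th[blk[2]]), 0.999 * bound)
    }
    th
  }
  theta <- project(theta)

  buildV <- function(th) {
    V <- off
    for (k in seq_len(K)) V <- V + th[k] * Vlist[[k]]
    V
  }
  remlLogLik <- function(th) {
    V <- buildV(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    chX <- tryCatch(chol(symmpart(XtViX)), error = function(e) NULL)
    if (is.null(chX)) return(list(ll = -Inf))
    beta <- chol2inv(chX) %*% (XtVi %*% y)
    P <- Vi - t(XtVi) %*% chol2inv(chX) %*% XtVi
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                  sum(y * Py))
    list(ll = ll, P = P, Py = Py, beta = beta, Vi = Vi)
  }

  cur <- remlLogLik(theta)
  if (!is.finite(cur$ll)) stop("initial variance components give a ",
                               "non-positive-definite V", call. = FALSE)
  converged <- FALSE
  iter <- 0
  AI <- NULL
  for (iter in seq_len(maxIter)) {
    P <- cur$P; Py <- cur$Py
    score <- numeric(K)
    Tk <- vector("list", K)
    for (k in seq_len(K)) {
      Tk[[k]] <- Vlist[[k]] %*% Py
      score[k] <- -0.5 * (sum(P * Vlist[[k]]) - sum(Py * Tk[[k]]))
    }
    PT <- lapply(Tk, function(t) P %*% t)
    AI <- matrix(0, K, K)
    for (k in seq_len(K)) for (l in k:K) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(Tk[[k]] * PT[[l]])
    }
    step <- tryCatch(solve(AI + diag(1e-10 * mean(diag(AI)), K), score),
                     error = function(e) score / diag(AI))
    ok <- FALSE
    fac <- 1
    for (half in 1:15) {
      cand <- project(theta + fac * step)
      new <- remlLogLik(cand)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-10) { ok <- TRUE; break }
      fac <- fac / 2
    }
    if (!ok) { converged <- TRUE; break }  # no uphill move left
    rel <- max(abs(cand - theta) / pmax(abs(theta), 1e-3 * vy))
    theta <- cand
    cur <- new
    if (verbose) message(sprintf("iter %d logLik %.6f", iter, cur$ll))
    if (rel < tol) { converged <- TRUE; break }
  }
  se <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, K))
  list(theta = theta, se = se, logLik = cur$ll, converged = converged,
       iterations = iter, AI = AI, beta = cur$beta,
       thetaCov = tryCatch(solve(AI), error = function(e)
         matrix(NA_real_, K, K)))
}
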