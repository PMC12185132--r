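#' Per-condition empirical covariance (correlation) set
#'
#' Splits a standardized expression matrix by condition, re-centers each
#' gene within the condition, forms `S_k = (1/n_k) X_k X_k'` and rescales
#' its diagonal to 1 (correlation scale) — the input the penalized joint
#' estimator consumes.
#'
#' @param standardized `ExpressionMatrix` at stage `"standardized"`.
#' @param samples `SampleTable` paired with it.
#' @return a `CovarianceSet`: list with `S` (named list of p x p
#'   correlation matrices), `n` (named sample counts), `conditions`,
#'   `gene_ids`.
#' @export
empirical_covariance <- function(standardized, samples) {
  .assert_stage(standardized, "standardized", "empirical_covariance")
  samples <- sample_table(as.data.frame(samples), standardized)
  v <- standardized$values
  conditions <- sort(unique(samples$condition))
  S <- list()
  n <- integer(0)
  for (ck in conditions) {
    X <- v[, samples$condition == ck, drop = FALSE]
    nk <- ncol(X)
    if (nk < 2) stop("condition with < 2 samples: ", ck)
    Xc <- X - rowMeans(X)
    Sk <- tcrossprod(Xc) / nk
    d <- sqrt(diag(Sk))
    d[d < 1e-12] <- 1e-12
    Sk <- Sk / outer(d, d)
    diag(Sk) <- 1
    S[[ck]] <- Sk
    n[ck] <- nk
  }
  structure(list(S = S, n = n, conditions = conditions,
                 gene_ids = rownames(v)), class = "CovarianceSet")
}

#' Penalty and solver configuration
#'
#' @param lambda1 sparsity penalty on off-diagonal precision entries.
#' @param lambda2 sequential fusion penalty between chain-adjacent
#'   conditions.
#' @param grid candidate penalty values searched by [aic_grid_search()]
#'   (the search covers `grid x grid`).
#' @param admm_max_iter ADMM iteration cap.
#' @param admm_tol convergence tolerance on the scaled primal and dual
#'   residual norms.
#' @param admm_rho ADMM step parameter (fixed, no adaptive scaling).
#' @param truncation absolute partial-correlation threshold below which an
#'   entry is not reported as a network edge.
#' @param adaptive use condition-adaptive fusion weights from
#'   [screening_weights()] rather than fusing every gene pair.
#' @return a `PenaltyConfig` list.
#' @export
penalty_config <- function(lambda1 = 0.03, lambda2 = 0.03,
                           grid = c(0.01, 0.03, 0.05),
                           admm_max_iter = 100, admm_tol = 0.001,
                           admm_rho = 1.0, truncation = 0.05,
                           adaptive = TRUE) {
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be >= 0")
  if (truncation <= 0 || truncation >= 1) stop("truncation must be in (0,1)")
  if (admm_max_iter < 1) stop("admm_max_iter must be >= 1")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, grid = grid,
                 admm_max_iter = admm_max_iter, admm_tol = admm_tol,
                 admm_rho = admm_rho, truncation = truncation,
                 adaptive = adaptive), class = "PenaltyConfig")
}

# ADMM for the sequential fused graphical lasso
#   min sum_k [tr(S_k Theta_k) - logdet Theta_k]
#       + lambda1 sum_k sum_{i!=j} |theta_ij^k|
#       + lambda2 sum_{k<K} sum_{i!=j} W_ij^{k,k+1} |theta_ij^k - theta_ij^{k+1}|
# with consensus splitting Theta_k = Z_k.  The likelihood is on the
# per-sample scale (each condition's S_k is its correlation matrix), so
# lambda2 = 0 decouples exactly into single-condition graphical lassos.
.admm_fused <- function(S_list, lambda1, lambda2, W_list = NULL,
                        rho = 1.0, max_iter = 100, tol = 1e-3) {
  K <- length(S_list)
  p <- nrow(S_list[[1]])
  ut <- which(upper.tri(S_list[[1]]))
  M <- length(ut)
  if (K > 1) {
    W <- matrix(1, K - 1, M)
    if (!is.null(W_list)) {
      stopifnot(length(W_list) == K - 1)
      for (k in seq_len(K - 1)) W[k, ] <- W_list[[k]][ut]
    }
  } else W <- matrix(0, 0, M)

  Theta <- Z <- U <- rep(list(diag(p)), K)
  for (k in seq_len(K)) U[[k]] <- matrix(0, p, p)
  scale <- sqrt(K * p * p)
  primal <- dual <- Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    # Theta update: eigen-decomposition expansion
    for (k in seq_len(K)) {
      Mk <- Z[[k]] - U[[k]] - S_list[[k]] / rho
      e <- eigen((Mk + t(Mk)) / 2, symmetric = TRUE)
      d_new <- (e$values + sqrt(e$values^2 + 4 / rho)) / 2
      Theta[[k]] <- e$vectors %*% (d_new * t(e$vectors))
    }
    # Z update: fused-chain prox per gene-pair coordinate
    A <- matrix(0, K, M)
    adiag <- matrix(0, K, p)
    for (k in seq_len(K)) {
      TU <- Theta[[k]] + U[[k]]
      A[k, ] <- TU[ut]
      adiag[k, ] <- diag(TU)
    }
    Znew_ut <- .fused_chain_prox(A, W, lambda1 / rho, lambda2 / rho)
    Z_old <- Z
    for (k in seq_len(K)) {
      Zk <- matrix(0, p, p)
      Zk[ut] <- Znew_ut[k, ]
      Zk <- Zk + t(Zk)
      diag(Zk) <- adiag[k, ]  # diagonal unpenalized, unfused
      Z[[k]] <- Zk
      U[[k]] <- U[[k]] + Theta[[k]] - Zk
    }
    primal <- sqrt(sum(vapply(seq_len(K), function(k)
      sum((Theta[[k]] - Z[[k]])^2), 0))) / scale
    dual <- rho * sqrt(sum(vapply(seq_len(K), function(k)
      sum((Z[[k]] - Z_old[[k]])^2), 0))) / scale
    if (primal < tol && dual < tol) { converged <- TRUE; break }
  }
  for (k in seq_len(K)) {
    Z[[k]] <- (Z[[k]] + t(Z[[k]])) / 2
    dimnames(Z[[k]]) <- dimnames(S_list[[k]])
  }
  list(theta = Z, iterations = it, primal = primal, dual = dual,
       converged = converged)
}

#' Single-condition graphical lasso
#'
#' Maximizes `logdet(Theta) - tr(S Theta) - lambda1 * sum_{i!=j} |theta_ij|`
#' (diagonal unpenalized) by ADMM.  Non-convergence within `max_iter` is
#' flagged on the result, not raised.
#'
#' @param S symmetric positive semi-definite covariance/correlation matrix.
#' @param lambda1 off-diagonal L1 penalty.
#' @param max_iter,tol,rho ADMM controls (see [penalty_config()]).
#' @return list with `theta` (sparse symmetric estimate), `iterations`,
#'   `primal`, `dual`, `converged`.
#' @export
glasso_single <- function(S, lambda1, max_iter = 100, tol = 1e-3, rho = 1.0) {
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("S must be symmetric")
  fit <- .admm_fused(list(S), lambda1, 0, NULL, rho = rho,
                     max_iter = max_iter, tol = tol)
  list(theta = fit$theta[[1]], iterations = fit$iterations,
       primal = fit$primal, dual = fit$dual, converged = fit$converged)
}

#' Penalized log-likelihood objective of the graphical lasso
#'
#' @param theta symmetric positive-definite precision matrix.
#' @param S covariance matrix.
#' @param lambda1 off-diagonal L1 penalty.
#' @return `logdet(theta) - tr(S theta) - lambda1 * sum_{i != j} |theta_ij|`.
#' @export
glasso_objective <- function(theta, S, lambda1) {
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  as.numeric(ld$modulus) - sum(S * theta) -
    lambda1 * (sum(abs(theta)) - sum(abs(diag(theta))))
}

#' Order conditions into the fusion chain
#'
#' Conditions are ordered by the leaf order of average-linkage hierarchical
#' clustering of Euclidean distances between per-condition mean expression
#' profiles, so that similar conditions sit adjacently in the sequential
#' fusion chain.  Conditions are name-sorted before clustering, which
#' resolves ties (and the K = 2 reflection) deterministically.
#'
#' @param standardized `ExpressionMatrix` at stage `"standardized"`.
#' @param samples `SampleTable`.
#' @return character vector: the K condition labels in chain order.
#' @export
order_conditions <- function(standardized, samples) {
  .assert_stage(standardized, "standardized", "order_conditions")
  samples <- sample_table(as.data.frame(samples), standardized)
  conditions <- sort(unique(samples$condition))
  K <- length(conditions)
  if (K < 2) return(conditions)
  prof <- t(vapply(conditions, function(ck)
    rowMeans(standardized$values[, samples$condition == ck, drop = FALSE]),
    numeric(nrow(standardized$values))))
  if (K == 2) return(conditions)
  hc <- hclust(dist(prof, method = "euclidean"), method = "average")
  conditions[hc$order]
}

#' Condition-adaptive fusion weights by correlation screening
#'
#' For each chain-adjacent condition pair and every gene pair, tests
#' equality of the two correlations with the Fisher z statistic
#' `z = (atanh r_k - atanh r_{k+1}) / sqrt(1/(n_k-3) + 1/(n_{k+1}-3))`;
#' two-sided p-values are BH-adjusted across all gene pairs of that
#' condition pair, and fusion is disabled (weight 0) where `q < alpha`.
#'
#' @param covs a `CovarianceSet` (its `S_k` are correlation matrices).
#' @param chain condition labels in fusion-chain order.
#' @param alpha FDR level for declaring a pair condition-specific.
#' @return `FusionWeights`: named list (`"k|k+1"`) of symmetric binary
#'   p x p matrices, diagonal 1.
#' @export
screening_weights <- function(covs, chain = covs$conditions, alpha = 0.05) {
  stopifnot(inherits(covs, "CovarianceSet"))
  stopifnot(all(chain %in% covs$conditions), !anyDuplicated(chain))
  if (any(covs$n[chain] < 4)) stop("screening needs n_k >= 4 per condition")
  p <- length(covs$gene_ids)
  ut <- which(upper.tri(diag(p)))
  out <- list()
  for (k in seq_len(length(chain) - 1)) {
    c1 <- chain[k]; c2 <- chain[k + 1]
    clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    r1 <- clamp(covs$S[[c1]][ut]); r2 <- clamp(covs$S[[c2]][ut])
    se <- sqrt(1 / (covs$n[c1] - 3) + 1 / (covs$n[c2] - 3))
    z <- (atanh(r1) - atanh(r2)) / se
    q <- p.adjust(2 * pnorm(-abs(z)), method = "BH")
    W <- matrix(1, p, p, dimnames = list(covs$gene_ids, covs$gene_ids))
    w_ut <- rep(1, length(ut))
    w_ut[q < alpha] <- 0
    W[ut] <- w_ut
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    out[[paste(c1, c2, sep = "|")]] <- W
  }
  structure(out, class = "FusionWeights")
}

#' Joint estimation of condition-specific precision matrices
#'
#' Sequential condition-adaptive fused graphical lasso: maximizes the summed
#' per-condition penalized log-likelihoods with an L1 sparsity penalty and a
#' fused penalty `lambda2 * W_ij^{k,k+1} |theta_ij^k - theta_ij^{k+1}|`
#' along the condition chain, solved by ADMM with consensus splitting.
#' The returned matrices are the sparse consensus copies, symmetrized and
#' checked for positive definiteness.
#'
#' @param covs a `CovarianceSet`.
#' @param cfg a [penalty_config()].
#' @param weights `FusionWeights` from [screening_weights()], or `NULL` to
#'   fuse every gene pair.
#' @param chain condition labels in fusion order (default: `covs$conditions`).
#' @return a `PrecisionSet`: list with `theta` (named list, chain order),
#'   `lambda1`, `lambda2`, `chain`, `n`, `iterations`, `primal`, `dual`,
#'   `converged`.
#' @export
joint_estimate <- function(covs, cfg = penalty_config(), weights = NULL,
                           chain = covs$conditions) {
  stopifnot(inherits(covs, "CovarianceSet"))
  if (length(chain) == 0) stop("empty condition chain")
  stopifnot(all(chain %in% covs$conditions))
  S_list <- covs$S[chain]
  W_list <- NULL
  if (!is.null(weights) && length(chain) > 1) {
    keys <- paste(chain[-length(chain)], chain[-1], sep = "|")
    miss <- setdiff(keys, names(weights))
    if (length(miss)) stop("weights missing for chain pairs: ",
                           paste(miss, collapse = ", "))
    W_list <- weights[keys]
  }
  fit <- .admm_fused(S_list, cfg$lambda1, cfg$lambda2, W_list,
                     rho = cfg$admm_rho, max_iter = cfg$admm_max_iter,
                     tol = cfg$admm_tol)
  for (k in seq_along(fit$theta)) {
    ev <- min(eigen(fit$theta[[k]], symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      stop("estimated precision matrix for condition '", chain[k],
           "' is not positive definite (solver defect)")
  }
  structure(list(theta = fit$theta, lambda1 = cfg$lambda1,
                 lambda2 = cfg$lambda2, chain = chain, n = covs$n[chain],
                 iterations = fit$iterations, primal = fit$primal,
                 dual = fit$dual, converged = fit$converged),
            class = "PrecisionSet")
}

#' @export
#' @method print PrecisionSet
print.PrecisionSet <- function(x, ...) {
  cat(sprintf(
    "PrecisionSet: %d conditions, p = %d, lambda1 = %g, lambda2 = %g, %s in %d iterations\n",
    length(x$theta), nrow(x$theta[[1]]), x$lambda1, x$lambda2,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' AIC over a penalty grid
#'
#' Fits [joint_estimate()] for every `(lambda1, lambda2)` pair in
#' `grid x grid` and scores
#' `AIC = sum_k [n_k tr(S_k Theta_k) - n_k logdet(Theta_k) + 2 E_k]`,
#' with `E_k` the number of nonzero upper-triangle entries
#' (`|theta| > 1e-10`).  The lowest-AIC fit wins; ties break toward smaller
#' `lambda1`, then smaller `lambda2`.  Non-convergent fits stay in the
#' table, flagged, and remain eligible.
#'
#' @inheritParams joint_estimate
#' @param grid candidate penalty values (searched as `grid x grid`).
#' @return list with `best` (a `PrecisionSet`) and `table` (one row per
#'   grid pair: `lambda1`, `lambda2`, `aic`, `edges`, `converged`,
#'   `iterations`).
#' @export
aic_grid_search <- function(covs, grid = c(0.01, 0.03, 0.05),
                            weights = NULL, chain = covs$conditions,
                            cfg = penalty_config()) {
  if (length(grid) == 0) stop("empty penalty grid")
  rows <- list()
  fits <- list()
  for (l1 in grid) for (l2 in grid) {
    cfg_i <- cfg
    cfg_i$lambda1 <- l1
    cfg_i$lambda2 <- l2
    fit <- joint_estimate(covs, cfg_i, weights = weights, chain = chain)
    edges <- vapply(fit$theta, function(Th)
      sum(abs(Th[upper.tri(Th)]) > 1e-10), 0L)
    aic <- sum(vapply(seq_along(fit$theta), function(k) {
      Th <- fit$theta[[k]]
      nk <- fit$n[k]
      ld <- determinant(Th, logarithm = TRUE)
      nk * sum(covs$S[[fit$chain[k]]] * Th) - nk * as.numeric(ld$modulus) +
        2 * edges[k]
    }, 0))
    rows[[length(rows) + 1]] <- data.frame(
      lambda1 = l1, lambda2 = l2, aic = aic, edges = sum(edges),
      converged = fit$converged, iterations = fit$iterations)
    fits[[length(fits) + 1]] <- fit
  }
  table <- do.call(rbind, rows)
  best_i <- order(table$aic, table$lambda1, table$lambda2)[1]
  list(best = fits[[best_i]], table = table)
}
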