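test_that("empirical covariance yields unit-diagonal per-condition correlations", {
  set.seed(1)
  n <- 200
  z <- matrix(rnorm(4 * 2 * n), 4, 2 * n)
  z[2, ] <- z[1, ]  # perfectly correlated pair
  dimnames(z) <- list(sprintf("g%03d", 1:4), sprintf("s%03d", 1:(2 * n)))
  em <- standardize_latent(z)
  meta <- data.frame(sample = colnames(z),
                     condition = rep(c("a", "b"), each = n),
                     batch = "b1")
  covs <- empirical_covariance(em, meta)
  for (k in c("a", "b")) {
    expect_equal(unname(diag(covs$S[[k]])), rep(1, 4))
    expect_equal(covs$S[[k]][1, 2], 1, tolerance = 1e-8)
    # independent genes stay within the Monte-Carlo bound
    expect_lt(abs(covs$S[[k]][3, 4]), 3 / sqrt(n))
    expect_true(isSymmetric(covs$S[[k]]))
  }
  expect_equal(unname(covs$n), c(n, n))
})

test_that("graphical lasso solves the diagonal and two-gene cases exactly", {
  f <- glasso_single(diag(3), 0.05, max_iter = 500, tol = 1e-8)
  expect_equal(f$theta, diag(3), tolerance = 1e-6)
  expect_true(f$converged)

  S2 <- matrix(c(1, 0.04, 0.04, 1), 2)
  f2 <- glasso_single(S2, 0.05, max_iter = 500, tol = 1e-8)
  expect_identical(f2$theta[1, 2], 0)  # |s12| <= lambda1 -> exact zero

  set.seed(2)
  S5 <- random_corr(5)
  fit <- glasso_single(S5, 0.2, max_iter = 2000, tol = 1e-8)
  orc <- oracle_glasso_dual(S5, 0.2)
  gap <- abs(glasso_objective(fit$theta, S5, 0.2) -
             glasso_objective(orc, S5, 0.2))
  expect_lt(gap, 1e-4)
})

test_that("non-convergence is flagged, not raised", {
  set.seed(3)
  f <- glasso_single(random_corr(10), 0.05, max_iter = 2, tol = 1e-12)
  expect_false(f$converged)
  expect_equal(f$iterations, 2)
})

test_that("condition ordering chains similar conditions adjacently", {
  set.seed(4)
  p <- 20; n <- 10
  base <- matrix(rnorm(p * n), p, n)
  z <- cbind(base + 5, matrix(rnorm(p * n), p, n), base + 5.01)
  dimnames(z) <- list(sprintf("g%03d", 1:p), sprintf("s%03d", 1:(3 * n)))
  meta <- data.frame(sample = colnames(z),
                     condition = rep(c("aa", "bb", "cc"), each = n),
                     batch = "b1")
  em <- standardize_latent(z)
  chain <- order_conditions(em, meta)
  expect_setequal(chain, c("aa", "bb", "cc"))
  # aa and cc share the profile and must be neighbors in the chain
  expect_equal(abs(diff(match(c("aa", "cc"), chain))), 1)

  meta2 <- meta[meta$condition != "cc", ]
  em2 <- em; em2$values <- em2$values[, meta2$sample]
  expect_equal(order_conditions(em2, meta2), c("aa", "bb"))
})

test_that("screening weights fuse identical conditions and split opposite ones", {
  p <- 6
  S <- random_corr(p)
  covs <- cov_set(list(a = S, b = S), c(100, 100))
  W <- screening_weights(covs, c("a", "b"), alpha = 0.05)
  expect_named(W, "a|b")
  expect_true(all(W[["a|b"]] == 1))  # z = 0 everywhere

  Spos <- diag(p); Sneg <- diag(p)
  Spos[1, 2] <- Spos[2, 1] <- 0.9
  Sneg[1, 2] <- Sneg[2, 1] <- -0.9
  covs2 <- cov_set(list(a = Spos, b = Sneg), c(100, 100))
  W2 <- screening_weights(covs2, c("a", "b"), alpha = 0.05)
  expect_equal(W2[["a|b"]][1, 2], 0)
  expect_true(isSymmetric(W2[["a|b"]]))

  # |r| = 1 is clamped, not an error
  Sone <- diag(p); Sone[1, 2] <- Sone[2, 1] <- 1
  covs3 <- cov_set(list(a = Sone, b = diag(p)), c(50, 50))
  expect_silent(screening_weights(covs3, c("a", "b")))

  expect_error(screening_weights(cov_set(list(a = S, b = S), c(3, 100)),
                                 c("a", "b")), "n_k >= 4")
})

test_that("joint estimation obeys the fusion limit laws", {
  set.seed(5)
  p <- 10
  S1 <- random_corr(p); S2 <- random_corr(p)
  covs <- cov_set(list(a = S1, b = S2), c(50, 50))

  # lambda2 = 0 decouples into independent graphical lassos
  j0 <- joint_estimate(covs, penalty_config(lambda1 = 0.05, lambda2 = 0,
                                            admm_max_iter = 500,
                                            admm_tol = 1e-6))
  g1 <- glasso_single(S1, 0.05, max_iter = 500, tol = 1e-6)
  g2 <- glasso_single(S2, 0.05, max_iter = 500, tol = 1e-6)
  expect_lt(max(abs(j0$theta[[1]] - g1$theta)), 1e-3)
  expect_lt(max(abs(j0$theta[[2]] - g2$theta)), 1e-3)

  # identical inputs give identical outputs whatever lambda2
  covs_same <- cov_set(list(a = S1, b = S1), c(50, 50))
  js <- joint_estimate(covs_same, penalty_config(lambda1 = 0.05, lambda2 = 0.5,
                                                 admm_max_iter = 500,
                                                 admm_tol = 1e-6))
  expect_lt(max(abs(js$theta[[1]] - js$theta[[2]])), 1e-6)

  # dominant fusion forces the two conditions together
  jf <- joint_estimate(covs, penalty_config(lambda1 = 0.05, lambda2 = 1000,
                                            admm_max_iter = 500,
                                            admm_tol = 1e-6))
  expect_lt(max(abs(jf$theta[[1]] - jf$theta[[2]])), 1e-3)

  expect_error(joint_estimate(covs, penalty_config(), chain = character(0)),
               "empty")
})

test_that("converged fits honor the residual contract and PD invariant", {
  set.seed(6)
  covs <- cov_set(list(a = random_corr(8), b = random_corr(8)), c(40, 40))
  fit <- joint_estimate(covs, penalty_config(lambda1 = 0.03, lambda2 = 0.03))
  if (fit$converged) {
    expect_lt(fit$primal, 0.001)
    expect_lt(fit$dual, 0.001)
  }
  for (Th in fit$theta) {
    expect_true(isSymmetric(Th, tol = 1e-10))
    expect_gt(min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("AIC grid search returns the full table and prefers sparser true models", {
  set.seed(7)
  covs <- cov_set(list(a = random_corr(6), b = random_corr(6)), c(30, 30))
  sel <- aic_grid_search(covs, grid = c(0.01, 0.03, 0.05))
  expect_equal(nrow(sel$table), 9)
  expect_true(all(c("lambda1", "lambda2", "aic", "edges", "converged")
                  %in% names(sel$table)))
  best_row <- sel$table[which.min(sel$table$aic), ]
  expect_equal(sel$best$lambda1, best_row$lambda1)

  one <- aic_grid_search(covs, grid = 0.03)
  expect_equal(nrow(one$table), 1)
  expect_equal(one$best$lambda1, 0.03)

  # explicit AIC terms on diagonal-true data: the dense model pays 2 per edge
  p <- 5; n <- 100
  S <- diag(p)
  aic_of <- function(Th) {
    E <- sum(abs(Th[upper.tri(Th)]) > 1e-10)
    n * sum(S * Th) - n * as.numeric(determinant(Th, TRUE)$modulus) + 2 * E
  }
  Th_diag <- diag(p)
  Th_sat <- diag(p); Th_sat[upper.tri(Th_sat)] <- 0.01
  Th_sat <- (Th_sat + t(Th_sat)); diag(Th_sat) <- 1
  expect_lt(aic_of(Th_diag), aic_of(Th_sat))
})

test_that("raising lambda1 never increases the edge count", {
  set.seed(8)
  covs <- cov_set(list(a = random_corr(12), b = random_corr(12)), c(60, 60))
  sel <- aic_grid_search(covs, grid = c(0.01, 0.03, 0.05))
  tab <- sel$table
  for (l2 in unique(tab$lambda2)) {
    sub <- tab[tab$lambda2 == l2, ]
    sub <- sub[order(sub$lambda1), ]
    expect_true(all(diff(sub$edges) <= 0))
  }
})

test_that("runtime grows moderately with problem size", {
  set.seed(9)
  time_fit <- function(p, K) {
    covs <- cov_set(setNames(lapply(seq_len(K), function(i) random_corr(p)),
                             paste0("c", seq_len(K))), rep(30, K))
    system.time(joint_estimate(covs, penalty_config(lambda1 = 0.05,
                                                    lambda2 = 0.05,
                                                    admm_max_iter = 5,
                                                    admm_tol = 1e-12)))[["elapsed"]]
  }
  t_small <- time_fit(50, 2)
  t_big <- time_fit(100, 4)
  # sanity only: ~2x conditions and ~8x eigen work must not explode
  expect_lt(t_big, 400 * t_small + 0.5)
})
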