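test_that("objective matches direct summation and its closed cases", {
  A_list <- lapply(1:2, rand_sym, N = 5)
  K <- 2
  H0 <- matrix(0, 5, K)
  S0 <- list(diag(K), diag(K))
  expect_equal(jsnmf_objective(A_list, H0, S0, alpha = 0),
               sum(vapply(A_list, function(A) sum(A^2), numeric(1))))

  # exact factorization gives zero at alpha = 0
  H <- withr::with_seed(3, matrix(runif(10), 5, K))
  S <- withr::with_seed(4, crossprod(matrix(runif(4), 2, 2)))
  A_exact <- H %*% S %*% t(H)
  expect_equal(jsnmf_objective(list(A_exact), H, list(S), alpha = 0), 0,
               tolerance = 1e-12)

  # random instance vs element-by-element oracle
  H <- withr::with_seed(5, matrix(runif(10), 5, K))
  S_list <- lapply(A_list, update_S, H = H)
  expect_equal(jsnmf_objective(A_list, H, S_list, alpha = 0.7),
               oracle_objective(A_list, H, S_list, 0.7),
               tolerance = 1e-10)
})

test_that("update_S is the clipped closed-form minimizer", {
  A <- rand_sym(4, seed = 2)
  expect_equal(update_S(A, diag(4)), A, tolerance = 1e-12)

  # orthogonal 0/1 block columns on a block-diagonal matrix: direct
  # hand computation of (H'H)^-1 H'AH (H'H)^-1
  A2 <- two_block_matrix(c(2, 2), w = 0.6)
  H2 <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  # block k has 2 nodes, intra-block weight sum 2*0.6; (H'H)^-1 = I/2
  expect_equal(update_S(A2, H2), diag(c(0.3, 0.3)), tolerance = 1e-12)

  # random instances agree with the independent oracle
  for (seed in 1:5) {
    A6 <- rand_sym(6, seed)
    H6 <- withr::with_seed(seed + 100, matrix(runif(12), 6, 2))
    expect_equal(suppressMessages(update_S(A6, H6)), oracle_update_S(A6, H6),
                 tolerance = 1e-10)
  }
})

test_that("the pre-clip S zeroes the Frobenius-term gradient", {
  A <- rand_sym(6, seed = 8)
  H <- withr::with_seed(9, matrix(runif(12), 6, 2))
  M <- crossprod(H)
  S <- solve(M, t(H)) %*% A %*% H %*% solve(M)   # pre-clip closed form
  grad <- -2 * t(H) %*% A %*% H + 2 * M %*% S %*% M
  expect_lt(max(abs(grad)), 1e-8)
})

test_that("update_H matches the straight-line formula and its fixed points", {
  # exact factorization with alpha = 0: numerator equals denominator
  H <- withr::with_seed(13, matrix(runif(12), 6, 2))
  S <- withr::with_seed(14, crossprod(matrix(runif(4), 2, 2)))
  A <- H %*% S %*% t(H)
  expect_equal(update_H(list(A), H, list(S), alpha = 0), H,
               tolerance = 1e-10)

  # zero entries stay zero
  Hz <- H; Hz[2, 1] <- 0; Hz[5, 2] <- 0
  out <- update_H(list(A), Hz, list(S), alpha = 0.5)
  expect_identical(out[2, 1], 0)
  expect_identical(out[5, 2], 0)

  # random multi-view instance vs entry-by-entry oracle
  A_list <- lapply(21:22, rand_sym, N = 6)
  S_list <- lapply(A_list, update_S, H = H)
  expect_equal(update_H(A_list, H, S_list, alpha = 0.5),
               oracle_update_H(A_list, H, S_list, alpha = 0.5),
               tolerance = 1e-10)
})

test_that("fit recovers exact planted blocks and respects K = 1", {
  A <- two_block_matrix(c(5, 5), w = 0.8)
  fit <- jsnmf_fit(list(A), jsnmf_config(K = 2, alpha = 0, seed = 7,
                                         max_iter = 200))
  expect_equal(adjusted_rand_index(fit$partition,
                                   partition(rep(1:2, each = 5))), 1)

  fit1 <- jsnmf_fit(list(A), jsnmf_config(K = 1, alpha = 0, seed = 7,
                                          max_iter = 50))
  expect_equal(unique(unclass(fit1$partition)), 1L)
})

test_that("replicated views reproduce the single-view factor", {
  A <- rand_sym(8, seed = 31, scale = 0.8)
  cfg <- jsnmf_config(K = 2, alpha = 0, seed = 5, max_iter = 80)
  f1 <- jsnmf_fit(list(A), cfg)
  f3 <- jsnmf_fit(list(A, A, A), cfg)
  expect_equal(f3$H, f1$H, tolerance = 1e-8)
  expect_equal(f3$objective_trace[1], 3 * f1$objective_trace[1],
               tolerance = 1e-8)
})

test_that("objective trace is non-increasing and factors stay non-negative", {
  for (seed in 1:4) {
    A_list <- lapply(seed * 10 + 1:2, rand_sym, N = 12)
    cfg <- jsnmf_config(K = 3, alpha = seed %% 2, seed = seed,
                        max_iter = 60)
    fit <- suppressMessages(jsnmf_fit(A_list, cfg))
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_gte(min(fit$H), 0)
    expect_gte(min(vapply(fit$S_list, min, numeric(1))), 0)
  }
})

test_that("a uniform node permutation permutes the rows of H", {
  A_list <- lapply(41:42, rand_sym, N = 10)
  perm <- withr::with_seed(6, sample(10))
  H0 <- withr::with_seed(7, matrix(runif(20), 10, 2))
  cfg <- jsnmf_config(K = 2, alpha = 1, seed = 1, max_iter = 40)
  f <- suppressMessages(jsnmf_fit(A_list, cfg, H_init = H0))
  fp <- suppressMessages(jsnmf_fit(lapply(A_list, function(A) A[perm, perm]),
                                   cfg, H_init = H0[perm, , drop = FALSE]))
  expect_equal(fp$H, f$H[perm, , drop = FALSE], tolerance = 1e-8)
})

test_that("degenerate and invalid configurations error cleanly", {
  A <- rand_sym(4, seed = 3)
  expect_error(jsnmf_fit(list(A), jsnmf_config(K = 6)), "exceeds")
  expect_error(normalize_and_assign(cbind(c(1, 2), c(0, 0))), "column")
})

test_that("normalize_and_assign scales columns and breaks ties low", {
  H <- cbind(c(0.2, 0.4), c(0.1, 0.1))
  na <- normalize_and_assign(H)
  expect_equal(na$H_norm[, 1], c(0.5, 1.0))
  expect_equal(max(na$H_norm[, 2]), 1)

  # equal normalized entries go to the smaller module index
  Ht <- cbind(c(1, 0.5), c(1, 0.2))
  expect_equal(unclass(normalize_and_assign(Ht)$partition)[1], 1L)
})

test_that("the representative run maximizes mean pairwise ARI", {
  p_a <- partition(c(1, 1, 2, 2, 3, 3))
  p_b <- partition(c(2, 2, 3, 3, 1, 1))   # same partition, relabeled
  p_c <- partition(c(1, 2, 1, 2, 1, 2))
  expect_equal(select_representative_run(list(p_a, p_b, p_c)), 1L)
  expect_equal(select_representative_run(list(p_c, p_c, p_c)), 1L)
  expect_equal(select_representative_run(list(p_a, p_c)), 1L)
  expect_error(select_representative_run(list(p_a)), "at least 2")
})
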