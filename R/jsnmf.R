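#' Configuration for the joint symmetric NMF optimizer
#'
#' @param K number of modules (1 <= K <= N).
#' @param alpha non-negative L1 sparsity weight on the shared indicator
#'   matrix H; the objective charges `4 * alpha * sum(H)`.
#' @param max_iter iteration cap; one iteration is all per-view S updates
#'   followed by one H update.
#' @param tol relative-objective convergence tolerance:
#'   `|O_t - O_{t-1}| / max(O_{t-1}, 1e-30) < tol` stops the loop.
#' @param seed RNG seed used for the uniform(0,1) initialization of H.
#' @param eps small stabilizer added to every denominator entry of the
#'   multiplicative update to avoid 0/0.
#' @param burnin length of the initialization burn-in: damped symmetric-NMF
#'   updates of H with every compression matrix pinned to the identity,
#'   run before the joint alternation starts. Uniform random H is nearly
#'   rank-one (all columns positively correlated), a basin from which the
#'   joint updates rarely escape; the identity-S phase first pulls the
#'   columns apart toward distinct dense subgraphs. Set 0 to disable.
#' @return list of class `jsnmf_config`.
#' @export
jsnmf_config <- function(K, alpha = 1, max_iter = 500, tol = 1e-6,
                         seed = 1L, eps = 1e-12, burnin = 100L) {
  stopifnot(K >= 1, alpha >= 0, max_iter >= 1, tol > 0, eps > 0,
            burnin >= 0)
  structure(list(K = as.integer(K), alpha = alpha,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), eps = eps,
                 burnin = as.integer(burnin)),
            class = "jsnmf_config")
}

as_view_list <- function(set) {
  if (inherits(set, "multiview_set")) lapply(set$views, unclass)
  else if (is.list(set)) lapply(set, function(v) unclass(as.matrix(v)))
  else list(unclass(as.matrix(set)))
}

#' Joint factorization objective
#'
#' `sum_v ||A^(v) - H S^(v) H'||_F^2 + 4 * alpha * sum(H)`; the L1 term is
#' the sum of all entries of H since H is non-negative.
#'
#' @param set a [multiview_set()] or list of symmetric matrices.
#' @param H N x K non-negative matrix.
#' @param S_list list of K x K non-negative matrices, one per view.
#' @param alpha sparsity weight.
#' @return non-negative scalar.
#' @export
jsnmf_objective <- function(set, H, S_list, alpha) {
  A_list <- as_view_list(set)
  if (length(A_list) != length(S_list)) stop("one S matrix per view required")
  if (nrow(A_list[[1]]) != nrow(H)) stop("H rows must match network size")
  fit <- 0
  for (v in seq_along(A_list)) {
    R <- A_list[[v]] - H %*% S_list[[v]] %*% t(H)
    fit <- fit + sum(R * R)
  }
  fit + 4 * alpha * sum(H)
}

#' Closed-form per-view S update
#'
#' Minimizes `||A - H S H'||_F^2` over unconstrained S:
#' `S = (H'H)^{-1} H'AH (H'H)^{-1}`, then clips negative entries to zero so
#' the non-negativity constraint on S holds. A message is emitted when
#' clipping changed any entry by more than 1e-8. Rank-deficient `H'H` falls
#' back to the Moore-Penrose pseudo-inverse with a warning.
#'
#' @param A_v symmetric non-negative matrix (one view).
#' @param H current N x K factor.
#' @param eps unused stabilizer kept for interface symmetry.
#' @return K x K non-negative matrix.
#' @export
update_S <- function(A_v, H, eps = 1e-12) {
  A_v <- unclass(as.matrix(A_v))
  M <- crossprod(H)                       # H'H, K x K
  HtAH <- t(H) %*% A_v %*% H
  Minv <- tryCatch(solve(M), error = function(e) {
    warning("H'H is rank-deficient; using pseudo-inverse")
    MASS::ginv(M)
  })
  S <- Minv %*% HtAH %*% Minv
  S <- (S + t(S)) / 2
  if (min(S) < -1e-8)
    message("update_S: clipped negative entries (min ", format(min(S)), ")")
  S[S < 0] <- 0
  S
}

#' One multiplicative update of the shared indicator matrix H
#'
#' `H <- H * (sum_v A^(v) H S^(v)) / (sum_v H S^(v) H'H S^(v) + alpha + eps)`
#' element-wise; the sparsity penalty enters every denominator entry, so
#' larger `alpha` uniformly shrinks H. Zero entries of H stay zero
#' (multiplicative rule).
#'
#' @inheritParams jsnmf_objective
#' @param eps stabilizer added to the denominator.
#' @return updated N x K non-negative matrix.
#' @export
update_H <- function(set, H, S_list, alpha, eps = 1e-12) {
  step_H(as_view_list(set), H, S_list, alpha, eps, gamma = 1)
}

# shared kernel: H * (num/den)^gamma; gamma < 1 is a damped step used by
# fit()'s monotonicity safeguard, gamma = 1 is the plain rule.
step_H <- function(A_list, H, S_list, alpha, eps, gamma = 1) {
  num <- matrix(0, nrow(H), ncol(H))
  den <- matrix(0, nrow(H), ncol(H))
  HtH <- crossprod(H)
  for (v in seq_along(A_list)) {
    S <- S_list[[v]]
    HS <- H %*% S
    num <- num + A_list[[v]] %*% HS
    den <- den + HS %*% HtH %*% S
  }
  ratio <- num / (den + alpha + eps)
  if (gamma != 1) ratio <- ratio^gamma
  H * ratio
}

#' Fit the joint symmetric factorization
#'
#' Alternates the closed-form S update over all views with one
#' multiplicative H update per iteration, recording the objective after
#' each full sweep. The objective trace is guaranteed non-increasing: a
#' candidate S that would raise the objective (possible after negativity
#' clipping) is rejected in favor of the previous S, and an H step that
#' overshoots is geometrically damped until the objective does not
#' increase.
#'
#' @param set a [multiview_set()] of preprocessed (symmetric, non-negative)
#'   views, or a list of such matrices.
#' @param config a [jsnmf_config()].
#' @param H_init optional explicit N x K non-negative starting matrix,
#'   overriding the seeded uniform draw (the burn-in still runs).
#' @return object of class `jsnmf_fit`: list with `H` (N x K), `S_list`,
#'   `objective_trace`, `iterations_run`, `converged`, plus `H_norm` and
#'   `partition` from [normalize_and_assign()] when the factorization is
#'   non-degenerate.
#' @export
jsnmf_fit <- function(set, config, H_init = NULL) {
  A_list <- as_view_list(set)
  N <- nrow(A_list[[1]])
  K <- config$K
  if (K > N) stop("K (", K, ") exceeds the number of nodes (", N, ")")
  for (A in A_list) {
    if (nrow(A) != N || ncol(A) != N) stop("views differ in size")
    if (min(A) < 0) stop("views must be non-negative; preprocess first")
  }
  alpha <- config$alpha; eps <- config$eps
  if (is.null(H_init)) {
    H <- withr::with_seed(config$seed,
                          matrix(stats::runif(N * K), N, K))
  } else {
    H <- as.matrix(H_init)
    if (nrow(H) != N || ncol(H) != K) stop("H_init must be N x K")
    if (min(H) < 0) stop("H_init must be non-negative")
  }
  # burn-in: damped symmetric-NMF steps with S^(v) = I, part of the
  # initialization (the recorded trace starts after it)
  for (b in seq_len(config$burnin)) {
    num <- den <- matrix(0, N, K)
    HtH <- crossprod(H)
    for (v in seq_along(A_list)) {
      num <- num + A_list[[v]] %*% H
      den <- den + H %*% HtH
    }
    H <- H * (0.5 + 0.5 * num / (den + eps))
  }
  S_list <- lapply(A_list, function(A)
    suppressWarnings(suppressMessages(update_S(A, H = H, eps = eps))))
  obj <- jsnmf_objective(A_list, H, S_list, alpha)
  trace <- numeric(config$max_iter + 1L)
  trace[1L] <- obj
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    # S sweep with rejection: keep the old S^(v) if the clipped closed form
    # would raise that view's fit term
    for (v in seq_along(A_list)) {
      S_new <- suppressWarnings(suppressMessages(update_S(A_list[[v]], H, eps)))
      old_fit <- view_fit(A_list[[v]], H, S_list[[v]])
      new_fit <- view_fit(A_list[[v]], H, S_new)
      if (new_fit <= old_fit + 1e-12 * max(1, old_fit)) S_list[[v]] <- S_new
    }
    # damped H step: plain multiplicative rule first, halve the exponent
    # while the objective would increase
    gamma <- 1
    repeat {
      H_new <- step_H(A_list, H, S_list, alpha, eps, gamma)
      obj_new <- jsnmf_objective(A_list, H_new, S_list, alpha)
      if (obj_new <= obj + 1e-12 * max(1, obj) || gamma < 1e-4) break
      gamma <- gamma / 2
    }
    if (obj_new <= obj + 1e-12 * max(1, obj)) H <- H_new else obj_new <- obj
    rel <- abs(obj_new - obj) / max(obj, 1e-30)
    obj <- obj_new
    trace[iter + 1L] <- obj
    if (rel < config$tol) { converged <- TRUE; break }
  }
  res <- structure(
    list(H = H, S_list = S_list,
         objective_trace = trace[seq_len(iter + 1L)],
         iterations_run = iter, converged = converged,
         config = config),
    class = "jsnmf_fit")
  assign_try <- tryCatch(normalize_and_assign(H), error = function(e) NULL)
  if (!is.null(assign_try)) {
    res$H_norm <- assign_try$H_norm
    res$partition <- assign_try$partition
  }
  res
}

view_fit <- function(A, H, S) {
  R <- A - H %*% S %*% t(H)
  sum(R * R)
}

#' @export
print.jsnmf_fit <- function(x, ...) {
  cat(sprintf(
    "jsnmf_fit: N=%d, K=%d, %d iterations (%s), objective %.6g -> %.6g\n",
    nrow(x$H), ncol(x$H), x$iterations_run,
    if (x$converged) "converged" else "iteration cap",
    x$objective_trace[1], x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Column-normalize H and harden it into a partition
#'
#' Each column of H is divided by its maximum (balancing module sizes);
#' node i joins the module whose entry in row i of the normalized matrix is
#' largest, ties going to the smallest module index. Empty modules are
#' permitted but reported via a message.
#'
#' @param H non-negative N x K matrix with at least one positive entry per
#'   column; an all-zero column is a degenerate factorization and errors.
#' @return list with `H_norm` and `partition` (a [partition()]).
#' @export
normalize_and_assign <- function(H) {
  H <- as.matrix(H)
  cmax <- apply(H, 2, max)
  bad <- which(cmax <= 0)
  if (length(bad))
    stop("degenerate factorization: column(s) ",
         paste(bad, collapse = ", "), " of H are all zero")
  H_norm <- sweep(H, 2, cmax, "/")
  labels <- apply(H_norm, 1, which.max)   # which.max = smallest index on ties
  p <- partition(labels, K = ncol(H))
  empty <- setdiff(seq_len(ncol(H)), unique(labels))
  if (length(empty))
    message("normalize_and_assign: empty module(s) ",
            paste(empty, collapse = ", "))
  list(H_norm = H_norm, partition = p)
}

#' Fit with random restarts and keep every run
#'
#' @param set as in [jsnmf_fit()].
#' @param config a [jsnmf_config()]; `config$seed` seeds run 1 and
#'   successive runs use `seed + run - 1`.
#' @param runs number of random restarts.
#' @return list of `jsnmf_fit` objects.
#' @export
jsnmf_restarts <- function(set, config, runs = 10) {
  stopifnot(runs >= 1)
  lapply(seq_len(runs), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    jsnmf_fit(set, cfg)
  })
}

#' Pick the run most similar to all others
#'
#' Returns the index maximizing the mean adjusted Rand index against every
#' other run's partition; ties break to the smallest index. With exactly
#' two runs the means tie and run 1 is returned.
#'
#' @param partitions list of at least two [partition()]s over one node set.
#' @return integer run index.
#' @export
select_representative_run <- function(partitions) {
  r <- length(partitions)
  if (r < 2) stop("need at least 2 runs to select a representative")
  ari <- matrix(1, r, r)
  for (i in seq_len(r - 1)) for (j in seq(i + 1, r)) {
    a <- adjusted_rand_index(partitions[[i]], partitions[[j]])
    ari[i, j] <- a; ari[j, i] <- a
  }
  mean_ari <- (rowSums(ari) - 1) / (r - 1)
  which.max(mean_ari)
}
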