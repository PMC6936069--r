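#' A hard partition of nodes into K modules
#'
#' @param labels integer vector, one module index in `1..K` per node; names
#'   (if any) carry node ids.
#' @param K number of modules; defaults to `max(labels)`. Empty modules are
#'   allowed (a label in `1..K` simply never occurring).
#' @return integer vector of class `partition` with attribute `K`.
#' @export
partition <- function(labels, K = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels contain NA")
  if (is.null(K)) K <- max(labels)
  K <- as.integer(K)
  if (any(labels < 1L | labels > K))
    stop("labels must lie in 1..K (K = ", K, ")")
  structure(labels, K = K, class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  sizes <- tabulate(unclass(x), nbins = attr(x, "K"))
  cat(sprintf("partition: %d nodes in %d modules (sizes: %s)\n",
              length(x), attr(x, "K"), paste(sizes, collapse = ", ")))
  invisible(x)
}

# Per-module intra-weight fraction W_k/T and volume fraction V_k/T, with
# T = sum(A) counting both orientations of every undirected edge. Both the
# numerators and T use the full double-sum convention, so the factors of 2
# cancel in every index built from them.
module_weight_fractions <- function(net, p) {
  A <- unclass(as.matrix(net))
  labels <- unclass(p)
  if (length(labels) != nrow(A)) stop("partition does not cover the network")
  K <- attr(p, "K")
  Tw <- sum(A)
  if (Tw <= 0) stop("network has zero total weight")
  deg <- rowSums(A)
  W <- V <- numeric(K)
  for (k in seq_len(K)) {
    in_k <- labels == k
    W[k] <- sum(A[in_k, in_k])
    V[k] <- sum(deg[in_k])
  }
  list(W_hat = W / Tw, V_hat = V / Tw, total = Tw)
}

#' Weighted modularity of a partition
#'
#' `sum_k (W_k/T - (V_k/T)^2)` where `W_k` is the intra-module weight of
#' module k (both orientations), `V_k` its volume (sum of weighted degrees)
#' and `T` the total weight of the network — the Newman–Girvan weighted
#' modularity. Lies in \[-1, 1); empty modules contribute 0.
#'
#' @param net a [weighted_network()].
#' @param p a [partition()] covering the nodes of `net`.
#' @return scalar modularity.
#' @export
weighted_modularity <- function(net, p) {
  f <- module_weight_fractions(net, p)
  sum(f$W_hat - f$V_hat^2)
}

#' Mean module conductance (compactness variant)
#'
#' Mean over non-empty modules of `W_k / V_k`, the probability that a
#' one-step random walk started inside module k stays inside it. In
#' \[0, 1\]; higher means more self-contained modules. Modules with zero
#' volume are excluded from the mean with a warning.
#'
#' @inheritParams weighted_modularity
#' @return scalar in \[0, 1\].
#' @export
mean_conductance <- function(net, p) {
  f <- module_weight_fractions(net, p)
  ok <- f$V_hat > 0
  if (!all(ok))
    warning(sum(!ok), " module(s) with zero volume excluded from conductance")
  if (!any(ok)) stop("no module has positive volume")
  mean(f$W_hat[ok] / f$V_hat[ok])
}

#' Coverage: intra-module fraction of total weight
#'
#' `sum_k W_k / T`, in \[0, 1\]; 1 when no weight crosses module borders.
#'
#' @inheritParams weighted_modularity
#' @return scalar in \[0, 1\].
#' @export
weight_coverage <- function(net, p) {
  f <- module_weight_fractions(net, p)
  sum(f$W_hat)
}

#' All three module-quality indices at once
#'
#' @inheritParams weighted_modularity
#' @return list with `modularity`, `conductance`, `coverage`,
#'   `per_module_W` (intra-weight fractions) and `per_module_V` (volume
#'   fractions).
#' @export
module_quality <- function(net, p) {
  f <- module_weight_fractions(net, p)
  ok <- f$V_hat > 0
  list(modularity = sum(f$W_hat - f$V_hat^2),
       conductance = mean(f$W_hat[ok] / f$V_hat[ok]),
       coverage = sum(f$W_hat),
       per_module_W = f$W_hat,
       per_module_V = f$V_hat)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert–Arabie chance-corrected agreement computed from the contingency
#' table: 1 for identical partitions up to label permutation, expectation 0
#' under independent random labelings.
#'
#' @param p1,p2 [partition()]s (or plain label vectors) over one node set.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(p1, p2) {
  a <- as.integer(unclass(p1)); b <- as.integer(unclass(p2))
  if (length(a) != length(b)) stop("partitions cover different node sets")
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)    # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Scan module count and sparsity settings, reporting quality indices
#'
#' For every (K, alpha) pair the factorization is refit with `runs` random
#' restarts, the representative run (highest mean ARI against the others)
#' is kept, and the three indices are reported twice: averaged over
#' per-view evaluations of the shared partition, and evaluated on the
#' element-wise average network.
#'
#' @param set a [multiview_set()] of preprocessed views.
#' @param K_values,alpha_values grids to scan.
#' @param runs restarts per cell.
#' @param seed base seed; each cell derives its own run seeds.
#' @param max_iter,tol forwarded to [jsnmf_config()].
#' @return data.frame with columns K, alpha, eval_mode
#'   (`individual_mean` or `average_network`), modularity, conductance,
#'   coverage — two rows per grid cell.
#' @export
quality_scan <- function(set, K_values, alpha_values, runs = 10, seed = 1L,
                         max_iter = 300, tol = 1e-6) {
  if (!inherits(set, "multiview_set")) set <- multiview_set(set)
  avg <- average_network(set)
  grid <- expand.grid(K = K_values, alpha = alpha_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", 2L * nrow(grid))
  for (g in seq_len(nrow(grid))) {
    K <- grid$K[g]; alpha <- grid$alpha[g]
    cfg <- jsnmf_config(K = K, alpha = alpha, max_iter = max_iter,
                        tol = tol, seed = seed + 1000L * (g - 1L))
    fits <- jsnmf_restarts(set, cfg, runs = runs)
    parts <- lapply(fits, `[[`, "partition")
    if (any(vapply(parts, is.null, logical(1))))
      stop("degenerate factorization in scan cell K=", K, ", alpha=", alpha)
    rep_idx <- if (runs >= 2) select_representative_run(parts) else 1L
    p <- parts[[rep_idx]]
    per_view <- vapply(set$views, function(v) {
      q <- suppressWarnings(module_quality(v, p))
      c(q$modularity, q$conductance, q$coverage)
    }, numeric(3))
    qa <- suppressWarnings(module_quality(avg, p))
    rows[[2 * g - 1]] <- data.frame(
      K = K, alpha = alpha, eval_mode = "individual_mean",
      modularity = mean(per_view[1, ]), conductance = mean(per_view[2, ]),
      coverage = mean(per_view[3, ]))
    rows[[2 * g]] <- data.frame(
      K = K, alpha = alpha, eval_mode = "average_network",
      modularity = qa$modularity, conductance = qa$conductance,
      coverage = qa$coverage)
  }
  do.call(rbind, rows)
}
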