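# Independent brute-force oracles: element-by-element loops, no shared code
# with the implementation under test.

# random symmetric non-negative matrix with zero diagonal
rand_sym <- function(N, seed, scale = 1) {
  withr::with_seed(seed, {
    A <- matrix(runif(N * N), N, N) * scale
    A <- (A + t(A)) / 2
    diag(A) <- 0
    A
  })
}

# objective by explicit summation over all matrix entries
oracle_objective <- function(A_list, H, S_list, alpha) {
  total <- 0
  for (v in seq_along(A_list)) {
    M <- H %*% S_list[[v]] %*% t(H)
    for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
      total <- total + (A_list[[v]][i, j] - M[i, j])^2
  }
  for (i in seq_len(nrow(H))) for (k in seq_len(ncol(H)))
    total <- total + 4 * alpha * H[i, k]
  total
}

# multiplicative H step written entry-by-entry
oracle_update_H <- function(A_list, H, S_list, alpha, eps = 1e-12) {
  N <- nrow(H); K <- ncol(H)
  out <- matrix(0, N, K)
  for (i in seq_len(N)) for (k in seq_len(K)) {
    num <- 0; den <- 0
    for (v in seq_along(A_list)) {
      AHS <- A_list[[v]] %*% H %*% S_list[[v]]
      HSHtHS <- H %*% S_list[[v]] %*% t(H) %*% H %*% S_list[[v]]
      num <- num + AHS[i, k]
      den <- den + HSHtHS[i, k]
    }
    out[i, k] <- H[i, k] * num / (den + alpha + eps)
  }
  out
}

# unconstrained closed-form S, negatives clipped, written independently
oracle_update_S <- function(A, H) {
  M <- t(H) %*% H
  S <- solve(M, t(H)) %*% A %*% H %*% solve(M)
  S <- (S + t(S)) / 2
  S[S < 0] <- 0
  S
}

# W_k, V_k and the three indices by explicit double loops over node pairs
brute_quality <- function(A, labels) {
  N <- nrow(A); K <- max(labels)
  Tw <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) Tw <- Tw + A[i, j]
  W <- V <- numeric(K)
  for (k in seq_len(K)) {
    for (i in seq_len(N)) {
      if (labels[i] != k) next
      for (j in seq_len(N)) {
        V[k] <- V[k] + A[i, j]
        if (labels[j] == k) W[k] <- W[k] + A[i, j]
      }
    }
  }
  W <- W / Tw; V <- V / Tw
  ok <- V > 0
  list(modularity = sum(W - V^2),
       conductance = mean(W[ok] / V[ok]),
       coverage = sum(W))
}

# Hubert-Arabie ARI via explicit counting over all node pairs
pair_count_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  np <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / np
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(1)
  (n11 - expected) / (maxi - expected)
}

# AUC as the Mann-Whitney pairwise statistic (ties count 1/2)
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# small planted two-block single view for optimizer tests
two_block_matrix <- function(sizes = c(5, 5), w = 0.8) {
  N <- sum(sizes)
  lab <- rep(seq_along(sizes), times = sizes)
  A <- ifelse(outer(lab, lab, "=="), w, 0)
  diag(A) <- 0
  A
}
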