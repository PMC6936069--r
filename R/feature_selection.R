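# linear-SVM weight vector w = t(coefs) %*% SV (one weight per feature)
linear_svm_weights <- function(X, y, cost) {
  model <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                      cost = cost, scale = FALSE)
  drop(crossprod(model$coefs, model$SV))
}

# internal RFE on an already-scaled matrix; returns kept column indices
rfe_rank <- function(X, y, cost, n_keep, step) {
  keep <- seq_len(ncol(X))
  while (length(keep) > n_keep) {
    w <- linear_svm_weights(X[, keep, drop = FALSE], y, cost)
    target <- max(n_keep, ceiling(length(keep) * (1 - step)))
    keep <- keep[order(abs(w), decreasing = TRUE)[seq_len(target)]]
    keep <- sort(keep)
  }
  keep
}

# k-fold AUC of a linear SVM on the selected columns; the PSO fitness
cv_auc <- function(X, y, cols, cost, nfolds = 3) {
  folds <- rep_len(seq_len(nfolds), length(y))
  scores <- numeric(length(y))
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(0.5)
    model <- e1071::svm(X[tr, cols, drop = FALSE],
                        factor(y[tr], levels = c(0, 1)),
                        kernel = "linear", cost = cost, scale = FALSE)
    scores[!tr] <- svm_margin(model, X[!tr, cols, drop = FALSE])
  }
  roc_curve(scores, y, threshold_mode = "score_range")$auc
}

# internal binary PSO on an already-scaled matrix; returns kept columns
pso_search <- function(X, y, cost, swarm_size, iterations, seed,
                       w_start = 0.9, w_end = 0.4, c1 = 2, c2 = 2) {
  F <- ncol(X)
  if (F == 1) return(1L)
  withr::with_seed(seed, {
    pos <- matrix(stats::runif(swarm_size * F) < 0.5, swarm_size, F)
    pos[1, ] <- TRUE                      # all-ones particle anchors fitness
    vel <- matrix(stats::runif(swarm_size * F, -1, 1), swarm_size, F)
    repair <- function(mask) {
      if (!any(mask)) mask[sample.int(F, 1)] <- TRUE
      mask
    }
    pos <- t(apply(pos, 1, repair))
    fitness <- apply(pos, 1, function(m) cv_auc(X, y, which(m), cost))
    pbest <- pos; pbest_fit <- fitness
    g <- which.max(fitness)
    gbest <- pos[g, ]; gbest_fit <- fitness[g]
    for (it in seq_len(iterations)) {
      w <- w_start - (w_start - w_end) * (it - 1) / max(1, iterations - 1)
      r1 <- matrix(stats::runif(swarm_size * F), swarm_size, F)
      r2 <- matrix(stats::runif(swarm_size * F), swarm_size, F)
      vel <- w * vel +
        c1 * r1 * (pbest - pos) +
        c2 * r2 * (matrix(gbest, swarm_size, F, byrow = TRUE) - pos)
      prob <- 1 / (1 + exp(-vel))
      pos <- matrix(stats::runif(swarm_size * F), swarm_size, F) < prob
      pos <- t(apply(pos, 1, repair))
      fitness <- apply(pos, 1, function(m) cv_auc(X, y, which(m), cost))
      better <- fitness > pbest_fit
      pbest[better, ] <- pos[better, , drop = FALSE]
      pbest_fit[better] <- fitness[better]
      g <- which.max(pbest_fit)
      if (pbest_fit[g] > gbest_fit) {
        gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
      }
    }
    which(gbest)
  })
}

#' Recursive feature elimination with a linear SVM ranker
#'
#' Repeatedly trains a linear SVM on the surviving (z-scored) features,
#' ranks them by absolute weight, and drops the bottom `step` fraction
#' until `n_keep` remain. With `step = 0.5`, going from 8 features to 2
#' takes exactly two elimination rounds (8 -> 4 -> 2).
#'
#' @param fm a `feature_matrix` with binary labels.
#' @param spec a [classifier_spec()] providing `cost`.
#' @param n_keep number of features to retain (>= 1, <= F).
#' @param step fraction of surviving features removed per round.
#' @return sorted integer vector of selected feature column indices.
#' @export
rfe_select <- function(fm, spec = classifier_spec("rfe_svm"),
                       n_keep = spec$hyperparameters$n_keep,
                       step = spec$hyperparameters$step) {
  X <- fm$features; y <- fm$labels
  if (is.null(y)) stop("feature matrix carries no labels")
  if (n_keep < 1 || n_keep > ncol(X))
    stop("n_keep must lie in 1..", ncol(X))
  sc <- scale_fold(X, X)
  rfe_rank(sc$train, y, cost = spec$hyperparameters$cost %||% 1,
           n_keep = n_keep, step = step)
}

#' Binary particle-swarm feature selection
#'
#' Each particle is a binary feature mask; velocities follow the standard
#' inertia/cognitive/social rule (inertia decaying linearly from 0.9 to
#' 0.4, c1 = c2 = 2) and positions are resampled through a sigmoid of the
#' velocity. Fitness is the internal 3-fold cross-validated AUC of a
#' linear SVM on the masked columns. The all-ones mask is seeded as one
#' initial particle, so the returned global best can never score below
#' using every feature on the internal criterion; all-zero candidate masks
#' are repaired by switching one random feature on.
#'
#' @param fm a `feature_matrix` with binary labels.
#' @param spec a [classifier_spec()] providing `cost`.
#' @param swarm_size particles (>= 2).
#' @param iterations velocity/position updates.
#' @param seed RNG seed; identical seeds give identical masks.
#' @return sorted integer vector of selected feature column indices.
#' @export
pso_select <- function(fm, spec = classifier_spec("pso_svm"),
                       swarm_size = spec$hyperparameters$swarm_size,
                       iterations = spec$hyperparameters$iterations,
                       seed = spec$seed) {
  X <- fm$features; y <- fm$labels
  if (is.null(y)) stop("feature matrix carries no labels")
  if (swarm_size < 2) stop("swarm_size must be >= 2")
  sc <- scale_fold(X, X)
  pso_search(sc$train, y, cost = spec$hyperparameters$cost %||% 1,
             swarm_size = swarm_size, iterations = iterations, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
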