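#' Specify a classifier for LOOCV evaluation
#'
#' Wraps the seven evaluated classifier families behind one interface.
#' SVM-family members emit a signed margin as the decision score and are
#' swept over the observed score range when building ROC curves; the
#' others emit a class-1 probability swept over \[0, 1\].
#'
#' @param method one of `"linear_svm"`, `"pso_svm"`, `"rfe_svm"`,
#'   `"random_forest"`, `"lda"`, `"lasso_logistic"`, `"knn"`.
#' @param seed RNG seed governing every stochastic part (tree bagging, PSO,
#'   internal CV folds).
#' @param ... method-specific hyperparameters: `cost` (SVM, default 1),
#'   `ntree` (random forest, default 500), `k` (kNN, default 5),
#'   `n_keep`/`step` (RFE), `swarm_size`/`iterations` (PSO).
#' @return list of class `classifier_spec` with elements `kind`,
#'   `hyperparameters`, `seed`.
#' @export
classifier_spec <- function(method = c("linear_svm", "pso_svm", "rfe_svm",
                                       "random_forest", "lda",
                                       "lasso_logistic", "knn"),
                            seed = 1L, ...) {
  kind <- match.arg(method)
  hp <- list(...)
  defaults <- switch(kind,
    linear_svm = list(cost = 1),
    pso_svm = list(cost = 1, swarm_size = 20, iterations = 30),
    rfe_svm = list(cost = 1, n_keep = 32, step = 0.5),
    random_forest = list(ntree = 500),
    lda = list(),
    lasso_logistic = list(nfolds = 3),
    knn = list(k = 5))
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(hp)] <- hp
  structure(list(kind = kind, hyperparameters = defaults,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Default threshold sweep for a classifier kind
#' @param spec a [classifier_spec()].
#' @return `"score_range"` for the SVM family, `"unit_interval"` otherwise.
#' @export
threshold_mode_for <- function(spec) {
  if (spec$kind %in% c("linear_svm", "pso_svm", "rfe_svm"))
    "score_range" else "unit_interval"
}

# z-score train columns, apply the train moments to test; zero-variance
# columns collapse to 0 in both (no information, no leakage)
scale_fold <- function(X_train, X_test) {
  mu <- colMeans(X_train)
  sd <- apply(X_train, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- Inf
  list(train = sweep(sweep(X_train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(X_test, 2, mu), 2, sd, "/"))
}

svm_margin <- function(model, X) {
  dv <- attr(stats::predict(model, X, decision.values = TRUE),
             "decision.values")
  # e1071's margin is signed toward the first factor level of the pair
  # named in the column ("0/1" => positive means class 0); orient so that
  # positive margin always means class "1"
  d <- drop(dv)
  if (startsWith(colnames(dv)[1], "0/")) -d else d
}

fit_and_score <- function(kind, hp, X_train, y_train, X_test, fold_seed) {
  y_f <- factor(y_train, levels = c(0, 1))
  if (kind %in% c("linear_svm", "pso_svm", "rfe_svm")) {
    model <- e1071::svm(X_train, y_f, kernel = "linear", cost = hp$cost,
                        scale = FALSE)
    return(svm_margin(model, X_test))
  }
  switch(kind,
    random_forest = {
      withr::with_seed(fold_seed, {
        model <- randomForest::randomForest(X_train, y_f, ntree = hp$ntree)
      })
      unname(stats::predict(model, X_test, type = "prob")[, "1"])
    },
    lda = {
      keep <- apply(X_train, 2, function(col) stats::sd(col) > 0)
      model <- suppressWarnings(
        MASS::lda(X_train[, keep, drop = FALSE], grouping = y_f))
      unname(stats::predict(model,
                            X_test[, keep, drop = FALSE])$posterior[, "1"])
    },
    lasso_logistic = {
      foldid <- rep_len(seq_len(hp$nfolds), length(y_train))
      # glmnet warns about small class counts on desk-scale cohorts
      cv <- suppressWarnings(
        glmnet::cv.glmnet(X_train, y_f, family = "binomial",
                          foldid = foldid, type.measure = "deviance"))
      as.numeric(stats::predict(cv, X_test, s = "lambda.min",
                                type = "response"))
    },
    knn = {
      k <- min(hp$k, length(y_train))
      pred <- withr::with_seed(fold_seed,
        class::knn(X_train, X_test, cl = y_f, k = k, prob = TRUE))
      pwin <- attr(pred, "prob")
      ifelse(pred == "1", pwin, 1 - pwin)
    },
    stop("unhandled classifier kind: ", kind))
}

#' Leave-one-out cross-validated decision scores
#'
#' Each subject is scored by a model trained on all other subjects.
#' Features are z-scored within the training fold only and the test row is
#' transformed with the training moments, so no information leaks from the
#' held-out subject. For `rfe_svm` and `pso_svm` the feature-selection step
#' is re-run inside every fold on the training subjects alone.
#'
#' @param fm a `feature_matrix` with binary labels (at least two subjects
#'   per class).
#' @param spec a [classifier_spec()].
#' @return numeric vector of per-subject decision scores (signed margin for
#'   the SVM family, class-1 probability otherwise), named by subject.
#' @export
loocv_scores <- function(fm, spec) {
  X <- fm$features
  y <- fm$labels
  if (is.null(y)) stop("feature matrix carries no labels")
  if (min(table(factor(y, levels = c(0, 1)))) < 2)
    stop("need at least 2 subjects per class")
  n <- nrow(X)
  hp <- spec$hyperparameters
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2)
      stop("training fold ", i, " contains a single class")
    sc <- scale_fold(X[tr, , drop = FALSE], X[i, , drop = FALSE])
    fold_seed <- spec$seed + i
    sel <- seq_len(ncol(X))
    if (spec$kind == "rfe_svm") {
      sel <- rfe_rank(sc$train, y[tr], cost = hp$cost,
                      n_keep = min(hp$n_keep, ncol(X)), step = hp$step)
    } else if (spec$kind == "pso_svm") {
      sel <- pso_search(sc$train, y[tr], cost = hp$cost,
                        swarm_size = hp$swarm_size,
                        iterations = hp$iterations, seed = fold_seed)
    }
    scores[i] <- fit_and_score(spec$kind, hp,
                               sc$train[, sel, drop = FALSE], y[tr],
                               sc$test[, sel, drop = FALSE], fold_seed)
  }
  names(scores) <- fm$subjects
  scores
}

#' ROC curve from decision scores
#'
#' At each threshold t a subject is predicted positive iff its score is
#' `>= t`; TPR = TP/P and FPR = FP/N. `"score_range"` sweeps the sorted
#' unique observed scores, `"unit_interval"` an even grid on \[0, 1\]
#' (`grid_points` points); both sweeps are bracketed by -Inf and +Inf so
#' the curve always contains (0,0) and (1,1).
#'
#' @param scores numeric decision scores.
#' @param labels binary 0/1 truth, same length.
#' @param threshold_mode `"score_range"` or `"unit_interval"`.
#' @param grid_points grid size for the unit-interval sweep.
#' @return object of class `roc_result`: list with `thresholds`
#'   (decreasing), `tpr`, `fpr`, and `auc` (filled by [roc_auc()]).
#' @export
roc_curve <- function(scores, labels,
                      threshold_mode = c("score_range", "unit_interval"),
                      grid_points = 101) {
  threshold_mode <- match.arg(threshold_mode)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0 || N == 0) stop("need at least one subject in each class")
  grid <- if (threshold_mode == "score_range") sort(unique(scores))
          else seq(0, 1, length.out = grid_points)
  thresholds <- c(Inf, rev(grid), -Inf)     # decreasing => FPR increasing
  tpr <- fpr <- numeric(length(thresholds))
  for (t in seq_along(thresholds)) {
    pos <- scores >= thresholds[t]
    tpr[t] <- sum(pos & labels == 1L) / P
    fpr[t] <- sum(pos & labels == 0L) / N
  }
  res <- structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                        auc = NA_real_, threshold_mode = threshold_mode),
                   class = "roc_result")
  res$auc <- roc_auc(res)
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: %d thresholds (%s sweep), AUC = %.4f\n",
              length(x$thresholds), x$threshold_mode, x$auc))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' Points are sorted by FPR (ties keep the higher-TPR point later, the
#' staircase's outer corner) and TPR is integrated over FPR by the
#' trapezoidal rule.
#'
#' @param roc a [roc_curve()] result.
#' @return scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  ord <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[ord]; y <- roc$tpr[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Compare module-restricted and whole-network features across classifiers
#'
#' For every classifier spec, runs LOOCV twice — once on edge features
#' restricted to module `module_k` of `p`, once on all pairwise features —
#' and reports both AUCs (threshold sweep chosen per classifier family).
#'
#' @param nets list of per-subject [weighted_network()]s.
#' @param labels binary class labels, one per subject.
#' @param p a [partition()] over the shared node set.
#' @param module_k index of the module whose edges form the restricted
#'   feature scope.
#' @param specs list of [classifier_spec()]s (named or not).
#' @return data.frame with columns classifier, scope
#'   (`module`/`whole_network`), n_features, auc.
#' @export
compare_feature_scopes <- function(nets, labels, p, module_k, specs) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  ids <- rownames(as.matrix(nets[[1]]))
  scope <- module_nodes(p, module_k, node_ids = ids)
  if (length(scope) < 2)
    stop("module ", module_k, " has fewer than 2 nodes")
  fm_mod <- extract_features(nets, scope = scope, labels = labels)
  fm_all <- extract_features(nets, scope = NULL, labels = labels)
  rows <- lapply(specs, function(spec) {
    auc_of <- function(fm) {
      sc <- loocv_scores(fm, spec)
      roc_curve(sc, fm$labels, threshold_mode = threshold_mode_for(spec))$auc
    }
    data.frame(classifier = spec$kind,
               scope = c("module", "whole_network"),
               n_features = c(ncol(fm_mod$features), ncol(fm_all$features)),
               auc = c(auc_of(fm_mod), auc_of(fm_all)))
  })
  do.call(rbind, rows)
}
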