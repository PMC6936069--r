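#' Configuration for planted-module multi-view network generation
#'
#' Emulates a cohort of correlation-weighted brain networks that share one
#' modular organization: every view draws edge weights around a common
#' within-module mean `p_in_mean` and between-module mean `p_out_mean`
#' (correlation scale, in \[0, 1\]) with per-view Gaussian jitter, then
#' the same negative-removal/threshold filter used on real networks is
#' applied.
#'
#' @param N nodes per network.
#' @param K planted modules.
#' @param n_views number of subjects/views.
#' @param module_sizes optional explicit sizes summing to `N`; default
#'   near-equal split.
#' @param p_in_mean,p_out_mean mean edge weight within / between modules;
#'   `0 <= p_out_mean < p_in_mean <= 1`.
#' @param noise_sd standard deviation of the per-edge jitter.
#' @param threshold post-generation cutoff, applied as in
#'   [preprocess_fbn()].
#' @param seed RNG seed.
#' @return list of class `planted_config`.
#' @export
planted_config <- function(N = 60, K = 3, n_views = 5,
                           module_sizes = NULL,
                           p_in_mean = 0.7, p_out_mean = 0.2,
                           noise_sd = 0.05, threshold = 0, seed = 1L) {
  stopifnot(N >= 2, K >= 1, K <= N, n_views >= 1,
            noise_sd >= 0, threshold >= 0)
  if (!(p_out_mean >= 0 && p_out_mean < p_in_mean && p_in_mean <= 1))
    stop("need 0 <= p_out_mean < p_in_mean <= 1")
  if (is.null(module_sizes)) {
    module_sizes <- rep(N %/% K, K)
    extra <- N - sum(module_sizes)
    if (extra > 0) module_sizes[seq_len(extra)] <-
        module_sizes[seq_len(extra)] + 1L
  }
  if (sum(module_sizes) != N) stop("module_sizes must sum to N")
  if (any(module_sizes < 1)) stop("every module needs at least one node")
  structure(list(N = as.integer(N), K = as.integer(K),
                 n_views = as.integer(n_views),
                 module_sizes = as.integer(module_sizes),
                 p_in_mean = p_in_mean, p_out_mean = p_out_mean,
                 noise_sd = noise_sd, threshold = threshold,
                 seed = as.integer(seed)),
            class = "planted_config")
}

planted_labels <- function(config) {
  rep(seq_len(config$K), times = config$module_sizes)
}

# one symmetric view around the given mean structure; weights clipped to
# [0,1], zero diagonal, then the standard filter
draw_view <- function(mean_mat, noise_sd, threshold, node_ids) {
  N <- nrow(mean_mat)
  W <- matrix(0, N, N)
  ut <- upper.tri(W)
  W[ut] <- stats::rnorm(sum(ut), mean = mean_mat[ut], sd = noise_sd)
  W <- W + t(W)
  W[W < 0] <- 0
  W[W > 1] <- 1
  diag(W) <- 0
  rownames(W) <- colnames(W) <- node_ids
  preprocess_fbn(W, threshold = threshold)
}

#' Generate multi-view networks with one planted partition
#'
#' @param config a [planted_config()].
#' @return list with `set` (a [multiview_set()]) and `partition` (the
#'   ground-truth [partition()], named by node). Deterministic given
#'   `config$seed`. Errors if the threshold disconnects every view.
#' @export
generate_multiview <- function(config) {
  labels <- planted_labels(config)
  node_ids <- paste0("V", seq_len(config$N))
  mean_mat <- ifelse(outer(labels, labels, "=="),
                     config$p_in_mean, config$p_out_mean)
  views <- withr::with_seed(config$seed,
    lapply(seq_len(config$n_views), function(v)
      draw_view(mean_mat, config$noise_sd, config$threshold, node_ids)))
  if (config$threshold > 0 &&
      !any(vapply(views, is_connected, logical(1))))
    stop("every generated view is disconnected at threshold ",
         config$threshold, "; lower the threshold")
  p <- partition(labels, K = config$K)
  names(p) <- node_ids
  list(set = multiview_set(views), partition = p)
}

#' Configuration for a labeled two-group cohort
#'
#' Extends [planted_config()] with a case/control design: control
#' subjects are plain draws from the planted model, while case subjects
#' have the mean weight of every within-`effect_module` edge shifted by
#' `+effect_delta` (clipped to \[0, 1\]), concentrating the group
#' difference inside one module.
#'
#' @param ... arguments passed to [planted_config()]; `n_views` is ignored
#'   in favor of `n_per_group`.
#' @param n_per_group subjects per class.
#' @param effect_module module index (1..K) carrying the group difference.
#' @param effect_delta non-negative mean shift for the positive class.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(..., n_per_group = 20, effect_module = 1,
                          effect_delta = 0.2) {
  base <- planted_config(...)
  stopifnot(n_per_group >= 2, effect_delta >= 0)
  if (effect_module < 1 || effect_module > base$K)
    stop("effect_module must lie in 1..K")
  base$n_per_group <- as.integer(n_per_group)
  base$effect_module <- as.integer(effect_module)
  base$effect_delta <- effect_delta
  class(base) <- c("cohort_config", class(base))
  base
}

#' Generate a labeled two-group cohort of networks
#'
#' @param config a [cohort_config()].
#' @return list with `networks` (list of 2*n_per_group
#'   [weighted_network()]s, controls first), `labels` (0 = control,
#'   1 = case), and `partition` (ground truth). Deterministic given
#'   `config$seed`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("need a cohort_config")
  labels_nodes <- planted_labels(config)
  node_ids <- paste0("V", seq_len(config$N))
  base_mean <- ifelse(outer(labels_nodes, labels_nodes, "=="),
                      config$p_in_mean, config$p_out_mean)
  in_eff <- labels_nodes == config$effect_module
  case_mean <- base_mean
  case_mean[in_eff, in_eff] <- pmin(1, base_mean[in_eff, in_eff] +
                                      config$effect_delta)
  nets <- withr::with_seed(config$seed, {
    controls <- lapply(seq_len(config$n_per_group), function(s)
      draw_view(base_mean, config$noise_sd, config$threshold, node_ids))
    cases <- lapply(seq_len(config$n_per_group), function(s)
      draw_view(case_mean, config$noise_sd, config$threshold, node_ids))
    c(controls, cases)
  })
  if (config$threshold > 0 &&
      !any(vapply(nets, is_connected, logical(1))))
    stop("every generated network is disconnected at threshold ",
         config$threshold, "; lower the threshold")
  y <- rep(c(0L, 1L), each = config$n_per_group)
  names(nets) <- paste0(ifelse(y == 0, "ctrl", "case"),
                        sequence(c(config$n_per_group, config$n_per_group)))
  p <- partition(labels_nodes, K = config$K)
  names(p) <- node_ids
  list(networks = nets, labels = y, partition = p)
}
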