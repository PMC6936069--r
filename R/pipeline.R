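#' Run the full module-based feature-selection pipeline
#'
#' Executes the end-to-end study design on a labeled cohort of networks:
#' (1) preprocess every network (negative removal + threshold);
#' (2) fit the joint factorization on the control group's networks only —
#' disease can alter modular organization, so modules are learned from
#' controls — with random restarts; (3) keep the representative run
#' (highest mean ARI against the other runs); (4) compute module-quality
#' indices per view and on the average network; (5) identify the module of
#' interest (explicit index, or best Jaccard match to a reference node
#' set, or the largest module); (6) extract module-scope and whole-network
#' edge features for all subjects and compare classifiers by LOOCV AUC.
#'
#' Every stage's outputs are written to `out_dir` as TSV/JSON, plus a
#' manifest recording parameters, seeds and completed stages. Reruns with
#' identical inputs and seed reproduce every artifact.
#'
#' @param networks list of per-subject networks (matrices or
#'   [weighted_network()]s) over one node set; raw signed correlations are
#'   fine, preprocessing is stage 1.
#' @param labels binary vector, 1 = case (positive class), 0 = control.
#' @param out_dir artifact directory (created if needed).
#' @param threshold edge-weight cutoff for [preprocess_fbn()].
#' @param K,alpha,max_iter,tol factorization settings ([jsnmf_config()]).
#' @param runs random restarts for the clustering stage.
#' @param seed global seed propagated to every stochastic stage.
#' @param cluster_on `"controls"` (default) or `"all"` subjects.
#' @param module_k explicit module index for the feature scope, or `NULL`.
#' @param reference_nodes node ids to match a module against when
#'   `module_k` is `NULL`.
#' @param specs list of [classifier_spec()]s for the comparison stage.
#' @return invisibly, a list with the partition, fit, quality table,
#'   selected module, comparison table and manifest path.
#' @export
run_pipeline <- function(networks, labels, out_dir,
                         threshold = 0.35, K = 4, alpha = 1,
                         max_iter = 300, tol = 1e-6, runs = 10, seed = 1L,
                         cluster_on = c("controls", "all"),
                         module_k = NULL, reference_nodes = NULL,
                         specs = list(classifier_spec("lda", seed = seed))) {
  cluster_on <- match.arg(cluster_on)
  labels <- as.integer(labels)
  if (length(labels) != length(networks))
    stop("one label per network required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  t0 <- Sys.time()

  # 1 -- preprocess
  nets <- lapply(networks, preprocess_fbn, threshold = threshold)
  connected <- vapply(nets, is_connected, logical(1))
  if (!all(connected))
    warning(sum(!connected), " network(s) disconnected at threshold ",
            threshold)
  stages <- c(stages, "preprocess")

  # 2 -- cluster on the designated group's views
  idx_cluster <- if (cluster_on == "controls") which(labels == 0L)
                 else seq_along(nets)
  if (!length(idx_cluster)) stop("no networks in the clustering group")
  set <- multiview_set(nets[idx_cluster])
  cfg <- jsnmf_config(K = K, alpha = alpha, max_iter = max_iter,
                      tol = tol, seed = seed)
  fits <- jsnmf_restarts(set, cfg, runs = runs)
  stages <- c(stages, "cluster")

  # 3 -- representative run
  parts <- lapply(fits, `[[`, "partition")
  if (any(vapply(parts, is.null, logical(1))))
    stop("stage cluster: degenerate factorization (all-zero H column)")
  rep_idx <- if (runs >= 2) select_representative_run(parts) else 1L
  fit <- fits[[rep_idx]]
  p <- fit$partition
  names(p) <- set$node_ids
  utils::write.table(
    data.frame(node_id = set$node_ids, module = unclass(p)),
    file.path(out_dir, "partition.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(iteration = seq_along(fit$objective_trace) - 1L,
               objective = fit$objective_trace),
    file.path(out_dir, "objective_trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(fit$H, digits = 10, trim = TRUE),
                     file.path(out_dir, "H.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  stages <- c(stages, "select_run")

  # 4 -- quality indices with the shared partition
  per_view <- vapply(set$views, function(v) {
    q <- suppressWarnings(module_quality(v, p))
    c(q$modularity, q$conductance, q$coverage)
  }, numeric(3))
  qa <- suppressWarnings(module_quality(average_network(set), p))
  quality <- data.frame(
    eval_mode = c("individual_mean", "average_network"),
    modularity = c(mean(per_view[1, ]), qa$modularity),
    conductance = c(mean(per_view[2, ]), qa$conductance),
    coverage = c(mean(per_view[3, ]), qa$coverage))
  utils::write.table(quality, file.path(out_dir, "quality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "metrics")

  # 5 -- module of interest
  overlap <- NA_real_
  if (is.null(module_k)) {
    if (!is.null(reference_nodes)) {
      m <- match_module_to_reference(p, reference_nodes)
      module_k <- m$module; overlap <- m$overlap
    } else {
      module_k <- which.max(tabulate(unclass(p), nbins = attr(p, "K")))
    }
  }
  stages <- c(stages, "match_module")

  # 6 -- feature extraction + classification comparison on all subjects
  comparison <- compare_feature_scopes(nets, labels, p, module_k, specs)
  utils::write.table(comparison, file.path(out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "classify")

  manifest <- list(
    package_version = as.character(utils::packageVersion("jsnmf")),
    r_version = R.version.string,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    parameters = list(threshold = threshold, K = K, alpha = alpha,
                      max_iter = max_iter, tol = tol, runs = runs,
                      seed = seed, cluster_on = cluster_on,
                      module_k = module_k),
    n_subjects = length(networks),
    n_cluster_views = length(idx_cluster),
    representative_run = rep_idx,
    module_overlap = overlap,
    disconnected_views = sum(!connected),
    stages_completed = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(partition = p, fit = fit, quality = quality,
                 module_k = module_k, comparison = comparison,
                 manifest = file.path(out_dir, "manifest.json")))
}
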