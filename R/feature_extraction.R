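#' Per-subject edge-weight feature matrix
#'
#' One row per subject, one column per unordered node pair (i < j in node
#' order) within the requested scope, in lexicographic pair order; the
#' column names are `"i|j"`. With `scope = NULL` all nodes participate and
#' the column count is `N(N-1)/2`; a module scope of m nodes yields
#' `m(m-1)/2` columns.
#'
#' @param nets list of [weighted_network()]s over one node set (one per
#'   subject); typically preprocessed, but raw signed correlation matrices
#'   are accepted when `allow_negative = TRUE`.
#' @param scope character vector of node ids (>= 2) or `NULL` for the whole
#'   network.
#' @param labels optional binary class vector (0/1), one per subject.
#' @param subjects optional subject ids; default `names(nets)` or `S1..Sn`.
#' @param allow_negative accept networks with negative entries (skips the
#'   [weighted_network()] validation).
#' @return object of class `feature_matrix`: list with `features`
#'   (subjects x F matrix), `feature_names`, `subjects`, `labels`.
#' @export
extract_features <- function(nets, scope = NULL, labels = NULL,
                             subjects = NULL, allow_negative = FALSE) {
  if (!length(nets)) stop("no networks supplied")
  mats <- lapply(nets, function(v) unclass(as.matrix(v)))
  ids <- rownames(mats[[1]])
  if (is.null(ids)) ids <- paste0("V", seq_len(nrow(mats[[1]])))
  for (m in mats) {
    if (nrow(m) != length(ids)) stop("networks differ in size")
    if (!allow_negative && min(m) < 0)
      stop("negative weights present; preprocess or set allow_negative")
  }
  if (is.null(scope)) scope <- ids
  scope <- as.character(scope)
  missing <- setdiff(scope, ids)
  if (length(missing))
    stop("scope nodes absent from networks: ", paste(missing, collapse = ", "))
  if (length(scope) < 2) stop("scope must contain at least 2 nodes")
  idx <- match(scope, ids)
  idx <- sort(idx)                         # keep node order, not scope order
  pairs <- which(upper.tri(diag(length(idx))), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  fnames <- paste(ids[idx][pairs[, 1]], ids[idx][pairs[, 2]], sep = "|")
  X <- matrix(NA_real_, length(mats), nrow(pairs))
  for (s in seq_along(mats)) {
    sub <- mats[[s]][idx, idx, drop = FALSE]
    X[s, ] <- sub[pairs]
  }
  colnames(X) <- fnames
  if (is.null(subjects)) {
    subjects <- names(nets)
    if (is.null(subjects)) subjects <- paste0("S", seq_along(nets))
  }
  rownames(X) <- subjects
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(nets)) stop("one label per subject required")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  }
  structure(list(features = X, feature_names = fnames,
                 subjects = subjects, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d edge features%s\n",
              nrow(x$features), ncol(x$features),
              if (is.null(x$labels)) "" else
                sprintf(" (%d positive / %d negative)",
                        sum(x$labels == 1), sum(x$labels == 0))))
  invisible(x)
}

#' Identify the module best matching a reference node set
#'
#' Scores each module by Jaccard overlap with the reference
#' (`|M_k ∩ R| / |M_k ∪ R|`) and returns the argmax, ties to the smallest
#' module index. Used to pin an anatomically defined system — e.g. the
#' default mode network's core regions — onto a data-driven partition.
#'
#' @param p a [partition()] whose names (or `node_ids`) identify the nodes.
#' @param reference_nodes non-empty character vector of node ids.
#' @param node_ids node ids aligned with `p`; defaults to `names(p)`.
#' @return list with `module` (index) and `overlap` (Jaccard value);
#'   a reference disjoint from every module returns module 1 with overlap 0
#'   and a warning.
#' @export
match_module_to_reference <- function(p, reference_nodes, node_ids = NULL) {
  if (!length(reference_nodes)) stop("reference node set is empty")
  if (is.null(node_ids)) node_ids <- names(p)
  if (is.null(node_ids)) stop("node ids needed to interpret the reference")
  labels <- unclass(p)
  K <- attr(p, "K")
  ref <- unique(as.character(reference_nodes))
  jac <- vapply(seq_len(K), function(k) {
    members <- node_ids[labels == k]
    inter <- length(intersect(members, ref))
    uni <- length(union(members, ref))
    if (uni == 0) 0 else inter / uni
  }, numeric(1))
  best <- which.max(jac)
  if (jac[best] == 0)
    warning("reference nodes overlap no module; returning module ", best)
  list(module = best, overlap = jac[best])
}

#' Node ids belonging to one module
#' @param p a [partition()] with node names or explicit `node_ids`.
#' @param k module index.
#' @param node_ids node ids aligned with `p`.
#' @return character vector of member node ids.
#' @export
module_nodes <- function(p, k, node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- names(p)
  if (is.null(node_ids)) stop("node ids required")
  node_ids[unclass(p) == k]
}

#' Write / read a feature matrix as TSV
#'
#' The TSV has a `subject` column, one column per `"i|j"` edge feature and,
#' when labels exist, a final `label` column.
#'
#' @param fm a `feature_matrix`.
#' @param path file path.
#' @return `read_feature_matrix` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(subject = fm$subjects, fm$features,
                   check.names = FALSE)
  if (!is.null(fm$labels)) df$label <- fm$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  subjects <- as.character(df$subject)
  df$subject <- NULL
  X <- as.matrix(df)
  rownames(X) <- subjects
  structure(list(features = X, feature_names = colnames(X),
                 subjects = subjects, labels = labels),
            class = "feature_matrix")
}
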