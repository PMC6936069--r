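#' Construct a weighted undirected network
#'
#' A weighted network is stored as a symmetric non-negative numeric matrix
#' with a zero diagonal; row and column names carry the node identifiers.
#' This is the common currency of the package: one subject's functional
#' brain network, with edge weights derived from Pearson correlations of
#' regional activity.
#'
#' @param weights square numeric matrix of edge weights.
#' @param node_ids character vector of unique node identifiers; defaults to
#'   existing dimnames, else `"V1"..."VN"`.
#' @param tol tolerance for the symmetry check.
#' @return a `weighted_network`: the validated matrix with class attribute.
#' @export
weighted_network <- function(weights, node_ids = NULL, tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("adjacency matrix must be square, got ", nrow(weights), "x", ncol(weights))
  if (anyNA(weights))
    stop("adjacency matrix contains NA/NaN entries")
  if (max(abs(weights - t(weights))) > tol)
    stop("adjacency matrix is asymmetric beyond tolerance ", format(tol))
  if (min(weights) < 0)
    stop("adjacency matrix has negative entries; remove or preprocess first")
  n <- nrow(weights)
  if (is.null(node_ids)) {
    node_ids <- if (!is.null(rownames(weights))) rownames(weights) else paste0("V", seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("length(node_ids) != matrix dimension")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  weights <- (weights + t(weights)) / 2   # wash out sub-tolerance asymmetry
  diag(weights) <- 0
  dimnames(weights) <- list(node_ids, node_ids)
  class(weights) <- c("weighted_network", class(weights))
  weights
}

#' @export
print.weighted_network <- function(x, ...) {
  nz <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("weighted_network: %d nodes, %d edges, total weight %.4g\n",
              nrow(x), nz, sum(x)))
  invisible(x)
}

#' Bundle per-subject networks sharing one node set
#'
#' @param views list of `weighted_network` (or symmetric matrices) with
#'   identical node identifiers in identical order.
#' @return a `multiview_set`, a list with elements `views` and `node_ids`.
#' @export
multiview_set <- function(views) {
  if (length(views) < 1) stop("need at least one view")
  views <- lapply(views, function(v) {
    if (inherits(v, "weighted_network")) v else weighted_network(v)
  })
  ids <- rownames(views[[1]])
  for (v in views[-1]) {
    if (!identical(rownames(v), ids))
      stop("all views must share one node_ids ordering")
  }
  structure(list(views = views, node_ids = ids, n = length(views)),
            class = "multiview_set")
}

#' @export
print.multiview_set <- function(x, ...) {
  cat(sprintf("multiview_set: %d views over %d nodes\n",
              x$n, length(x$node_ids)))
  invisible(x)
}

#' Read a network from a delimited file
#'
#' Two formats are supported. `"dense"`: a whitespace- or comma-delimited
#' square numeric matrix, optionally with a header row of node ids; the
#' matrix must already be symmetric within `tol`. `"edgelist"`: three
#' columns (source, target, weight); each row is mirrored so the result is
#' undirected, and duplicate (i,j)/(j,i) rows must agree in weight.
#'
#' @param path file path.
#' @param format `"dense"` or `"edgelist"`.
#' @param node_ids for edge lists, the full ordered node set (edge lists
#'   need not mention isolated nodes); defaults to the sorted ids seen.
#' @param tol symmetry tolerance for dense input.
#' @return a [weighted_network()].
#' @export
read_network <- function(path, format = c("dense", "edgelist"),
                         node_ids = NULL, tol = 1e-8) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dense") {
    first <- readLines(path, n = 1L)
    has_header <- is.na(suppressWarnings(
      as.numeric(strsplit(trimws(first), "[,\t ]+")[[1]][1])))
    m <- as.matrix(utils::read.table(path, header = has_header,
                                     sep = "", check.names = FALSE))
    if (!is.numeric(m)) stop("dense matrix file has non-numeric entries")
    if (has_header) rownames(m) <- colnames(m)
    if (anyNA(m)) stop("dense matrix file contains NA/NaN")
    if (nrow(m) != ncol(m)) stop("dense matrix file is not square")
    if (max(abs(m - t(m))) > tol)
      stop("dense matrix is asymmetric beyond tolerance ", format(tol))
    return(weighted_network(m, tol = tol))
  }
  el <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("source", "target", "weight"),
                          colClasses = c("character", "character", "numeric"))
  if (anyNA(el$weight)) stop("edge list contains NA weights")
  if (is.null(node_ids)) node_ids <- sort(unique(c(el$source, el$target)))
  node_ids <- as.character(node_ids)
  missing <- setdiff(unique(c(el$source, el$target)), node_ids)
  if (length(missing))
    stop("edge list mentions nodes absent from node_ids: ",
         paste(missing, collapse = ", "))
  n <- length(node_ids)
  A <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(el))) {
    i <- el$source[r]; j <- el$target[r]; w <- el$weight[r]
    key <- paste(sort(c(i, j)), collapse = "\r")
    prev <- get0(key, envir = seen)
    if (!is.null(prev) && abs(prev - w) > tol)
      stop("conflicting duplicate edge-list rows for (", i, ",", j, "): ",
           prev, " vs ", w)
    assign(key, w, envir = seen)
    A[i, j] <- w
    A[j, i] <- w
  }
  weighted_network(A, node_ids, tol = tol)
}

#' Write a network as a dense delimited matrix with a header of node ids
#' @param net a [weighted_network()].
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  utils::write.table(format(unclass(net), digits = 10, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a node metadata table
#'
#' Tab-separated columns `node_id`, optionally `x`, `y`, `z` (spatial
#' coordinates, e.g. MNI-152 mm) and `label`. Coordinates must be all
#' present or all absent per row.
#'
#' @param path TSV path with a header row.
#' @return data.frame with unique `node_id`.
#' @export
read_node_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"node_id" %in% names(tab)) stop("node table needs a node_id column")
  tab$node_id <- as.character(tab$node_id)
  if (anyDuplicated(tab$node_id)) stop("duplicate node_id in node table")
  coord <- intersect(c("x", "y", "z"), names(tab))
  if (length(coord) %in% c(1L, 2L))
    stop("coordinate columns must be x, y and z together")
  if (length(coord) == 3L) {
    nmiss <- rowSums(is.na(tab[coord]))
    if (any(nmiss %in% c(1L, 2L)))
      stop("rows must have all three coordinates or none")
  }
  tab
}

#' Filter a functional brain network the way correlation FBNs are built
#'
#' Negative correlations are removed first, then weights below `threshold`
#' are zeroed; a weight exactly equal to the threshold survives. The
#' diagonal is forced to zero. The filter is idempotent and never increases
#' an entry.
#'
#' @param net matrix or [weighted_network()]; may contain negative entries.
#' @param threshold non-negative cutoff (default 0.35, the conventional
#'   correlation cutoff for retaining non-noise edges).
#' @return a [weighted_network()] whose non-zero entries are all
#'   `>= threshold`.
#' @export
preprocess_fbn <- function(net, threshold = 0.35) {
  if (threshold < 0) stop("threshold must be >= 0")
  W <- unclass(as.matrix(net))
  if (anyNA(W)) stop("network contains NA entries")
  W[W < 0] <- 0
  W[W < threshold] <- 0
  diag(W) <- 0
  weighted_network(W, rownames(net))
}

#' Is the positive-weight graph connected?
#'
#' @param net a [weighted_network()].
#' @return `TRUE` iff edges with weight > 0 form a single connected
#'   component spanning all nodes (an isolated node makes it `FALSE`).
#' @export
is_connected <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(unclass(as.matrix(net)) > 0,
                                           mode = "undirected", diag = FALSE)
  igraph::is_connected(g)
}

#' Element-wise mean network of a multi-view set
#'
#' @param set a [multiview_set()] (views are expected to be preprocessed
#'   already; the mean of symmetric non-negative matrices is again one).
#' @return a [weighted_network()].
#' @export
average_network <- function(set) {
  if (!inherits(set, "multiview_set")) set <- multiview_set(set)
  acc <- Reduce(`+`, lapply(set$views, unclass))
  weighted_network(acc / set$n, set$node_ids)
}
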