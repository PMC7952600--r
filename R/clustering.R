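pca_scores <- function(u, n_pcs) {
  n_pcs <- min(n_pcs, ncol(u), nrow(u) - 1L)
  p <- stats::prcomp(u, center = TRUE, scale. = FALSE)
  p$x[, seq_len(n_pcs), drop = FALSE]
}

# Shared-nearest-neighbor graph with Jaccard weights over the k-nearest
# neighbor sets (self included), pruned below 1/15.
snn_graph <- function(scores, k, prune = 1 / 15) {
  n <- nrow(scores)
  if (n <= k) stop("fewer cells than n_neighbors")
  nn <- RANN::nn2(scores, k = k)$nn.idx
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  g
}

#' Embed corrected antibody profiles in two dimensions
#'
#' Principal components of the corrected matrix feed a k-nearest-neighbor
#' UMAP layout. Defaults follow the conventional parameterization for this
#' assay: 15 neighbors, first 16 principal components, minimum distance 0.2
#' (0.1 for continuum-like samples).
#'
#' @param u Corrected antibody matrix (cells x antibodies).
#' @param n_neighbors Neighborhood size (>= 2).
#' @param n_pcs Number of principal components (capped at the antibody
#'   count); use `Inf` for all.
#' @param min_dist UMAP minimum distance.
#' @param seed Random seed; identical seeds reproduce coordinates exactly.
#' @return List of class `embedding_result`: `coords` (cells x 2 matrix),
#'   `pcs` (the PCA scores used), and `params`.
#' @export
embed_cells <- function(u, n_neighbors = 15, n_pcs = 16, min_dist = 0.2,
                        seed = 0) {
  stopifnot(n_neighbors >= 2)
  if (nrow(u) < n_neighbors) stop("fewer cells than n_neighbors")
  scores <- pca_scores(u, n_pcs)
  set.seed(seed)
  coords <- uwot::umap(scores, n_neighbors = n_neighbors,
                       min_dist = min_dist, metric = "euclidean",
                       n_threads = 1, n_sgd_threads = 0)
  rownames(coords) <- rownames(u)
  colnames(coords) <- c("umap1", "umap2")
  structure(list(coords = coords, pcs = scores,
                 params = list(n_neighbors = n_neighbors,
                               n_pcs = ncol(scores), min_dist = min_dist,
                               metric = "euclidean", seed = seed)),
            class = "embedding_result")
}

#' Assign phenotypic clusters with the Leiden algorithm
#'
#' Builds a shared-nearest-neighbor graph on principal-component scores and
#' partitions it with Leiden community detection (modularity objective) at
#' the given resolution: 0.1 for simple mixtures such as cell-line controls,
#' 1 for patient and PBMC samples.
#'
#' @param u Corrected matrix (ignored when `graph` is supplied).
#' @param resolution Leiden resolution parameter.
#' @param n_neighbors,n_pcs Graph construction parameters (as in
#'   [embed_cells()]).
#' @param seed Random seed.
#' @param graph Optional precomputed `igraph` (e.g. to reuse across
#'   resolutions).
#' @return Integer vector of cluster labels, contiguous from 0, ordered by
#'   decreasing cluster size; attributes `resolution` and `graph`.
#' @export
cluster_cells <- function(u = NULL, resolution = 1, n_neighbors = 15,
                          n_pcs = 16, seed = 0, graph = NULL) {
  if (is.null(graph)) {
    if (is.null(u)) stop("supply a corrected matrix or a graph")
    graph <- snn_graph(pca_scores(u, n_pcs), k = n_neighbors)
  }
  if (igraph::vcount(graph) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(graph)$weight,
                               n_iterations = 10)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- as.integer(relab[as.character(memb)])
  if (!is.null(u) && !is.null(rownames(u))) names(labels) <- rownames(u)
  structure(labels, resolution = resolution, graph = graph)
}

#' Mean expression of each antibody per cluster
#' @param u Corrected matrix (cells x antibodies).
#' @param labels Cluster labels (one per row of `u`).
#' @return Matrix clusters x antibodies of column means.
#' @export
cluster_means <- function(u, labels) {
  stopifnot(nrow(u) == length(labels))
  m <- rowsum(u, group = labels) / as.vector(table(labels))
  m[order(as.integer(rownames(m))), , drop = FALSE]
}

#' Name clusters from marker rules
#'
#' Each rule maps a marker to a population name (e.g. CD3 -> "T cell"). A
#' cluster is named after the rule whose marker scores highest for it, where
#' the score is the cluster's mean expression standardized across clusters.
#' Clusters whose top rule marker is not elevated (z <= 0), or whose top
#' marker is claimed by conflicting rules, keep their numeric label. When
#' several clusters earn the same name they are suffixed `_1`, `_2`, ... in
#' label order.
#'
#' @param means Cluster x antibody mean matrix from [cluster_means()].
#' @param rules Named character vector: `c(CD3 = "T cell", ...)`. Duplicate
#'   marker names constitute a conflict.
#' @return Character vector of cluster names, one per row of `means`.
#' @export
annotate_clusters <- function(means, rules = character()) {
  out <- rownames(means)
  if (length(rules) == 0) return(out)
  markers <- intersect(names(rules), colnames(means))
  conflicted <- unique(names(rules)[duplicated(names(rules))])
  if (length(conflicted))
    warning("conflicting rules for marker(s): ",
            paste(conflicted, collapse = ", "))
  markers <- setdiff(markers, conflicted)
  if (length(markers) == 0) return(out)
  z <- scale(means[, markers, drop = FALSE])
  z[is.nan(z)] <- 0
  for (i in seq_len(nrow(means))) {
    j <- which.max(z[i, ])
    if (z[i, j] > 0) out[i] <- unname(rules[markers[j]])
  }
  dup_names <- unique(out[duplicated(out) & !out %in% rownames(means)])
  for (nm in dup_names) {
    idx <- which(out == nm)
    out[idx] <- paste0(nm, "_", seq_along(idx))
  }
  out
}
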