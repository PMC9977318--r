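#' k-nearest-neighbor index matrix (Euclidean)
#'
#' @param embedding numeric matrix, observations in rows.
#' @param k number of neighbors (excluding the point itself).
#' @return n x k integer matrix of neighbor row indices, nearest first.
#' @keywords internal
knn_index <- function(embedding, k) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) stop("k_neighbors must be smaller than the number of cells")
  sq <- rowSums(embedding^2)
  idx <- matrix(0L, n, k)
  chunk <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * embedding[rows, , drop = FALSE] %*% t(embedding)
    for (ii in seq_along(rows)) {
      d <- d2[ii, ]
      d[rows[ii]] <- Inf
      idx[rows[ii], ] <- order(d)[seq_len(k)]
    }
  }
  idx
}

#' Shared-nearest-neighbor graph
#'
#' Builds the kNN graph and re-weights edges by the Jaccard overlap of the
#' two endpoints' neighbor sets. A point's neighbor set is itself plus its
#' `k` nearest neighbors. Edges with Jaccard weight below `prune` are
#' removed (1/15 by convention).
#'
#' @param embedding observations x dims matrix.
#' @param k neighborhood size.
#' @param prune minimum retained Jaccard weight.
#' @return an [igraph::graph] with edge attribute `weight`.
#' @export
snn_graph <- function(embedding, k, prune = 1 / 15) {
  n <- nrow(embedding)
  nn <- knn_index(embedding, k)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  # candidate edges: kNN pairs in either direction
  ei <- rep(seq_len(n), each = k)
  ej <- as.vector(t(nn))
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  keyed <- unique(cbind(lo, hi))
  w <- vapply(seq_len(nrow(keyed)), function(r) {
    jaccard_index(sets[[keyed[r, 1L]]], sets[[keyed[r, 2L]]])
  }, 0)
  keep <- w >= prune
  igraph::graph_from_data_frame(
    data.frame(from = keyed[keep, 1L], to = keyed[keep, 2L], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
}

#' SNN modularity clustering
#'
#' Louvain community detection (multilevel refinement) on the
#' shared-nearest-neighbor graph at the given resolution. Deterministic
#' given the seed.
#'
#' @param embedding observations x dims matrix (e.g. PCA scores).
#' @param k_neighbors neighborhood size of the SNN graph.
#' @param resolution modularity resolution.
#' @param seed integer seed.
#' @return integer vector of cluster labels (1-based, sized by decreasing
#'   frequency so cluster 1 is the largest).
#' @export
snn_cluster <- function(embedding, k_neighbors = 25L, resolution = 1.5,
                        seed = 1L) {
  g <- snn_graph(embedding, k_neighbors)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm))
  # relabel by decreasing cluster size for stable presentation
  sizes <- sort(table(labels), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  as.integer(remap[as.character(labels)])
}

#' Per-cell silhouette widths in an embedding
#'
#' Standard silhouette s(i) = (b - a) / max(a, b) on Euclidean distances.
#'
#' @param embedding observations x dims matrix.
#' @param labels cluster labels (>= 2 distinct, no singleton-only
#'   clusterings).
#' @return numeric vector of silhouette widths, one per observation.
#' @export
silhouette_by_cluster <- function(embedding, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  if (all(table(labels) == 1L)) stop("all clusters are singletons")
  sil <- cluster::silhouette(labels, stats::dist(embedding))
  as.numeric(sil[, "sil_width"])
}

#' Bootstrap cluster stability (Jaccard)
#'
#' Repeatedly subsamples a fraction of the cells, reruns normalization-free
#' clustering on the subsample embedding, and records for each original
#' cluster the maximum Jaccard similarity with any new cluster, restricted
#' to subsampled cells.
#'
#' @param embedding observations x dims matrix used for clustering.
#' @param labels reference clustering of all observations.
#' @param k_neighbors,resolution clustering parameters for the reruns.
#' @param n_boot number of bootstrap repetitions.
#' @param frac subsampling fraction in (0, 1].
#' @param seed integer seed.
#' @return matrix `n_boot` x clusters of Jaccard values in \[0, 1\].
#' @export
bootstrap_stability <- function(embedding, labels, k_neighbors = 25L,
                                resolution = 1.5, n_boot = 100L, frac = 0.8,
                                seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  labels <- as.character(labels)
  orig <- split(seq_along(labels), labels)
  out <- matrix(NA_real_, n_boot, length(orig),
                dimnames = list(NULL, names(orig)))
  n <- nrow(embedding)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    sub <- sort(sample.int(n, round(frac * n)))
    sub_seed <- sample.int(2147483L, 1L)
    new_lab <- snn_cluster(embedding[sub, , drop = FALSE], k_neighbors,
                           resolution, seed = sub_seed)
    new <- split(sub, new_lab)
    for (cl in names(orig)) {
      a <- intersect(orig[[cl]], sub)
      out[b, cl] <- if (length(a) == 0L) NA_real_ else
        max(vapply(new, function(bset) jaccard_index(a, bset), 0))
    }
  }
  out
}

#' Dendrogram over cluster centroids
#'
#' Hierarchical clustering of per-cluster centroid positions in the
#' embedding (complete linkage on Euclidean distances by default).
#'
#' @param embedding observations x dims matrix.
#' @param labels cluster labels.
#' @param method linkage passed to [stats::hclust()].
#' @return an `hclust` tree whose leaves are the cluster labels.
#' @export
cluster_dendrogram <- function(embedding, labels, method = "complete") {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  cent <- do.call(rbind, lapply(split(seq_along(labels), labels), function(i)
    colMeans(embedding[i, , drop = FALSE])))
  stats::hclust(stats::dist(cent), method = method)
}

#' Write a cluster dendrogram as Newick
#'
#' @param tree an `hclust` from [cluster_dendrogram()].
#' @param path output file.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
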