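#' Call marker-positive cells from spot counts
#'
#' A cell is positive for a gene when its spot count strictly exceeds the
#' threshold. The default of 10 corresponds to the average background spot
#' load per cell per gene measured in samples lacking the probed gene.
#'
#' @param spot_counts cells x genes non-negative integer matrix.
#' @param threshold spot-count threshold (strict inequality).
#' @return logical matrix of the same shape.
#' @export
call_positive <- function(spot_counts, threshold = 10) {
  spot_counts <- as.matrix(spot_counts)
  if (any(spot_counts < 0)) stop("spot counts must be non-negative")
  if (threshold < 0) stop("threshold must be >= 0")
  spot_counts > threshold
}

#' FISH clustering parameters (two passes)
#'
#' Pass 1 is a coarse clustering used to strip non-neurons; pass 2 is the
#' fine clustering of retained neurons.
#'
#' @param k1,res1 pass-1 SNN neighborhood and resolution.
#' @param k2,res2 pass-2 SNN neighborhood and resolution.
#' @param n_pcs principal components; `NULL` uses all gene dimensions.
#' @param seed integer seed.
#' @return list of class `fish_cluster_params`.
#' @export
fish_cluster_params <- function(k1 = 25L, res1 = 0.2, k2 = 45L, res2 = 1.0,
                                n_pcs = NULL, seed = 1L) {
  structure(list(k1 = as.integer(k1), res1 = res1, k2 = as.integer(k2),
                 res2 = res2, n_pcs = n_pcs, seed = as.integer(seed)),
            class = "fish_cluster_params")
}

# z-score raw spot counts per gene (no log transform, to limit the weight
# of false-positive spot detections) and embed with PCA
fish_embedding <- function(spot_counts, n_pcs = NULL) {
  z <- zscore_columns(as.matrix(spot_counts), sd_type = "sample",
                      na_error = FALSE)
  if (is.null(n_pcs) || n_pcs >= ncol(z)) return(z)
  pca_embed(t(z), n_pcs = n_pcs)
}

#' Remove non-neurons from a FISH sample
#'
#' Runs the coarse pass-1 SNN clustering on z-scored raw spot counts and
#' removes clusters that look non-neuronal: median soma volume below
#' `volume_cutoff` AND fraction of cells positive for the neuronal marker
#' gene below `marker_cutoff`.
#'
#' @param spot_counts cells x genes integer matrix.
#' @param cell_records data frame with a `volume` column, rows aligned
#'   with `spot_counts`.
#' @param neuronal_marker column name of the pan-neuronal marker gene.
#' @param params a [fish_cluster_params()].
#' @param volume_cutoff median soma volume (um^3) below which a cluster
#'   is a non-neuron candidate.
#' @param marker_cutoff neuronal-marker positive fraction below which a
#'   cluster is a non-neuron candidate.
#' @param spot_threshold positive-call threshold for the marker gene.
#' @return list with `keep` (logical per cell), `pass1_labels`, and
#'   `report` (data frame per pass-1 cluster: size, median volume,
#'   marker-positive fraction, removed flag).
#' @export
filter_nonneurons <- function(spot_counts, cell_records, neuronal_marker,
                              params = fish_cluster_params(),
                              volume_cutoff = 600, marker_cutoff = 0.2,
                              spot_threshold = 10) {
  spot_counts <- as.matrix(spot_counts)
  if (nrow(cell_records) != nrow(spot_counts))
    stop("cell_records rows must align with spot_counts")
  if (!neuronal_marker %in% colnames(spot_counts))
    stop("neuronal marker gene not in the panel: ", neuronal_marker)
  emb <- fish_embedding(spot_counts, params$n_pcs)
  labels <- snn_cluster(emb, params$k1, params$res1, seed = params$seed)
  pos <- call_positive(spot_counts[, neuronal_marker, drop = FALSE],
                       spot_threshold)[, 1L]
  report <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    i <- labels == cl
    data.frame(cluster = cl, n = sum(i),
               median_volume = stats::median(cell_records$volume[i]),
               marker_positive_fraction = mean(pos[i]))
  }))
  report$removed <- report$median_volume < volume_cutoff &
    report$marker_positive_fraction < marker_cutoff
  keep <- !(labels %in% report$cluster[report$removed])
  if (!any(keep)) stop("non-neuron filter removed every cluster")
  list(keep = keep, pass1_labels = labels, report = report)
}

#' Cluster FISH neurons into molecular clusters
#'
#' Pass-2 SNN clustering of z-scored raw spot counts (no log transform).
#' Cluster labels are reordered so cluster 1 has the highest
#' cluster-average total spot count. An optional merge list joins cluster
#' pairs before reordering.
#'
#' @param spot_counts cells x genes integer matrix (neurons only).
#' @param params a [fish_cluster_params()].
#' @param merge optional list of integer vectors of raw labels to merge.
#' @return integer vector of molecular-cluster labels with attribute
#'   `"avg_total_spots"` (the per-label ordering statistic).
#' @export
fish_cluster <- function(spot_counts, params = fish_cluster_params(),
                         merge = NULL) {
  spot_counts <- as.matrix(spot_counts)
  if (nrow(spot_counts) <= params$k2)
    stop("fewer cells than the k2 neighborhood size")
  emb <- fish_embedding(spot_counts, params$n_pcs)
  labels <- snn_cluster(emb, params$k2, params$res2, seed = params$seed)
  if (!is.null(merge)) {
    for (grp in merge) labels[labels %in% grp] <- min(grp)
    labels <- as.integer(factor(labels))
  }
  totals <- rowSums(spot_counts)
  avg <- vapply(split(totals, labels), mean, 0)
  remap <- stats::setNames(seq_along(avg), names(sort(avg, decreasing = TRUE)))
  out <- as.integer(remap[as.character(labels)])
  attr(out, "avg_total_spots") <- sort(avg, decreasing = TRUE)
  out
}

#' Map FISH neurons to reference clusters
#'
#' Pearson correlation between each FISH cell's z-profile and reference
#' cluster mean profiles over the shared gene panel; each cell receives
#' the highest-correlation reference label. Also returns the molecular
#' cluster x reference cluster correspondence-fraction matrix.
#'
#' @param fish_z cells x genes z-score matrix (FISH).
#' @param mc_labels molecular-cluster label per FISH cell.
#' @param model reference [cluster_model()].
#' @param exclude molecular clusters excluded from the correspondence
#'   matrix (e.g. clusters outside the region of interest).
#' @return list with `assignment` (from [assign_by_correlation()]) and
#'   `correspondence` (MC x reference fraction matrix; rows sum to 1).
#' @export
map_fish_to_scrna <- function(fish_z, mc_labels, model, exclude = NULL) {
  shared <- intersect(colnames(fish_z), model$genes)
  if (length(shared) < 2L) stop("empty shared gene panel")
  a <- assign_by_correlation(fish_z, model, shared)
  keep <- !(as.character(mc_labels) %in% as.character(exclude))
  tab <- table(factor(mc_labels[keep]),
               factor(a$assigned[keep],
                      levels = c(rownames(model$profiles), "unassigned"),
                      exclude = NULL))
  colnames(tab)[is.na(colnames(tab))] <- "unassigned"
  list(assignment = a, correspondence = row_fractions(tab))
}

#' Soma morphometrics by cluster with effect sizes
#'
#' Each cluster is compared with all remaining cells for each morphology
#' feature using the two-sided Wilcoxon rank-sum test; effect sizes are
#' Cohen's d (pooled SD) and the rank-biserial correlation
#' rg = 1 - 2U/(n1 n2), where U counts cluster-vs-rest pairs in which the
#' cluster value is lower (ties count 1/2). p-values are Bonferroni
#' corrected across clusters x features. A contrast is flagged
#' `reportable` when the corrected p is below `alpha` and the effect is
#' at least medium (|d| > 0.5 or |rg| > 0.28).
#'
#' @param cell_records data frame of morphology features.
#' @param labels cluster label per cell.
#' @param features feature column names.
#' @param alpha significance level on the corrected p-value.
#' @param min_cluster_size clusters smaller than this are skipped.
#' @return data frame: `cluster`, `feature`, group means, `p_val`,
#'   `p_val_adj`, `cohens_d`, `rank_biserial`, `reportable`.
#' @export
morphometrics_compare <- function(cell_records, labels,
                                  features = c("volume", "solidity", "axis_ratio"),
                                  alpha = 0.05, min_cluster_size = 3L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  rows <- list()
  for (cl in sort(unique(labels))) {
    i <- labels == cl
    if (sum(i) < min_cluster_size) {
      warning("cluster ", cl, " has fewer than ", min_cluster_size,
              " cells; skipped")
      next
    }
    for (f in features) {
      a <- cell_records[[f]][i]
      b <- cell_records[[f]][!i]
      n1 <- length(a); n2 <- length(b)
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                   (n1 + n2 - 2))
      d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
      # W = #{a > b} + ties/2 ; U (a below b) = n1 n2 - W
      W <- suppressWarnings(
        as.numeric(stats::wilcox.test(a, b)$statistic))
      rg <- 1 - 2 * (n1 * n2 - W) / (n1 * n2)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, feature = f, mean_cluster = mean(a),
        mean_rest = mean(b), p_val = p, cohens_d = d, rank_biserial = rg)
    }
  }
  out <- do.call(rbind, rows)
  out$p_val_adj <- pmin(out$p_val * nrow(out), 1)
  out$reportable <- out$p_val_adj < alpha &
    (abs(out$cohens_d) > 0.5 | abs(out$rank_biserial) > 0.28)
  out
}
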