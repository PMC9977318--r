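#' Differential expression parameter set
#'
#' @param logfc_threshold minimum natural-log fold change (cluster vs
#'   rest, computed on mean expm1 of log-normalized expression) for a gene
#'   to be tested.
#' @param min_pct minimum expressing fraction in at least one of the two
#'   groups.
#' @param alpha significance level applied to adjusted p-values.
#' @return list of class `de_params`. The test is the two-sided Wilcoxon
#'   rank-sum test with Bonferroni correction over all genes in the matrix.
#' @export
de_params <- function(logfc_threshold = 0.75, min_pct = 0.25, alpha = 0.05) {
  if (logfc_threshold < 0 || min_pct < 0) stop("thresholds must be >= 0")
  structure(list(logfc_threshold = logfc_threshold, min_pct = min_pct,
                 alpha = alpha), class = "de_params")
}

#' One-vs-rest marker gene test per cluster
#'
#' For each cluster, genes passing the log fold-change and expressing-
#' fraction pre-filters are tested cluster-vs-rest with the Wilcoxon
#' rank-sum test; p-values are Bonferroni-adjusted over all genes in the
#' input matrix. `pct.1` is the fraction of in-cluster cells with a
#' nonzero count, `pct.2` the fraction outside the cluster.
#'
#' @param lognorm genes x cells log-normalized expression matrix.
#' @param labels cluster label per cell.
#' @param params a [de_params()].
#' @param counts optional genes x cells raw counts used for the pct
#'   columns; defaults to `lognorm > 0`.
#' @return data frame with columns `cluster`, `gene`, `avg_logFC`,
#'   `pct.1`, `pct.2`, `p_val`, `p_val_adj`, sorted within cluster by
#'   increasing adjusted p then decreasing logFC.
#' @export
differential_expression <- function(lognorm, labels, params = de_params(),
                                    counts = NULL) {
  lognorm <- as.matrix(lognorm)
  labels <- as.character(labels)
  if (length(labels) != ncol(lognorm))
    stop("labels length must equal the number of cells")
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  expressed <- if (is.null(counts)) lognorm > 0 else as.matrix(counts) > 0
  n_genes_total <- nrow(lognorm)
  res <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    if (sum(in_cl) < 3L) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    pct1 <- rowMeans(expressed[, in_cl, drop = FALSE])
    pct2 <- rowMeans(expressed[, !in_cl, drop = FALSE])
    mu1 <- rowMeans(expm1(lognorm[, in_cl, drop = FALSE]))
    mu2 <- rowMeans(expm1(lognorm[, !in_cl, drop = FALSE]))
    logfc <- log(mu1 + 1) - log(mu2 + 1)
    test <- which(logfc >= params$logfc_threshold &
                    pmax(pct1, pct2) >= params$min_pct)
    if (!length(test)) next
    p <- vapply(test, function(g) {
      suppressWarnings(
        stats::wilcox.test(lognorm[g, in_cl], lognorm[g, !in_cl])$p.value)
    }, 0)
    tab <- data.frame(cluster = cl, gene = rownames(lognorm)[test],
                      avg_logFC = logfc[test], pct.1 = pct1[test],
                      pct.2 = pct2[test], p_val = p,
                      p_val_adj = pmin(p * n_genes_total, 1),
                      stringsAsFactors = FALSE)
    res[[cl]] <- tab[order(tab$p_val_adj, -tab$avg_logFC), ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
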