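#' QC parameter set for reference single-cell counts
#'
#' Defaults follow common practice for deeply sequenced sorted neurons:
#' genes kept when detected in at least `min_cells_per_gene` cells; cells
#' kept when the number of detected genes lies in `gene_range` (and above
#' `min_genes_per_cell`), the mitochondrial read fraction is below
#' `max_mito_fraction`, and the UMI total is below `max_umi`.
#'
#' @param min_cells_per_gene minimum cells expressing a gene.
#' @param min_genes_per_cell minimum detected genes per cell.
#' @param gene_range detected-gene interval (doublet / low-quality filter).
#' @param max_mito_fraction maximum mitochondrial fraction (strict).
#' @param max_umi maximum UMI count per cell (strict).
#' @param mito_pattern regex identifying mitochondrial genes by name.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_cells_per_gene = 5L,
                      min_genes_per_cell = 200L,
                      gene_range = c(1500, 7500),
                      max_mito_fraction = 0.055,
                      max_umi = 2e5,
                      mito_pattern = "^mt-") {
  if (gene_range[1] >= gene_range[2]) stop("gene_range lower must be < upper")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must be in [0, 1]")
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell,
                 gene_range = gene_range,
                 max_mito_fraction = max_mito_fraction,
                 max_umi = max_umi, mito_pattern = mito_pattern),
            class = "qc_params")
}

#' Filter a count matrix on standard QC bounds
#'
#' Iterates gene and cell filters to a fixed point so the operation is
#' idempotent: genes detected in too few cells are dropped, then cells
#' failing any per-cell bound (detected genes, mitochondrial fraction,
#' UMI total) are dropped, until nothing changes. Row and column order of
#' the survivors is preserved.
#'
#' @param counts genes x cells matrix of non-negative integer counts.
#' @param params a [qc_params()].
#' @return filtered genes x cells matrix (possibly with zero columns, in
#'   which case a warning is raised).
#' @export
qc_filter <- function(counts, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  repeat {
    detected <- rowSums(counts > 0)
    keep_genes <- detected >= params$min_cells_per_gene
    counts2 <- counts[keep_genes, , drop = FALSE]
    genes_per_cell <- colSums(counts2 > 0)
    umi <- colSums(counts2)
    mito <- grepl(params$mito_pattern, rownames(counts2))
    mito_frac <- if (any(mito)) colSums(counts2[mito, , drop = FALSE]) / pmax(umi, 1)
                 else rep(0, ncol(counts2))
    keep_cells <- genes_per_cell >= params$min_genes_per_cell &
      genes_per_cell >= params$gene_range[1] &
      genes_per_cell <= params$gene_range[2] &
      mito_frac < params$max_mito_fraction &
      umi < params$max_umi
    counts2 <- counts2[, keep_cells, drop = FALSE]
    if (identical(dim(counts2), dim(counts))) break
    counts <- counts2
  }
  if (ncol(counts) == 0L)
    warning("qc_filter removed every cell")
  counts
}

#' Clustering parameter set
#'
#' @param n_hvg number of highly variable genes to retain.
#' @param n_pcs number of principal components for the embedding.
#' @param k_neighbors neighborhood size of the SNN graph.
#' @param resolution modularity resolution.
#' @param seed seed for graph clustering.
#' @param regress_covariates covariate names (columns of the cell metadata
#'   built internally: `nUMI`, `mito_fraction`) removed by linear
#'   regression before z-scoring.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(n_hvg = 5000L, n_pcs = 40L, k_neighbors = 25L,
                           resolution = 1.5, seed = 1L,
                           regress_covariates = c("nUMI", "mito_fraction")) {
  if (n_pcs > n_hvg) stop("n_pcs must be <= n_hvg")
  if (k_neighbors < 2L) stop("k_neighbors must be >= 2")
  structure(list(n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs),
                 k_neighbors = as.integer(k_neighbors),
                 resolution = resolution, seed = as.integer(seed),
                 regress_covariates = regress_covariates),
            class = "cluster_params")
}

# vst-style standardized variance: rank genes by variance of log counts
# standardized against a polynomial mean-variance trend
hvg_rank <- function(lognorm) {
  mu <- rowMeans(lognorm)
  v <- apply(lognorm, 1L, stats::var)
  ok <- v > 0
  std_var <- rep(-Inf, length(v))
  if (sum(ok) >= 10L) {
    fit <- stats::lm(log10(v[ok]) ~ stats::poly(mu[ok], degree = 2L))
    std_var[ok] <- log10(v[ok]) - stats::fitted(fit)
  } else {
    std_var[ok] <- v[ok]
  }
  order(std_var, decreasing = TRUE)
}

#' Normalize, select variable genes, regress covariates and z-score
#'
#' Per-cell total-count normalization (to 10,000 counts) followed by
#' log1p; the top `n_hvg` genes are kept by standardized variance against
#' a polynomial mean-variance trend; each gene is regressed on the
#' requested covariates (UMI total and mitochondrial fraction by default)
#' and the residuals are z-scored per gene.
#'
#' @param counts QC-filtered genes x cells count matrix.
#' @param params a [cluster_params()].
#' @param mito_pattern regex identifying mitochondrial genes.
#' @return genes x cells z-score matrix (HVG rows only), with attribute
#'   `"hvg"` giving the selected gene names.
#' @export
normalize_scale <- function(counts, params = cluster_params(),
                            mito_pattern = "^mt-") {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("zero-total cell(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  lognorm <- log1p(sweep(counts, 2L, totals, "/") * 1e4)
  n_hvg <- min(params$n_hvg, nrow(lognorm))
  hvg <- rownames(lognorm)[hvg_rank(lognorm)[seq_len(n_hvg)]]
  x <- lognorm[hvg, , drop = FALSE]

  covars <- list(nUMI = totals,
                 mito_fraction = {
                   mito <- grepl(mito_pattern, rownames(counts))
                   if (any(mito)) colSums(counts[mito, , drop = FALSE]) / totals
                   else rep(0, ncol(counts))
                 })
  use <- intersect(params$regress_covariates, names(covars))
  if (length(use)) {
    cm <- do.call(cbind, covars[use])
    keep <- apply(cm, 2L, function(v) stats::var(v) > 0)
    if (any(keep)) {
      cm <- cm[, keep, drop = FALSE]
      mm <- cbind(1, cm)
      # least-squares residuals of every gene on the covariates at once
      beta <- solve(crossprod(mm), crossprod(mm, t(x)))
      x <- x - t(mm %*% beta)
    } else {
      x <- x - rowMeans(x)
    }
  } else {
    x <- x - rowMeans(x)
  }
  s <- sqrt(rowSums(x^2) / (ncol(x) - 1L))
  s[s == 0] <- 1
  z <- x / s
  attr(z, "hvg") <- hvg
  z
}

#' PCA embedding of a z-scored expression matrix
#'
#' @param z genes x cells z-score matrix (e.g. from [normalize_scale()]).
#' @param n_pcs number of components.
#' @return cells x n_pcs score matrix with attribute `"var_explained"`.
#' @export
pca_embed <- function(z, n_pcs = 40L) {
  n_pcs <- min(n_pcs, nrow(z) - 1L, ncol(z) - 1L)
  p <- stats::prcomp(t(z), center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- p$x[, seq_len(n_pcs), drop = FALSE]
  attr(emb, "var_explained") <- (p$sdev^2 / sum(p$sdev^2))[seq_len(n_pcs)]
  emb
}
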