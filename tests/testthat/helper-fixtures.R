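# Shared fixtures: all synthetic, built in code at test time.

# well-separated Gaussian blobs in `d` dimensions
make_blobs <- function(n_per, centers, sd = 0.2, d = NULL, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  if (!is.null(d) && ncol(centers) < d)
    centers <- cbind(centers, matrix(0, nrow(centers), d - ncol(centers)))
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2L,
          centers[k, ], "+")))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# small simulation config for fast tests
small_sim <- function(seed = 1, ...) {
  sim_config(n_clusters = 5L, n_cells_ref = 400L, n_cells_fish = 1500L,
             n_genes = 60L, seed = seed, ...)
}

# QC parameters scaled to the synthetic gene universe
sim_qc <- function() {
  qc_params(min_genes_per_cell = 10L, gene_range = c(10, Inf), max_umi = Inf)
}

# log-normalize counts the same way the package does internally
lognorm_counts <- function(counts) {
  log1p(sweep(counts, 2L, colSums(counts), "/") * 1e4)
}
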