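#' Define a regular voxel grid
#'
#' @param origin numeric length-2 or 3 (um).
#' @param spacing isotropic voxel spacing (um), > 0.
#' @param dims integer voxel counts per axis.
#' @return list of class `voxel_grid` with voxel-center coordinate matrix
#'   in `$centers` (voxels x dims).
#' @export
voxel_grid <- function(origin, spacing, dims) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (length(origin) != length(dims)) stop("origin/dims length mismatch")
  axes <- lapply(seq_along(dims), function(a)
    origin[a] + (seq_len(dims[a]) - 0.5) * spacing)
  centers <- as.matrix(do.call(expand.grid, axes))
  colnames(centers) <- c("x", "y", "z")[seq_along(dims)]
  structure(list(origin = origin, spacing = spacing, dims = as.integer(dims),
                 centers = centers),
            class = "voxel_grid")
}

#' Grid covering a set of cell positions
#' @param positions cells x dims coordinate matrix.
#' @param spacing voxel spacing (um).
#' @param pad padding added around the bounding box (um).
#' @return a [voxel_grid()].
#' @export
grid_for_cells <- function(positions, spacing = 25, pad = 0) {
  positions <- as.matrix(positions)
  lo <- apply(positions, 2L, min) - pad
  hi <- apply(positions, 2L, max) + pad
  dims <- pmax(1L, ceiling((hi - lo) / spacing))
  voxel_grid(lo, spacing, dims)
}

#' Reconstruct per-gene expression images on a voxel grid
#'
#' Each gene's image is the Gaussian-kernel-weighted average of the cells'
#' z-scored expression values: voxel v gets
#' sum_i w(v,i) z_i / sum_i w(v,i) with w = exp(-d^2 / (2 h^2)). Voxels
#' with negligible total weight are set to 0.
#'
#' @param positions cells x dims coordinate matrix (um).
#' @param z cells x genes z-score matrix.
#' @param grid a [voxel_grid()].
#' @param bandwidth Gaussian kernel bandwidth h (um).
#' @return list of class `voxel_images`: `values` (voxels x genes),
#'   `weight` (total kernel weight per voxel), `grid`.
#' @export
voxelize_expression <- function(positions, z, grid, bandwidth = 25) {
  positions <- as.matrix(positions)
  z <- as.matrix(z)
  if (nrow(positions) == 0L) stop("no cells to voxelize")
  if (nrow(positions) != nrow(z)) stop("positions and z must align")
  d <- ncol(grid$centers)
  positions <- positions[, seq_len(d), drop = FALSE]
  V <- nrow(grid$centers)
  num <- matrix(0, V, ncol(z))
  den <- numeric(V)
  sqc <- rowSums(positions^2)
  chunk <- max(1L, floor(5e6 / max(nrow(positions), 1L)))
  for (start in seq(1L, V, by = chunk)) {
    rows <- start:min(start + chunk - 1L, V)
    gc_ <- grid$centers[rows, , drop = FALSE]
    d2 <- outer(rowSums(gc_^2), sqc, "+") - 2 * gc_ %*% t(positions)
    w <- exp(-pmax(d2, 0) / (2 * bandwidth^2))
    num[rows, ] <- w %*% z
    den[rows] <- rowSums(w)
  }
  vals <- num / pmax(den, .Machine$double.eps)
  vals[den < 1e-12, ] <- 0
  colnames(vals) <- colnames(z)
  structure(list(values = vals, weight = den, grid = grid),
            class = "voxel_images")
}

#' PCA of spatial expression images
#'
#' Voxels are observations, genes are variables. Returns per-component
#' score images ("eigen images"), gene loadings and variance-explained
#' fractions.
#'
#' @param images a [voxel_images()] from [voxelize_expression()].
#' @param occupied_only use only voxels with positive kernel weight.
#' @return list: `scores` (voxels x PCs, zero-filled on empty voxels),
#'   `loadings` (genes x PCs), `var_explained`.
#' @export
spatial_pca <- function(images, occupied_only = TRUE) {
  stopifnot(inherits(images, "voxel_images"))
  if (ncol(images$values) < 2L) stop("need at least 2 genes")
  use <- if (occupied_only) images$weight >= 1e-12 else
    rep(TRUE, nrow(images$values))
  x <- images$values[use, , drop = FALSE]
  if (all(apply(x, 2L, stats::var) == 0)) stop("constant expression images")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- matrix(0, nrow(images$values), ncol(p$x))
  scores[use, ] <- p$x
  colnames(scores) <- colnames(p$x)
  list(scores = scores, loadings = p$rotation,
       var_explained = p$sdev^2 / sum(p$sdev^2))
}

#' Select parcellation genes by mean loading magnitude
#'
#' Genes are ranked by the mean absolute loading over the top principal
#' components.
#'
#' @param loadings genes x PCs loading matrix.
#' @param n_top_pcs components to average over.
#' @param n_genes genes to return.
#' @return character vector of gene names, best first.
#' @export
select_parcellation_genes <- function(loadings, n_top_pcs = 4L, n_genes = 3L) {
  if (n_top_pcs > ncol(loadings)) stop("n_top_pcs exceeds available PCs")
  score <- rowMeans(abs(loadings[, seq_len(n_top_pcs), drop = FALSE]))
  names(sort(score, decreasing = TRUE))[seq_len(n_genes)]
}

#' Otsu threshold of a numeric vector
#'
#' Between-class variance maximization over a 256-bin histogram of the
#' value range; the returned threshold is the lower edge of the first bin
#' of the upper class, so classification is `value >= threshold`.
#'
#' @param values numeric vector with >= 2 distinct values.
#' @param n_bins histogram bins.
#' @return numeric threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L) stop("constant values: no Otsu threshold")
  edges <- seq(min(values), max(values), length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                     n_bins), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[n_bins]
  # between-class variance for cut after bin t
  bcv <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  t_best <- which.max(bcv[-n_bins])
  edges[t_best + 1L]
}

#' Per-gene Otsu classification and combined class label
#'
#' Each gene is thresholded with [otsu_threshold()]; a cell is positive
#' for the gene when its value is at or above the threshold. The per-gene
#' sign tuple is mapped to a named class through `class_map`; tuples
#' without an entry become `"unassigned"`.
#'
#' @param values cells x genes numeric matrix (raw spot counts by
#'   default).
#' @param class_map named character vector; names are `+`/`-` sign
#'   strings in gene column order (e.g. `"+-+"`), values are region
#'   names. `NULL` uses the sign strings themselves as class labels.
#' @return list: `positive` (logical cells x genes), `thresholds`,
#'   `class` (character per cell).
#' @export
otsu_classify <- function(values, class_map = NULL) {
  values <- as.matrix(values)
  thresholds <- apply(values, 2L, otsu_threshold)
  positive <- sweep(values, 2L, thresholds, ">=")
  signs <- apply(positive, 1L, function(r)
    paste(ifelse(r, "+", "-"), collapse = ""))
  cls <- if (is.null(class_map)) signs else {
    out <- unname(class_map[signs])
    out[is.na(out)] <- "unassigned"
    out
  }
  list(positive = positive, thresholds = thresholds, class = cls)
}

#' Gaussian-process parameters for probabilistic segmentation
#'
#' @param length_scale RBF length scale, in units of coordinate SD
#'   (coordinates are rescaled to unit variance before fitting).
#' @param grid_spacing prediction grid spacing (um).
#' @param prob_threshold probability threshold of the segmentation mask.
#' @param max_training_points training subsample cap (exact GP cost grows
#'   cubically).
#' @param seed subsampling seed.
#' @return list of class `gp_params`.
#' @export
gp_params <- function(length_scale = 1.0, grid_spacing = 25,
                      prob_threshold = 0.5, max_training_points = 2000L,
                      seed = 1L) {
  if (length_scale <= 0) stop("length_scale must be > 0")
  if (prob_threshold <= 0 || prob_threshold >= 1)
    stop("prob_threshold must be in (0, 1)")
  structure(list(length_scale = length_scale, grid_spacing = grid_spacing,
                 prob_threshold = prob_threshold,
                 max_training_points = as.integer(max_training_points),
                 seed = as.integer(seed)),
            class = "gp_params")
}

#' Gaussian-process probabilistic parcellation
#'
#' Fits a Gaussian-process classifier (RBF kernel) on cell positions and
#' per-cell class labels, then predicts class probabilities on a voxel
#' grid and at the cell positions themselves. Coordinates are rescaled to
#' unit variance so the length scale is meaningful at any tissue size.
#' Multiclass problems are handled one-vs-rest with renormalization so
#' per-voxel probabilities sum to 1.
#'
#' @param positions cells x dims coordinate matrix (um).
#' @param classes class label per cell (>= 2 classes, >= 10 cells each).
#' @param params a [gp_params()].
#' @param grid optional [voxel_grid()]; defaults to a grid covering the
#'   cells at `params$grid_spacing`.
#' @return list of class `parcellation_map`: `grid`, `prob` (voxels x
#'   classes, rows sum to 1), `voxel_class`, `mask` (argmax probability >
#'   threshold), `cell_class` (predicted class per cell), `cell_prob`.
#' @export
gp_segment <- function(positions, classes, params = gp_params(),
                       grid = NULL) {
  positions <- as.matrix(positions)
  classes <- factor(classes)
  if (nlevels(classes) < 2L) stop("need at least 2 classes")
  if (any(table(classes) < 10L))
    stop("each class needs at least 10 cells")
  grid <- grid %||% grid_for_cells(positions, params$grid_spacing)

  ctr <- colMeans(positions)
  scl <- apply(positions, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(positions, 2L, ctr), 2L, scl, "/")

  set.seed(params$seed)
  idx <- if (nrow(xs) > params$max_training_points)
    sort(sample.int(nrow(xs), params$max_training_points)) else seq_len(nrow(xs))
  xtr <- xs[idx, , drop = FALSE]
  ytr <- droplevels(classes[idx])
  sigma <- 1 / (2 * params$length_scale^2)  # rbfdot: exp(-sigma |x - x'|^2)
  fit <- kernlab::gausspr(xtr, ytr, kernel = "rbfdot",
                          kpar = list(sigma = sigma))

  predict_prob <- function(newx) {
    p <- kernlab::predict(fit, newx, type = "probabilities")
    colnames(p) <- fit@lev
    p <- p[, levels(classes)[levels(classes) %in% colnames(p)], drop = FALSE]
    p / pmax(rowSums(p), .Machine$double.eps)
  }
  gs <- sweep(sweep(grid$centers[, seq_len(ncol(xs)), drop = FALSE],
                    2L, ctr), 2L, scl, "/")
  prob <- matrix(NA_real_, nrow(gs), nlevels(ytr))
  chunk <- 5000L
  for (start in seq(1L, nrow(gs), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(gs))
    prob[rows, ] <- predict_prob(gs[rows, , drop = FALSE])
  }
  colnames(prob) <- levels(ytr)
  cell_prob <- matrix(NA_real_, nrow(xs), nlevels(ytr),
                      dimnames = list(NULL, levels(ytr)))
  for (start in seq(1L, nrow(xs), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(xs))
    cell_prob[rows, ] <- predict_prob(xs[rows, , drop = FALSE])
  }
  voxel_class <- colnames(prob)[max.col(prob, ties.method = "first")]
  structure(list(
    grid = grid, prob = prob, voxel_class = voxel_class,
    mask = apply(prob, 1L, max) > params$prob_threshold,
    cell_class = colnames(cell_prob)[max.col(cell_prob, ties.method = "first")],
    cell_prob = cell_prob),
    class = "parcellation_map")
}

#' Cluster-by-subregion enrichment
#'
#' @param mc_labels molecular-cluster label per cell.
#' @param subregions subregion label per cell.
#' @return clusters x subregions fraction matrix; rows sum to 1.
#' @export
subregion_enrichment <- function(mc_labels, subregions) {
  if (length(mc_labels) != length(subregions))
    stop("labels must align")
  row_fractions(table(as.character(mc_labels), as.character(subregions)))
}
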