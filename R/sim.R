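#' Simulation configuration
#'
#' Builds the configuration object shared by [simulate_reference_counts()]
#' and [simulate_fish_sample()]. The defaults describe a reference
#' experiment of 13 molecular clusters profiled at 1,500 cells, a FISH
#' sample of 5,000 segmented cells in a 2500 x 4000 x 100 um tissue slab
#' with two molecularly distinct spatial domains, five retrograde tracer
#' channels with 78% labeling efficiency and a 1% collateral rate, and a
#' marker-gene program that is near-binary: an "on" gene has negative
#' binomial counts around `marker_mean`, every gene additionally receives
#' uniform background spots averaging `background_rate` per cell.
#'
#' The gene universe is laid out deterministically: gene 1 is a pan-neuronal
#' marker (a Gad1 analog, expressed in every neuron), the next
#' `n_clusters * n_marker_genes_per_cluster` genes are exclusive cluster
#' markers, followed by `n_shared_genes` broadly shared program genes
#' (expressed in roughly half the clusters), and the remainder are
#' background-only genes. The FISH panel is the union of the neuronal
#' marker, the cluster markers and the shared genes.
#'
#' @param n_clusters number of molecular clusters.
#' @param n_cells_ref cells in the reference (scRNA-seq-like) experiment.
#' @param n_cells_fish segmented cells in a FISH sample (neurons plus
#'   non-neurons).
#' @param n_genes total genes in the reference universe.
#' @param n_marker_genes_per_cluster exclusive near-binary markers per
#'   cluster.
#' @param n_shared_genes broadly expressed program genes in the panel.
#' @param marker_mean expected counts of an "on" gene.
#' @param background_rate expected background spots per cell per gene
#'   (Poisson; the field-reported average is 10).
#' @param nb_dispersion negative binomial size parameter for "on" genes
#'   (larger = closer to Poisson).
#' @param n_targets number of tracer channels / projection targets.
#' @param target_names names of the projection targets.
#' @param projection_prob `n_clusters x n_targets` probability table; row
#'   k gives the probability that a cluster-k neuron projects to each
#'   target (row sums may be < 1; the remainder is "no projection").
#' @param labeling_efficiency probability that a truly projecting neuron
#'   is labeled by the tracer.
#' @param collateral_rate fraction of cells that project to >= 2 targets.
#' @param tracer_background_mu,tracer_background_sigma lognormal
#'   parameters (meanlog/sdlog) of per-channel background intensity.
#' @param tracer_signal_amplitude additive intensity of a labeled cell.
#' @param slab_dim tissue slab dimensions in um (x, y, z).
#' @param subregion_layout list of spatial domains; each entry is a list
#'   with `name`, `xlim`, `ylim`, optional `zlim`, and `weights`, a
#'   length-`n_clusters` vector of per-cluster density weights.
#' @param nonneuron_fraction fraction of segmented cells that are
#'   non-neurons (small somata, background-only spot counts).
#' @param nonneuron_background_rate background spot rate in non-neurons
#'   (lower than in neurons: background spot load scales with soma size).
#' @param morphology_params data frame with one row per cluster (plus a
#'   `"NN"` row for non-neurons) and columns `volume_mean`, `volume_sd`,
#'   `solidity_mean`, `solidity_sd`, `axis_ratio_mean`, `axis_ratio_sd`.
#' @param seed integer seed; all generators are deterministic given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 13L,
                       n_cells_ref = 1500L,
                       n_cells_fish = 5000L,
                       n_genes = 300L,
                       n_marker_genes_per_cluster = 2L,
                       n_shared_genes = 2L,
                       marker_mean = 50,
                       background_rate = 10,
                       nb_dispersion = 4,
                       n_targets = 5L,
                       target_names = NULL,
                       projection_prob = NULL,
                       labeling_efficiency = 0.78,
                       collateral_rate = 0.01,
                       tracer_background_mu = log(100),
                       tracer_background_sigma = 0.4,
                       tracer_signal_amplitude = 400,
                       slab_dim = c(2500, 4000, 100),
                       subregion_layout = NULL,
                       nonneuron_fraction = 0.15,
                       nonneuron_background_rate = 3,
                       morphology_params = NULL,
                       seed = 1L) {
  n_clusters <- as.integer(n_clusters)
  n_targets <- as.integer(n_targets)
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (n_cells_ref < 1L || n_cells_fish < 1L || n_genes < 1L)
    stop("non-positive dimensions in simulation config")
  if (background_rate < 0 || nonneuron_background_rate < 0)
    stop("background_rate must be >= 0")
  for (p in c(labeling_efficiency, collateral_rate, nonneuron_fraction))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")

  if (is.null(target_names)) {
    target_names <- c("BNST", "lateralSN", "vlPAG", "PBN", "PCRt")[seq_len(min(n_targets, 5L))]
    if (n_targets > 5L)
      target_names <- c(target_names, paste0("target", 6:n_targets))
  }
  if (length(target_names) != n_targets) stop("target_names length != n_targets")

  if (is.null(projection_prob)) {
    projection_prob <- matrix(0.05, n_clusters, n_targets)
    for (k in seq_len(n_clusters))
      projection_prob[k, (k - 1L) %% n_targets + 1L] <- 0.6
  }
  projection_prob <- as.matrix(projection_prob)
  if (!all(dim(projection_prob) == c(n_clusters, n_targets)))
    stop("projection_prob must be n_clusters x n_targets")
  if (any(projection_prob < 0) || any(projection_prob > 1))
    stop("projection_prob entries must be in [0, 1]")
  dimnames(projection_prob) <- list(paste0("C", seq_len(n_clusters)), target_names)

  n_marker_total <- n_clusters * n_marker_genes_per_cluster
  n_panel <- 1L + n_marker_total + n_shared_genes
  if (n_genes < n_panel)
    stop("n_genes must be at least ", n_panel, " to hold the marker panel")

  if (is.null(subregion_layout)) {
    w1 <- ifelse(seq_len(n_clusters) <= ceiling(n_clusters / 2), 0.9, 0.1)
    subregion_layout <- list(
      list(name = "lateral", xlim = c(0, slab_dim[1] / 2),
           ylim = c(0, slab_dim[2]), weights = w1),
      list(name = "medial", xlim = c(slab_dim[1] / 2, slab_dim[1]),
           ylim = c(0, slab_dim[2]), weights = 1 - w1)
    )
  }
  for (dom in subregion_layout) {
    if (diff(dom$xlim) <= 0 || diff(dom$ylim) <= 0)
      stop("each spatial domain must have positive extent")
    if (length(dom$weights) != n_clusters)
      stop("domain weights must have length n_clusters")
  }

  if (is.null(morphology_params)) {
    morphology_params <- data.frame(
      cluster = c(paste0("C", seq_len(n_clusters)), "NN"),
      volume_mean = c(2500, rep(1500, n_clusters - 1L), 300),
      volume_sd = c(800, rep(400, n_clusters - 1L), 100),
      solidity_mean = c(rep(0.9, n_clusters), 0.85),
      solidity_sd = c(rep(0.05, n_clusters), 0.08),
      axis_ratio_mean = c(rep(0.65, n_clusters), 0.75),
      axis_ratio_sd = c(rep(0.15, n_clusters), 0.12),
      stringsAsFactors = FALSE
    )
  }

  cfg <- list(
    n_clusters = n_clusters, n_cells_ref = as.integer(n_cells_ref),
    n_cells_fish = as.integer(n_cells_fish), n_genes = as.integer(n_genes),
    n_marker_genes_per_cluster = as.integer(n_marker_genes_per_cluster),
    n_shared_genes = as.integer(n_shared_genes),
    marker_mean = marker_mean, background_rate = background_rate,
    nb_dispersion = nb_dispersion,
    n_targets = n_targets, target_names = target_names,
    projection_prob = projection_prob,
    labeling_efficiency = labeling_efficiency,
    collateral_rate = collateral_rate,
    tracer_background_mu = tracer_background_mu,
    tracer_background_sigma = tracer_background_sigma,
    tracer_signal_amplitude = tracer_signal_amplitude,
    slab_dim = slab_dim, subregion_layout = subregion_layout,
    nonneuron_fraction = nonneuron_fraction,
    nonneuron_background_rate = nonneuron_background_rate,
    morphology_params = morphology_params,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Gene program of a simulation configuration
#'
#' Returns gene names, panel membership, and the genes x clusters "expressed"
#' indicator matrix implied by a [sim_config()].
#'
#' @param config a `sim_config`.
#' @return list with `genes`, `panel_genes`, `neuronal_marker`,
#'   `cluster_markers` (list per cluster), and `expressed`
#'   (genes x clusters logical matrix).
#' @export
sim_gene_program <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_clusters
  m <- config$n_marker_genes_per_cluster
  genes <- sprintf("gene_%03d", seq_len(config$n_genes))
  neuronal_marker <- genes[1L]
  cluster_markers <- lapply(seq_len(K), function(k)
    genes[1L + ((k - 1L) * m + 1L):(k * m)])
  names(cluster_markers) <- paste0("C", seq_len(K))
  shared <- if (config$n_shared_genes > 0)
    genes[1L + K * m + seq_len(config$n_shared_genes)] else character(0)

  expressed <- matrix(FALSE, config$n_genes, K,
                      dimnames = list(genes, paste0("C", seq_len(K))))
  expressed[neuronal_marker, ] <- TRUE
  for (k in seq_len(K)) expressed[cluster_markers[[k]], k] <- TRUE
  # shared program genes: deterministic half-and-half split of clusters
  for (i in seq_along(shared)) {
    on <- which((seq_len(K) + i) %% 2L == 0L)
    expressed[shared[i], on] <- TRUE
  }
  list(genes = genes,
       panel_genes = c(neuronal_marker, unlist(cluster_markers), shared),
       neuronal_marker = neuronal_marker,
       cluster_markers = cluster_markers,
       shared_genes = shared,
       expressed = expressed)
}

# NB draw with Poisson limit at infinite size parameter
rnb <- function(n, mu, size) {
  if (!is.finite(size)) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate reference single-cell counts
#'
#' Draws a genes x cells integer count matrix with cluster-structured,
#' near-binary marker programs: genes flagged "on" for a cell's cluster are
#' negative binomial with mean `marker_mean` (dispersion `nb_dispersion`);
#' every gene additionally receives Poisson background counts with mean
#' `background_rate`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (genes x cells integer matrix), `truth`
#'   (data frame: `cell_id`, `cluster`) and `program` (see
#'   [sim_gene_program()]).
#' @export
simulate_reference_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "reference"))
  prog <- sim_gene_program(config)
  K <- config$n_clusters
  n <- config$n_cells_ref
  cluster <- paste0("C", sample.int(K, n, replace = TRUE))
  counts <- matrix(0L, config$n_genes, n,
                   dimnames = list(prog$genes,
                                   sprintf("refcell_%04d", seq_len(n))))
  if (config$background_rate > 0)
    counts[] <- stats::rpois(length(counts), config$background_rate)
  for (k in seq_len(K)) {
    idx <- which(cluster == paste0("C", k))
    on <- which(prog$expressed[, k])
    if (length(idx) && length(on)) {
      counts[on, idx] <- counts[on, idx] +
        rnb(length(on) * length(idx), config$marker_mean, config$nb_dispersion)
    }
  }
  storage.mode(counts) <- "integer"
  list(counts = counts,
       truth = data.frame(cell_id = colnames(counts), cluster = cluster,
                          stringsAsFactors = FALSE),
       program = prog)
}

# draw projection target sets for neurons; returns cells x targets logical
draw_projections <- function(cluster_idx, config) {
  n <- length(cluster_idx)
  K <- config$n_clusters
  P <- config$projection_prob
  proj <- matrix(FALSE, n, config$n_targets,
                 dimnames = list(NULL, config$target_names))
  collateral <- stats::runif(n) < config$collateral_rate
  for (i in seq_len(n)) {
    p <- P[cluster_idx[i], ]
    if (collateral[i] && sum(p > 0) >= 2L) {
      # collateral mechanism: two distinct targets, probability-weighted
      tg <- sample.int(config$n_targets, 2L, prob = p / sum(p))
      while (tg[1L] == tg[2L])
        tg[2L] <- sample.int(config$n_targets, 1L, prob = p / sum(p))
      proj[i, tg] <- TRUE
    } else {
      u <- stats::runif(1)
      cs <- cumsum(p)
      hit <- which(u < cs)
      if (length(hit)) proj[i, hit[1L]] <- TRUE
    }
  }
  proj
}

#' Simulate a FISH sample with tracer channels and morphology
#'
#' Generates one tissue sample: 3D soma centroids drawn from
#' domain-weighted cluster densities in a rectangular slab, spot counts for
#' the marker-gene panel (expressed genes NB around `marker_mean` plus
#' Poisson background for every gene), per-channel tracer intensities
#' (lognormal background plus an additive signal when the cell projects to
#' the channel's target and is labeled, which happens with probability
#' `labeling_efficiency`), and per-cluster soma morphology. A configurable
#' fraction of cells are non-neurons: small somata, background-only counts.
#'
#' @param config a [sim_config()].
#' @param sample_id sample identifier recorded per cell.
#' @return list with `spots` (cells x panel-genes integer matrix), `cells`
#'   (data frame: `cell_id`, `sample_id`, `x`, `y`, `z`, `volume`,
#'   `solidity`, `axis_ratio`), `tracer` (cells x targets intensity
#'   matrix), and `truth` (list: `cluster`, `subregion`, `is_neuron`,
#'   `projects` and `labeled` cells x targets logical matrices, `program`).
#' @export
simulate_fish_sample <- function(config, sample_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$subregion_layout) == 0L) stop("subregion_layout is empty")
  set.seed(derive_seed(config$seed, paste0("fish_", sample_id)))
  prog <- sim_gene_program(config)
  panel <- prog$panel_genes
  K <- config$n_clusters
  n <- config$n_cells_fish
  n_nn <- round(n * config$nonneuron_fraction)
  n_neu <- n - n_nn
  is_neuron <- c(rep(TRUE, n_neu), rep(FALSE, n_nn))
  cluster_idx <- c(sample.int(K, n_neu, replace = TRUE), rep(NA_integer_, n_nn))
  cluster <- ifelse(is_neuron, paste0("C", cluster_idx), "NN")

  # positions: per-cluster domain choice weighted by density x area
  layout <- config$subregion_layout
  areas <- vapply(layout, function(d) diff(d$xlim) * diff(d$ylim), 0)
  dom_idx <- integer(n)
  for (i in seq_len(n)) {
    w <- if (is_neuron[i]) {
      vapply(layout, function(d) d$weights[cluster_idx[i]], 0) * areas
    } else areas
    dom_idx[i] <- sample.int(length(layout), 1L, prob = w / sum(w))
  }
  x <- y <- z <- numeric(n)
  for (i in seq_len(n)) {
    d <- layout[[dom_idx[i]]]
    x[i] <- stats::runif(1, d$xlim[1], d$xlim[2])
    y[i] <- stats::runif(1, d$ylim[1], d$ylim[2])
    zl <- d$zlim %||% c(0, config$slab_dim[3])
    z[i] <- stats::runif(1, zl[1], zl[2])
  }
  subregion <- vapply(layout, function(d) d$name, "")[dom_idx]

  # spot counts over the panel
  spots <- matrix(0L, n, length(panel),
                  dimnames = list(sprintf("cell_%05d", seq_len(n)), panel))
  bg <- ifelse(is_neuron, config$background_rate, config$nonneuron_background_rate)
  for (j in seq_along(panel))
    spots[, j] <- stats::rpois(n, bg)
  expressed_panel <- prog$expressed[panel, , drop = FALSE]
  for (k in seq_len(K)) {
    idx <- which(is_neuron & cluster_idx == k)
    on <- which(expressed_panel[, k])
    if (length(idx) && length(on)) {
      spots[idx, on] <- spots[idx, on] +
        rnb(length(idx) * length(on), config$marker_mean, config$nb_dispersion)
    }
  }
  storage.mode(spots) <- "integer"

  # projections, labeling, tracer intensities
  projects <- matrix(FALSE, n, config$n_targets,
                     dimnames = list(rownames(spots), config$target_names))
  projects[is_neuron, ] <- draw_projections(cluster_idx[is_neuron], config)
  labeled <- projects &
    matrix(stats::runif(n * config$n_targets) < config$labeling_efficiency,
           n, config$n_targets)
  tracer <- matrix(stats::rlnorm(n * config$n_targets,
                                 config$tracer_background_mu,
                                 config$tracer_background_sigma),
                   n, config$n_targets,
                   dimnames = dimnames(projects))
  tracer <- tracer + labeled * config$tracer_signal_amplitude

  # morphology
  mp <- config$morphology_params
  rowfor <- match(cluster, mp$cluster)
  volume <- pmax(stats::rnorm(n, mp$volume_mean[rowfor], mp$volume_sd[rowfor]), 50)
  solidity <- pmin(pmax(stats::rnorm(n, mp$solidity_mean[rowfor],
                                     mp$solidity_sd[rowfor]), 0.2), 1)
  axis_ratio <- pmin(pmax(stats::rnorm(n, mp$axis_ratio_mean[rowfor],
                                       mp$axis_ratio_sd[rowfor]), 0.05), 1)

  cells <- data.frame(cell_id = rownames(spots), sample_id = sample_id,
                      x = x, y = y, z = z, volume = volume,
                      solidity = solidity, axis_ratio = axis_ratio,
                      stringsAsFactors = FALSE)
  list(spots = spots, cells = cells, tracer = tracer,
       truth = list(cluster = cluster, subregion = subregion,
                    is_neuron = is_neuron, projects = projects,
                    labeled = labeled, program = prog))
}
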