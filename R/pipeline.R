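#' Pipeline configuration
#'
#' Assembles the configuration driving [run_pipeline()]. Any prefix of the
#' stage sequence `simulate`, `sc_cluster`, `select_markers`, `fish_type`,
#' `assign_projections`, `parcellate`, `predict_projections` can be run.
#' All randomness derives from the single root `seed` via per-stage
#' derived seeds.
#'
#' @param out_dir output directory.
#' @param stages stage names to execute (a prefix of the full sequence).
#' @param seed root seed.
#' @param sim a [sim_config()] (its own seed is overridden by the root
#'   seed).
#' @param qc a [qc_params()]; the default here relaxes the count-depth
#'   bounds to the synthetic gene universe.
#' @param sc a [cluster_params()].
#' @param de a [de_params()].
#' @param marker_max_size greedy panel size.
#' @param marker_whitelist genes always added to the panel (e.g.
#'   neuromodulatory receptors chosen a priori).
#' @param fish a [fish_cluster_params()].
#' @param gp a [gp_params()].
#' @param parcellation_genes number of genes used for parcellation.
#' @param predict a [predict_params()].
#' @param inputs named list of input file paths used when `simulate` is
#'   not among the stages (`ref_dir`, `spots`, `cells`, `tracer`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "sc_cluster",
                                       "select_markers", "fish_type",
                                       "assign_projections", "parcellate",
                                       "predict_projections"),
                            seed = 1L,
                            sim = sim_config(),
                            qc = qc_params(min_genes_per_cell = 10L,
                                           gene_range = c(10, Inf),
                                           max_umi = Inf),
                            sc = cluster_params(),
                            de = de_params(),
                            marker_max_size = 29L,
                            marker_whitelist = character(0),
                            fish = fish_cluster_params(),
                            gp = gp_params(),
                            parcellation_genes = 3L,
                            predict = predict_params(n_repeats = 2L,
                                                     n_permutations = 10L,
                                                     lambda = 0.01),
                            inputs = list()) {
  all_stages <- c("simulate", "sc_cluster", "select_markers", "fish_type",
                  "assign_projections", "parcellate", "predict_projections")
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "))
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 sim = sim, qc = qc, sc = sc, de = de,
                 marker_max_size = as.integer(marker_max_size),
                 marker_whitelist = marker_whitelist, fish = fish, gp = gp,
                 parcellation_genes = as.integer(parcellation_genes),
                 predict = predict, inputs = inputs),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the [pipeline_config()] defaults;
#' nested blocks (`sim`, `sc`, ...) are passed to the corresponding
#' constructors.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(out_dir = y$out_dir %||% ".")
  if (!is.null(y$stages)) args$stages <- y$stages
  if (!is.null(y$seed)) args$seed <- y$seed
  for (block in c("sim", "qc", "sc", "de", "fish", "gp", "predict")) {
    if (!is.null(y[[block]])) {
      ctor <- switch(block, sim = sim_config, qc = qc_params,
                     sc = cluster_params, de = de_params,
                     fish = fish_cluster_params, gp = gp_params,
                     predict = predict_params)
      args[[block]] <- do.call(ctor, y[[block]])
    }
  }
  for (fld in c("marker_max_size", "marker_whitelist",
                "parcellation_genes", "inputs"))
    if (!is.null(y[[fld]])) args[[fld]] <- y[[fld]]
  do.call(pipeline_config, args)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order, writing each stage's outputs
#' under `out_dir/<stage>/` and an append-only JSON manifest recording
#' seeds and MD5 hashes of every file written. A stage failure aborts
#' with the stage name and cause.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # inputs must exist before any computation
  for (p in unlist(config$inputs))
    if (!file.exists(p)) stop("missing input path: ", p)
  need_sim <- !"simulate" %in% config$stages
  if (need_sim && length(config$stages) &&
      !all(c("spots", "cells", "tracer") %in% names(config$inputs)) &&
      any(config$stages %in% c("fish_type", "assign_projections",
                               "parcellate", "predict_projections")))
    stop("missing input path: spots/cells/tracer files are required when ",
         "the simulate stage is disabled")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())
  outputs <- character(0)

  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    dir <- file.path(config$out_dir, name)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- tryCatch(fn(dir),
                      error = function(e)
                        stop("stage '", name, "' failed: ", conditionMessage(e),
                             call. = FALSE))
    manifest$stages[[name]] <<- list(
      seed = derive_seed(config$seed, name),
      files = as.list(tools::md5sum(files)))
    outputs <<- c(outputs, files)
  }

  run_stage("simulate", function(dir) {
    cfg <- config$sim
    cfg$seed <- derive_seed(config$seed, "simulate")
    state$sim_cfg <- cfg
    state$ref <- simulate_reference_counts(cfg)
    state$fish <- simulate_fish_sample(cfg)
    p1 <- write_counts_mtx(state$ref$counts, dir, "ref_counts")
    c(p1,
      write_stage_csv(state$ref$truth, file.path(dir, "ref_truth.csv")),
      write_stage_csv(state$fish$spots, file.path(dir, "fish_spots.csv")),
      write_stage_csv(state$fish$cells, file.path(dir, "fish_cells.csv")),
      write_stage_csv(state$fish$tracer, file.path(dir, "fish_tracer.csv")),
      write_stage_csv(
        data.frame(cell_id = state$fish$cells$cell_id,
                   cluster = state$fish$truth$cluster,
                   subregion = state$fish$truth$subregion),
        file.path(dir, "fish_truth.csv")))
  })

  run_stage("sc_cluster", function(dir) {
    counts <- if (is.null(state$ref))
      read_counts_mtx(config$inputs$ref_dir, "ref_counts") else state$ref$counts
    counts <- qc_filter(counts, config$qc)
    sc <- config$sc
    sc$seed <- derive_seed(config$seed, "sc_cluster")
    z <- normalize_scale(counts, sc)
    emb <- pca_embed(z, sc$n_pcs)
    labels <- snn_cluster(emb, sc$k_neighbors, sc$resolution, seed = sc$seed)
    sil <- silhouette_by_cluster(emb, labels)
    lognorm <- log1p(sweep(counts, 2L, colSums(counts), "/") * 1e4)
    de <- differential_expression(lognorm, labels, config$de)
    tree <- cluster_dendrogram(emb, labels)
    state$sc <- list(counts = counts, z = z, emb = emb, labels = labels,
                     lognorm = lognorm, de = de)
    c(write_stage_csv(data.frame(cell_id = colnames(counts),
                                 cluster = labels, silhouette = sil),
                      file.path(dir, "clusters.csv")),
      write_stage_csv(de, file.path(dir, "de_table.csv")),
      write_dendrogram_newick(tree, file.path(dir, "dendrogram.nwk")))
  })

  run_stage("select_markers", function(dir) {
    de <- state$sc$de
    cand <- filter_candidates(de)
    size <- min(config$marker_max_size, length(cand))
    # z-profiles over all genes for self-mapping
    zc <- zscore_columns(t(state$sc$lognorm), sd_type = "sample",
                         na_error = FALSE)
    gp <- greedy_panel(zc, state$sc$labels, cand, size)
    panel <- union(gp$panel, config$marker_whitelist)
    state$panel <- panel
    c(write_stage_csv(data.frame(rank = seq_along(gp$panel),
                                 gene = gp$panel,
                                 accuracy = gp$accuracy),
                      file.path(dir, "panel.csv")),
      write_stage_csv(data.frame(gene = panel),
                      file.path(dir, "panel_final.csv")))
  })

  run_stage("fish_type", function(dir) {
    fish <- state$fish %||% list(
      spots = as.matrix(utils::read.csv(config$inputs$spots, row.names = 1L)),
      cells = utils::read.csv(config$inputs$cells),
      tracer = as.matrix(utils::read.csv(config$inputs$tracer, row.names = 1L)))
    fp <- config$fish
    fp$seed <- derive_seed(config$seed, "fish_type")
    marker <- colnames(fish$spots)[1L]
    nn <- filter_nonneurons(fish$spots, fish$cells, marker, fp)
    spots <- fish$spots[nn$keep, , drop = FALSE]
    cells <- fish$cells[nn$keep, , drop = FALSE]
    mc <- fish_cluster(spots, fp)
    fz <- zscore_columns(spots, sd_type = "sample", na_error = FALSE)
    morph <- morphometrics_compare(cells, mc)
    state$fish_typed <- list(spots = spots, cells = cells, mc = mc, z = fz,
                             keep = nn$keep)
    files <- c(
      write_stage_csv(nn$report, file.path(dir, "nonneuron_report.csv")),
      write_stage_csv(data.frame(cell_id = cells$cell_id, mc = mc),
                      file.path(dir, "mc_labels.csv")),
      write_stage_csv(morph, file.path(dir, "morphometrics.csv")))
    if (!is.null(state$sc)) {
      shared <- intersect(colnames(fz), rownames(state$sc$z))
      if (length(shared) >= 2L) {
        model <- cluster_model(state$sc$z[shared, , drop = FALSE],
                               state$sc$labels)
        mp <- map_fish_to_scrna(fz, mc, model)
        files <- c(files, write_stage_csv(mp$correspondence,
                                          file.path(dir, "correspondence.csv")))
      }
    }
    files
  })

  run_stage("assign_projections", function(dir) {
    ft <- state$fish_typed
    tracer <- state$fish$tracer[ft$keep, , drop = FALSE]
    zt <- zscore_intensities(tracer)
    labeled <- state$fish$truth$labeled[ft$keep, , drop = FALSE]
    thr <- vapply(colnames(zt), function(ch)
      youden_threshold(zt[, ch], labeled[, ch])$threshold, 0)
    calls <- call_projections(zt, thr)
    frac <- projection_by_cluster(calls$calls, ft$mc)
    state$projection <- list(calls = calls, thresholds = thr)
    c(write_stage_csv(data.frame(channel = names(thr), threshold = thr),
                      file.path(dir, "thresholds.csv")),
      write_stage_csv(calls$calls, file.path(dir, "calls.csv")),
      write_stage_csv(frac, file.path(dir, "projection_by_cluster.csv")))
  })

  run_stage("parcellate", function(dir) {
    ft <- state$fish_typed
    pos <- as.matrix(ft$cells[, c("x", "y")])
    grid <- grid_for_cells(pos, config$gp$grid_spacing)
    imgs <- voxelize_expression(pos, ft$z, grid)
    pca <- spatial_pca(imgs)
    genes <- select_parcellation_genes(pca$loadings, n_genes =
                                         config$parcellation_genes)
    oc <- otsu_classify(ft$spots[, genes, drop = FALSE])
    gp <- config$gp
    gp$seed <- derive_seed(config$seed, "parcellate")
    keep_cls <- names(which(table(oc$class) >= 10L))
    use <- oc$class %in% keep_cls
    seg <- gp_segment(pos[use, , drop = FALSE], oc$class[use], gp, grid)
    subregion <- rep(NA_character_, nrow(pos))
    subregion[use] <- seg$cell_class
    enr <- subregion_enrichment(ft$mc[use], seg$cell_class)
    state$parcellation <- list(seg = seg, subregion = subregion,
                               genes = genes)
    c(write_stage_csv(data.frame(gene = genes),
                      file.path(dir, "parcellation_genes.csv")),
      write_stage_csv(data.frame(cell_id = ft$cells$cell_id,
                                 subregion = subregion),
                      file.path(dir, "subregions.csv")),
      write_stage_csv(enr, file.path(dir, "enrichment.csv")))
  })

  run_stage("predict_projections", function(dir) {
    ft <- state$fish_typed
    ds <- build_dataset(ft$z, state$projection$calls$calls,
                        group_hindbrain = TRUE,
                        min_class_size = config$predict$n_folds)
    pp <- config$predict
    pp$seed <- derive_seed(config$seed, "predict")
    report <- train_eval(ds$features, ds$labels, pp)
    perm <- permutation_test(ds$features, ds$labels, pp)
    jsonlite::write_json(
      list(auc_per_class = as.list(report$auc_per_class),
           auc_mean = report$auc_mean, f1_macro = report$f1_macro,
           permutation_p = perm$p_value),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
    c(file.path(dir, "report.json"),
      write_stage_csv(report$confusion, file.path(dir, "confusion.csv")))
  })

  manifest$outputs <- as.list(tools::md5sum(outputs))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
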