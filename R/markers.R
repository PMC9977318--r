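#' Candidate marker filter
#'
#' Thresholds applied to a differential-expression table to keep genes
#' with near-binary on/off behavior: significant after correction, a
#' sufficient fold change, a high expressing fraction inside the cluster
#' and a low one outside.
#'
#' @param max_adjusted_p adjusted p-value cutoff (inclusive).
#' @param min_avg_logfc minimum average log fold change (inclusive).
#' @param min_pct1 minimum in-cluster expressing fraction.
#' @param max_pct2 maximum out-of-cluster expressing fraction.
#' @return list of class `marker_filter`.
#' @export
marker_filter <- function(max_adjusted_p = 0.05, min_avg_logfc = 0.55,
                          min_pct1 = 0, max_pct2 = 1) {
  if (max_adjusted_p < 0 || max_adjusted_p > 1) stop("max_adjusted_p in [0,1]")
  if (min_pct1 < 0 || min_pct1 > 1 || max_pct2 < 0 || max_pct2 > 1)
    stop("pct thresholds in [0,1]")
  structure(list(max_adjusted_p = max_adjusted_p,
                 min_avg_logfc = min_avg_logfc,
                 min_pct1 = min_pct1, max_pct2 = max_pct2),
            class = "marker_filter")
}

#' Filter and rank candidate marker genes
#'
#' @param de_table output of [differential_expression()].
#' @param filter a [marker_filter()].
#' @return character vector of unique candidate genes, ranked by
#'   decreasing binarity (`pct.1 - pct.2`), ties broken by fold change.
#' @export
filter_candidates <- function(de_table, filter = marker_filter()) {
  need <- c("gene", "avg_logFC", "pct.1", "pct.2", "p_val_adj")
  if (!all(need %in% names(de_table)))
    stop("de_table must have columns: ", paste(need, collapse = ", "))
  keep <- de_table$p_val_adj <= filter$max_adjusted_p &
    de_table$avg_logFC >= filter$min_avg_logfc &
    de_table$pct.1 >= filter$min_pct1 &
    de_table$pct.2 <= filter$max_pct2
  tab <- de_table[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    warning("no candidate genes pass the marker filter")
    return(character(0))
  }
  tab <- tab[order(-(tab$pct.1 - tab$pct.2), -tab$avg_logFC), ]
  unique(tab$gene)
}

#' Cluster model: per-cluster mean z-scored profiles
#'
#' @param z genes x cells z-score matrix.
#' @param labels cluster label per cell.
#' @return object of class `cluster_model` with `profiles` (clusters x
#'   genes matrix) and `genes`.
#' @export
cluster_model <- function(z, labels) {
  z <- as.matrix(z)
  labels <- as.character(labels)
  if (anyDuplicated(rownames(z))) stop("duplicate gene names")
  prof <- do.call(rbind, lapply(split(seq_along(labels), labels), function(i)
    rowMeans(z[, i, drop = FALSE])))
  structure(list(profiles = prof, genes = colnames(prof)),
            class = "cluster_model")
}

#' Assign cells to reference clusters by Pearson correlation
#'
#' Each cell's z-profile over `gene_subset` is correlated with every
#' cluster's mean profile; the cell is assigned the cluster with the
#' highest correlation (ties broken by the lowest cluster index). Cells
#' with zero variance over the subset are flagged unassignable (`NA`).
#'
#' @param cell_z cells x genes z-score matrix (columns named by gene).
#' @param model a [cluster_model()].
#' @param gene_subset genes to use (>= 2, all present in the model).
#' @return data frame with `assigned` (cluster label or `NA`), `r` (its
#'   correlation) and `tie` (logical: argmax was not unique).
#' @export
assign_by_correlation <- function(cell_z, model, gene_subset = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  gene_subset <- gene_subset %||% model$genes
  if (length(gene_subset) < 2L) stop("need at least 2 genes")
  if (!all(gene_subset %in% model$genes))
    stop("gene_subset must be a subset of the model genes")
  if (!all(gene_subset %in% colnames(cell_z)))
    stop("gene_subset missing from the cell profiles")
  x <- as.matrix(cell_z)[, gene_subset, drop = FALSE]
  p <- model$profiles[, gene_subset, drop = FALSE]
  # round so analytically tied correlations (e.g. +/-1 on two-gene panels)
  # break deterministically by cluster order rather than by float noise
  r <- round(row_cor(x, p), 9L)
  cl_names <- rownames(model$profiles)
  pick <- apply(r, 1L, function(v) {
    if (all(is.na(v))) return(c(NA_integer_, NA_real_, 0))
    m <- max(v, na.rm = TRUE)
    w <- which(v == m)
    c(w[1L], m, as.numeric(length(w) > 1L))
  })
  data.frame(assigned = cl_names[pick[1L, ]], r = pick[2L, ],
             tie = pick[3L, ] > 0, stringsAsFactors = FALSE,
             row.names = rownames(x))
}

#' Mapping accuracy and assignment-fraction matrix
#'
#' @param assigned assigned cluster labels (`NA` = unassignable).
#' @param truth true cluster labels, same length.
#' @return list with `accuracy` (fraction of cells whose assignment
#'   equals truth; unassignable cells count as wrong) and `matrix` (true
#'   clusters x assigned clusters + `"unassigned"` fractions; rows sum
#'   to 1).
#' @export
mapping_accuracy <- function(assigned, truth) {
  if (length(assigned) != length(truth))
    stop("assigned and truth must have equal length")
  truth <- as.character(truth)
  assigned <- as.character(assigned)
  assigned[is.na(assigned)] <- "unassigned"
  acc <- mean(assigned == truth)
  lev_t <- sort(unique(truth))
  lev_a <- c(sort(unique(assigned[assigned != "unassigned"])), "unassigned")
  tab <- table(factor(truth, lev_t), factor(assigned, lev_a))
  list(accuracy = acc, matrix = row_fractions(tab))
}

# accuracy of a panel: assign every cell by correlation and compare to truth
panel_accuracy <- function(cell_z, model, truth, panel) {
  a <- assign_by_correlation(cell_z, model, panel)
  mean(!is.na(a$assigned) & a$assigned == truth)
}

#' Greedy accuracy-maximizing marker panel
#'
#' Builds a marker panel one gene at a time, at each step adding the
#' candidate that maximizes the fraction of cells correctly re-assigned
#' to their own cluster by [assign_by_correlation()]. Correlation needs
#' at least two genes, so the first step selects the best *pair* by
#' exhaustive search over candidate pairs. Ties are broken
#' lexicographically by gene identifier, making the procedure
#' deterministic.
#'
#' @param cell_z cells x genes z-score matrix.
#' @param truth true cluster label per cell.
#' @param candidates candidate gene identifiers (>= `max_size`).
#' @param max_size final panel size (>= 2).
#' @param model optional [cluster_model()]; defaults to cluster means of
#'   `cell_z` under `truth` (self-mapping).
#' @return list with `panel` (ordered genes) and `accuracy` (accuracy
#'   after each panel size; `accuracy[i]` corresponds to
#'   `panel[seq_len(i)]`, starting at size 2).
#' @export
greedy_panel <- function(cell_z, truth, candidates, max_size,
                         model = NULL) {
  if (max_size < 2L) stop("max_size must be >= 2 (correlation needs 2 genes)")
  candidates <- sort(unique(as.character(candidates)))
  if (length(candidates) < max_size)
    stop("need at least max_size candidate genes")
  model <- model %||% cluster_model(t(cell_z), truth)
  truth <- as.character(truth)

  # first step: best pair
  pairs <- utils::combn(candidates, 2L)
  acc2 <- vapply(seq_len(ncol(pairs)), function(i)
    panel_accuracy(cell_z, model, truth, pairs[, i]), 0)
  best <- which.max(acc2)   # ties: first in lexicographic pair order
  panel <- pairs[, best]
  accuracy <- rep(NA_real_, max_size)
  accuracy[2L] <- acc2[best]

  while (length(panel) < max_size) {
    remaining <- setdiff(candidates, panel)
    acc <- vapply(remaining, function(g)
      panel_accuracy(cell_z, model, truth, c(panel, g)), 0)
    g <- remaining[which.max(acc)]  # ties: lexicographic (remaining sorted)
    panel <- c(panel, g)
    accuracy[length(panel)] <- max(acc)
  }
  list(panel = panel, accuracy = accuracy)
}
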