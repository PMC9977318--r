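#' Z-score tracer intensities per channel
#'
#' Each tracer channel is centered and scaled independently over all cells
#' of a sample. The population SD (divide by n) is the default.
#'
#' @param tracer cells x channels intensity matrix (non-negative).
#' @param sd_type `"population"` or `"sample"`.
#' @return z-scored matrix of the same shape.
#' @export
zscore_intensities <- function(tracer, sd_type = "population") {
  tracer <- as.matrix(tracer)
  if (nrow(tracer) < 2L) stop("need at least 2 cells")
  zscore_columns(tracer, sd_type = sd_type, na_error = TRUE)
}

#' Youden-optimal classification threshold
#'
#' Sweeps candidate thresholds at the midpoints between consecutive
#' sorted unique values of the calibration scores; positives are values
#' strictly above the threshold. Returns the threshold maximizing the
#' Youden index J = sensitivity + specificity - 1 (ties broken toward the
#' lowest threshold).
#'
#' @param z numeric scores of the calibration cells.
#' @param labels logical (or 0/1): `TRUE` for cells known to project.
#' @return list of class `youden_result`: `threshold`, `J`,
#'   `sensitivity`, `specificity`, and `roc` (data frame of all swept
#'   points with 1-specificity and sensitivity).
#' @export
youden_threshold <- function(z, labels) {
  labels <- as.logical(labels)
  if (length(z) != length(labels)) stop("z and labels must align")
  if (!any(labels) || all(labels))
    stop("calibration set must contain both positives and negatives")
  u <- sort(unique(z))
  cand <- if (length(u) == 1L) u - 1 else
    c(u[1L] - diff(range(u)) / 2 - 1e-9, (u[-length(u)] + u[-1L]) / 2)
  n1 <- sum(labels); n0 <- sum(!labels)
  # counts at each unique value, cumulated so the sweep is O(n log n)
  iu <- match(z, u)
  pos_at <- tabulate(iu[labels], length(u))
  neg_at <- tabulate(iu[!labels], length(u))
  # candidate j sits below u[j]: positives above = all with value >= u[j]
  pos_above <- rev(cumsum(rev(pos_at)))
  neg_below <- c(0, cumsum(neg_at))[seq_along(u)]
  sens <- pos_above / n1
  spec <- neg_below / n0
  J <- sens + spec - 1
  best <- which(J == max(J))[1L]   # candidates ascend: first = lowest
  structure(list(threshold = cand[best], J = J[best],
                 sensitivity = sens[best], specificity = spec[best],
                 roc = data.frame(threshold = cand, fpr = 1 - spec,
                                  tpr = sens, J = J)),
            class = "youden_result")
}

#' Call projection targets per cell
#'
#' A target belongs to a cell's projection set when its z-scored tracer
#' intensity is strictly above the channel threshold. Cells are
#' categorized `unlabeled` (0 targets), `single` (1) or `collateral`
#' (>= 2).
#'
#' @param z_tracer cells x channels z-scored intensities.
#' @param thresholds named numeric vector, one threshold per channel.
#' @return list with `calls` (logical cells x channels matrix),
#'   `category` (factor per cell), and `collateral_pairs` (counts per
#'   pairwise target combination among collateral cells).
#' @export
call_projections <- function(z_tracer, thresholds) {
  z_tracer <- as.matrix(z_tracer)
  ch <- colnames(z_tracer)
  if (!all(ch %in% names(thresholds)))
    stop("missing thresholds for channel(s): ",
         paste(setdiff(ch, names(thresholds)), collapse = ", "))
  calls <- sweep(z_tracer, 2L, thresholds[ch], ">")
  nt <- rowSums(calls)
  category <- factor(ifelse(nt == 0L, "unlabeled",
                            ifelse(nt == 1L, "single", "collateral")),
                     levels = c("unlabeled", "single", "collateral"))
  pairs <- utils::combn(ch, 2L)
  pair_counts <- stats::setNames(vapply(seq_len(ncol(pairs)), function(i)
    sum(calls[, pairs[1L, i]] & calls[, pairs[2L, i]] & nt >= 2L), 0L),
    paste(pairs[1L, ], pairs[2L, ], sep = "+"))
  list(calls = calls, category = category, collateral_pairs = pair_counts)
}

#' Projection fractions by molecular cluster
#'
#' @param calls logical cells x targets matrix (from
#'   [call_projections()]`$calls`).
#' @param mc_labels molecular-cluster label per cell.
#' @return clusters x targets matrix; entry = fraction of the cluster's
#'   cells calling that target (collateral cells count once per target).
#' @export
projection_by_cluster <- function(calls, mc_labels) {
  calls <- as.matrix(calls)
  if (nrow(calls) != length(mc_labels))
    stop("labels must align with calls")
  do.call(rbind, lapply(split(seq_len(nrow(calls)), as.character(mc_labels)),
                        function(i) colMeans(calls[i, , drop = FALSE])))
}
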