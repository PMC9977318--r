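#' Z-score the columns of a matrix
#'
#' Centers and scales each column. The population standard deviation
#' (divide by n) is the default convention used throughout the package for
#' tracer intensities and spot counts; the sample convention (n - 1) is
#' available for compatibility with other toolchains.
#'
#' @param x numeric matrix (observations in rows).
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by n-1).
#' @param na_error error when a column has zero variance? If `FALSE`,
#'   zero-variance columns are returned as all-zero.
#' @return matrix of the same shape with columns centered and scaled.
#' @export
zscore_columns <- function(x, sd_type = c("population", "sample"),
                           na_error = TRUE) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 observations to z-score")
  mu <- colMeans(x)
  cx <- sweep(x, 2L, mu)
  ss <- colSums(cx^2)
  denom <- if (sd_type == "population") n else n - 1L
  s <- sqrt(ss / denom)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    if (na_error) {
      stop("zero-variance column(s): ",
           paste(colnames(x)[zero] %||% which(zero), collapse = ", "))
    }
    s[zero] <- 1
  }
  sweep(cx, 2L, s, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Jaccard index between two sets
#'
#' @param a,b vectors interpreted as sets (duplicates ignored).
#' @return |a ∩ b| / |a ∪ b|; 0 when both sets are empty.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed from the Mann-Whitney U statistic with midrank handling of
#' ties, i.e. the probability that a random positive scores higher than a
#' random negative (ties count 1/2).
#'
#' @param scores numeric predictions, higher = more positive.
#' @param labels logical or 0/1 vector of true classes.
#' @return AUC in \[0, 1\]; `NA` when one class is absent.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson correlation of each row of `x` against each row of `y`
#'
#' @param x n x p matrix; @param y m x p matrix.
#' @return n x m matrix of correlations; rows of `x` with zero variance
#'   yield `NA` correlations.
#' @keywords internal
row_cor <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  xs <- sqrt(rowSums(xc^2))
  ys <- sqrt(rowSums(yc^2))
  r <- (xc %*% t(yc)) / outer(xs, ys)
  r[!is.finite(r)] <- NA_real_
  r
}

#' Fraction-of-row normalization
#' @keywords internal
row_fractions <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab)
  rs[rs == 0] <- 1
  sweep(tab, 1L, rs, "/")
}

#' Derive a child seed from a root seed
#'
#' Deterministic per-stage seeds below 2^31 so one root seed drives the
#' whole pipeline without reusing streams across stages.
#' @keywords internal
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + 1009L * (h %% 10007L)) %% 2147483L + 1L
}
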