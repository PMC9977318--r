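#' Parameters for projection-class prediction
#'
#' @param n_repeats randomized repeats of stratified cross-validation.
#' @param n_folds folds per repeat.
#' @param n_permutations label shuffles of the permutation test.
#' @param lambda ridge penalty; `NULL` selects it per training fold by
#'   internal 3-fold cross-validation over a logarithmic grid of 10
#'   strengths.
#' @param metric score used by the permutation test: mean one-vs-rest
#'   `"auc"` or macro `"f1"`.
#' @param seed integer seed; the full procedure is deterministic given it.
#' @return list of class `predict_params`.
#' @export
predict_params <- function(n_repeats = 20L, n_folds = 5L,
                           n_permutations = 100L, lambda = NULL,
                           metric = c("auc", "f1"), seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 n_permutations = as.integer(n_permutations),
                 lambda = lambda, metric = match.arg(metric),
                 seed = as.integer(seed)),
            class = "predict_params")
}

#' Build the prediction dataset from projection calls
#'
#' Collateral cells (two or more called targets) are excluded; remaining
#' cells are labeled with their single target or `"unlabeled"`. With
#' `group_hindbrain = TRUE` the hindbrain targets are merged into one
#' `"hindbrain"` class.
#'
#' @param z_expr cells x genes z-scored expression matrix.
#' @param calls logical cells x targets call matrix.
#' @param group_hindbrain merge `hindbrain_targets` into one class?
#' @param hindbrain_targets targets regarded as hindbrain.
#' @param min_class_size classes smaller than this raise an error
#'   (defaults to the number of folds a stratified CV needs).
#' @return list with `features` (matrix) and `labels` (factor).
#' @export
build_dataset <- function(z_expr, calls, group_hindbrain = FALSE,
                          hindbrain_targets = c("PBN", "PCRt", "vlPAG"),
                          min_class_size = 5L) {
  z_expr <- as.matrix(z_expr)
  calls <- as.matrix(calls)
  if (nrow(z_expr) != nrow(calls)) stop("expression and calls must align")
  nt <- rowSums(calls)
  keep <- nt <= 1L
  lab <- rep("unlabeled", nrow(calls))
  hit <- which(nt == 1L)
  lab[hit] <- colnames(calls)[max.col(calls[hit, , drop = FALSE])]
  if (group_hindbrain)
    lab[lab %in% hindbrain_targets] <- "hindbrain"
  labels <- factor(lab[keep])
  small <- names(which(table(labels) < min_class_size))
  if (length(small))
    stop("class(es) with fewer than ", min_class_size, " cells: ",
         paste(small, collapse = ", "))
  list(features = z_expr[keep, , drop = FALSE], labels = labels)
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    i <- which(labels == cl)
    fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  fold
}

# inverse-class-frequency observation weights (multiclass convention)
class_weights <- function(labels) {
  tab <- table(labels)
  w <- length(labels) / (nlevels(labels) * tab[as.character(labels)])
  as.numeric(w)
}

lambda_grid <- 10^seq(1, -4, length.out = 10)

# fit a binary L2 logistic model; returns standardized coefficients and a
# probability predictor
fit_binary_ridge <- function(x, y, weights, lambda = NULL) {
  y <- as.numeric(y)
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                            weights = weights, lambda = lambda_grid,
                            nfolds = 3L, type.measure = "deviance")
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        weights = weights, lambda = lambda)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  list(beta_std = beta * apply(x, 2L, stats::sd),
       predict = function(newx)
         as.numeric(stats::predict(fit, newx, type = "response")),
       lambda = lambda)
}

#' Train and evaluate the one-vs-rest projection predictor
#'
#' One L2-penalized logistic model per class, with observation weights
#' inversely proportional to class frequency. For each of `n_repeats`
#' randomized repeats of stratified `n_folds`-fold cross-validation,
#' out-of-fold class probabilities are pooled; one-vs-rest AUC per class
#' and macro f1 are computed per repeat and averaged. The confusion
#' matrix pools all repeats and is row-normalized (true positives over
#' class size).
#'
#' @param features cells x genes matrix.
#' @param labels factor of class labels.
#' @param params a [predict_params()].
#' @return list of class `prediction_report`: `auc_per_class`,
#'   `auc_mean`, `f1_per_class`, `f1_macro`, `confusion` (row-normalized),
#'   `oof_prob` (last repeat's out-of-fold probabilities).
#' @export
train_eval <- function(features, labels, params = predict_params()) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  K <- nlevels(labels)
  set.seed(params$seed)
  w <- class_weights(labels)
  auc_rep <- matrix(NA_real_, params$n_repeats, K,
                    dimnames = list(NULL, levels(labels)))
  f1_rep <- matrix(NA_real_, params$n_repeats, K,
                   dimnames = list(NULL, levels(labels)))
  confusion <- matrix(0, K, K, dimnames = list(levels(labels), levels(labels)))
  oof <- NULL
  for (rep_i in seq_len(params$n_repeats)) {
    fold <- stratified_folds(labels, params$n_folds)
    prob <- matrix(NA_real_, length(labels), K,
                   dimnames = list(NULL, levels(labels)))
    for (f in seq_len(params$n_folds)) {
      tr <- fold != f
      for (cl in levels(labels)) {
        m <- fit_binary_ridge(features[tr, , drop = FALSE],
                              labels[tr] == cl, w[tr], params$lambda)
        prob[!tr, cl] <- m$predict(features[!tr, , drop = FALSE])
      }
    }
    pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                   levels = levels(labels))
    for (cl in levels(labels)) {
      auc_rep[rep_i, cl] <- auc_rank(prob[, cl], labels == cl)
      tp <- sum(pred == cl & labels == cl)
      fp <- sum(pred == cl & labels != cl)
      fn <- sum(pred != cl & labels == cl)
      f1_rep[rep_i, cl] <- if (2 * tp + fp + fn == 0) NA_real_ else
        2 * tp / (2 * tp + fp + fn)
    }
    confusion <- confusion + table(labels, pred)
    oof <- prob
  }
  structure(list(
    auc_per_class = colMeans(auc_rep),
    auc_mean = mean(colMeans(auc_rep)),
    f1_per_class = colMeans(f1_rep, na.rm = TRUE),
    f1_macro = mean(colMeans(f1_rep, na.rm = TRUE)),
    confusion = row_fractions(confusion),
    oof_prob = oof),
    class = "prediction_report")
}

# scalar score of a dataset under the chosen metric
prediction_score <- function(features, labels, params) {
  rep <- train_eval(features, labels, params)
  if (params$metric == "auc") rep$auc_mean else rep$f1_macro
}

#' Permutation test of the projection predictor
#'
#' The class-label vector is shuffled `n_permutations` times (jointly, so
#' class frequencies are preserved) and the cross-validated score is
#' recomputed each time. The empirical p-value is
#' (1 + #\{null >= observed\}) / (1 + n_permutations).
#'
#' @param features cells x genes matrix.
#' @param labels factor of class labels.
#' @param params a [predict_params()].
#' @return list: `observed`, `null_scores`, `p_value`.
#' @export
permutation_test <- function(features, labels, params = predict_params()) {
  if (params$n_permutations < 1L) stop("n_permutations must be >= 1")
  labels <- droplevels(factor(labels))
  observed <- prediction_score(features, labels, params)
  set.seed(derive_seed(params$seed, "permutation"))
  null_scores <- vapply(seq_len(params$n_permutations), function(b) {
    perm <- sample(labels)
    p2 <- params
    p2$seed <- derive_seed(params$seed, paste0("perm", b))
    prediction_score(features, perm, p2)
  }, 0)
  list(observed = observed, null_scores = null_scores,
       p_value = (1 + sum(null_scores >= observed)) /
         (1 + params$n_permutations))
}

#' Recursive feature elimination per projection class
#'
#' For each class, a one-vs-rest L2 logistic model is fitted repeatedly;
#' at each step the feature with the smallest standardized coefficient
#' magnitude is removed, and the cross-validated one-vs-rest AUC of the
#' remaining panel is recorded. The ranking lists features best first
#' (rank 1 = the last surviving feature).
#'
#' @param features cells x genes matrix (>= 2 features).
#' @param labels factor of class labels.
#' @param params a [predict_params()]; `n_repeats` repeats of
#'   `n_folds`-fold CV score each panel size.
#' @return list per class, each with `ranking` (feature names, best
#'   first) and `auc_vs_k` (named numeric: CV AUC with the top-k
#'   features, k = 1..p).
#' @export
rfe_rank <- function(features, labels, params = predict_params()) {
  features <- as.matrix(features)
  if (ncol(features) < 2L) stop("need at least 2 features")
  labels <- droplevels(factor(labels))
  w <- class_weights(labels)
  set.seed(derive_seed(params$seed, "rfe"))

  cv_auc <- function(cols, ybin) {
    auc <- numeric(params$n_repeats)
    for (r in seq_len(params$n_repeats)) {
      fold <- stratified_folds(labels, params$n_folds)
      prob <- numeric(length(ybin))
      for (f in seq_len(params$n_folds)) {
        tr <- fold != f
        xtr <- features[tr, cols, drop = FALSE]
        if (length(cols) == 1L) {
          d <- data.frame(y = as.numeric(ybin[tr]), x = xtr[, 1L])
          m <- suppressWarnings(stats::glm(y ~ x, binomial(), d,
                                           weights = w[tr]))
          prob[!tr] <- stats::predict(
            m, data.frame(x = features[!tr, cols]), type = "response")
        } else {
          m <- fit_binary_ridge(xtr, ybin[tr], w[tr], params$lambda)
          prob[!tr] <- m$predict(features[!tr, cols, drop = FALSE])
        }
      }
      auc[r] <- auc_rank(prob, ybin)
    }
    mean(auc)
  }

  out <- list()
  for (cl in levels(labels)) {
    ybin <- labels == cl
    remaining <- colnames(features)
    elim_order <- character(0)
    auc_vs_k <- stats::setNames(rep(NA_real_, ncol(features)),
                                seq_len(ncol(features)))
    while (length(remaining) >= 1L) {
      auc_vs_k[length(remaining)] <- cv_auc(remaining, ybin)
      if (length(remaining) == 1L) break
      m <- fit_binary_ridge(features[, remaining, drop = FALSE], ybin, w,
                            params$lambda)
      drop_ft <- remaining[which.min(abs(m$beta_std))]
      elim_order <- c(elim_order, drop_ft)
      remaining <- setdiff(remaining, drop_ft)
    }
    out[[cl]] <- list(ranking = c(remaining, rev(elim_order)),
                      auc_vs_k = auc_vs_k)
  }
  out
}
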