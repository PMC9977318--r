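# small labeled dataset with a planted linear rule on one feature
planted_rule_data <- function(n = 300, p = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- factor(ifelse(x[, 1] > 0, "pos", "neg"))
  list(x = x, y = y)
}

fast_params <- function(lambda = 0.05, ...) {
  predict_params(n_repeats = 1L, n_folds = 3L, lambda = lambda, ...)
}

test_that("collateral cells are excluded and hindbrain grouping applied", {
  z <- matrix(rnorm(60), 10, 6)
  calls <- matrix(FALSE, 10, 5,
                  dimnames = list(NULL, c("BNST", "lateralSN", "vlPAG",
                                          "PBN", "PCRt")))
  calls[1, c("PBN", "PCRt")] <- TRUE              # collateral: dropped
  calls[2, "PBN"] <- TRUE
  calls[3, "BNST"] <- TRUE
  ds <- build_dataset(z, calls, group_hindbrain = TRUE, min_class_size = 1)
  expect_equal(nrow(ds$features), 9L)
  expect_equal(as.character(ds$labels[1]), "hindbrain")   # the PBN cell
  expect_equal(as.character(ds$labels[2]), "BNST")
  expect_equal(sum(ds$labels == "unlabeled"), 7L)
  # without collaterals the row count is preserved
  calls2 <- calls; calls2[1, ] <- FALSE
  ds2 <- build_dataset(z, calls2, min_class_size = 1)
  expect_equal(nrow(ds2$features), 10L)
  # undersized classes raise an error naming the class
  expect_error(build_dataset(z, calls, min_class_size = 5), "BNST")
})

test_that("the rank-based AUC agrees with an independent ROC implementation", {
  set.seed(1)
  scores <- rnorm(80)
  labels <- scores + rnorm(80) > 0
  a1 <- auc_rank(scores, labels)
  a2 <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                       direction = "<")))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("a separable rule is learned almost perfectly", {
  d <- planted_rule_data(n = 240, seed = 2)
  rep <- train_eval(d$x, d$y, fast_params(seed = 3))
  expect_gte(rep$auc_mean, 0.99)
  expect_equal(unname(rowSums(rep$confusion)), rep(1, 2), tolerance = 1e-9)
})

test_that("label-independent features give chance-level AUC", {
  set.seed(4)
  n <- 2000
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(sample(c("a", "b"), n, replace = TRUE))
  rep <- train_eval(x, y, fast_params(seed = 5))
  expect_gt(rep$auc_mean, 0.45)
  expect_lt(rep$auc_mean, 0.55)
})

test_that("evaluation is seed-deterministic end to end", {
  d <- planted_rule_data(n = 150, seed = 6)
  r1 <- train_eval(d$x, d$y, fast_params(seed = 11))
  r2 <- train_eval(d$x, d$y, fast_params(seed = 11))
  expect_identical(r1$auc_per_class, r2$auc_per_class)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("permutation test attains the minimum p under strong signal", {
  d <- planted_rule_data(n = 200, seed = 7)
  pt <- permutation_test(d$x, d$y, fast_params(n_permutations = 100L,
                                               seed = 8))
  expect_length(pt$null_scores, 100L)
  expect_true(all(pt$null_scores < pt$observed))
  expect_equal(pt$p_value, 1 / 101)
  expect_error(permutation_test(d$x, d$y, fast_params(n_permutations = 0L)),
               "n_permutations")
})

test_that("RFE ranks a single informative feature first with a flat tail", {
  set.seed(9)
  n <- 200
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, c("info", paste0("noise", 1:9))))
  y <- factor(ifelse(x[, "info"] + rnorm(n, 0, 0.3) > 0, "hit", "miss"))
  rk <- rfe_rank(x, y, fast_params(seed = 10))
  expect_equal(rk$hit$ranking[1], "info")
  expect_setequal(rk$hit$ranking, colnames(x))
  # AUC is near-flat after the informative feature enters
  expect_lt(abs(rk$hit$auc_vs_k["1"] - rk$hit$auc_vs_k["10"]), 0.05)
  expect_gt(rk$hit$auc_vs_k["1"], 0.9)
})

test_that("elimination order matches an independent refit oracle on a 3-feature toy", {
  set.seed(12)
  n <- 400
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  score <- 1.5 * x[, "a"] + 0.6 * x[, "b"] + 0 * x[, "c"]
  y <- factor(ifelse(score + rnorm(n) > 0, "p", "n"))
  prm <- fast_params(lambda = 1e-4, seed = 13)   # near-unpenalized
  rk <- rfe_rank(x, y, prm)
  # oracle: refit plain logistic regression at each step, drop the
  # smallest standardized coefficient
  remaining <- c("a", "b", "c")
  order_oracle <- character(0)
  while (length(remaining) > 1) {
    fit <- glm(I(y == "p") ~ ., binomial(),
               data.frame(x[, remaining, drop = FALSE]))
    co <- coef(fit)[-1] * apply(x[, remaining, drop = FALSE], 2, sd)
    drop_ft <- remaining[which.min(abs(co))]
    order_oracle <- c(order_oracle, drop_ft)
    remaining <- setdiff(remaining, drop_ft)
  }
  ranking_oracle <- c(remaining, rev(order_oracle))
  expect_equal(rk$p$ranking, ranking_oracle)
})
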