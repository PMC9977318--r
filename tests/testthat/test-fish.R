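test_that("positive calls use a strict threshold", {
  m <- matrix(c(0, 10, 11, 25), 2, 2)
  pos <- call_positive(m, 10)
  expect_identical(as.vector(pos), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(call_positive(m, 0), m > 0)
  expect_error(call_positive(m - 1), "non-negative")
})

test_that("positive fraction of a background-only gene matches the Poisson tail", {
  set.seed(10)
  n <- 10000
  counts <- matrix(rpois(n, 10), ncol = 1)
  frac <- mean(call_positive(counts, 10))
  expected <- 1 - ppois(10, 10)          # exact CDF oracle
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("planted non-neurons are removed and all-neuron input is untouched", {
  cfg <- small_sim(seed = 21)
  fish <- simulate_fish_sample(cfg)
  marker <- fish$truth$program$neuronal_marker
  nn <- filter_nonneurons(fish$spots, fish$cells, marker)
  truth_nn <- !fish$truth$is_neuron
  # recall and precision of the removal against ground truth
  expect_gt(sum(!nn$keep & truth_nn) / sum(truth_nn), 0.95)
  expect_gt(sum(nn$keep & !truth_nn) / sum(!truth_nn), 0.95)
  expect_true(any(nn$report$removed))
  # retained fraction tracks the configured neuron fraction
  expect_lt(abs(mean(nn$keep) - (1 - cfg$nonneuron_fraction)), 0.03)

  cfg2 <- small_sim(seed = 22, nonneuron_fraction = 0)
  fish2 <- simulate_fish_sample(cfg2)
  nn2 <- filter_nonneurons(fish2$spots, fish2$cells,
                           fish2$truth$program$neuronal_marker)
  expect_true(all(nn2$keep))
})

test_that("FISH clustering recovers planted clusters and orders labels by total spots", {
  cfg <- small_sim(seed = 23, nonneuron_fraction = 0)
  fish <- simulate_fish_sample(cfg)
  mc <- fish_cluster(fish$spots, fish_cluster_params(seed = 4))
  expect_gt(mclust::adjustedRandIndex(mc, fish$truth$cluster), 0.9)
  # ordering contract: cluster-average total spot counts non-increasing
  totals <- rowSums(fish$spots)
  avg <- vapply(split(totals, mc), mean, 0)
  expect_true(all(diff(avg[order(as.integer(names(avg)))]) <= 1e-9))
  # relabeling is a permutation: size multiset preserved
  raw <- snn_cluster(projfish:::fish_embedding(fish$spots, NULL), 45, 1.0,
                     seed = 4)
  expect_setequal(as.integer(table(mc)), as.integer(table(raw)))
})

test_that("cells generated from a reference centroid map back to it", {
  cfg <- small_sim(seed = 25, nonneuron_fraction = 0)
  ref <- simulate_reference_counts(cfg)
  fish <- simulate_fish_sample(cfg)
  panel <- intersect(colnames(fish$spots), rownames(ref$counts))
  zr <- t(scale(t(lognorm_counts(ref$counts)[panel, ])))
  model <- cluster_model(zr, ref$truth$cluster)
  fz <- zscore_columns(fish$spots, na_error = FALSE)
  mp <- map_fish_to_scrna(fz, fish$truth$cluster, model)
  expect_equal(unname(rowSums(mp$correspondence)), rep(1, cfg$n_clusters),
               tolerance = 1e-9)
  # planted correspondence: each true cluster maps dominantly to itself
  for (k in paste0("C", seq_len(cfg$n_clusters)))
    expect_equal(colnames(mp$correspondence)[which.max(mp$correspondence[k, ])], k)
})

test_that("correspondence matrix honours exclusions and hand tallies", {
  prof <- rbind(A = c(2, -1, 0), B = c(-1, 2, 0))
  colnames(prof) <- paste0("g", 1:3)
  model <- structure(list(profiles = prof, genes = colnames(prof)),
                     class = "cluster_model")
  fz <- rbind(c(2, -1, 0), c(2, -1, 0.1), c(-1, 2, 0), c(-1.1, 2, 0),
              c(2, -1, 0))
  colnames(fz) <- paste0("g", 1:3)
  mc <- c("m1", "m1", "m2", "m2", "m3")
  mp <- map_fish_to_scrna(fz, mc, model, exclude = "m3")
  expect_false("m3" %in% rownames(mp$correspondence))
  expect_equal(unname(mp$correspondence["m1", "A"]), 1)
  expect_equal(unname(mp$correspondence["m2", "B"]), 1)
})

test_that("morphometric effect sizes match hand-computed formulas", {
  a <- c(5, 6, 7, 8, 9, 10)
  b <- c(1, 2, 3, 4, 5, 6)
  rec <- data.frame(volume = c(a, b))
  lab <- rep(c("A", "B"), each = 6)
  out <- morphometrics_compare(rec, lab, features = "volume")
  # Cohen's d by hand: pooled SD over the 6-vs-6 toy
  sp <- sqrt((5 * var(a) + 5 * var(b)) / 10)
  d_manual <- (mean(a) - mean(b)) / sp
  expect_equal(out$cohens_d[out$cluster == "A"], d_manual, tolerance = 1e-12)
  # rank-biserial by hand: U = #{(i,j): a_i < b_j} + ties/2
  U <- sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
  rg_manual <- 1 - 2 * U / 36
  expect_equal(out$rank_biserial[out$cluster == "A"], rg_manual,
               tolerance = 1e-12)
})

test_that("complete separation gives rg = 1; identical groups are not reportable", {
  rec <- data.frame(volume = c(11:16, 1:6))
  lab <- rep(c("hi", "lo"), each = 6)
  out <- morphometrics_compare(rec, lab, features = "volume")
  expect_equal(out$rank_biserial[out$cluster == "hi"], 1)
  expect_equal(out$rank_biserial[out$cluster == "lo"], -1)

  set.seed(11)
  v <- rnorm(40, 10)
  rec2 <- data.frame(volume = c(v, v))
  lab2 <- rep(c("A", "B"), each = 40)
  out2 <- morphometrics_compare(rec2, lab2, features = "volume")
  expect_false(any(out2$reportable))
  expect_equal(out2$cohens_d, c(0, 0), tolerance = 1e-12)
})

test_that("a one-pooled-SD volume shift is reportable, unshifted clusters are not", {
  hits <- 0L
  false_flags <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    rec <- data.frame(volume = c(rnorm(5 * n, 1500, 300),
                                 rnorm(n, 1800, 300)))
    lab <- c(rep(paste0("plain", 1:5), each = n), rep("shifted", n))
    out <- morphometrics_compare(rec, lab, features = "volume")
    if (out$reportable[out$cluster == "shifted"]) hits <- hits + 1L
    false_flags <- false_flags +
      sum(out$reportable[out$cluster != "shifted"])
  }
  expect_gte(hits, 9L)
  expect_lte(false_flags, 1L)
})
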