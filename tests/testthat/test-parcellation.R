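# independent Otsu oracle: evaluate the histogram between-class variance at
# every possible bin cut with plain arithmetic
brute_otsu <- function(values, n_bins = 256L) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1L)
  bin <- pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  best <- -Inf; best_t <- NA
  for (t in seq_len(n_bins - 1L)) {
    lo <- bin <= t; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo); w1 <- mean(hi)
    m0 <- mean(mids[bin[lo]]); m1 <- mean(mids[bin[hi]])
    bcv <- w0 * w1 * (m0 - m1)^2
    if (bcv > best) { best <- bcv; best_t <- edges[t + 1L] }
  }
  best_t
}

test_that("voxelization reduces to the containing voxel in the delta limit", {
  g <- voxel_grid(c(0, 0), spacing = 25, dims = c(4, 4))
  pos <- matrix(c(37.5, 62.5), 1)    # center of voxel (2, 3)
  z <- matrix(2.5, 1, 1, dimnames = list(NULL, "g1"))
  img <- voxelize_expression(pos, z, g, bandwidth = 1)
  nz <- which(img$values != 0)
  expect_length(nz, 1L)
  expect_equal(img$grid$centers[nz, ], c(x = 37.5, y = 62.5))
  expect_equal(img$values[nz], 2.5)
})

test_that("constant z gives a constant image over the occupied support", {
  set.seed(16)
  pos <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  z <- matrix(1.7, 50, 1, dimnames = list(NULL, "g1"))
  g <- voxel_grid(c(0, 0), 20, c(5, 5))
  img <- voxelize_expression(pos, z, g, bandwidth = 15)
  occ <- img$weight >= 1e-12
  expect_equal(unname(img$values[occ, 1]), rep(1.7, sum(occ)),
               tolerance = 1e-9)
})

test_that("two-cell voxel values equal the closed-form Gaussian kernel sum", {
  g <- voxel_grid(c(0, 0), 10, c(3, 3))
  pos <- rbind(c(5, 5), c(25, 15))
  z <- matrix(c(1, -2), 2, 1, dimnames = list(NULL, "g1"))
  h <- 12
  img <- voxelize_expression(pos, z, g, bandwidth = h)
  for (v in seq_len(nrow(g$centers))) {
    d2 <- rowSums((matrix(g$centers[v, ], 2, 2, byrow = TRUE) - pos)^2)
    w <- exp(-d2 / (2 * h^2))
    expect_equal(unname(img$values[v, 1]), unname(sum(w * z[, 1]) / sum(w)),
                 tolerance = 1e-9)
  }
  expect_error(voxelize_expression(pos[0, ], z[0, , drop = FALSE], g), "no cells")
})

test_that("spatial PCA isolates the only varying gene and orders variance", {
  g <- voxel_grid(c(0, 0), 10, c(10, 10))
  set.seed(17)
  pos <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  z <- cbind(flat1 = rep(0.5, 300), grad = pos[, 1] / 50 - 1,
             flat2 = rep(-0.2, 300))
  img <- voxelize_expression(pos, z, g, bandwidth = 10)
  p <- spatial_pca(img)
  expect_gte(abs(p$loadings["grad", 1]), 0.99)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-9)
})

test_that("two orthogonal planted patterns are recovered by two components", {
  g <- voxel_grid(c(0, 0), 10, c(10, 10))
  pos <- as.matrix(expand.grid(seq(2.5, 97.5, by = 5), seq(2.5, 97.5, by = 5)))
  pat1 <- sin(pos[, 1] / 100 * 2 * pi)
  pat2 <- sin(pos[, 2] / 100 * 2 * pi)
  z <- cbind(a = pat1, b = -pat1, c = pat2, d = pat2)
  img <- voxelize_expression(pos, z, g, bandwidth = 5)
  p <- spatial_pca(img)
  vox1 <- sin((g$centers[, 1]) / 100 * 2 * pi)
  vox2 <- sin((g$centers[, 2]) / 100 * 2 * pi)
  occ <- img$weight >= 1e-12
  r1 <- c(abs(cor(p$scores[occ, 1], vox1[occ])),
          abs(cor(p$scores[occ, 2], vox1[occ])))
  r2 <- c(abs(cor(p$scores[occ, 1], vox2[occ])),
          abs(cor(p$scores[occ, 2], vox2[occ])))
  expect_gt(max(r1), 0.95)
  expect_gt(max(r2), 0.95)
  expect_false(which.max(r1) == which.max(r2))  # each pattern found once
})

test_that("parcellation gene selection ranks by mean loading magnitude", {
  L <- rbind(g1 = c(0.9, 0.8), g2 = c(0.1, 0.2), g3 = c(0.5, -0.6))
  sel <- select_parcellation_genes(L, n_top_pcs = 2, n_genes = 2)
  # brute force: mean absolute loadings 0.85, 0.15, 0.55
  expect_equal(sel, c("g1", "g3"))
  expect_length(select_parcellation_genes(L, 2, 3), 3L)
  expect_error(select_parcellation_genes(L, 5, 1), "exceeds")
})

test_that("Otsu splits a gapped sample at the gap and matches brute force", {
  v <- c(0, 0, 0, 10, 10, 10)
  t0 <- otsu_threshold(v)
  expect_gt(t0, 0); expect_lte(t0, 10)
  cls <- otsu_classify(matrix(v, ncol = 1, dimnames = list(NULL, "g")))
  expect_equal(unname(cls$positive[, 1]), rep(c(FALSE, TRUE), each = 3))

  set.seed(19)
  for (i in 1:25) {
    v <- c(rnorm(25, 0), rnorm(25, runif(1, 2, 8)))
    expect_equal(otsu_threshold(v), brute_otsu(v), tolerance = 1e-9)
  }
  expect_error(otsu_threshold(rep(3, 5)), "constant")
})

test_that("well-separated bimodal values are classified with <1% error", {
  set.seed(20)
  n <- 4000
  truth <- rep(c(FALSE, TRUE), each = n / 2)
  v <- ifelse(truth, rnorm(n, 10, 1), rnorm(n, 0, 1))   # 5 SD of pooled sep
  pos <- v >= otsu_threshold(v)
  expect_lt(mean(pos != truth), 0.01)
})

test_that("combined Otsu classes map sign tuples to named regions", {
  m <- cbind(g1 = c(0, 0, 10, 10), g2 = c(0, 10, 0, 10))
  cm <- c("--" = "south", "-+" = "east", "+-" = "west", "++" = "north")
  cls <- otsu_classify(m, class_map = cm)
  expect_equal(cls$class, c("south", "east", "west", "north"))
})

test_that("GP segmentation places the boundary at the symmetry plane", {
  set.seed(21)
  n <- 300
  pos <- rbind(cbind(runif(n, 0, 90), runif(n, 0, 200)),
               cbind(runif(n, 110, 200), runif(n, 0, 200)))
  cls <- rep(c("L", "R"), each = n)
  seg <- gp_segment(pos, cls, gp_params(grid_spacing = 10))
  expect_equal(unname(rowSums(seg$prob)), rep(1, nrow(seg$prob)),
               tolerance = 1e-6)
  # predicted voxel class flips within one grid spacing of x = 100
  xs <- seg$grid$centers[, 1]
  wrongL <- xs < 90 & seg$voxel_class == "R"
  wrongR <- xs > 110 & seg$voxel_class == "L"
  expect_lt(mean(wrongL | wrongR), 0.02)
  # cells themselves are recovered
  expect_gt(mean(seg$cell_class == cls), 0.95)
  expect_error(gp_segment(pos, rep("L", 2 * n)), "2 classes")
})

test_that("subregion enrichment rows are exact fractions summing to one", {
  mc <- c("m1", "m1", "m1", "m2", "m2")
  sr <- c("a", "a", "b", "b", "b")
  e <- subregion_enrichment(mc, sr)
  expect_equal(unname(e["m1", ]), c(2 / 3, 1 / 3))
  expect_equal(unname(rowSums(e)), c(1, 1), tolerance = 1e-9)
  one <- subregion_enrichment(c("m1", "m1"), c("a", "a"))
  expect_equal(unname(one["m1", "a"]), 1)
})
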