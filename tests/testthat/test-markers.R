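de_row <- function(gene, lfc = 1, p1 = 0.9, p2 = 0.1, padj = 0.01,
                   cluster = "A") {
  data.frame(cluster = cluster, gene = gene, avg_logFC = lfc, pct.1 = p1,
             pct.2 = p2, p_val = padj, p_val_adj = padj)
}

test_that("candidate filtering applies the significance and fold-change cutoffs", {
  de <- rbind(de_row("good"),
              de_row("notsig", padj = 0.2),
              de_row("weakfc", lfc = 0.54),
              de_row("perfect", p1 = 1, p2 = 0, lfc = 2))
  out <- filter_candidates(de, marker_filter())
  expect_false("notsig" %in% out)
  expect_false("weakfc" %in% out)
  expect_equal(out[1], "perfect")   # best binarity ranks first
  expect_true("good" %in% out)
  expect_warning(filter_candidates(de_row("x", padj = 0.9)), "no candidate")
})

test_that("correlation assignment recovers identical profiles with r = 1", {
  prof <- rbind(A = c(2, 0, 1, -1), B = c(-1, 2, 0, 1), C = c(0, -1, 2, 1))
  colnames(prof) <- paste0("g", 1:4)
  model <- structure(list(profiles = prof, genes = colnames(prof)),
                     class = "cluster_model")
  cells <- prof[c("B", "A", "C"), ]
  a <- assign_by_correlation(cells, model)
  expect_equal(a$assigned, c("B", "A", "C"))
  expect_equal(a$r, rep(1, 3), tolerance = 1e-12)
})

test_that("constant cell profiles are flagged unassignable", {
  prof <- rbind(A = c(1, 0, 2), B = c(0, 2, 1))
  colnames(prof) <- paste0("g", 1:3)
  model <- structure(list(profiles = prof, genes = colnames(prof)),
                     class = "cluster_model")
  cells <- rbind(c(5, 5, 5), c(1, 0, 2))
  colnames(cells) <- paste0("g", 1:3)
  a <- assign_by_correlation(cells, model)
  expect_true(is.na(a$assigned[1]))
  expect_equal(a$assigned[2], "A")
})

test_that("assignments equal a brute-force correlation table on a toy", {
  set.seed(8)
  prof <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("A", "B", "C"), paste0("g", 1:4)))
  model <- structure(list(profiles = prof, genes = colnames(prof)),
                     class = "cluster_model")
  cells <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
  a <- assign_by_correlation(cells, model)
  for (i in 1:10) {
    rs <- sapply(rownames(prof), function(k) cor(cells[i, ], prof[k, ]))
    expect_equal(a$assigned[i], names(which.max(rs)))
    expect_equal(a$r[i], max(rs), tolerance = 1e-8)
  }
})

test_that("correlation assignment is invariant to affine rescaling of a cell", {
  set.seed(9)
  prof <- matrix(rnorm(15), 3, 5,
                 dimnames = list(c("A", "B", "C"), paste0("g", 1:5)))
  model <- structure(list(profiles = prof, genes = colnames(prof)),
                     class = "cluster_model")
  cells <- matrix(rnorm(25), 5, 5, dimnames = list(NULL, paste0("g", 1:5)))
  a1 <- assign_by_correlation(cells, model)
  a2 <- assign_by_correlation(cells * 3.7 + 11, model)
  expect_equal(a1$assigned, a2$assigned)
  expect_equal(a1$r, a2$r, tolerance = 1e-9)
})

test_that("mapping accuracy and the assignment-fraction matrix are exact", {
  truth <- c("A", "A", "A", "B", "B", "B", "C", "C", "C", "C")
  assigned <- c("A", "A", "B", "B", "B", NA, "C", "C", "A", "C")
  m <- mapping_accuracy(assigned, truth)
  expect_equal(m$accuracy, 7 / 10)
  # hand tally: A -> A 2/3, B 1/3; B -> B 2/3, unassigned 1/3
  expect_equal(unname(m$matrix["A", "A"]), 2 / 3)
  expect_equal(unname(m$matrix["B", "unassigned"]), 1 / 3)
  expect_equal(unname(rowSums(m$matrix)), rep(1, 3))
  expect_equal(mapping_accuracy(truth, truth)$accuracy, 1)
  expect_equal(mapping_accuracy(rep(NA, 10), truth)$accuracy, 0)
  expect_error(mapping_accuracy(assigned[1:5], truth), "equal length")
})

# planted panel: K clusters, one exclusive binary marker each, plus noise genes
planted_panel_data <- function(K = 4, n_per = 25, noise_genes = 4, seed = 3) {
  set.seed(seed)
  n <- K * n_per
  truth <- rep(paste0("C", 1:K), each = n_per)
  z <- matrix(rnorm(n * noise_genes, 0, 1), n, noise_genes,
              dimnames = list(NULL, paste0("noise", seq_len(noise_genes))))
  for (k in 1:K) {
    v <- ifelse(truth == paste0("C", k), 1, -0.5) + rnorm(n, 0, 0.01)
    z <- cbind(z, v)
    colnames(z)[ncol(z)] <- paste0("marker", k)
  }
  list(z = z, truth = truth)
}

test_that("greedy panel reaches perfect accuracy with planted exclusive markers", {
  d <- planted_panel_data()
  gp <- greedy_panel(d$z, d$truth, colnames(d$z), max_size = 4)
  expect_equal(gp$accuracy[4], 1)
  expect_setequal(gp$panel, paste0("marker", 1:4))
})

test_that("the first greedy selection equals exhaustive pair search on a 6-gene toy", {
  d <- planted_panel_data(K = 3, n_per = 15, noise_genes = 3, seed = 5)
  cand <- colnames(d$z)
  gp <- greedy_panel(d$z, d$truth, cand, max_size = 2)
  # independent brute force over all pairs with plain cor() assignment
  centro <- t(sapply(sort(unique(d$truth)), function(k)
    colMeans(d$z[d$truth == k, , drop = FALSE])))
  pair_acc <- function(pair) {
    ok <- vapply(seq_len(nrow(d$z)), function(i) {
      # same tie rule as the package: round, then first maximum
      rs <- round(apply(centro[, pair], 1, function(p) cor(d$z[i, pair], p)), 9)
      names(which.max(rs)) == d$truth[i]
    }, TRUE)
    mean(ok)
  }
  pairs <- combn(sort(cand), 2)
  accs <- apply(pairs, 2, pair_acc)
  expect_equal(sort(gp$panel), sort(pairs[, which.max(accs)]))
  expect_equal(gp$accuracy[2], max(accs))
})

test_that("greedy panel construction is deterministic", {
  d <- planted_panel_data(seed = 7)
  g1 <- greedy_panel(d$z, d$truth, colnames(d$z), max_size = 5)
  g2 <- greedy_panel(d$z, d$truth, colnames(d$z), max_size = 5)
  expect_identical(g1, g2)
  expect_true(all(g1$accuracy[-1] >= 0 & g1$accuracy[-1] <= 1))
  expect_error(greedy_panel(d$z, d$truth, colnames(d$z), max_size = 1), ">= 2")
})
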