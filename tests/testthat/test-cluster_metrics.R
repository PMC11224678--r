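make_emb <- function(X, barcodes = sprintf("c%d", seq_len(nrow(X)))) {
  structure(list(barcodes = barcodes, vectors = X,
                 coverage = rep(1L, nrow(X))),
            class = "cell_embeddings")
}

test_that("clustering recovers trivially separable structure", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, 0, 0.05), 20), matrix(rnorm(40, 10, 0.05), 20))
  truth <- rep(0:1, each = 20)
  emb <- make_emb(X)
  for (m in c("kmeans", "hc")) {
    asg <- cluster_cells(emb, m, k = 2, seed = 1L)
    expect_equal(ari(truth, asg$labels), 1)
    expect_setequal(asg$labels, 0:1)  # contiguous 0..K-1
  }
  asg_l <- cluster_cells(emb, "louvain", k_graph = 15L, seed = 1L)
  expect_equal(ari(truth, asg_l$labels), 1)

  expect_equal(unique(cluster_cells(make_emb(matrix(1, 5, 2)), "hc", k = 1)$labels), 0L)
  expect_error(cluster_cells(emb, "kmeans", k = 100), "exceeds")
  # NaN cells are excluded
  X2 <- X; X2[1, ] <- NaN
  asg2 <- suppressWarnings(cluster_cells(make_emb(X2), "kmeans", k = 2, seed = 1L))
  expect_length(asg2$labels, 39L)
})

test_that("louvain splits two disconnected cliques into two communities", {
  # two tight point clouds far apart with k_graph small enough that the kNN
  # graph is two disconnected components: modularity must find exactly 2
  set.seed(7)
  X <- rbind(matrix(rnorm(20, 0, 0.01), 10), matrix(rnorm(20, 100, 0.01), 10))
  asg <- cluster_cells(make_emb(X), "louvain", k_graph = 9L, seed = 1L)
  expect_equal(length(unique(asg$labels)), 2L)
  expect_equal(ari(rep(0:1, each = 10), asg$labels), 1)
})

test_that("ARI/AMI/homogeneity match hand values and frozen external oracle", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ami(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(homogeneity(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # permutation invariance
  expect_equal(ari(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  # hand-computed contingency value
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  # frozen values computed with scikit-learn metrics on the same labelings
  expect_equal(ami(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5, tolerance = 1e-9)
  expect_equal(ari(c(0, 0, 1, 1, 2), c(0, 1, 1, 2, 2)), -0.25, tolerance = 1e-9)
  expect_equal(ami(c(0, 0, 1, 1, 2), c(0, 1, 1, 2, 2)), -0.25, tolerance = 1e-9)
  expect_equal(homogeneity(c(0, 0, 1, 1, 2), c(0, 1, 1, 2, 2)),
               0.474350987614, tolerance = 1e-9)
  expect_equal(ari(c(0, 0, 0, 1, 1, 2), c(1, 1, 0, 0, 2, 2)),
               0.074074074074, tolerance = 1e-9)
  expect_equal(ami(c(0, 0, 0, 1, 1, 2), c(1, 1, 0, 0, 2, 2)),
               0.083726783787, tolerance = 1e-9)
  expect_equal(homogeneity(c(0, 0, 0, 1, 1, 2), c(1, 1, 0, 0, 2, 2)),
               0.543112347359, tolerance = 1e-9)
  expect_error(ari(c(0, 1), c(0, 1, 1)), "length")
})

test_that("partition scores agree with brute-force oracles on all partitions of n = 4", {
  parts <- all_partitions(4)
  for (a in parts) for (b in parts) {
    expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-12)
    expect_equal(ami(a, b), oracle_ami(a, b), tolerance = 1e-9)
    expect_equal(homogeneity(a, b), oracle_homogeneity(a, b), tolerance = 1e-12)
  }
})

test_that("gini index: closed forms, brute force, scale invariance", {
  expect_equal(gini_index(c(1, 1, 1)), 0)
  expect_equal(gini_index(c(0, 0, 1)), 2 / 3)
  expect_equal(gini_index(c(1, 2, 3)), 8 / 36)
  expect_warning(expect_equal(gini_index(c(0, 0)), 0), "all-zero")
  set.seed(9)
  for (rep in 1:10) {
    x <- stats::rexp(sample(2:12, 1))
    expect_equal(gini_index(x), oracle_gini(x), tolerance = 1e-12)
    expect_equal(gini_index(3.7 * x), gini_index(x), tolerance = 1e-12)
    expect_lte(gini_index(x), (length(x) - 1) / length(x))
  }
})

ragi_fixture <- function() {
  # 6 cells, 3 clusters of 2; region 1 marker (only cluster 0 accessible),
  # regions 2-3 housekeeping (everyone accessible), region 4 unused filler
  m <- rbind(c(1, 1, 1, 0), c(1, 1, 1, 0),
             c(0, 1, 1, 0), c(0, 1, 1, 0),
             c(0, 1, 1, 0), c(0, 1, 1, 0))
  mat <- tiny_matrix(m)
  asg <- structure(list(barcodes = mat$barcodes, labels = rep(0:2, each = 2),
                        method = "manual", params = list()),
                   class = "cluster_assignment")
  list(mat = mat, asg = asg)
}

test_that("RAGI composes gini over activities as in the closed form", {
  fx <- ragi_fixture()
  sigs <- signature_sets(marker_sets = list(m1 = 1L),
                         housekeeping_sets = list(h1 = c(2L, 3L)))
  out <- ragi(fx$mat, fx$asg, sigs)
  # marker activity (1,0,0) -> gini 2/3; housekeeping uniform -> 0
  expect_equal(out$ragi, 2 / 3)
  expect_equal(out$mean_marker_gini, 2 / 3)
  expect_equal(out$mean_housekeeping_gini, 0)
  expect_equal(nrow(out$per_gene), 2L)

  # markers == housekeeping sets gives RAGI 0 by self-difference
  sigs2 <- signature_sets(marker_sets = list(m1 = c(2L, 3L)),
                          housekeeping_sets = list(h1 = c(2L, 3L)))
  expect_equal(ragi(fx$mat, fx$asg, sigs2)$ragi, 0)

  # genes with no regions in the matrix are excluded with a warning
  sigs3 <- signature_sets(marker_sets = list(m1 = 1L, gone = 99L),
                          housekeeping_sets = list(h1 = c(2L, 3L)))
  expect_warning(out3 <- ragi(fx$mat, fx$asg, sigs3), "gone")
  expect_equal(out3$ragi, 2 / 3)
})

test_that("RAGI on a hand fixture matches a brute-force activity computation", {
  fx <- ragi_fixture()
  # brute force: per gene, per cluster mean over cells of mean accessibility
  brute_activity <- function(mat, labels, set) {
    B <- as.matrix(mat$counts) > 0
    vapply(sort(unique(labels)), function(cl) {
      cells <- which(labels == cl)
      mean(vapply(cells, function(i) mean(B[i, set]), 0))
    }, 0)
  }
  sigs <- signature_sets(marker_sets = list(m1 = c(1L, 4L)),
                         housekeeping_sets = list(h1 = c(2L, 3L)))
  out <- ragi(fx$mat, fx$asg, sigs)
  exp_marker <- oracle_gini(brute_activity(fx$mat, fx$asg$labels, c(1L, 4L)))
  exp_house <- oracle_gini(brute_activity(fx$mat, fx$asg$labels, c(2L, 3L)))
  expect_equal(out$ragi, exp_marker - exp_house, tolerance = 1e-12)
})

test_that("RAGI grows as markers become more cluster-specific", {
  scores <- vapply(c(0.05, 0.15, 0.3), function(p_high) {
    sim <- generate_synthetic(synthetic_spec(n_types = 3L, cells_per_type = 30L,
                                             n_regions = 150L, signature_size = 15L,
                                             housekeeping_size = 15L,
                                             p_high = p_high, p_low = 0.02,
                                             p_house = 0.8, seed = 77L))
    asg <- structure(list(barcodes = sim$matrix$barcodes,
                          labels = as.integer(factor(sim$labels)) - 1L,
                          method = "truth", params = list()),
                     class = "cluster_assignment")
    ragi(sim$matrix, asg, sim$signatures)$ragi
  }, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("subsampled RAGI degenerates to a single full call and is seed-stable", {
  sim <- small_sim()
  model <- train_region_embeddings(build_documents(sim$matrix),
                                   training_config(dim = 8L, epochs = 3L, seed = 1L))
  emb <- embed_all(sim$matrix, model)
  n <- length(sim$matrix$barcodes)
  out <- subsampled_ragi(sim$matrix, list(direct = emb), sim$signatures,
                         n_sub = n, reps = 1L, methods = "kmeans", k = 2L,
                         seed = 3L)
  # n_sub = n covers every cell: must equal one full ragi call at the same
  # derived clustering seed
  full <- ragi(sim$matrix,
               cluster_cells(emb, "kmeans", k = 2L,
                             seed = chromembed:::derive_seed(3L, 1L, 1L)),
               sim$signatures)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mean_ragi, full$ragi)
  # identical sources under identical seeds give identical distributions
  out2 <- subsampled_ragi(sim$matrix, list(a = emb, b = emb), sim$signatures,
                          n_sub = 40L, reps = 3L, methods = "kmeans", k = 2L,
                          seed = 3L)
  expect_equal(out2$mean_ragi[out2$source == "a"],
               out2$mean_ragi[out2$source == "b"])
  expect_error(subsampled_ragi(sim$matrix, list(a = emb), sim$signatures,
                               n_sub = n + 1L, reps = 1L), "exceeds")
})
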