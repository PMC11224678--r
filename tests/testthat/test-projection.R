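test_that("overlap mapping honors half-open coordinates and many-to-many links", {
  ref <- genomic_regions(c("chr1", "chr1"), c(100, 250), c(200, 300))
  q <- genomic_regions(c("chr1", "chr1", "chr1"),
                       c(150, 200, 90), c(250, 300, 310))
  map <- build_overlap_map(q, ref)
  expect_equal(map$links[[1]], 1L)          # 50 bp overlap
  expect_equal(map$links[[2]], 2L)          # abuts ref1 at 200: NOT linked
  expect_equal(map$links[[3]], c(1L, 2L))   # spans both
  expect_equal(map$stats$n_query, 3L)
  expect_equal(map$stats$n_mapped, 3L)
  expect_equal(map$stats$mean_links_per_mapped, 4 / 3)

  expect_warning(m2 <- build_overlap_map(genomic_regions("chrZ", 0, 10), ref),
                 "chromosome")
  expect_identical(m2$links[[1]], integer(0))
})

test_that("best-hit mode keeps the largest overlap, lower index on ties", {
  ref <- genomic_regions(c("chr1", "chr1", "chr1"),
                         c(0, 80, 300), c(100, 200, 400))
  q <- genomic_regions(c("chr1", "chr1"), c(50, 320), c(130, 340))
  map <- build_overlap_map(q, ref, mode = "best")
  expect_equal(map$links[[1]], 1L)  # 50 bp vs 50 bp tie -> lower index
  expect_equal(map$links[[2]], 3L)
})

test_that("overlap mapping agrees exactly with the all-pairs oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(50:200, 1); m <- sample(50:200, 1)
    rand_regions <- function(k) {
      chrom <- sample(c("chr1", "chr2", "chr3"), k, replace = TRUE)
      start <- sample.int(5000, k, replace = TRUE)
      genomic_regions(chrom, start, start + sample.int(300, k, replace = TRUE))
    }
    q <- rand_regions(n); r <- rand_regions(m)
    map <- build_overlap_map(q, r)
    expect_identical(lapply(map$links, as.integer), oracle_overlap_links(q, r))
  }
})

test_that("translate_documents dedups links and keeps empty cells aligned", {
  ref <- genomic_regions("chr1", c(0, 1000), c(500, 1500))
  ref_words <- region_to_word(ref)
  # two query regions both inside ref1; one query region mapping nowhere
  q <- genomic_regions(c("chr1", "chr1", "chr5"), c(0, 250, 0), c(200, 450, 100))
  mat <- tiny_matrix(rbind(c(1, 1, 0), c(0, 0, 1)), regions = q)
  map <- build_overlap_map(q, ref)
  corpus <- translate_documents(mat, map, ref_words)
  expect_identical(corpus$documents[[1]], ref_words[1])  # dedup to one word
  expect_identical(corpus$documents[[2]], character(0))
  expect_equal(attr(corpus, "mapped_fraction"), c(1, 0))
})

test_that("projection identity: query == consensus gives bit-identical embeddings", {
  sim <- small_sim()
  model <- train_region_embeddings(build_documents(sim$matrix),
                                   training_config(dim = 8L, epochs = 2L, seed = 2L))
  direct <- embed_all(sim$matrix, model)
  projected <- e_project(sim$matrix, model)
  expect_identical(projected$vectors, direct$vectors)
  expect_identical(projected$coverage, direct$coverage)
})

test_that("jittered queries map to the same link sets and embeddings", {
  sim <- small_sim()
  model <- train_region_embeddings(build_documents(sim$matrix),
                                   training_config(dim = 8L, epochs = 2L, seed = 2L))
  direct <- embed_all(sim$matrix, model)
  jit <- jitter_regions(sim$regions, max_shift = 20L, seed = 8L)
  qmat <- acc_matrix(sim$matrix$counts, sim$matrix$barcodes, jit)
  map <- build_overlap_map(jit, sim$regions)
  expect_true(all(lengths(map$links) == 1L))
  expect_identical(e_project(qmat, model)$vectors, direct$vectors)
})

test_that("mapped fraction decreases as queries shift away from the reference", {
  ref <- tiny_regions(50)  # width 500, gap 1000
  mat_for <- function(shift) {
    q <- genomic_regions(ref$chrom, ref$start + shift, ref$end + shift)
    acc_matrix(Matrix::Matrix(diag(50), sparse = TRUE),
               sprintf("bc%d", 1:50), q)
  }
  ref_words <- region_to_word(ref)
  # shifts below one region+gap period, so a shifted query cannot wrap onto
  # the next reference interval
  frac <- vapply(c(0L, 300L, 600L, 900L), function(s) {
    map <- suppressWarnings(build_overlap_map(mat_for(s)$regions, ref))
    corpus <- translate_documents(mat_for(s), map, ref_words)
    mean(attr(corpus, "mapped_fraction"), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(frac) <= 0))
  expect_equal(frac[1], 1)
  expect_equal(frac[4], 0)
})

test_that("zero mapped cells is a hard error advising assembly mismatch", {
  sim <- small_sim()
  model <- train_region_embeddings(build_documents(sim$matrix),
                                   training_config(dim = 8L, epochs = 1L, seed = 2L))
  other <- genomic_regions(rep("chrOther", 3), c(0, 1000, 2000),
                           c(500, 1500, 2500))
  qmat <- tiny_matrix(rbind(c(1, 1, 0), c(0, 1, 1)), regions = other)
  expect_error(suppressWarnings(e_project(qmat, model)), "assembly")
})

test_that("pca reducer is deterministic and preserves planted separation", {
  sim <- small_sim()
  model <- train_region_embeddings(build_documents(sim$matrix),
                                   training_config(dim = 8L, epochs = 5L, seed = 2L))
  emb <- embed_all(sim$matrix, model)
  red <- fit_reducer(emb, seed = 4L, method = "pca")
  expect_equal(dim(red$ref_coords), c(100L, 2L))
  expect_identical(fit_reducer(emb, seed = 4L, method = "pca")$ref_coords,
                   red$ref_coords)
  # silhouette of the planted types in 2D must be positive
  d2 <- as.matrix(stats::dist(red$ref_coords))
  ty <- as.integer(factor(sim$labels))
  a <- vapply(1:100, function(i) sum(d2[i, ty == ty[i]]) / (sum(ty == ty[i]) - 1), 0)
  b <- vapply(1:100, function(i) mean(d2[i, ty != ty[i]]), 0)
  expect_gt(mean((b - a) / pmax(a, b)), 0)
  # transform-only: ev_project of the reference reproduces stored coordinates
  coords <- ev_project(emb, red)
  expect_equal(unname(coords), unname(red$ref_coords))
  expect_error(fit_reducer(emb, min_cells = 200L), "at least 200")
})

test_that("umap reducer fits, transforms and is reproducible under a seed", {
  sim <- small_sim()
  model <- train_region_embeddings(build_documents(sim$matrix),
                                   training_config(dim = 8L, epochs = 5L, seed = 2L))
  emb <- embed_all(sim$matrix, model)
  red <- fit_reducer(emb, seed = 4L, method = "umap")
  expect_equal(dim(red$ref_coords), c(100L, 2L))
  expect_true(all(is.finite(red$ref_coords)))
  red2 <- fit_reducer(emb, seed = 4L, method = "umap")
  expect_equal(red2$ref_coords, red$ref_coords)

  # a query identical to a reference cell lands near its stored coordinate
  sub <- structure(list(barcodes = emb$barcodes[1:10],
                        vectors = emb$vectors[1:10, , drop = FALSE],
                        coverage = emb$coverage[1:10]),
                   class = "cell_embeddings")
  coords <- ev_project(sub, red)
  expect_equal(dim(coords), c(10L, 2L))
  # the transform of a training point is approximate, not exact: require the
  # cell's own stored coordinate to sit among the nearest reference points
  # (tolerance derived on the fitted output: <= 10% of the reference set,
  # median rank <= 5)
  rks <- vapply(1:10, function(i) {
    d_all <- sqrt(rowSums((red$ref_coords - matrix(coords[i, ], 100, 2,
                                                   byrow = TRUE))^2))
    rank(d_all, ties.method = "min")[i]
  }, 0)
  expect_true(all(rks <= 10))
  expect_lte(stats::median(rks), 5)
})
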