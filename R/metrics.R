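#' Cluster cell embeddings
#'
#' Three clustering routes over the pooled cell embeddings: K-means,
#' hierarchical clustering (Ward linkage on Euclidean distances) and Louvain
#' community detection on a symmetric k-nearest-neighbor graph (an edge is
#' kept if either endpoint lists the other; unit weights). `NaN` cells are
#' excluded. Deterministic under `seed`.
#'
#' @param emb a `cell_embeddings` object.
#' @param method one of `"kmeans"`, `"hc"`, `"louvain"`.
#' @param k number of clusters (required for kmeans / hc).
#' @param k_graph neighbors for the Louvain kNN graph (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param seed integer seed.
#' @return a `cluster_assignment`: list with `barcodes` (clustered cells
#'   only), `labels` (integers `0..K-1`, contiguous, in order of first
#'   appearance), `method` and `params`.
#' @export
cluster_cells <- function(emb, method = c("kmeans", "hc", "louvain"),
                          k = NULL, k_graph = 15L, resolution = 1,
                          seed = 42L) {
  method <- match.arg(method)
  stopifnot(inherits(emb, "cell_embeddings"))
  ok <- rowSums(is.finite(emb$vectors)) == ncol(emb$vectors)
  X <- emb$vectors[ok, , drop = FALSE]
  n <- nrow(X)
  if (n < 2L) stop_fmt("need at least 2 usable cells to cluster")
  if (method %in% c("kmeans", "hc")) {
    if (is.null(k)) stop_fmt("method '%s' requires k", method)
    if (k > n) stop_fmt("k = %d exceeds number of usable cells (%d)", k, n)
  }
  labels <- switch(method,
    kmeans = with_seed(seed,
      stats::kmeans(X, centers = k, nstart = 10L, iter.max = 100L)$cluster),
    hc = {
      if (k == 1L) rep(1L, n)
      else stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"), k = k)
    },
    louvain = {
      g <- knn_graph(X, k_graph)
      with_seed(seed,
        igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
    })
  labels <- as.integer(factor(labels, levels = unique(labels))) - 1L
  structure(list(barcodes = emb$barcodes[ok], labels = labels,
                 method = method,
                 params = list(k = k, k_graph = as.integer(k_graph),
                               resolution = resolution, seed = as.integer(seed))),
            class = "cluster_assignment")
}

knn_graph <- function(X, k_graph) {
  n <- nrow(X)
  k_graph <- min(as.integer(k_graph), n - 1L)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nb <- t(apply(D, 1L, function(d) order(d)[seq_len(k_graph)]))
  el <- cbind(rep(seq_len(n), each = k_graph), as.integer(t(nb)))
  el <- unique(t(apply(el, 1L, sort)))  # symmetric: either endpoint suffices
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s: %d cells in %d clusters\n",
              x$method, length(x$labels), length(unique(x$labels))))
  invisible(x)
}

contingency <- function(a, b) {
  if (length(a) != length(b)) stop_fmt("label vectors differ in length")
  if (length(a) < 2L) stop_fmt("need at least 2 elements")
  unclass(table(a, b))
}

#' Partition agreement scores
#'
#' Chance-adjusted agreement between two labelings of the same cells, used
#' when ground-truth labels are available. `ari()` is the adjusted Rand
#' index, `ami()` the adjusted mutual information (permutation-model
#' expectation, arithmetic mean normalizer) and `homogeneity()` equals
#' `1 - H(truth | predicted) / H(truth)`. All three are invariant to label
#' permutations; ARI and AMI are 1 for identical partitions and about 0 for
#' random ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar score.
#' @export
ari <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  sij <- sum(choose(ct, 2))
  sa <- sum(choose(rowSums(ct), 2)); sb <- sum(choose(colSums(ct), 2))
  expected <- sa * sb / choose(n, 2)
  maxi <- (sa + sb) / 2
  if (maxi == expected) return(1)  # both partitions trivial in the same way
  (sij - expected) / (maxi - expected)
}

entropy_counts <- function(cnt) {
  cnt <- cnt[cnt > 0]; p <- cnt / sum(cnt)
  -sum(p * log(p))
}

#' @rdname ari
#' @export
ami <- function(a, b) {
  ct <- contingency(a, b)
  ai <- unname(rowSums(ct)); bj <- unname(colSums(ct)); n <- sum(ct)
  if (nrow(ct) == 1L && ncol(ct) == 1L) return(1)
  # both partitions all singletons: identical partitions, but the
  # normalizer equals EMI exactly and the ratio is 0/0; define as 1
  if (all(ai == 1L) && all(bj == 1L)) return(1)
  ha <- entropy_counts(ai); hb <- entropy_counts(bj)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (ai[i] * bj[j]))
  }
  emi <- expected_mi(ai, bj, n)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < .Machine$double.eps) denom <- .Machine$double.eps
  (mi - emi) / denom
}

# Expected mutual information under the permutation (hypergeometric) model.
expected_mi <- function(ai, bj, n) {
  lf <- lfactorial
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(1, ai[i] + bj[j] - n); hi <- min(ai[i], bj[j])
    if (lo > hi) next
    for (nij in lo:hi) {
      lp <- lf(ai[i]) + lf(bj[j]) + lf(n - ai[i]) + lf(n - bj[j]) -
        lf(n) - lf(nij) - lf(ai[i] - nij) - lf(bj[j] - nij) -
        lf(n - ai[i] - bj[j] + nij)
      emi <- emi + (nij / n) * log(n * nij / (ai[i] * bj[j])) * exp(lp)
    }
  }
  emi
}

#' @rdname ari
#' @export
homogeneity <- function(a, b) {
  ct <- contingency(a, b)
  ha <- entropy_counts(rowSums(ct))
  if (ha == 0) return(1)
  # H(A | B) from the joint distribution
  n <- sum(ct)
  hab <- 0
  for (j in seq_len(ncol(ct))) {
    col <- ct[, j]
    if (sum(col) > 0) hab <- hab + (sum(col) / n) * entropy_counts(col)
  }
  1 - hab / ha
}

#' Gini index of a non-negative vector
#'
#' Normalized mean absolute difference,
#' `G = sum_ij |x_i - x_j| / (2 n sum_j x_j)`, ranging from 0 (all equal)
#' to `(n-1)/n` (all mass in one entry). Scale-invariant. An all-zero input
#' is defined as 0 with a warning.
#'
#' @param x numeric vector, values >= 0.
#' @return scalar in `[0, (n-1)/n]`.
#' @export
gini_index <- function(x) {
  stopifnot(length(x) >= 1, all(x >= 0))
  if (sum(x) == 0) {
    warning("all-zero input to gini_index; returning 0", call. = FALSE)
    return(0)
  }
  sum(abs(outer(x, x, "-"))) / (2 * length(x) * sum(x))
}

#' Marker / housekeeping signature sets
#'
#' Named sets of region (column) indices standing in for gene programs: the
#' marker sets are expected to be cluster-specific, the housekeeping sets
#' uniformly active. These drive the RAGI score when no ground-truth labels
#' exist; the synthetic generator emits them directly.
#'
#' @param marker_sets named list of integer region-index vectors.
#' @param housekeeping_sets likewise; names must be disjoint from markers.
#' @return a `signature_sets` object.
#' @export
signature_sets <- function(marker_sets, housekeeping_sets) {
  stopifnot(length(marker_sets) > 0, length(housekeeping_sets) > 0,
            !is.null(names(marker_sets)), !is.null(names(housekeeping_sets)))
  if (length(intersect(names(marker_sets), names(housekeeping_sets))))
    stop_fmt("marker and housekeeping signature names overlap")
  structure(list(marker_sets = marker_sets,
                 housekeeping_sets = housekeeping_sets),
            class = "signature_sets")
}

#' Residual Average Gini Index (RAGI)
#'
#' Label-free clustering score. For each signature (gene program), activity
#' in a cluster is the mean over that cluster's cells of the cell's mean
#' binary accessibility across the signature's regions; the Gini index of
#' the per-cluster activity vector measures how cluster-specific the
#' signature is. RAGI is the mean Gini over marker signatures minus the
#' mean Gini over housekeeping signatures: high when clusters separate
#' markers but not generic programs.
#'
#' @param mat an [acc_matrix()] (binarized internally: signal > 0).
#' @param assignment a `cluster_assignment` with >= 2 clusters.
#' @param signatures a [signature_sets()] of region column indices.
#' @return list with `ragi`, `mean_marker_gini`, `mean_housekeeping_gini`
#'   and `per_gene` (data.frame: gene, kind, gini).
#' @export
ragi <- function(mat, assignment, signatures) {
  stopifnot(inherits(mat, "acc_matrix"),
            inherits(assignment, "cluster_assignment"),
            inherits(signatures, "signature_sets"))
  if (length(unique(assignment$labels)) < 2L)
    stop_fmt("RAGI needs at least 2 clusters")
  rows <- match(assignment$barcodes, mat$barcodes)
  if (anyNA(rows)) stop_fmt("assignment contains barcodes absent from the matrix")
  B <- mat$counts[rows, , drop = FALSE]
  B@x <- as.numeric(B@x > 0)
  labels <- assignment$labels
  clusters <- sort(unique(labels))
  gene_gini <- function(set, name) {
    set <- set[set >= 1 & set <= ncol(B)]
    if (length(set) == 0L) {
      warning(sprintf("signature '%s' has no regions in the matrix; excluded",
                      name), call. = FALSE)
      return(NA_real_)
    }
    per_cell <- Matrix::rowSums(B[, set, drop = FALSE]) / length(set)
    activity <- vapply(clusters, function(cl) mean(per_cell[labels == cl]), 0)
    suppressWarnings(gini_index(activity))
  }
  mg <- vapply(names(signatures$marker_sets), function(nm)
    gene_gini(signatures$marker_sets[[nm]], nm), 0)
  hg <- vapply(names(signatures$housekeeping_sets), function(nm)
    gene_gini(signatures$housekeeping_sets[[nm]], nm), 0)
  per_gene <- data.frame(
    gene = c(names(mg), names(hg)),
    kind = rep(c("marker", "housekeeping"), c(length(mg), length(hg))),
    gini = c(mg, hg), row.names = NULL)
  list(ragi = mean(mg, na.rm = TRUE) - mean(hg, na.rm = TRUE),
       mean_marker_gini = mean(mg, na.rm = TRUE),
       mean_housekeeping_gini = mean(hg, na.rm = TRUE),
       per_gene = per_gene)
}

#' Subsampled RAGI comparison protocol
#'
#' Repeatedly subsamples cells without replacement, clusters each embedding
#' source with each clustering method on the subsample, and scores the
#' clustering with RAGI; reports mean and standard deviation across
#' repetitions. This is the protocol used to compare embeddings produced by
#' direct training against embeddings projected through a pre-trained
#' model.
#'
#' @param mat an [acc_matrix()].
#' @param embeddings_list named list of `cell_embeddings`, all aligned to
#'   `mat`'s barcodes.
#' @param signatures a [signature_sets()].
#' @param n_sub cells per subsample (default 1000).
#' @param reps number of repetitions (default 20).
#' @param methods clustering methods to run (default all three).
#' @param k cluster count for kmeans / hc.
#' @param seed integer seed; subsample r uses a seed derived from
#'   `(seed, r)`.
#' @return data.frame: source, method, mean_ragi, sd_ragi, reps; the
#'   per-rep scores are attached as the `scores` attribute.
#' @export
subsampled_ragi <- function(mat, embeddings_list, signatures, n_sub = 1000L,
                            reps = 20L, methods = c("hc", "kmeans", "louvain"),
                            k = NULL, seed = 42L) {
  stopifnot(inherits(mat, "acc_matrix"), length(embeddings_list) > 0,
            !is.null(names(embeddings_list)))
  n <- length(mat$barcodes)
  if (n_sub > n) stop_fmt("n_sub = %d exceeds n_cells = %d", n_sub, n)
  out <- list(); scores <- list()
  for (r in seq_len(reps)) {
    take <- sort(with_seed(derive_seed(seed, r), sample.int(n, n_sub)))
    sub_mat <- acc_matrix(mat$counts[take, , drop = FALSE],
                          mat$barcodes[take], mat$regions)
    for (src in names(embeddings_list)) {
      emb <- embeddings_list[[src]]
      idx <- match(mat$barcodes[take], emb$barcodes)
      if (anyNA(idx)) stop_fmt("embedding source '%s' missing barcodes", src)
      sub_emb <- structure(list(barcodes = emb$barcodes[idx],
                                vectors = emb$vectors[idx, , drop = FALSE],
                                coverage = emb$coverage[idx]),
                           class = "cell_embeddings")
      for (m in methods) {
        asg <- cluster_cells(sub_emb, method = m, k = k,
                             seed = derive_seed(seed, r, match(m, methods)))
        sc <- ragi(sub_mat, asg, signatures)$ragi
        scores[[length(scores) + 1L]] <-
          data.frame(source = src, method = m, rep = r, ragi = sc)
      }
    }
  }
  scores <- do.call(rbind, scores)
  agg <- stats::aggregate(ragi ~ source + method, scores,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(source = agg$source, method = agg$method,
                    mean_ragi = agg$ragi[, "mean"], sd_ragi = agg$ragi[, "sd"],
                    reps = reps)
  attr(out, "scores") <- scores
  out
}
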