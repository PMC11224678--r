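# Independent brute-force oracles used by the dual-route checks. These stay
# deliberately naive (loops, direct formulas) and never call package code
# paths they verify.

# All set partitions of n elements as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, max_used) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (lab in 0:(max_used + 1L))
      grow(c(labels, lab), max(max_used, lab))
  }
  grow(integer(0), -1L)
  out
}

# Loop-built contingency table.
oracle_contingency <- function(a, b) {
  ua <- unique(a); ub <- unique(b)
  ct <- matrix(0L, length(ua), length(ub))
  for (i in seq_along(a))
    ct[match(a[i], ua), match(b[i], ub)] <- ct[match(a[i], ua), match(b[i], ub)] + 1L
  ct
}

oracle_ari <- function(a, b) {
  ct <- oracle_contingency(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) sij <- sij + comb2(ct[i, j])
  sa <- sum(comb2(rowSums(ct))); sb <- sum(comb2(colSums(ct)))
  expected <- sa * sb / comb2(n)
  maxi <- (sa + sb) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

oracle_entropy <- function(labels) {
  p <- as.numeric(table(labels)) / length(labels)
  -sum(ifelse(p > 0, p * log(p), 0))
}

oracle_mi <- function(a, b) {
  ct <- oracle_contingency(a, b); n <- length(a)
  mi <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    nij <- ct[i, j]
    if (nij > 0)
      mi <- mi + (nij / n) * log(n * nij / (sum(ct[i, ]) * sum(ct[, j])))
  }
  mi
}

# Expected MI by direct summation over the hypergeometric model, written
# with plain factorials (n <= 6 keeps everything exact in doubles).
oracle_emi <- function(a, b) {
  ct <- oracle_contingency(a, b); n <- length(a)
  ai <- rowSums(ct); bj <- colSums(ct)
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(1, ai[i] + bj[j] - n); hi <- min(ai[i], bj[j])
    if (lo > hi) next
    for (nij in lo:hi) {
      p <- factorial(ai[i]) * factorial(bj[j]) * factorial(n - ai[i]) *
        factorial(n - bj[j]) / (factorial(n) * factorial(nij) *
        factorial(ai[i] - nij) * factorial(bj[j] - nij) *
        factorial(n - ai[i] - bj[j] + nij))
      emi <- emi + p * (nij / n) * log(n * nij / (ai[i] * bj[j]))
    }
  }
  emi
}

oracle_ami <- function(a, b) {
  ha <- oracle_entropy(a); hb <- oracle_entropy(b)
  if (length(unique(a)) == 1L && length(unique(b)) == 1L) return(1)
  # all-singletons vs all-singletons: 0/0 by construction, defined as 1
  if (length(unique(a)) == length(a) && length(unique(b)) == length(b)) return(1)
  emi <- oracle_emi(a, b)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < .Machine$double.eps) denom <- .Machine$double.eps
  (oracle_mi(a, b) - emi) / denom
}

oracle_homogeneity <- function(a, b) {
  ha <- oracle_entropy(a)
  if (ha == 0) return(1)
  n <- length(a)
  hab <- 0
  for (bl in unique(b)) {
    sel <- b == bl
    hab <- hab + sum(sel) / n * oracle_entropy(a[sel])
  }
  1 - hab / ha
}

oracle_gini <- function(x) {
  s <- 0
  for (i in seq_along(x)) for (j in seq_along(x)) s <- s + abs(x[i] - x[j])
  s / (2 * length(x) * sum(x))
}

# All-pairs interval overlap (O(n*m)).
oracle_overlap_links <- function(query, reference) {
  lapply(seq_len(nrow(query)), function(q) {
    hits <- integer(0)
    for (r in seq_len(nrow(reference))) {
      if (query$chrom[q] == reference$chrom[r] &&
          min(query$end[q], reference$end[r]) -
          max(query$start[q], reference$start[r]) > 0)
        hits <- c(hits, r)
    }
    hits
  })
}

# Central-difference numerical gradient of sgns_loss.
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    up <- x; up[i] <- up[i] + eps
    dn <- x; dn[i] <- dn[i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}
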