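#' Specification of a synthetic accessibility dataset
#'
#' Describes a binary cells x regions matrix with planted cell-type
#' structure: each of `n_types` cell types owns a disjoint block of
#' `signature_size` signature regions that its cells open with probability
#' `p_high`; one shared block of `housekeeping_size` regions is open with
#' probability `p_house` uniformly across types; every remaining background
#' region is open with probability `p_low`. Regions are laid out as
#' non-overlapping fixed-width intervals on synthetic chromosomes.
#'
#' @param n_types number of planted cell types C.
#' @param cells_per_type cells per type.
#' @param n_regions total number of regions R.
#' @param signature_size signature regions per type.
#' @param housekeeping_size shared uniformly-accessible regions.
#' @param p_high accessibility probability of a cell's own signature block.
#' @param p_low background accessibility probability.
#' @param p_house housekeeping accessibility probability (same for all
#'   types).
#' @param region_width,region_gap interval layout in bp (defaults 500 and
#'   1000).
#' @param seed integer seed; generation is deterministic under it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_types = 5L, cells_per_type = 100L,
                           n_regions = 2000L, signature_size = 50L,
                           housekeeping_size = 50L, p_high = 0.3,
                           p_low = 0.01, p_house = 0.8,
                           region_width = 500L, region_gap = 1000L,
                           seed = 42L) {
  spec <- list(n_types = as.integer(n_types),
               cells_per_type = as.integer(cells_per_type),
               n_regions = as.integer(n_regions),
               signature_size = as.integer(signature_size),
               housekeeping_size = as.integer(housekeeping_size),
               p_high = p_high, p_low = p_low, p_house = p_house,
               region_width = as.integer(region_width),
               region_gap = as.integer(region_gap),
               seed = as.integer(seed))
  if (spec$n_types * spec$signature_size + spec$housekeeping_size > spec$n_regions)
    stop_fmt("signature blocks (%d) + housekeeping (%d) exceed n_regions (%d)",
             spec$n_types * spec$signature_size, spec$housekeeping_size,
             spec$n_regions)
  if (!(spec$p_low >= 0 && spec$p_low < spec$p_high && spec$p_high <= 1))
    stop_fmt("need 0 <= p_low < p_high <= 1")
  if (spec$p_house < 0 || spec$p_house > 1) stop_fmt("p_house out of [0, 1]")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic accessibility dataset
#'
#' Samples entry (cell, region) ~ Bernoulli(p) with p set by block
#' membership (see [synthetic_spec()]). Signature blocks occupy the first
#' `C * signature_size` region columns (type t owns block t), followed by
#' the housekeeping block, then background. Each type's cells sit on their
#' own synthetic chromosome-free layout: regions are placed consecutively
#' on chromosomes `chrS1, chrS2, ...` with at most 2000 regions each.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (an [acc_matrix()]), `labels` (named
#'   character, barcode -> type), `signatures` (a [signature_sets()]:
#'   marker set per type plus the housekeeping set) and `regions`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  C <- spec$n_types; R <- spec$n_regions
  n <- C * spec$cells_per_type
  per_chrom <- 2000L
  chrom_idx <- ((seq_len(R) - 1L) %/% per_chrom) + 1L
  within <- (seq_len(R) - 1L) %% per_chrom
  step <- spec$region_width + spec$region_gap
  regions <- genomic_regions(sprintf("chrS%d", chrom_idx),
                             within * step,
                             within * step + spec$region_width)
  type <- rep(seq_len(C), each = spec$cells_per_type)
  barcodes <- sprintf("cell_%04d", seq_len(n))
  labels <- stats::setNames(sprintf("type%d", type), barcodes)

  # per-column probability, per type
  sig_cols <- lapply(seq_len(C), function(t)
    ((t - 1L) * spec$signature_size + 1L):(t * spec$signature_size))
  house_cols <- (C * spec$signature_size + 1L):(C * spec$signature_size +
                                                  spec$housekeeping_size)
  prob <- matrix(spec$p_low, C, R)
  prob[, house_cols] <- spec$p_house
  for (t in seq_len(C)) prob[t, sig_cols[[t]]] <- spec$p_high

  entries <- with_seed(spec$seed, {
    ij <- lapply(seq_len(n), function(cell) {
      open <- which(stats::runif(R) < prob[type[cell], ])
      if (length(open)) cbind(cell, open) else NULL
    })
    do.call(rbind, ij)
  })
  m <- if (is.null(entries))
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, R))
  else
    Matrix::sparseMatrix(i = entries[, 1], j = entries[, 2], x = 1,
                         dims = c(n, R))
  sigs <- signature_sets(
    marker_sets = stats::setNames(sig_cols, sprintf("marker_type%d", seq_len(C))),
    housekeeping_sets = list(housekeeping = house_cols))
  list(matrix = acc_matrix(m, barcodes, regions), labels = labels,
       signatures = sigs, regions = regions)
}

#' Drop non-zero entries to simulate data loss
#'
#' Removes exactly `round(rate * nnz)` non-zero entries, chosen uniformly
#' without replacement, and sets them to zero; zeros are never touched, so
#' nnz after corruption is deterministic. This mirrors dropout experiments
#' that delete non-zero accessibility values until a target fraction of the
#' data is lost (e.g. ~80% loss takes a 2.8%-dense matrix to 0.56%).
#'
#' @param mat an [acc_matrix()].
#' @param rate fraction of non-zeros to remove, in `[0, 1)`.
#' @param seed integer seed.
#' @return a corrupted [acc_matrix()].
#' @export
apply_dropout <- function(mat, rate, seed = 42L) {
  stopifnot(inherits(mat, "acc_matrix"), rate >= 0, rate < 1)
  m <- mat$counts
  nnz <- length(m@x)
  n_drop <- round(rate * nnz)
  if (n_drop > 0) {
    drop_idx <- with_seed(seed, sample.int(nnz, n_drop))
    m@x[drop_idx] <- 0
    m <- Matrix::drop0(m)
  }
  acc_matrix(m, mat$barcodes, mat$regions)
}

#' Jitter regions by random coordinate shifts
#'
#' Shifts each region by an integer drawn uniformly from
#' `[-max_shift, +max_shift]`, preserving widths. Requires the input
#' regions to be non-overlapping with inter-region gaps of at least
#' `2 * max_shift` (per chromosome), so a jittered region can only overlap
#' its own origin — the controlled test bed for overlap-based projection.
#'
#' @param regions regions `data.frame`, per-chromosome non-overlapping.
#' @param max_shift maximum absolute shift in bp.
#' @param min_gap required gap between consecutive regions (default
#'   `2 * max_shift`).
#' @param seed integer seed.
#' @return jittered regions `data.frame` in the same order.
#' @export
jitter_regions <- function(regions, max_shift, min_gap = 2L * max_shift,
                           seed = 42L) {
  validate_regions(regions)
  stopifnot(max_shift >= 0, min_gap >= 2L * max_shift)
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1L) {
      gaps <- r$start[-1L] - r$end[-nrow(r)]
      if (any(gaps < min_gap))
        stop_fmt("regions on %s closer than min_gap = %d bp (min gap found: %d)",
                 ch, min_gap, min(gaps))
    }
  }
  shift <- with_seed(seed,
                     sample.int(2L * max_shift + 1L, nrow(regions),
                                replace = TRUE) - max_shift - 1L)
  out <- regions
  out$start <- regions$start + shift
  out$end <- regions$end + shift
  if (any(out$start < 0)) {
    # clip at the chromosome origin by shifting right instead
    neg <- out$start < 0
    out$start[neg] <- regions$start[neg] - shift[neg]
    out$end[neg] <- regions$end[neg] - shift[neg]
  }
  validate_regions(out)
  out
}
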