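# Small fixtures built in code at test time.

tiny_regions <- function(n, chrom = "chr1", width = 500L, gap = 1000L) {
  genomic_regions(rep(chrom, n),
                  (seq_len(n) - 1L) * (width + gap),
                  (seq_len(n) - 1L) * (width + gap) + width)
}

tiny_matrix <- function(m, barcodes = sprintf("bc%d", seq_len(nrow(m))),
                        regions = tiny_regions(ncol(m))) {
  acc_matrix(Matrix::Matrix(m, sparse = TRUE), barcodes, regions)
}

# A hand-sized model with fixed 2-d vectors for pooling oracles.
tiny_model <- function(words, vecs) {
  region_model(vocab = words, input_vectors = vecs,
               context_vectors = vecs * 0, metadata = list(dimension = ncol(vecs)))
}

write_mtx_fixture <- function(dir, header_rows, header_cols, entries,
                              barcodes, regions) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("%%MatrixMarket matrix coordinate real general",
             sprintf("%d %d %d", header_rows, header_cols, nrow(entries)),
             sprintf("%d %d %g", entries[, 1], entries[, 2], entries[, 3]))
  writeLines(lines, file.path(dir, "m.mtx"))
  writeLines(barcodes, file.path(dir, "b.tsv"))
  write_bed(regions, file.path(dir, "r.bed"))
  list(mtx = file.path(dir, "m.mtx"), barcodes = file.path(dir, "b.tsv"),
       regions = file.path(dir, "r.bed"))
}

# The standard small synthetic world used across module tests (fast).
small_sim <- function(seed = 5L) {
  generate_synthetic(synthetic_spec(n_types = 2L, cells_per_type = 50L,
                                    n_regions = 200L, signature_size = 20L,
                                    housekeeping_size = 10L, p_high = 0.5,
                                    p_low = 0.02, p_house = 0.8, seed = seed))
}
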