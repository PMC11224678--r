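#' Accessibility matrix container
#'
#' A sparse cells x regions matrix of non-negative counts with cell barcodes
#' on rows and genomic regions on columns. Values greater than one are kept
#' as-is; binarization (signal defined as anything greater than zero) happens
#' only when documents are built for training.
#'
#' @param counts a sparse or dense numeric matrix, cells x regions.
#' @param barcodes character vector of unique cell identifiers (row axis).
#' @param regions regions `data.frame` (column axis), see [genomic_regions()].
#' @return an object of class `acc_matrix` with fields `counts` (a
#'   `dgCMatrix`), `barcodes` and `regions`.
#' @export
acc_matrix <- function(counts, barcodes, regions) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  barcodes <- as.character(barcodes)
  validate_regions(regions)
  if (nrow(counts) != length(barcodes))
    stop_fmt("barcode count (%d) does not match matrix rows (%d)",
             length(barcodes), nrow(counts))
  if (ncol(counts) != nrow(regions))
    stop_fmt("region count (%d) does not match matrix columns (%d)",
             nrow(regions), ncol(counts))
  if (anyDuplicated(barcodes)) stop_fmt("barcodes are not unique")
  if (length(counts@x) && min(counts@x) < 0) stop_fmt("negative entries not allowed")
  structure(list(counts = counts, barcodes = barcodes, regions = regions),
            class = "acc_matrix")
}

#' @export
print.acc_matrix <- function(x, ...) {
  cat(sprintf("<acc_matrix> %d cells x %d regions, nnz = %d (density %.3g%%)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.acc_matrix <- function(x) dim(x$counts)

#' Read an accessibility matrix from MatrixMarket + sidecars
#'
#' Reads a MatrixMarket coordinate file together with a one-barcode-per-line
#' TSV and a BED file of regions. The canonical orientation is cells x
#' regions; when the MTX header dimensions instead match (regions, cells) the
#' matrix is transposed automatically and a notice is logged (10X-style
#' exports are commonly regions x cells). Storage stays sparse throughout.
#'
#' @param matrix_path MatrixMarket coordinate file (1-based indices).
#' @param barcodes_path one cell identifier per line.
#' @param regions_path BED3+ file of column regions.
#' @return an [acc_matrix()].
#' @export
read_mtx <- function(matrix_path, barcodes_path, regions_path) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- data.table::fread(barcodes_path, header = FALSE, sep = "\t",
                                colClasses = "character")[[1]]
  regions <- read_bed(regions_path)
  nb <- length(barcodes); nr <- nrow(regions)
  if (nrow(m) == nb && ncol(m) == nr) {
    # canonical orientation
  } else if (nrow(m) == nr && ncol(m) == nb) {
    log_notice(sprintf("MTX is regions x cells (%d x %d); transposing to cells x regions",
                       nrow(m), ncol(m)))
    m <- Matrix::t(m)
  } else {
    stop_fmt(paste0("MTX dimensions %d x %d match neither cells x regions ",
                    "(%d x %d) nor regions x cells: check sidecar files"),
             nrow(m), ncol(m), nb, nr)
  }
  acc_matrix(m, barcodes, regions)
}

#' Write an accessibility matrix as MTX + sidecars
#'
#' Inverse of [read_mtx()]: writes `matrix.mtx`, `barcodes.tsv` and
#' `regions.bed` into `dir` in the canonical cells x regions orientation.
#'
#' @param mat an [acc_matrix()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named file paths.
#' @export
write_mtx <- function(mat, dir) {
  stopifnot(inherits(mat, "acc_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             barcodes = file.path(dir, "barcodes.tsv"),
             regions = file.path(dir, "regions.bed"))
  Matrix::writeMM(mat$counts, paths[["matrix"]])
  writeLines(mat$barcodes, paths[["barcodes"]])
  write_bed(mat$regions, paths[["regions"]])
  invisible(paths)
}
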