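#' Build region-word documents from an accessibility matrix
#'
#' Each cell becomes a document whose words are the tokens of the regions
#' where the cell shows signal, signal being defined as any value greater
#' than zero. Duplicate words cannot arise (one matrix column per region);
#' values above one carry no extra weight. Empty rows yield empty documents
#' (kept so document order stays aligned with matrix rows) and a warning
#' naming the barcode.
#'
#' @param mat an [acc_matrix()].
#' @return an object of class `region_corpus`: a list with `documents` (list
#'   of character vectors, one per cell, in matrix row order), `barcodes`,
#'   and `vocabulary_counts` (named integer, word -> number of documents
#'   containing it).
#' @export
build_documents <- function(mat) {
  stopifnot(inherits(mat, "acc_matrix"))
  words <- region_to_word(mat$regions)
  # column-compressed over cells: t() gives per-cell index runs
  tm <- Matrix::t(mat$counts)
  p <- tm@p; i <- tm@i; x <- tm@x
  docs <- vector("list", length(mat$barcodes))
  for (c_idx in seq_along(docs)) {
    if (p[c_idx + 1L] > p[c_idx]) {
      idx <- (p[c_idx] + 1L):p[c_idx + 1L]
      keep <- idx[x[idx] > 0]
      docs[[c_idx]] <- words[i[keep] + 1L]
    } else {
      docs[[c_idx]] <- character(0)
    }
  }
  empty <- lengths(docs) == 0L
  if (any(empty))
    warning(sprintf("%d cell(s) with no accessible regions: %s",
                    sum(empty),
                    paste(utils::head(mat$barcodes[empty], 5), collapse = ", ")),
            call. = FALSE)
  new_corpus(docs, mat$barcodes)
}

new_corpus <- function(documents, barcodes) {
  counts <- table(unlist(documents, use.names = FALSE))
  vc <- stats::setNames(as.integer(counts), names(counts))
  structure(list(documents = documents, barcodes = barcodes,
                 vocabulary_counts = vc),
            class = "region_corpus")
}

#' @export
print.region_corpus <- function(x, ...) {
  cat(sprintf("<region_corpus> %d documents, %d distinct words, %d tokens\n",
              length(x$documents), length(x$vocabulary_counts),
              sum(lengths(x$documents))))
  invisible(x)
}

#' Shuffle the words of one document
#'
#' Accessible regions have no inherent order, so skip-gram context is
#' simulated by randomly permuting each document. The permutation is uniform
#' and deterministic under the supplied seed; the input is not modified.
#'
#' @param words character vector (one document's words).
#' @param seed integer seed for the permutation.
#' @return the same multiset of words in permuted order.
#' @export
shuffle_document <- function(words, seed) {
  n <- length(words)
  if (n <= 1L) return(words)
  with_seed(seed, words[sample.int(n)])
}

#' Export a corpus as plain text
#'
#' One document per line, words separated by single spaces; the format
#' accepted by common word-embedding trainers.
#'
#' @param corpus a `region_corpus`.
#' @param path output file.
#' @export
export_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "region_corpus"))
  writeLines(vapply(corpus$documents, paste, "", collapse = " "), path)
  invisible(path)
}
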