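#' Pool region embeddings into a cell embedding
#'
#' A cell's embedding is the unweighted arithmetic mean of the input vectors
#' of its accessible regions. Words absent from the model vocabulary are
#' skipped and counted in an out-of-vocabulary tally; a cell with no
#' in-vocabulary words gets an all-`NaN` vector with coverage 0 and is
#' excluded from clustering downstream.
#'
#' @param words character vector: one cell's region words.
#' @param model a `region_model`.
#' @return list with `vector` (length d) and `coverage` (number of words
#'   that contributed).
#' @export
embed_cell <- function(words, model) {
  stopifnot(inherits(model, "region_model"))
  hit <- words[words %in% model$vocab]
  d <- ncol(model$input_vectors)
  if (length(hit) == 0L) {
    warning("cell has no in-vocabulary regions; returning NaN embedding",
            call. = FALSE)
    return(list(vector = rep(NaN, d), coverage = 0L))
  }
  if (length(hit) < length(words))
    log_notice(sprintf("%d out-of-vocabulary word(s) skipped",
                       length(words) - length(hit)))
  V <- model$input_vectors[hit, , drop = FALSE]
  list(vector = colSums(V) / nrow(V), coverage = length(hit))
}

#' Embed every cell of a matrix or corpus
#'
#' Row i of the result is the pooled embedding of cell i's accessible
#' regions. Because pooling is a mean over an unordered set, the result is
#' invariant to any permutation of a cell's words (and hence to document
#' shuffling).
#'
#' @param x an [acc_matrix()] or a `region_corpus`.
#' @param model a `region_model`.
#' @return a `cell_embeddings` object: list with `barcodes`, `vectors`
#'   (n_cells x d, `NaN` rows for uncovered cells) and `coverage`.
#' @export
embed_all <- function(x, model) {
  corpus <- if (inherits(x, "acc_matrix")) build_documents(x) else x
  stopifnot(inherits(corpus, "region_corpus"), inherits(model, "region_model"))
  d <- ncol(model$input_vectors)
  n <- length(corpus$documents)
  vecs <- matrix(NaN, n, d)
  coverage <- integer(n)
  oov <- 0L
  idx <- stats::setNames(seq_along(model$vocab), model$vocab)
  for (i in seq_len(n)) {
    words <- corpus$documents[[i]]
    j <- idx[words]
    j <- j[!is.na(j)]
    oov <- oov + (length(words) - length(j))
    coverage[i] <- length(j)
    if (length(j)) {
      V <- model$input_vectors[j, , drop = FALSE]
      vecs[i, ] <- colSums(V) / nrow(V)
    }
  }
  if (oov > 0)
    log_notice(sprintf("%d out-of-vocabulary word occurrence(s) skipped", oov))
  if (any(coverage == 0L))
    warning(sprintf("%d cell(s) have no in-vocabulary regions (NaN embedding): %s",
                    sum(coverage == 0L),
                    paste(utils::head(corpus$barcodes[coverage == 0L], 5),
                          collapse = ", ")), call. = FALSE)
  structure(list(barcodes = corpus$barcodes, vectors = vecs,
                 coverage = coverage),
            class = "cell_embeddings")
}

#' @export
print.cell_embeddings <- function(x, ...) {
  cat(sprintf("<cell_embeddings> %d cells x %d dims, %d uncovered\n",
              nrow(x$vectors), ncol(x$vectors), sum(x$coverage == 0L)))
  invisible(x)
}

#' Write / read cell embeddings as TSV
#'
#' One line per cell: barcode followed by d floats (17 significant digits,
#' exact round trip).
#'
#' @param emb a `cell_embeddings` object.
#' @param path output file.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "cell_embeddings"))
  body <- matrix(format_full(emb$vectors), nrow = nrow(emb$vectors))
  data.table::fwrite(data.table::data.table(barcode = emb$barcodes,
                                            as.data.frame(body)),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  vecs <- as.matrix(dt[, -1, with = FALSE])
  dimnames(vecs) <- NULL
  # true per-region coverage is not stored in the TSV; keep only the
  # covered / uncovered distinction
  coverage <- ifelse(rowSums(is.finite(vecs)) > 0, NA_integer_, 0L)
  structure(list(barcodes = dt[[1]], vectors = vecs, coverage = coverage),
            class = "cell_embeddings")
}
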