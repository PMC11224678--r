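#' Region embedding model bundle
#'
#' The pre-trainable artifact: a vocabulary of region words, the paired
#' input/context vector tables of the skip-gram model, the consensus region
#' set the vocabulary was built from, and training metadata. Cell embeddings
#' and projection of unseen datasets both consume this object.
#'
#' @param vocab character vector of region words, in index order.
#' @param input_vectors |V| x d numeric matrix (the embeddings used
#'   downstream), rownames = vocab.
#' @param context_vectors |V| x d numeric matrix, same shape.
#' @param consensus regions `data.frame` parallel to `vocab` (parsed back
#'   from the words if omitted).
#' @param metadata named list; must contain `dimension`.
#' @return an object of class `region_model`.
#' @export
region_model <- function(vocab, input_vectors, context_vectors,
                         consensus = NULL, metadata = list()) {
  vocab <- as.character(vocab)
  input_vectors <- as.matrix(input_vectors)
  context_vectors <- as.matrix(context_vectors)
  if (!identical(dim(input_vectors), dim(context_vectors)))
    stop_fmt("input and context vector tables differ in shape")
  if (nrow(input_vectors) != length(vocab))
    stop_fmt("vocabulary size (%d) does not match vector rows (%d)",
             length(vocab), nrow(input_vectors))
  if (is.null(consensus)) consensus <- word_to_region(vocab) else validate_regions(consensus)
  d <- ncol(input_vectors)
  if (is.null(metadata$dimension)) metadata$dimension <- d
  if (metadata$dimension != d)
    stop_fmt("metadata dimension (%s) does not match vector width (%d)",
             metadata$dimension, d)
  rownames(input_vectors) <- rownames(context_vectors) <- vocab
  structure(list(vocab = vocab, input_vectors = input_vectors,
                 context_vectors = context_vectors, consensus = consensus,
                 metadata = metadata),
            class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("<region_model> %d region words, dimension %d\n",
              length(x$vocab), ncol(x$input_vectors)))
  if (!is.null(x$metadata$epochs))
    cat(sprintf("  trained %s epochs, window %s, decay %s, seed %s\n",
                x$metadata$epochs, x$metadata$window, x$metadata$decay,
                x$metadata$seed))
  invisible(x)
}

# 17 significant digits round-trips an IEEE double exactly through text
format_full <- function(x) sprintf("%.17g", x)

write_vector_table <- function(words, mat, path) {
  body <- matrix(format_full(mat), nrow = nrow(mat))
  data.table::fwrite(data.table::data.table(word = words,
                                            as.data.frame(body)),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
}

read_vector_table <- function(path, d, what) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) - 1L != d)
    stop_fmt("%s: row width %d does not match dimension %d", what, ncol(dt) - 1L, d)
  words <- dt[[1]]
  mat <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(mat)) stop_fmt("%s: non-numeric vector entries", what)
  dimnames(mat) <- list(words, NULL)
  mat
}

#' Save / load a region model directory
#'
#' On-disk layout is a directory of plain text files: `vectors.tsv` (word
#' then d floats per line), `context_vectors.tsv`, `consensus.bed` and
#' `metadata.txt` (`key=value` lines). Floats are written with 17
#' significant digits so `load_model(save_model(m))` reproduces the vectors
#' exactly.
#'
#' @param model a `region_model`.
#' @param dir directory to write (created if absent).
#' @return `save_model`: invisibly, `dir`. `load_model`: a `region_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "region_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vector_table(model$vocab, model$input_vectors,
                     file.path(dir, "vectors.tsv"))
  write_vector_table(model$vocab, model$context_vectors,
                     file.path(dir, "context_vectors.tsv"))
  write_bed(model$consensus, file.path(dir, "consensus.bed"))
  md <- model$metadata
  writeLines(sprintf("%s=%s", names(md),
                     vapply(md, function(v)
                       if (is.numeric(v)) format_full(v) else as.character(v), "")),
             file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @param dir model directory written by `save_model`.
#' @export
load_model <- function(dir) {
  mpath <- file.path(dir, "metadata.txt")
  if (!file.exists(mpath)) stop_fmt("not a model directory (no metadata.txt): %s", dir)
  kv <- strsplit(readLines(mpath), "=", fixed = TRUE)
  metadata <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(metadata) <- vapply(kv, `[`, "", 1L)
  d <- as.integer(metadata$dimension)
  iv <- read_vector_table(file.path(dir, "vectors.tsv"), d, "vectors.tsv")
  cv <- read_vector_table(file.path(dir, "context_vectors.tsv"), d, "context_vectors.tsv")
  if (!identical(rownames(iv), rownames(cv)))
    stop_fmt("vectors.tsv and context_vectors.tsv disagree on vocabulary")
  word_to_region(rownames(iv))  # validate: every word must parse to a region
  bed <- file.path(dir, "consensus.bed")
  consensus <- if (file.exists(bed)) read_bed(bed) else word_to_region(rownames(iv))
  region_model(vocab = rownames(iv), input_vectors = iv, context_vectors = cv,
               consensus = consensus, metadata = metadata)
}
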