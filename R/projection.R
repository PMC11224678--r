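#' Map query regions onto a reference consensus by interval overlap
#'
#' Links every query region to every reference region on the same chromosome
#' with at least `min_overlap` bp of overlap (half-open coordinates:
#' `overlap = min(ends) - max(starts)`, abutting intervals do not overlap).
#' This is the bridge that casts a new dataset into the feature space of a
#' pre-trained model. By default a query keeps *all* overlapping reference
#' links (many-to-many); `mode = "best"` keeps only the reference with the
#' largest overlap (ties broken by lower reference index).
#'
#' @param query,reference regions `data.frame`s, 0-based half-open.
#' @param mode `"all"` (default) or `"best"`.
#' @param min_overlap minimum overlap in bp (default 1).
#' @param min_overlap_frac additionally require overlap >= this fraction of
#'   the query width (default 0).
#' @return an `overlap_map`: list with `query_regions`, `links` (per query,
#'   integer indices into `reference`) and `stats`
#'   (`n_query`, `n_mapped`, `mean_links_per_mapped`).
#' @export
build_overlap_map <- function(query, reference, mode = c("all", "best"),
                              min_overlap = 1L, min_overlap_frac = 0) {
  mode <- match.arg(mode)
  validate_regions(query, "query"); validate_regions(reference, "reference")
  links <- rep(list(integer(0)), nrow(query))
  if (nrow(query) > 0 && nrow(reference) > 0 &&
      length(intersect(unique(query$chrom), unique(reference$chrom))) == 0L) {
    warning("query and reference share no chromosomes; no regions mapped",
            call. = FALSE)
  } else if (nrow(query) > 0 && nrow(reference) > 0) {
    qg <- GenomicRanges::GRanges(query$chrom,
                                 IRanges::IRanges(query$start + 1L, query$end))
    rg <- GenomicRanges::GRanges(reference$chrom,
                                 IRanges::IRanges(reference$start + 1L, reference$end))
    hits <- GenomicRanges::findOverlaps(qg, rg, minoverlap = as.integer(min_overlap))
    qh <- S4Vectors::queryHits(hits); rh <- S4Vectors::subjectHits(hits)
    ov <- pmin(query$end[qh], reference$end[rh]) -
      pmax(query$start[qh], reference$start[rh])
    if (min_overlap_frac > 0) {
      keep <- ov >= min_overlap_frac * (query$end[qh] - query$start[qh])
      qh <- qh[keep]; rh <- rh[keep]; ov <- ov[keep]
    }
    if (length(qh)) {
      if (mode == "best") {
        o <- order(qh, -ov, rh)
        qh <- qh[o]; rh <- rh[o]
        first <- !duplicated(qh)
        qh <- qh[first]; rh <- rh[first]
      }
      sp <- split(rh, qh)
      links[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
    }
  }
  n_mapped <- sum(lengths(links) > 0L)
  structure(list(query_regions = query, links = links,
                 stats = list(n_query = nrow(query), n_mapped = n_mapped,
                              mean_links_per_mapped =
                                if (n_mapped) sum(lengths(links)) / n_mapped else NA_real_)),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("<overlap_map> %d query regions, %d mapped (mean %.2f links/mapped)\n",
              x$stats$n_query, x$stats$n_mapped,
              x$stats$mean_links_per_mapped %||% NA_real_))
  invisible(x)
}

#' Translate query documents into the reference vocabulary
#'
#' Each query cell's document becomes the deduplicated union (in first-
#' encounter order, following the query's column order) of the reference
#' words linked from its accessible query regions. Cells whose regions all
#' map nowhere get empty documents and surface as `NaN` embeddings
#' downstream. The per-cell fraction of accessible regions that mapped is
#' recorded in the `mapped_fraction` attribute.
#'
#' @param query_matrix an [acc_matrix()] over the query region set.
#' @param map an `overlap_map` built from the query regions against the
#'   model consensus.
#' @param ref_words reference vocabulary words, parallel to the reference
#'   side of `map`.
#' @return a `region_corpus` in the reference vocabulary.
#' @export
translate_documents <- function(query_matrix, map, ref_words) {
  stopifnot(inherits(query_matrix, "acc_matrix"), inherits(map, "overlap_map"))
  if (nrow(map$query_regions) != ncol(query_matrix$counts))
    stop_fmt("overlap map covers %d regions but matrix has %d columns",
             nrow(map$query_regions), ncol(query_matrix$counts))
  tm <- Matrix::t(query_matrix$counts)
  p <- tm@p; i <- tm@i; x <- tm@x
  n <- length(query_matrix$barcodes)
  docs <- vector("list", n)
  mapped_frac <- rep(NA_real_, n)
  for (c_idx in seq_len(n)) {
    if (p[c_idx + 1L] > p[c_idx]) {
      idx <- (p[c_idx] + 1L):p[c_idx + 1L]
      qreg <- i[idx[x[idx] > 0]] + 1L
      ref_idx <- unique(unlist(map$links[qreg], use.names = FALSE))
      docs[[c_idx]] <- if (length(ref_idx)) ref_words[ref_idx] else character(0)
      mapped_frac[c_idx] <- mean(lengths(map$links[qreg]) > 0L)
    } else {
      docs[[c_idx]] <- character(0)
    }
  }
  out <- suppressWarnings(new_corpus(docs, query_matrix$barcodes))
  attr(out, "mapped_fraction") <- mapped_frac
  out
}

#' E-projection: embed unseen cells through a pre-trained model
#'
#' Maps the query region set onto the model's consensus by overlap, rewrites
#' each cell's document in the reference vocabulary, and pools the reference
#' input vectors by averaging. When the query regions equal the consensus
#' exactly, the result is bit-identical to [embed_all()] on the same matrix
#' (projection identity).
#'
#' @param query_matrix an [acc_matrix()].
#' @param model a `region_model`.
#' @param ... passed to [build_overlap_map()] (`mode`, `min_overlap`, ...).
#' @return a `cell_embeddings` object with the overlap map's statistics in
#'   the `projection_stats` attribute.
#' @export
e_project <- function(query_matrix, model, ...) {
  stopifnot(inherits(model, "region_model"))
  consensus <- word_to_region(model$vocab)  # index-aligned with the vectors
  map <- build_overlap_map(query_matrix$regions, consensus, ...)
  corpus <- translate_documents(query_matrix, map, model$vocab)
  if (sum(lengths(corpus$documents)) == 0L)
    stop_fmt(paste0("no query cell mapped to the reference consensus; ",
                    "check that query and model use the same genome assembly"))
  emb <- suppressWarnings(embed_all(corpus, model))
  if (any(emb$coverage == 0L))
    warning(sprintf("%d query cell(s) mapped to no reference region",
                    sum(emb$coverage == 0L)), call. = FALSE)
  attr(emb, "projection_stats") <- map$stats
  attr(emb, "mapped_fraction") <- attr(corpus, "mapped_fraction")
  emb
}

#' Fit a 2D reducer on reference cell embeddings
#'
#' Fits a two-dimensional manifold projection (UMAP; `method = "pca"` offers
#' a cheap linear alternative) on the non-`NaN` reference embeddings and
#' stores both the fitted model and the reference 2D coordinates, so that
#' unseen cells can later be pushed through the *same* fitted model
#' ([ev_project()]) and plotted over the reference topology. The UMAP
#' backend runs single-threaded with a fixed random state and is
#' reproducible under `seed`.
#'
#' @param emb reference `cell_embeddings`.
#' @param seed integer seed for the reducer fit.
#' @param method `"umap"` (default) or `"pca"`.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15, 0.1,
#'   Euclidean metric).
#' @param min_cells minimum number of usable cells (default 20).
#' @param model_path where to persist the fitted UMAP model (a file;
#'   defaults to a session temporary file).
#' @return a `reducer_model`: list with `method`, `ref_coords`
#'   (n x 2, `NaN` rows for uncovered cells), `barcodes`, `seed` and
#'   backend-specific fields.
#' @export
fit_reducer <- function(emb, seed = 42L, method = c("umap", "pca"),
                        n_neighbors = 15L, min_dist = 0.1,
                        min_cells = 20L, model_path = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(emb, "cell_embeddings"))
  ok <- rowSums(is.finite(emb$vectors)) == ncol(emb$vectors)
  if (sum(ok) < min_cells)
    stop_fmt("only %d usable cells; need at least %d to fit a reducer",
             sum(ok), min_cells)
  X <- emb$vectors[ok, , drop = FALSE]
  coords <- matrix(NaN, nrow(emb$vectors), 2L)
  if (method == "pca") {
    ctr <- colMeans(X)
    sv <- svd(sweep(X, 2, ctr), nu = 0, nv = 2)
    # fix sign for determinism: largest-magnitude loading positive
    for (j in 1:2) if (sv$v[which.max(abs(sv$v[, j])), j] < 0) sv$v[, j] <- -sv$v[, j]
    coords[ok, ] <- sweep(X, 2, ctr) %*% sv$v
    backend <- list(center = ctr, rotation = sv$v)
  } else {
    model_path <- model_path %||% tempfile(fileext = ".umap.pkl")
    in_tsv <- tempfile(fileext = ".tsv"); out_tsv <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(in_tsv, out_tsv)), add = TRUE)
    data.table::fwrite(as.data.frame(X), in_tsv, sep = "\t", col.names = FALSE)
    run_python_reducer("fit", in_tsv, out_tsv, model_path,
                       seed = seed, n_neighbors = n_neighbors,
                       min_dist = min_dist)
    coords[ok, ] <- as.matrix(data.table::fread(out_tsv, header = FALSE))
    backend <- list(model_path = model_path)
  }
  structure(c(list(method = method, ref_coords = coords,
                   barcodes = emb$barcodes, seed = as.integer(seed),
                   n_neighbors = as.integer(n_neighbors),
                   min_dist = min_dist), backend),
            class = "reducer_model")
}

#' EV-projection: transform query embeddings through a fitted reducer
#'
#' Pushes query cell embeddings through the reducer fitted on the reference
#' (never refit), so the resulting 2D coordinates live in the reference
#' coordinate frame and can be overlaid on the stored reference layout.
#' `NaN` query cells are dropped with a warning listing their barcodes.
#'
#' @param emb query `cell_embeddings`.
#' @param reducer a `reducer_model` from [fit_reducer()].
#' @return matrix (n_usable x 2) with barcodes as rownames.
#' @export
ev_project <- function(emb, reducer) {
  stopifnot(inherits(emb, "cell_embeddings"), inherits(reducer, "reducer_model"))
  ok <- rowSums(is.finite(emb$vectors)) == ncol(emb$vectors)
  if (!any(ok)) stop_fmt("no usable query cells to project")
  if (any(!ok))
    warning(sprintf("dropping %d NaN query cell(s): %s", sum(!ok),
                    paste(utils::head(emb$barcodes[!ok], 5), collapse = ", ")),
            call. = FALSE)
  X <- emb$vectors[ok, , drop = FALSE]
  if (reducer$method == "pca") {
    coords <- sweep(X, 2, reducer$center) %*% reducer$rotation
  } else {
    in_tsv <- tempfile(fileext = ".tsv"); out_tsv <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(in_tsv, out_tsv)), add = TRUE)
    data.table::fwrite(as.data.frame(X), in_tsv, sep = "\t", col.names = FALSE)
    run_python_reducer("transform", in_tsv, out_tsv, reducer$model_path)
    coords <- as.matrix(data.table::fread(out_tsv, header = FALSE))
  }
  dimnames(coords) <- list(emb$barcodes[ok], NULL)
  coords
}

run_python_reducer <- function(cmd, in_tsv, out_tsv, model_path,
                               seed = NULL, n_neighbors = NULL, min_dist = NULL) {
  script <- system.file("python", "umap_reducer.py", package = "chromembed")
  if (!nzchar(script)) stop_fmt("bundled umap_reducer.py not found")
  args <- c(script, cmd, "--in-tsv", in_tsv, "--out-tsv", out_tsv,
            "--model", model_path)
  if (cmd == "fit")
    args <- c(args, "--seed", seed, "--n-neighbors", n_neighbors,
              "--min-dist", min_dist)
  res <- suppressWarnings(system2("python", shQuote(as.character(args)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0)
    stop_fmt("UMAP backend failed (exit %d):\n%s", status,
             paste(utils::tail(res, 10), collapse = "\n"))
  invisible(NULL)
}
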