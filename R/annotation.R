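#' Fit a KNN cell-type annotator on reference embeddings
#'
#' Stores labeled reference cell embeddings for k-nearest-neighbor
#' classification of query cells. Cosine distance is the default: pooled
#' cell embeddings are averages of region vectors, so direction carries the
#' signal. Query data are expected to be E-projected through the same
#' region model the reference embeddings came from; classifying embeddings
#' from incompatible spaces is meaningless.
#'
#' @param emb reference `cell_embeddings` (`NaN` cells are excluded).
#' @param labels character/factor labels, parallel to `emb$barcodes`;
#'   at least 2 classes.
#' @param k_nn neighbors to vote (default 10).
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return an `annotation_model`.
#' @export
fit_annotator <- function(emb, labels, k_nn = 10L,
                          metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(emb, "cell_embeddings"))
  labels <- as.character(labels)
  if (length(labels) != length(emb$barcodes))
    stop_fmt("labels (%d) do not match cells (%d)", length(labels),
             length(emb$barcodes))
  ok <- rowSums(is.finite(emb$vectors)) == ncol(emb$vectors)
  X <- emb$vectors[ok, , drop = FALSE]; labels <- labels[ok]
  if (length(unique(labels)) < 2L) stop_fmt("need at least 2 reference classes")
  if (k_nn > nrow(X))
    stop_fmt("k_nn = %d exceeds the %d usable reference cells", k_nn, nrow(X))
  structure(list(vectors = X, labels = labels,
                 barcodes = emb$barcodes[ok],
                 k_nn = as.integer(k_nn), metric = metric),
            class = "annotation_model")
}

#' @export
print.annotation_model <- function(x, ...) {
  cat(sprintf("<annotation_model> %d reference cells, %d classes, k = %d (%s)\n",
              nrow(x$vectors), length(unique(x$labels)), x$k_nn, x$metric))
  invisible(x)
}

query_ref_dist <- function(Q, R, metric) {
  if (metric == "euclidean") {
    qn <- rowSums(Q^2); rn <- rowSums(R^2)
    D <- outer(qn, rn, "+") - 2 * Q %*% t(R)
    sqrt(pmax(D, 0))
  } else {
    qn <- sqrt(rowSums(Q^2)); rn <- sqrt(rowSums(R^2))
    qn[qn == 0] <- 1; rn[rn == 0] <- 1
    1 - (Q %*% t(R)) / outer(qn, rn)
  }
}

#' Annotate query cells by KNN vote
#'
#' Each query cell takes the majority label among its `k_nn` nearest
#' reference cells. Distance ties are broken by lower reference index; a
#' tied vote falls back to the label of the single nearest neighbor.
#' `NaN` query cells are returned unlabeled and flagged.
#'
#' @param model an `annotation_model`.
#' @param emb query `cell_embeddings` of the same dimension.
#' @return an `annotation_result` data.frame: `barcode`, `label`,
#'   `confidence` (vote fraction) and `mean_distance` (to the voting
#'   neighbors); unlabeled cells carry `NA` label and `flagged = TRUE`.
#' @export
annotate_cells <- function(model, emb) {
  stopifnot(inherits(model, "annotation_model"),
            inherits(emb, "cell_embeddings"))
  if (ncol(emb$vectors) != ncol(model$vectors))
    stop_fmt("query dimension %d does not match reference dimension %d",
             ncol(emb$vectors), ncol(model$vectors))
  n <- nrow(emb$vectors)
  res <- data.frame(barcode = emb$barcodes, label = NA_character_,
                    confidence = NA_real_, mean_distance = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  ok <- rowSums(is.finite(emb$vectors)) == ncol(emb$vectors)
  res$flagged[!ok] <- TRUE
  if (any(ok)) {
    D <- query_ref_dist(emb$vectors[ok, , drop = FALSE], model$vectors,
                        model$metric)
    k <- model$k_nn
    rows <- which(ok)
    for (qi in seq_along(rows)) {
      nb <- order(D[qi, ], seq_len(ncol(D)))[seq_len(k)]  # index breaks ties
      votes <- table(model$labels[nb])
      top <- names(votes)[votes == max(votes)]
      lab <- if (length(top) == 1L) top else model$labels[nb[1L]]
      res$label[rows[qi]] <- lab
      res$confidence[rows[qi]] <- max(votes) / k
      res$mean_distance[rows[qi]] <- mean(D[qi, nb[model$labels[nb] == lab]])
    }
  }
  class(res) <- c("annotation_result", "data.frame")
  res
}

#' Map predicted classes onto another label scheme
#'
#' Substitutes predicted labels through a mapping table, e.g. collapsing a
#' fine-grained reference label set onto the coarser classes of another
#' annotation tool before comparison. With `passthrough = TRUE` unmapped
#' labels are kept verbatim; otherwise an unmapped label is an error.
#'
#' @param predictions character vector (or `annotation_result`).
#' @param mapping named character vector: old label -> new label.
#' @param passthrough keep unmapped labels as-is (default `FALSE`).
#' @return relabeled predictions, same shape as the input.
#' @export
map_classes <- function(predictions, mapping, passthrough = FALSE) {
  is_res <- inherits(predictions, "annotation_result")
  labs <- if (is_res) predictions$label else as.character(predictions)
  known <- is.na(labs) | labs %in% names(mapping)
  if (!passthrough && any(!known))
    stop_fmt("unmapped label(s): %s",
             paste(unique(labs[!known]), collapse = ", "))
  mapped <- ifelse(!is.na(labs) & labs %in% names(mapping),
                   unname(mapping[labs]), labs)
  if (is_res) { predictions$label <- mapped; predictions } else mapped
}

#' Evaluate annotations against ground truth
#'
#' Aligns predictions and truth by barcode and computes the confusion
#' matrix, per-class precision / recall / F1, macro F1 (unweighted class
#' mean) and weighted F1 (truth-support weighted). Classes with no
#' predictions or no truth cells score 0 where the quotient is undefined.
#'
#' @param predicted an `annotation_result` or named character vector
#'   (names = barcodes).
#' @param truth named character vector of true labels (names = barcodes).
#' @return list with `confusion` (truth rows x predicted columns),
#'   `per_class` data.frame, `macro_f1`, `weighted_f1`, `accuracy`, `n`.
#' @export
evaluate_annotation <- function(predicted, truth) {
  if (inherits(predicted, "annotation_result"))
    predicted <- stats::setNames(predicted$label, predicted$barcode)
  stopifnot(!is.null(names(predicted)), !is.null(names(truth)))
  common <- intersect(names(predicted)[!is.na(predicted)], names(truth))
  if (length(common) == 0L) stop_fmt("no overlapping barcodes between predictions and truth")
  p <- as.character(predicted[common]); t <- as.character(truth[common])
  classes <- sort(unique(c(p, t)))
  conf <- table(factor(t, classes), factor(p, classes))
  names(dimnames(conf)) <- c("truth", "predicted")
  tp <- diag(conf); support <- rowSums(conf); predn <- colSums(conf)
  precision <- ifelse(predn > 0, tp / predn, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = classes, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          support = as.numeric(support), row.names = NULL)
  list(confusion = conf, per_class = per_class,
       macro_f1 = mean(f1),
       weighted_f1 = sum(f1 * support) / sum(support),
       accuracy = sum(tp) / length(common), n = length(common))
}
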