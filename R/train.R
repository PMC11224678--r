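#' Training configuration for the region embedding model
#'
#' Hyperparameters for skip-gram training with negative sampling. The core
#' defaults are a context window of 5, an embedding dimension of 100, 100
#' epochs and an exponential learning-rate schedule with decay 0.95 per
#' epoch (constant within an epoch). The remaining knobs follow standard
#' word2vec conventions: initial learning rate 0.025, 5 negative samples per
#' positive pair, noise distribution proportional to document frequency
#' raised to 0.75, and `min_count = 1` so that no region is silently dropped
#' from the vocabulary.
#'
#' @param dim embedding dimension d.
#' @param window maximum context window; the effective window for each
#'   target is drawn uniformly from `1..window`.
#' @param epochs number of passes over the corpus; each document is
#'   re-shuffled every epoch.
#' @param decay per-epoch exponential decay of the learning rate.
#' @param learning_rate initial learning rate (epoch e uses
#'   `learning_rate * decay^e`).
#' @param negatives number of negative samples per positive pair.
#' @param min_count keep words occurring in at least this many documents.
#' @param noise_exponent exponent of the negative-sampling noise
#'   distribution.
#' @param seed integer seed; training is bit-reproducible under it.
#' @return a `training_config` list.
#' @export
training_config <- function(dim = 100L, window = 5L, epochs = 100L,
                            decay = 0.95, learning_rate = 0.025,
                            negatives = 5L, min_count = 1L,
                            noise_exponent = 0.75, seed = 42L) {
  cfg <- list(dim = as.integer(dim), window = as.integer(window),
              epochs = as.integer(epochs), decay = decay,
              learning_rate = learning_rate, negatives = as.integer(negatives),
              min_count = as.integer(min_count),
              noise_exponent = noise_exponent, seed = as.integer(seed))
  stopifnot(cfg$dim >= 1, cfg$window >= 1, cfg$epochs >= 1,
            cfg$decay > 0, cfg$decay <= 1, cfg$learning_rate > 0,
            cfg$negatives >= 1, cfg$min_count >= 1)
  structure(cfg, class = "training_config")
}

#' Build the training vocabulary
#'
#' Words occurring in at least `min_count` documents are retained and
#' indexed deterministically: descending document count, ties broken
#' lexicographically by word.
#'
#' @param corpus a `region_corpus`.
#' @param min_count minimum document frequency.
#' @return named integer vector: document count per word, in index order.
#' @export
build_vocabulary <- function(corpus, min_count = 1L) {
  stopifnot(inherits(corpus, "region_corpus"))
  vc <- corpus$vocabulary_counts
  vc <- vc[vc >= min_count]
  if (length(vc) == 0L) stop_fmt("empty vocabulary (min_count = %d)", min_count)
  vc[order(-vc, names(vc), method = "radix")]
}

#' Negative-sampling noise distribution
#'
#' `p(w)` proportional to `count(w)^noise_exponent`, normalized to sum to 1.
#' Exponent 0 gives a uniform distribution; exponent 1 the raw frequencies.
#'
#' @param counts named positive counts per word.
#' @param noise_exponent exponent applied to the counts.
#' @return named probability vector in the same order.
#' @export
noise_distribution <- function(counts, noise_exponent = 0.75) {
  stopifnot(length(counts) > 0, all(counts > 0))
  p <- as.numeric(counts)^noise_exponent
  stats::setNames(p / sum(p), names(counts))
}

#' Skip-gram negative-sampling loss
#'
#' `L = -log sigma(u_pos . v) - sum_i log sigma(-u_neg_i . v)` with
#' `sigma(x) = 1 / (1 + exp(-x))`; always non-negative.
#'
#' @param v_target input vector of the target word (length d).
#' @param u_pos context vector of the observed context word.
#' @param u_negs matrix (k x d) of context vectors of the sampled negatives.
#' @return scalar loss.
#' @export
sgns_loss <- function(v_target, u_pos, u_negs) {
  u_negs <- matrix(u_negs, ncol = length(v_target))
  # log sigma(x) computed stably as -log1p(exp(-x)) for either sign
  log_sigma <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
  -log_sigma(sum(u_pos * v_target)) -
    sum(log_sigma(-as.numeric(u_negs %*% v_target)))
}

#' One SGD step on the SGNS loss
#'
#' Applies a single gradient-descent step on [sgns_loss()] with respect to
#' the target's input vector and the context vectors of the positive and
#' negative words. All other rows are untouched. This calls the same
#' compiled kernel used by [train_region_embeddings()].
#'
#' @param tables list with `input` and `context` matrices (|V| x d).
#' @param target_idx,context_idx 1-based row indices of target and positive
#'   context.
#' @param negatives 1-based row indices of the sampled negatives.
#' @param lr learning rate.
#' @return updated `tables` (the input list is not modified).
#' @export
sgns_step <- function(tables, target_idx, context_idx, negatives, lr) {
  W <- tables$input + 0; C <- tables$context + 0  # force copies
  cpp_sgns_step(W, C, as.integer(target_idx) - 1L,
                as.integer(context_idx) - 1L,
                as.integer(negatives) - 1L, lr)
  list(input = W, context = C)
}

#' Train region embeddings on a corpus
#'
#' Runs skip-gram training with negative sampling over the shuffled
#' documents: every epoch each document receives a fresh uniform permutation
#' (seeded from the global seed, the epoch and the document index), an
#' effective window is drawn per target position, and one SGD step is
#' applied per (target, context) pair with `negatives` noise words.
#' Training is single-threaded and bit-reproducible under `config$seed`.
#'
#' @param corpus a `region_corpus` from [build_documents()].
#' @param config a [training_config()].
#' @return a `region_model` bundle, see [region_model()].
#' @export
train_region_embeddings <- function(corpus, config = training_config()) {
  stopifnot(inherits(corpus, "region_corpus"), inherits(config, "training_config"))
  if (sum(lengths(corpus$documents)) == 0L) stop_fmt("empty corpus: no words to train on")
  vocab <- build_vocabulary(corpus, config$min_count)
  words <- names(vocab)
  noise <- noise_distribution(vocab, config$noise_exponent)
  idx <- stats::setNames(seq_along(words), words)
  docs <- lapply(corpus$documents, function(w) {
    j <- idx[w]
    as.integer(j[!is.na(j)]) - 1L
  })
  fit <- cpp_train_sgns(docs, length(words), config$dim, config$window,
                        config$epochs, config$learning_rate, config$decay,
                        config$negatives, cumsum(noise), config$seed)
  rownames(fit$input) <- rownames(fit$context) <- words
  region_model(vocab = words,
               input_vectors = fit$input,
               context_vectors = fit$context,
               consensus = word_to_region(words),
               metadata = list(dimension = config$dim, window = config$window,
                               epochs = config$epochs, decay = config$decay,
                               learning_rate = config$learning_rate,
                               negatives = config$negatives,
                               min_count = config$min_count,
                               noise_exponent = config$noise_exponent,
                               seed = config$seed,
                               n_consensus_regions = length(words)))
}
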