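#' @title Word embeddings
#' @description
#' Vocabulary construction and word-vector initialisation. Vectors can be
#' random (uniform in \[-0.1, 0.1\]) or pretrained with skip-gram negative
#' sampling on the working corpus; either way they seed the embedding table
#' that supervised training optionally fine-tunes.
#' @name embeddings
NULL

UNK_TOKEN <- "<unk>"

# run expr with a private RNG state so library calls do not perturb the
# caller's random stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a vocabulary from a token corpus
#'
#' Tokens with frequency at least `min_count` get their own row; everything
#' else maps to the unknown token, which is always present.
#'
#' @param corpus list of character token vectors (sentences/segments).
#' @param min_count minimum frequency for inclusion (default 1).
#' @return object of class `rae_vocab`: `tokens` (character, unknown token
#'   first), `index` (named integer), `unk_index`, `counts`.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  toks <- unlist(corpus, use.names = FALSE)
  if (length(toks) == 0) stop("empty corpus", call. = FALSE)
  tab <- table(toks)
  keep <- names(tab)[tab >= min_count]
  keep <- setdiff(sort(keep), UNK_TOKEN)
  tokens <- c(UNK_TOKEN, keep)
  idx <- seq_along(tokens)
  names(idx) <- tokens
  structure(list(tokens = tokens, index = idx, unk_index = 1L,
                 counts = c(sum(tab[!(names(tab) %in% keep)]),
                            as.integer(tab[keep]))),
            class = "rae_vocab")
}

#' @export
print.rae_vocab <- function(x, ...) {
  cat(sprintf("<rae_vocab> %d tokens (incl. %s)\n", length(x$tokens), UNK_TOKEN))
  invisible(x)
}

#' Map tokens to vocabulary indices
#'
#' Unknown tokens map to the unknown-token index; lookups never fail.
#'
#' @param vocab an `rae_vocab`.
#' @param tokens character vector.
#' @return integer vector of 1-based indices.
#' @export
token_ids <- function(vocab, tokens) {
  idx <- vocab$index[tokens]
  idx[is.na(idx)] <- vocab$unk_index
  unname(idx)
}

new_embedding_table <- function(vocab, vectors) {
  stopifnot(ncol(vectors) == length(vocab$tokens))
  colnames(vectors) <- vocab$tokens
  structure(list(vocab = vocab, vectors = vectors,
                 unk_index = vocab$unk_index),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens x %d dims\n",
              ncol(x$vectors), nrow(x$vectors)))
  invisible(x)
}

#' Random embedding initialisation
#'
#' Entries i.i.d. uniform in \[-0.1, 0.1\]; the same seed always yields the
#' same table and the caller's RNG state is left untouched.
#'
#' @param vocab an `rae_vocab`.
#' @param vector_dim vector dimensionality (>= 2).
#' @param seed integer seed.
#' @return an `embedding_table`.
#' @export
init_embeddings <- function(vocab, vector_dim = 50L, seed = 42L) {
  stopifnot(vector_dim >= 2)
  V <- length(vocab$tokens)
  vecs <- with_seed(seed, matrix(runif(vector_dim * V, -0.1, 0.1),
                                 nrow = vector_dim))
  new_embedding_table(vocab, vecs)
}

#' Pretrain embeddings with skip-gram negative sampling
#'
#' A desk-scale word2vec-style pretraining pass: skip-gram with negative
#' sampling (unigram^0.75 noise distribution), fixed context window,
#' single-threaded and deterministic for a given seed. Vectors start from
#' [init_embeddings()] with the same seed, so `epochs = 0` returns exactly
#' the random initialisation.
#'
#' @param corpus list of character token vectors; at least 100 tokens in
#'   total.
#' @param vector_dim vector dimensionality.
#' @param epochs passes over the corpus (default 5).
#' @param seed integer seed.
#' @param window context window half-width (default 4).
#' @param negative negative samples per positive (default 5).
#' @param learning_rate SGD step (default 0.025).
#' @param min_count vocabulary threshold.
#' @return an `embedding_table`.
#' @export
pretrain_skipgram <- function(corpus, vector_dim = 50L, epochs = 5L,
                              seed = 42L, window = 4L, negative = 5L,
                              learning_rate = 0.025, min_count = 1L) {
  ntok <- length(unlist(corpus, use.names = FALSE))
  if (ntok < 100)
    stop("corpus too small for pretraining (", ntok, " tokens, need >= 100)",
         call. = FALSE)
  vocab <- build_vocab(corpus, min_count = min_count)
  init <- init_embeddings(vocab, vector_dim, seed)
  if (epochs == 0) return(init)
  sent_idx <- lapply(corpus, function(s) token_ids(vocab, s))
  sent_idx <- sent_idx[lengths(sent_idx) > 1]
  vecs <- cpp_skipgram(sent_idx, init$vectors, as.numeric(vocab$counts),
                       as.integer(window), as.integer(negative),
                       learning_rate, as.integer(epochs), as.integer(seed))
  if (any(!is.finite(vecs)))
    stop("non-finite embeddings after pretraining", call. = FALSE)
  new_embedding_table(vocab, vecs)
}

#' Look up token vectors
#'
#' @param table an `embedding_table`.
#' @param tokens character vector.
#' @return matrix with one column per token (unknown tokens get the unknown
#'   vector).
#' @export
lookup_tokens <- function(table, tokens) {
  table$vectors[, token_ids(table$vocab, tokens), drop = FALSE]
}

#' Cosine similarity of two tokens
#'
#' @param table an `embedding_table`.
#' @param a,b tokens.
#' @return cosine similarity in \[-1, 1\].
#' @export
token_cosine <- function(table, a, b) {
  va <- lookup_tokens(table, a)[, 1]
  vb <- lookup_tokens(table, b)[, 1]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Save an embedding table to a vector text file
#' @param table an `embedding_table`.
#' @param path output path.
#' @export
save_embeddings <- function(table, path) {
  write_word_vectors(table$vocab$tokens, table$vectors, path)
}

#' Load an embedding table from a vector text file
#' @param path vector file path.
#' @return an `embedding_table` (the unknown token is added with a zero
#'   vector if the file lacks one).
#' @export
load_embeddings <- function(path) {
  wv <- read_word_vectors(path)
  tokens <- wv$tokens
  vecs <- wv$vectors
  if (!(UNK_TOKEN %in% tokens)) {
    tokens <- c(UNK_TOKEN, tokens)
    vecs <- cbind(matrix(0, nrow(vecs), 1), vecs)
  } else if (tokens[1] != UNK_TOKEN) {
    ord <- c(which(tokens == UNK_TOKEN), which(tokens != UNK_TOKEN))
    tokens <- tokens[ord]; vecs <- vecs[, ord, drop = FALSE]
  }
  idx <- seq_along(tokens); names(idx) <- tokens
  vocab <- structure(list(tokens = tokens, index = idx, unk_index = 1L,
                          counts = rep(1L, length(tokens))),
                     class = "rae_vocab")
  new_embedding_table(vocab, vecs)
}
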