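# Shared builders: tiny models and candidate sets assembled in code.

benchmark_table_path <- function() {
  system.file("extdata", "benchmark_map.csv", package = "raerank")
}

# candidate set with given token sequences and 0/1 labels (bypasses the
# preprocessing pipeline for unit tests of the model layer)
make_cset <- function(token_seqs, labels, id = "q1") {
  pairs <- lapply(seq_along(token_seqs), function(i) {
    list(tokens = token_seqs[[i]], q_len = 1L, doc_id = "d1",
         begin = (i - 1L) * 10L, end = (i - 1L) * 10L + 5L,
         text = paste(token_seqs[[i]], collapse = " "),
         relevant = as.integer(labels[i]))
  })
  structure(list(question_id = id, pairs = pairs,
                 labels = as.integer(labels), N = length(pairs),
                 m = sum(labels)), class = "candidate_set")
}

# small random model over an explicit vocabulary; emb_scale > 1 moves the
# parameter point away from the near-zero embedding regime (used by the
# finite-difference gradient checks, where the numeric oracle's truncation
# error grows sharply close to the parent-normalization singularity)
make_model <- function(dim = 6, tokens = letters[1:10], seed = 3,
                       config = NULL, emb_scale = 1) {
  if (is.null(config)) config <- rae_config(vector_dim = dim, seed = seed)
  vocab <- build_vocab(list(tokens))
  emb <- init_embeddings(vocab, dim, seed = seed)
  emb$vectors <- emb$vectors * emb_scale
  init_model(emb, config)
}

# random candidate sets over the model's vocabulary
make_random_csets <- function(n_q = 2, n_cand = 3, n_tok = 4,
                              tokens = letters[1:10], seed = 1) {
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); expr
  }
  withr_seed(seed, {
    lapply(seq_len(n_q), function(q) {
      seqs <- lapply(seq_len(n_cand), function(i)
        sample(tokens, n_tok, replace = TRUE))
      labels <- rep(0L, n_cand)
      labels[sample.int(n_cand, sample(1:2, 1))] <- 1L
      make_cset(seqs, labels, id = paste0("q", q))
    })
  })
}

# full-coordinate central-difference check of the analytic gradient with
# structures and ranking order frozen; returns the maximum relative error
gradient_fd_max_relerr <- function(csets, model, eps = 1e-5) {
  g <- gradient(csets, model)
  strs <- attr(g, "structures")
  dens <- attr(g, "denoms")
  obj <- function(m2) objective(csets, m2, structures = strs, denoms = dens)
  perturb <- function(model, comp, idx, delta) {
    if (comp == "emb")
      model$embeddings$vectors[idx] <- model$embeddings$vectors[idx] + delta
    else if (comp == "Wlabel") model$Wlabel[idx] <- model$Wlabel[idx] + delta
    else model$rae[[comp]][idx] <- model$rae[[comp]][idx] + delta
    model
  }
  worst <- 0
  for (comp in c("W1", "b1", "W2", "b2", "Wlabel", "emb")) {
    garr <- g[[comp]]
    for (idx in seq_along(garr)) {
      num <- (obj(perturb(model, comp, idx, eps)) -
                obj(perturb(model, comp, idx, -eps))) / (2 * eps)
      re <- abs(num - garr[idx]) / max(1, abs(num), abs(garr[idx]))
      worst <- max(worst, re)
    }
  }
  worst
}
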