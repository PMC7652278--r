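#' @title Semi-supervised ranking model
#' @description
#' Extends the recursive autoencoder with a softmax relatedness classifier
#' on every internal node and a listwise ranking loss. For one question
#' with candidate set `C` (labels `L`, predicted root distributions `D`,
#' relevant count `m`), the per-question loss is
#' `beta * Er + (1 - beta) * sum of per-pair tree errors`, where the tree
#' error sums `alpha * Erec + (1 - alpha) * EcE` over internal nodes and
#' the ranking error is `Er = -log( sum_i d1(i) / i )` over the relevant
#' candidates ordered by descending predicted relevance probability `d1`
#' (literal form; the inner sum can exceed 1 for `m >= 2`, so `Er` may be
#' negative -- it still falls as the relevant probabilities rise). The full
#' objective averages per-question losses and adds an L2 penalty
#' `lambda/2 ||theta||^2`.
#' @name rank_model
NULL

#' Initialise a full model
#'
#' Bundles RAE parameters, the label matrix and the embedding table; the
#' collection is the trainable parameter set `theta`.
#'
#' @param embeddings an `embedding_table` (from [init_embeddings()],
#'   [pretrain_skipgram()] or [load_embeddings()]).
#' @param config an [rae_config()]; `vector_dim` must match the table.
#' @return object of class `rae_model`: `rae` (`rae_params`), `Wlabel`
#'   (2 x dim), `embeddings`, `config`.
#' @export
init_model <- function(embeddings, config = rae_config()) {
  n <- nrow(embeddings$vectors)
  if (n != config$vector_dim)
    stop("embedding dimension ", n, " != config vector_dim ",
         config$vector_dim, call. = FALSE)
  rae <- init_rae_params(n, seed = config$seed)
  r <- 1 / sqrt(n)
  Wlabel <- with_seed(config$seed + 1L, matrix(runif(2 * n, -r, r), 2, n))
  structure(list(rae = rae, Wlabel = Wlabel, embeddings = embeddings,
                 config = config),
            class = "rae_model")
}

#' @export
print.rae_model <- function(x, ...) {
  cat(sprintf("<rae_model> dim %d, vocab %d, alpha %.2f beta %.2f\n",
              nrow(x$embeddings$vectors), ncol(x$embeddings$vectors),
              x$config$alpha, x$config$beta))
  invisible(x)
}

#' Classify a node vector
#'
#' Softmax over the two logits `Wlabel p`; the first component `d1` is the
#' predicted probability of a question-answer relation.
#'
#' @param p node vector.
#' @param Wlabel 2 x dim label matrix (or an `rae_model`).
#' @return numeric vector `c(d1, d2)` summing to 1.
#' @export
classify_node <- function(p, Wlabel) {
  if (inherits(Wlabel, "rae_model")) Wlabel <- Wlabel$Wlabel
  z <- drop(Wlabel %*% p)
  if (any(!is.finite(z))) stop("non-finite logits", call. = FALSE)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Cross-entropy of a predicted distribution against a one-hot label
#'
#' `-sum_k t_k log d_k` with natural logarithm; zero probabilities under
#' the target are clipped at 1e-12 with a warning.
#'
#' @param d distribution `c(d1, d2)`.
#' @param t one-hot target, `c(1, 0)` for relevant, `c(0, 1)` otherwise.
#' @return nonnegative scalar.
#' @export
cross_entropy <- function(d, t) {
  stopifnot(length(d) == 2, length(t) == 2, all(t %in% c(0, 1)), sum(t) == 1)
  k <- which(t == 1)
  if (d[k] <= 0) {
    warning("clipping zero probability in cross-entropy")
    d[k] <- 1e-12
  }
  -log(d[k])
}

label_onehot <- function(relevant) if (relevant) c(1, 0) else c(0, 1)

#' Tree error of one question-snippet pair
#'
#' Sums `alpha * Erec + (1 - alpha) * EcE` over the internal nodes of the
#' pair's composition tree, every node classified against the pair-level
#' label. The weighted reconstruction error is recomputed from the stored
#' node vectors. A single-token pair has no internal node and contributes
#' zero (degenerate case).
#'
#' @param tree a `composition_tree`.
#' @param relevant logical or 0/1 pair label.
#' @param model an `rae_model` (or list with `rae` and `Wlabel`).
#' @param alpha reconstruction-vs-cross-entropy weight.
#' @return nonnegative scalar.
#' @export
tree_error <- function(tree, relevant, model, alpha = 0.2) {
  if (tree$L == 1) return(0)
  t <- label_onehot(as.logical(relevant))
  total <- 0
  for (i in seq_len(nrow(tree$triplets))) {
    pid <- tree$triplets[i, 1]
    a <- tree$triplets[i, 2]; b <- tree$triplets[i, 3]
    nd <- tree$nodes[[pid]]
    r <- reconstruct(nd$vector, model$rae)
    erec <- recon_error_weighted(tree$nodes[[a]]$vector,
                                 tree$nodes[[b]]$vector, r$c1, r$c2,
                                 tree$nodes[[a]]$n, tree$nodes[[b]]$n)
    ece <- cross_entropy(classify_node(nd$vector, model$Wlabel), t)
    total <- total + alpha * erec + (1 - alpha) * ece
  }
  total
}

#' Listwise ranking error of a candidate set
#'
#' `-log( sum_{i=1..m} d1(i) / denom_i )` with natural logarithm. Under the
#' default `relevant_index` variant the relevant candidates are ordered by
#' descending `d1` and `denom_i = i`; under `global_rank` the denominator
#' is the candidate's position in the full ranking of all N candidates.
#' With no relevant candidate the loss is undefined and an error is raised
#' (training skips such questions).
#'
#' @param d1 predicted relevance probabilities, one per candidate.
#' @param labels 0/1 relevance labels aligned with `d1`.
#' @param variant `"relevant_index"` (default) or `"global_rank"`.
#' @param denoms optional frozen denominators (vector aligned with `d1`,
#'   zero at irrelevant positions) to hold the ranking fixed during
#'   differentiation checks.
#' @return scalar; can be negative once the inner sum exceeds 1.
#' @export
ranking_error <- function(d1, labels,
                          variant = c("relevant_index", "global_rank"),
                          denoms = NULL) {
  variant <- match.arg(variant)
  stopifnot(length(d1) == length(labels))
  rel <- which(labels == 1)
  if (length(rel) == 0)
    stop("ranking error undefined: no relevant candidate (m = 0)",
         call. = FALSE)
  if (is.null(denoms)) denoms <- ranking_denominators(d1, labels, variant)
  -log(sum(d1[rel] / denoms[rel]))
}

#' Ranking denominators for the listwise loss
#'
#' @inheritParams ranking_error
#' @return numeric vector aligned with `d1`; zero at irrelevant positions.
#' @export
ranking_denominators <- function(d1, labels,
                                 variant = c("relevant_index", "global_rank")) {
  variant <- match.arg(variant)
  rel <- which(labels == 1)
  denoms <- numeric(length(d1))
  if (variant == "global_rank") {
    pos <- order(-d1, seq_along(d1))       # stable descending
    rank_of <- integer(length(d1))
    rank_of[pos] <- seq_along(d1)
    denoms[rel] <- rank_of[rel]
  } else {
    ord <- rel[order(-d1[rel], seq_along(rel))]
    denoms[ord] <- seq_along(ord)
  }
  denoms
}

# token index lists for the C++ core
cset_token_idx <- function(cset, vocab) {
  lapply(cset$pairs, function(p) as.integer(token_ids(vocab, p$tokens)))
}

cpp_eval_cset <- function(cset, model, structures = NULL, denoms = NULL,
                          want_grad = FALSE) {
  cfg <- model$config
  cpp_question_eval(cset_token_idx(cset, model$embeddings$vocab),
                    as.integer(cset$labels), model$embeddings$vectors,
                    model$rae$W1, model$rae$b1, model$rae$W2, model$rae$b2,
                    model$Wlabel, cfg$alpha, cfg$beta, cfg$normalize_parent,
                    cfg$merge_criterion == "weighted",
                    cfg$ranking_error_variant, structures, denoms,
                    want_grad, cfg$fine_tune_embeddings)
}

#' Per-question loss
#'
#' `beta * Er + (1 - beta) * sum over pairs of tree errors`. This is the
#' R-level reference route (greedy trees built with the package's tree
#' operations); [objective()] uses the compiled path.
#'
#' @param cset a `candidate_set`.
#' @param model an `rae_model`.
#' @return scalar loss.
#' @export
question_loss <- function(cset, model) {
  cfg <- model$config
  if (cset$m == 0)
    stop("question ", cset$question_id, " has no relevant candidate",
         call. = FALSE)
  d1 <- numeric(cset$N)
  terr <- numeric(cset$N)
  for (i in seq_len(cset$N)) {
    X <- lookup_tokens(model$embeddings, cset$pairs[[i]]$tokens)
    tree <- greedy_build_tree(X, model$rae, cfg$normalize_parent,
                              cfg$merge_criterion == "weighted")
    d1[i] <- classify_node(tree$nodes[[tree$root]]$vector, model$Wlabel)[1]
    terr[i] <- tree_error(tree, cset$labels[i], model, cfg$alpha)
  }
  er <- ranking_error(d1, cset$labels, cfg$ranking_error_variant)
  cfg$beta * er + (1 - cfg$beta) * sum(terr)
}

model_param_sq_norm <- function(model) {
  s <- sum(model$rae$W1^2) + sum(model$rae$b1^2) + sum(model$rae$W2^2) +
    sum(model$rae$b2^2) + sum(model$Wlabel^2)
  if (model$config$regularize_embeddings)
    s <- s + sum(model$embeddings$vectors^2)
  s
}

#' Full training objective
#'
#' Mean of per-question losses plus `lambda/2 ||theta||^2` (embedding rows
#' enter the penalty only when `regularize_embeddings` is set). Questions
#' with no relevant candidate are skipped with a warning. Tree structures
#' and ranking denominators may be passed in to freeze the discrete choices
#' (used by finite-difference gradient checks); otherwise both are
#' recomputed at the current parameters.
#'
#' @param csets list of `candidate_set` objects.
#' @param model an `rae_model`.
#' @param structures optional list (one entry per candidate set) of triplet
#'   matrices as returned in the `structures` field of a previous
#'   evaluation.
#' @param denoms optional list of frozen ranking denominators.
#' @return scalar objective value.
#' @export
objective <- function(csets, model, structures = NULL, denoms = NULL) {
  usable <- vapply(csets, function(cs) cs$m > 0, TRUE)
  if (!any(usable)) stop("no question with a relevant candidate", call. = FALSE)
  if (any(!usable))
    warning(sprintf("skipping %d question(s) with m = 0", sum(!usable)))
  idx <- which(usable)
  losses <- vapply(seq_along(idx), function(k) {
    q <- idx[k]
    res <- cpp_eval_cset(csets[[q]], model,
                         structures = if (!is.null(structures)) structures[[q]],
                         denoms = if (!is.null(denoms)) denoms[[q]])
    res$loss
  }, 0)
  mean(losses) + model$config$lambda_reg / 2 * model_param_sq_norm(model)
}

zero_grads <- function(model) {
  n <- nrow(model$embeddings$vectors)
  list(W1 = matrix(0, n, 2 * n), b1 = numeric(n),
       W2 = matrix(0, 2 * n, n), b2 = numeric(2 * n),
       Wlabel = matrix(0, 2, n),
       emb = matrix(0, n, ncol(model$embeddings$vectors)))
}

add_reg_grad <- function(g, model) {
  lam <- model$config$lambda_reg
  g$W1 <- g$W1 + lam * model$rae$W1
  g$b1 <- g$b1 + lam * model$rae$b1
  g$W2 <- g$W2 + lam * model$rae$W2
  g$b2 <- g$b2 + lam * model$rae$b2
  g$Wlabel <- g$Wlabel + lam * model$Wlabel
  if (model$config$regularize_embeddings)
    g$emb <- g$emb + lam * model$embeddings$vectors
  g
}

#' Analytic gradient of the objective
#'
#' Exact gradient of [objective()] with the tree structures and the ranking
#' order held fixed; both are computed at the current parameters unless
#' supplied. Returns arrays shaped like the parameters (`W1`, `b1`, `W2`,
#' `b2`, `Wlabel`, `emb`; the embedding gradient is zero unless
#' `fine_tune_embeddings` is on).
#'
#' @inheritParams objective
#' @return list of gradient arrays, plus the frozen `structures` and
#'   `denoms` as attributes.
#' @export
gradient <- function(csets, model, structures = NULL, denoms = NULL) {
  usable <- which(vapply(csets, function(cs) cs$m > 0, TRUE))
  if (!length(usable)) stop("no question with a relevant candidate", call. = FALSE)
  g <- zero_grads(model)
  used_str <- vector("list", length(csets))
  used_den <- vector("list", length(csets))
  for (q in usable) {
    res <- cpp_eval_cset(csets[[q]], model,
                         structures = if (!is.null(structures)) structures[[q]],
                         denoms = if (!is.null(denoms)) denoms[[q]],
                         want_grad = TRUE)
    for (nm in c("W1", "b1", "W2", "b2", "Wlabel", "emb"))
      g[[nm]] <- g[[nm]] + res$grad[[nm]] / length(usable)
    used_str[[q]] <- res$structures
    used_den[[q]] <- res$denom
  }
  bad <- names(g)[vapply(g, function(x) any(!is.finite(x)), TRUE)]
  if (length(bad))
    stop("non-finite gradient in component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  g <- add_reg_grad(g, model)
  attr(g, "structures") <- used_str
  attr(g, "denoms") <- used_den
  g
}

#' Train the ranking model
#'
#' Per-question stochastic gradient descent: each epoch visits the
#' questions in a freshly shuffled order (seeded), rebuilds every pair's
#' greedy tree and the ranking order at the current parameters, and takes
#' one step against the per-question loss gradient plus the L2 term.
#' Questions with no relevant candidate are skipped (counted in the
#' returned history). Identical data, config and seed give identical
#' results.
#'
#' @param csets list of `candidate_set` objects (the training questions).
#' @param config an [rae_config()].
#' @param embeddings optional pre-built `embedding_table`; by default a
#'   random table over the training vocabulary is created with the config
#'   seed.
#' @param model optional warm-start `rae_model` (overrides `embeddings`).
#' @return an `rae_model` with a `history` attribute: data frame of epoch
#'   and mean per-question loss, plus `objective_initial`,
#'   `objective_final` and `n_skipped`.
#' @export
train_ranker <- function(csets, config = rae_config(), embeddings = NULL,
                         model = NULL) {
  if (is.null(model)) {
    if (is.null(embeddings)) {
      vocab <- build_vocab(lapply(csets, function(cs)
        unlist(lapply(cs$pairs, `[[`, "tokens"))), config$min_count)
      embeddings <- init_embeddings(vocab, config$vector_dim, config$seed)
    }
    model <- init_model(embeddings, config)
  } else {
    config <- model$config
  }
  usable <- which(vapply(csets, function(cs) cs$m > 0, TRUE))
  n_skipped <- length(csets) - length(usable)
  if (n_skipped > 0)
    message(sprintf("skipping %d question(s) with no relevant candidate",
                    n_skipped))
  if (!length(usable)) stop("no trainable question", call. = FALSE)

  obj0 <- objective(csets[usable], model)
  history <- data.frame(epoch = integer(), mean_loss = numeric())
  lr <- config$learning_rate
  lam <- config$lambda_reg

  if (config$epochs > 0) {
    orders <- with_seed(config$seed, {
      lapply(seq_len(config$epochs), function(e) sample(usable))
    })
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (q in orders[[ep]]) {
        res <- cpp_eval_cset(csets[[q]], model, want_grad = TRUE)
        if (!is.finite(res$loss))
          stop("training diverged at epoch ", ep, ", question ",
               csets[[q]]$question_id, " (non-finite loss)", call. = FALSE)
        ep_loss <- ep_loss + res$loss
        g <- res$grad
        model$rae$W1 <- model$rae$W1 - lr * (g$W1 + lam * model$rae$W1)
        model$rae$b1 <- model$rae$b1 - lr * (g$b1 + lam * model$rae$b1)
        model$rae$W2 <- model$rae$W2 - lr * (g$W2 + lam * model$rae$W2)
        model$rae$b2 <- model$rae$b2 - lr * (g$b2 + lam * model$rae$b2)
        model$Wlabel <- model$Wlabel - lr * (g$Wlabel + lam * model$Wlabel)
        if (config$fine_tune_embeddings) {
          embg <- g$emb
          if (config$regularize_embeddings)
            embg <- embg + lam * model$embeddings$vectors
          model$embeddings$vectors <- model$embeddings$vectors - lr * embg
        }
      }
      history <- rbind(history,
                       data.frame(epoch = ep,
                                  mean_loss = ep_loss / length(usable)))
    }
  }
  attr(model, "history") <- list(per_epoch = history,
                                 objective_initial = obj0,
                                 objective_final = objective(csets[usable], model),
                                 n_skipped = n_skipped,
                                 seed = config$seed,
                                 config_hash = config_hash(config))
  model
}

#' Score a candidate set
#'
#' Predicted relevance probability `d1` of every pair: the root node's
#' distribution under the current parameters.
#'
#' @param cset a `candidate_set`.
#' @param model an `rae_model`.
#' @return numeric vector of `d1` values.
#' @export
score_candidates <- function(cset, model) {
  cpp_eval_cset(cset, model)$d1
}

#' Rank the candidates of one question
#'
#' Sorts by descending predicted relevance probability, keeps the original
#' candidate order on ties, and truncates to `cutoff` snippets.
#'
#' @param cset a `candidate_set`.
#' @param model an `rae_model`, or NULL when `d1` is given.
#' @param d1 optional precomputed scores aligned with the candidates.
#' @param cutoff maximum snippets returned (default 10).
#' @return a prediction record: list with `question_id` and
#'   `ranked_snippets` (data frame `doc_id`, `begin`, `end`, `score`), plus
#'   attribute `order` (the full permutation before truncation).
#' @export
rank_candidates <- function(cset, model = NULL, d1 = NULL, cutoff = 10L) {
  if (is.null(d1)) {
    if (is.null(model)) stop("either model or d1 required", call. = FALSE)
    d1 <- score_candidates(cset, model)
  }
  stopifnot(length(d1) == cset$N)
  ord <- order(-d1, seq_along(d1))    # stable: ties keep original order
  top <- head(ord, cutoff)
  sn <- data.frame(
    doc_id = vapply(cset$pairs[top], `[[`, "", "doc_id"),
    begin = vapply(cset$pairs[top], `[[`, 0, "begin"),
    end = vapply(cset$pairs[top], `[[`, 0, "end"),
    score = d1[top], stringsAsFactors = FALSE)
  rownames(sn) <- NULL
  structure(list(question_id = cset$question_id, ranked_snippets = sn),
            order = ord, d1 = d1, class = "prediction_record")
}

#' Rank all candidate sets
#'
#' @param csets list of `candidate_set` objects.
#' @param model an `rae_model`.
#' @param cutoff per-question snippet cap.
#' @return list of prediction records.
#' @export
predict_rankings <- function(csets, model, cutoff = 10L) {
  lapply(csets, rank_candidates, model = model, cutoff = cutoff)
}

#' MAP of a model on labelled candidate sets
#'
#' Ranks every candidate set, computes truncated average precision per
#' question against its labels and averages. Questions with no relevant
#' candidate are excluded.
#'
#' @param csets list of `candidate_set` objects.
#' @param model an `rae_model`.
#' @param cutoff truncation depth.
#' @return scalar MAP.
#' @export
model_map <- function(csets, model, cutoff = 10L) {
  aps <- vapply(csets[vapply(csets, function(cs) cs$m > 0, TRUE)],
                function(cs) {
    pr <- rank_candidates(cs, model, cutoff = cutoff)
    ord <- attr(pr, "order")
    average_precision(cs$labels[ord], cutoff = cutoff, m = cs$m)
  }, 0)
  mean_average_precision(aps)
}

#' Save a model checkpoint
#'
#' Single JSON archive holding every parameter array, the config and its
#' hash, and the vocabulary; full double precision.
#'
#' @param model an `rae_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config),
              config_hash = config_hash(model$config),
              vocab = model$embeddings$vocab$tokens,
              emb = model$embeddings$vectors,
              W1 = model$rae$W1, b1 = model$rae$b1,
              W2 = model$rae$W2, b2 = model$rae$b2,
              Wlabel = model$Wlabel)
  # I(17) significant digits: exact round-trip for IEEE doubles
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path written by [save_model()].
#' @return an `rae_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cfg <- do.call(rae_config, obj$config[setdiff(names(obj$config), character())])
  tokens <- obj$vocab
  idx <- seq_along(tokens); names(idx) <- tokens
  vocab <- structure(list(tokens = tokens, index = idx,
                          unk_index = which(tokens == UNK_TOKEN)[1],
                          counts = rep(1L, length(tokens))),
                     class = "rae_vocab")
  emb <- new_embedding_table(vocab, as.matrix(obj$emb))
  rae <- structure(list(W1 = as.matrix(obj$W1), b1 = as.numeric(obj$b1),
                        W2 = as.matrix(obj$W2), b2 = as.numeric(obj$b2)),
                   class = "rae_params")
  structure(list(rae = rae, Wlabel = as.matrix(obj$Wlabel), embeddings = emb,
                 config = cfg), class = "rae_model")
}
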