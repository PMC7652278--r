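test_that("node classification is a two-class softmax", {
  expect_equal(classify_node(c(1, 1), matrix(0, 2, 2)), c(0.5, 0.5))
  # logits (ln 3, 0) -> (0.75, 0.25)
  W <- rbind(c(log(3), 0), c(0, 0))
  expect_equal(classify_node(c(1, 0), W), c(0.75, 0.25))
  # monotone in the first logit
  d1s <- vapply(seq(-3, 3, 0.5), function(l)
    classify_node(c(1, 0), rbind(c(l, 0), c(0.7, 0)))[1], 0)
  expect_true(all(diff(d1s) > 0))
  set.seed(1)
  for (i in 1:20) {
    d <- classify_node(rnorm(4), matrix(rnorm(8), 2))
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0))
  }
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), c(1, 0)), log(2))
  expect_equal(cross_entropy(c(0.25, 0.75), c(0, 1)), -log(0.75))
  expect_warning(ce <- cross_entropy(c(0, 1), c(1, 0)), "clipping")
  expect_equal(ce, -log(1e-12))
})

test_that("tree error collapses correctly at the alpha extremes", {
  model <- make_model(dim = 5, seed = 21)
  X <- lookup_tokens(model$embeddings, c("a", "b", "c", "d"))
  tree <- greedy_build_tree(X, model$rae)
  # alpha = 1: summed weighted reconstruction error, labels ignored
  e1_rel <- tree_error(tree, 1, model, alpha = 1)
  e1_irr <- tree_error(tree, 0, model, alpha = 1)
  expect_equal(e1_rel, e1_irr)
  expect_equal(e1_rel, tree$total_error, tolerance = 1e-12)
  # alpha = 0: summed node cross-entropies
  e0 <- tree_error(tree, 1, model, alpha = 0)
  ce_sum <- sum(vapply(seq_len(nrow(tree$triplets)), function(i) {
    cross_entropy(classify_node(tree$nodes[[tree$triplets[i, 1]]]$vector,
                                model$Wlabel), c(1, 0))
  }, 0))
  expect_equal(e0, ce_sum, tolerance = 1e-12)
  # single-token pair: no internal node, zero error
  single <- greedy_build_tree(lookup_tokens(model$embeddings, "a"), model$rae)
  expect_equal(tree_error(single, 1, model), 0)
})

test_that("the listwise ranking error matches its analytic cases", {
  expect_equal(ranking_error(1, 1), 0)                      # -log 1
  expect_equal(ranking_error(0.5, 1), log(2), tolerance = 1e-12)
  # two relevant candidates with d1 = 0.9, 0.8 -> -log(0.9/1 + 0.8/2)
  expect_equal(ranking_error(c(0.9, 0.8, 0.1), c(1, 1, 0)),
               -log(1.3), tolerance = 1e-12)
  expect_error(ranking_error(c(0.4, 0.2), c(0, 0)), "m = 0")
})

test_that("ranking-error variants assign the stated denominators", {
  d1 <- c(0.9, 0.3, 0.8, 0.5)
  labels <- c(1, 0, 1, 0)
  # relevant_index: relevant candidates ranked among themselves
  expect_equal(ranking_denominators(d1, labels, "relevant_index"),
               c(1, 0, 2, 0))
  # global_rank: positions within the full ranking (0.9, 0.8, 0.5, 0.3)
  expect_equal(ranking_denominators(d1, labels, "global_rank"),
               c(1, 0, 2, 0))
  d1b <- c(0.2, 0.9, 0.4, 0.5)
  expect_equal(ranking_denominators(d1b, labels, "global_rank"),
               c(4, 0, 3, 0))
  expect_equal(ranking_error(d1b, labels, "global_rank"),
               -log(0.2 / 4 + 0.4 / 3), tolerance = 1e-12)
})

test_that("the per-question loss combines its parts with beta", {
  cs <- make_cset(list(c("a", "b", "c"), c("b", "d"), c("a", "d", "e")),
                  c(1, 0, 1))
  model0 <- make_model(dim = 5, seed = 22,
                       config = rae_config(vector_dim = 5, beta = 0, seed = 22))
  model1 <- make_model(dim = 5, seed = 22,
                       config = rae_config(vector_dim = 5, beta = 1, seed = 22))
  model5 <- make_model(dim = 5, seed = 22,
                       config = rae_config(vector_dim = 5, beta = 0.5, seed = 22))
  l0 <- question_loss(cs, model0)   # pure per-pair error sum
  l1 <- question_loss(cs, model1)   # pure ranking error
  l5 <- question_loss(cs, model5)
  expect_equal(l5, 0.5 * l1 + 0.5 * l0, tolerance = 1e-12)
  d1 <- score_candidates(cs, model1)
  expect_equal(l1, ranking_error(d1, cs$labels), tolerance = 1e-10)
})

test_that("the objective averages question losses and adds the L2 term", {
  csets <- make_random_csets(n_q = 3, seed = 31)
  cfg0 <- rae_config(vector_dim = 5, lambda_reg = 0, seed = 23)
  model <- make_model(dim = 5, seed = 23, config = cfg0)
  expect_equal(objective(csets[1], model), question_loss(csets[[1]], model),
               tolerance = 1e-10)
  obj0 <- objective(csets, model)
  lam <- 0.01
  model_l <- model
  model_l$config$lambda_reg <- lam
  sqn <- sum(model$rae$W1^2) + sum(model$rae$b1^2) + sum(model$rae$W2^2) +
    sum(model$rae$b2^2) + sum(model$Wlabel^2)
  expect_equal(objective(csets, model_l), obj0 + lam / 2 * sqn,
               tolerance = 1e-10)
})

test_that("the analytic gradient matches central differences on small instances", {
  # a handful here; the full 50-instance sweep runs in the acceptance suite
  for (seed in 1:5) {
    model <- make_model(dim = 5, tokens = letters[1:8], seed = seed,
                        config = rae_config(vector_dim = 5, alpha = 0.3,
                                            beta = 0.4, lambda_reg = 1e-3,
                                            seed = seed), emb_scale = 10)
    csets <- make_random_csets(n_q = 2, n_cand = 3, n_tok = 4,
                               tokens = letters[1:8], seed = 100 + seed)
    expect_lt(gradient_fd_max_relerr(csets, model), 1e-6)
  }
})

test_that("the regulariser gradient is exactly lambda * theta", {
  model <- make_model(dim = 4, seed = 24,
                      config = rae_config(vector_dim = 4, lambda_reg = 0.05,
                                          alpha = 1, beta = 0, seed = 24))
  # a single-token pair contributes no tree error at alpha = 1, beta = 0,
  # so the data part of the gradient vanishes for W2 and Wlabel
  cs <- make_cset(list("a"), 1)
  g <- gradient(list(cs), model)
  expect_equal(g$W2, 0.05 * model$rae$W2, tolerance = 1e-12)
  expect_equal(g$Wlabel, 0.05 * model$Wlabel, tolerance = 1e-12)
})

test_that("candidate ranking sorts by probability with stable ties", {
  cs <- make_cset(list(c("a", "b"), c("c", "d"), c("e", "f")), c(1, 0, 0))
  pr <- rank_candidates(cs, d1 = c(0.2, 0.9, 0.2))
  expect_equal(attr(pr, "order"), c(2L, 1L, 3L))
  # all equal -> original order preserved
  pr_tie <- rank_candidates(cs, d1 = c(0.5, 0.5, 0.5))
  expect_equal(attr(pr_tie, "order"), 1:3)
  # permutation property: nothing lost or duplicated before truncation
  set.seed(2)
  for (i in 1:10) {
    d1 <- runif(3)
    expect_setequal(attr(rank_candidates(cs, d1 = d1), "order"), 1:3)
  }
  # truncation to the cutoff
  big <- make_cset(lapply(1:15, function(i) c("a", "b")), rep(c(1, 0), c(1, 14)))
  expect_equal(nrow(rank_candidates(big, d1 = seq(1, 0.1, length.out = 15) *
                                      0.9)$ranked_snippets), 10)
})

test_that("the worked two-candidate example ranks as described", {
  cs <- make_cset(list(c("q", "s1"), c("q", "s2")), c(1, 0))
  # confident classifier: relevant candidate scored 1.00 vs 0.99
  pr_good <- rank_candidates(cs, d1 = c(1.00, 0.99))
  ord <- attr(pr_good, "order")
  expect_equal(ord[1], 1L)
  expect_equal(average_precision(cs$labels[ord], m = 1), 1.0)
  # hesitant classifier: 0.51 vs 0.52 puts the irrelevant snippet on top
  pr_bad <- rank_candidates(cs, d1 = c(0.51, 0.52))
  ordb <- attr(pr_bad, "order")
  expect_equal(ordb[1], 2L)
  expect_equal(average_precision(cs$labels[ordb], m = 1), 0.5)
})

test_that("models survive a checkpoint round-trip", {
  model <- make_model(dim = 4, seed = 25)
  csets <- make_random_csets(n_q = 1, tokens = letters[1:10], seed = 41)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(back$rae$W1, model$rae$W1, tolerance = 1e-15)
  expect_equal(back$embeddings$vectors, model$embeddings$vectors,
               tolerance = 1e-15)
  expect_equal(score_candidates(csets[[1]], back),
               score_candidates(csets[[1]], model), tolerance = 1e-12)
})
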