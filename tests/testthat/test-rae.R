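params_1d <- function() {
  structure(list(W1 = matrix(c(1, 1), 1, 2), b1 = 0.25,
                 W2 = matrix(c(2, 3), 2, 1), b2 = c(0, 0)),
            class = "rae_params")
}

test_that("composition applies the tanh affine map with optional normalisation", {
  p0 <- structure(list(W1 = matrix(0, 2, 4), b1 = c(0, 0),
                       W2 = matrix(0, 4, 2), b2 = numeric(4)),
                  class = "rae_params")
  expect_equal(compose(c(1, 2), c(3, 4), p0, normalize = FALSE), c(0, 0))
  expect_equal(compose(0.5, 0.25, params_1d(), normalize = FALSE),
               tanh(1.0))
  # unit length whenever the pre-activation is nonzero
  set.seed(1)
  pr <- init_rae_params(5, seed = 2)
  for (i in 1:20) {
    p <- compose(rnorm(5), rnorm(5), pr, normalize = TRUE)
    expect_equal(sqrt(sum(p^2)), 1, tolerance = 1e-12)
  }
  expect_error(compose(c(1, 2, 3), c(1, 2), pr), "length")
})

test_that("reconstruction is the stated linear map", {
  expect_equal(reconstruct(0.5, params_1d()), list(c1 = 1.0, c2 = 1.5))
  pr <- init_rae_params(4, seed = 3)
  p <- rnorm(4)
  a <- 2.5
  r1 <- reconstruct(p, pr)
  ra <- reconstruct(a * p, pr)
  expect_equal(c(ra$c1, ra$c2) - pr$b2, a * (c(r1$c1, r1$c2) - pr$b2),
               tolerance = 1e-12)
})

test_that("reconstruction errors follow their closed forms", {
  expect_equal(recon_error_plain(c(1, 2), c(3, 4), c(1, 2), c(3, 4)), 0)
  expect_equal(recon_error_plain(c(1, 0), c(5, 5), c(0, 0), c(5, 5)), 0.5)
  set.seed(4)
  for (i in 1:10) {
    c1 <- rnorm(3); c2 <- rnorm(3); c1p <- rnorm(3); c2p <- rnorm(3)
    expect_equal(recon_error_plain(c1, c2, c1p, c2p),
                 0.5 * (sum((c1 - c1p)^2) + sum((c2 - c2p)^2)))
    # weighted form is symmetric under swapping the children
    expect_equal(recon_error_weighted(c1, c2, c1p, c2p, 3, 1),
                 recon_error_weighted(c2, c1, c2p, c1p, 1, 3))
    # equal counts give the arithmetic mean of squared distances
    expect_equal(recon_error_weighted(c1, c2, c1p, c2p, 2, 2),
                 (sum((c1 - c1p)^2) + sum((c2 - c2p)^2)) / 2)
  }
  # n1 = 3, n2 = 1 with squared distances 0.2 and 0.6 -> 0.3
  expect_equal(recon_error_weighted(c(sqrt(0.2)), c(sqrt(0.6)), 0, 0, 3, 1),
               0.3)
  expect_error(recon_error_weighted(1, 1, 0, 0, 0, 1), ">= 1")
})

test_that("greedy construction merges the cheapest adjacent pair first", {
  # with W2 = 0 the reconstruction is zero, so the weighted merge error is
  # the count-weighted mean of the children's squared norms: making x2, x3
  # tiny forces their merge first
  pr <- init_rae_params(2, seed = 5)
  pr$W2[] <- 0; pr$b2[] <- 0
  leaves <- cbind(c(2, 0), c(0.01, 0), c(0, 0.01), c(0, 3), c(1.5, 1.5))
  tree <- greedy_build_tree(leaves, pr)
  expect_equal(unname(tree$triplets[1, ]), c(6L, 2L, 3L))
  # after replacing (x2, x3) by y1 the sequence is (x1, y1, x4, x5)
  expect_equal(tree$L, 5)
  expect_equal(nrow(tree$triplets), 4)
})

test_that("composition trees satisfy their structural invariants", {
  pr <- init_rae_params(4, seed = 6)
  set.seed(7)
  for (L in c(1, 2, 5, 9)) {
    leaves <- matrix(rnorm(4 * L), 4)
    tree <- greedy_build_tree(leaves, pr)
    expect_equal(nrow(tree$triplets), L - 1)
    expect_equal(tree$nodes[[tree$root]]$n, L)
    for (i in seq_len(nrow(tree$triplets))) {
      pid <- tree$triplets[i, 1]
      expect_equal(tree$nodes[[pid]]$n,
                   tree$nodes[[tree$triplets[i, 2]]]$n +
                     tree$nodes[[tree$triplets[i, 3]]]$n)
      expect_gte(tree$nodes[[pid]]$recon_error, 0)
      expect_equal(sqrt(sum(tree$nodes[[pid]]$vector^2)), 1,
                   tolerance = 1e-12)
    }
    # in-order traversal of the leaves recovers the input order
    inorder <- integer()
    rec <- function(id) {
      ch <- tree$nodes[[id]]$children
      if (is.null(ch)) inorder <<- c(inorder, id)
      else { rec(ch[1]); rec(ch[2]) }
    }
    rec(tree$root)
    expect_equal(inorder, seq_len(L))
    # determinism
    tree2 <- greedy_build_tree(leaves, pr)
    expect_identical(tree$triplets, tree2$triplets)
  }
  expect_equal(greedy_build_tree(matrix(rnorm(4), 4), pr)$total_error, 0)
  expect_error(greedy_build_tree(matrix(numeric(), 4, 0), pr), "leaf")
})

test_that("two leaves always produce exactly one merge", {
  set.seed(8)
  for (i in 1:5) {
    pr <- init_rae_params(3, seed = i)
    tree <- greedy_build_tree(matrix(rnorm(6), 3), pr)
    expect_equal(nrow(tree$triplets), 1)
    expect_equal(unname(tree$triplets[1, ]), c(3L, 1L, 2L))
  }
})

test_that("the R and compiled greedy constructions agree", {
  pr <- init_rae_params(5, seed = 9)
  set.seed(10)
  for (i in 1:10) {
    L <- sample(3:8, 1)
    leaves <- matrix(rnorm(5 * L), 5)
    tree <- greedy_build_tree(leaves, pr)
    cpp <- raerank:::cpp_greedy_structure(leaves, pr$W1, pr$b1, pr$W2,
                                          pr$b2, matrix(0, 2, 5), TRUE, TRUE)
    expect_equal(unname(tree$triplets[, 2:3]), unname(cpp[, 1:2]))
  }
})

test_that("exhaustive search enumerates the Catalan number of trees", {
  pr <- init_rae_params(3, seed = 11)
  set.seed(12)
  t4 <- exhaustive_best_tree(matrix(rnorm(12), 3), pr)
  expect_equal(attr(t4, "n_trees"), 5)          # Catalan(3)
  t2 <- exhaustive_best_tree(matrix(rnorm(6), 3), pr)
  expect_equal(attr(t2, "n_trees"), 1)
  expect_error(exhaustive_best_tree(matrix(rnorm(33), 3), pr), "10 leaves")
})

test_that("the exhaustive tree never exceeds the greedy tree's error", {
  pr <- init_rae_params(4, seed = 13)
  set.seed(14)
  for (i in 1:15) {
    L <- sample(5:7, 1)
    leaves <- matrix(rnorm(4 * L), 4)
    g <- greedy_build_tree(leaves, pr)
    e <- exhaustive_best_tree(leaves, pr)
    expect_lte(e$total_error, g$total_error + 1e-12)
  }
  # for two leaves the single bracketing makes them identical
  leaves <- matrix(rnorm(8), 4)
  expect_equal(exhaustive_best_tree(leaves, pr)$total_error,
               greedy_build_tree(leaves, pr)$total_error)
})

test_that("trees serialise to bracketed strings", {
  pr <- init_rae_params(2, seed = 15)
  pr$W2[] <- 0
  leaves <- cbind(c(2, 0), c(0.01, 0), c(0, 0.01))
  tree <- greedy_build_tree(leaves, pr)
  expect_equal(tree_to_string(tree), "(x1 (x2 x3))")
  single <- greedy_build_tree(matrix(c(1, 1), 2), pr)
  expect_equal(tree_to_string(single), "x1")
})
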