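#' @title Recursive autoencoder core
#' @description
#' The unsupervised building block: two adjacent node vectors `c1`, `c2`
#' are composed into a parent `p = tanh(W1 [c1; c2] + b1)` (optionally
#' scaled to unit length), the parent is decoded back with
#' `[c1'; c2'] = W2 p + b2`, and the merge is scored by how well the
#' children are reconstructed. A composition tree over a token sequence is
#' built greedily: the adjacent pair with the lowest reconstruction error
#' is merged until a single root remains. Reconstruction error comes in the
#' plain form `1/2 ||[c1;c2] - [c1';c2']||^2` and the word-count-weighted
#' form `(n1 ||c1 - c1'||^2 + n2 ||c2 - c2'||^2) / (n1 + n2)` used during
#' tree construction and training.
#' @name rae_core
NULL

#' Initialise RAE parameters
#'
#' Composition and reconstruction weights drawn uniformly from
#' \[-r, r\] with `r = 1/sqrt(2 * vector_dim)`; biases start at zero.
#'
#' @param vector_dim node vector dimensionality.
#' @param seed integer seed.
#' @return object of class `rae_params`: `W1` (dim x 2 dim), `b1` (dim),
#'   `W2` (2 dim x dim), `b2` (2 dim).
#' @export
init_rae_params <- function(vector_dim, seed = 42L) {
  n <- as.integer(vector_dim)
  r <- 1 / sqrt(2 * n)
  with_seed(seed, {
    structure(list(W1 = matrix(runif(n * 2 * n, -r, r), n, 2 * n),
                   b1 = numeric(n),
                   W2 = matrix(runif(2 * n * n, -r, r), 2 * n, n),
                   b2 = numeric(2 * n)),
              class = "rae_params")
  })
}

check_vec <- function(v, n, what) {
  if (!is.numeric(v) || length(v) != n)
    stop(what, " must be a numeric vector of length ", n, call. = FALSE)
}

#' Compose two child vectors into a parent
#'
#' `p = tanh(W1 [c1; c2] + b1)`, optionally scaled to unit Euclidean
#' length. Normalisation guards against the degenerate optimum where all
#' node vectors shrink toward zero to make reconstruction trivially cheap.
#'
#' @param c1,c2 child vectors of length `vector_dim`.
#' @param params an `rae_params`.
#' @param normalize scale the parent to unit length (default TRUE).
#' @return the parent vector.
#' @export
compose <- function(c1, c2, params, normalize = TRUE) {
  n <- length(params$b1)
  check_vec(c1, n, "c1"); check_vec(c2, n, "c2")
  p <- tanh(drop(params$W1 %*% c(c1, c2)) + params$b1)
  if (normalize) {
    nrm <- sqrt(sum(p^2))
    if (nrm > 0) p <- p / nrm
  }
  p
}

#' Reconstruct the children from a parent vector
#'
#' `[c1'; c2'] = W2 p + b2`, split into the two reconstructed children.
#'
#' @param p parent vector of length `vector_dim`.
#' @param params an `rae_params`.
#' @return list with `c1` and `c2`.
#' @export
reconstruct <- function(p, params) {
  n <- length(params$b1)
  check_vec(p, n, "p")
  r <- drop(params$W2 %*% p) + params$b2
  list(c1 = r[seq_len(n)], c2 = r[n + seq_len(n)])
}

#' Plain reconstruction error
#'
#' `1/2 ||[c1; c2] - [c1'; c2']||^2`.
#'
#' @param c1,c2 original children.
#' @param c1p,c2p reconstructed children.
#' @return nonnegative scalar.
#' @export
recon_error_plain <- function(c1, c2, c1p, c2p) {
  0.5 * (sum((c1 - c1p)^2) + sum((c2 - c2p)^2))
}

#' Word-count-weighted reconstruction error
#'
#' `(n1 ||c1 - c1'||^2 + n2 ||c2 - c2'||^2) / (n1 + n2)`; the counts are
#' the numbers of words under each child, so heavier subtrees weigh more.
#' Note there is no 1/2 factor, unlike the plain form.
#'
#' @param c1,c2 original children.
#' @param c1p,c2p reconstructed children.
#' @param n1,n2 word counts under each child (>= 1).
#' @return nonnegative scalar.
#' @export
recon_error_weighted <- function(c1, c2, c1p, c2p, n1, n2) {
  if (n1 < 1 || n2 < 1) stop("word counts must be >= 1", call. = FALSE)
  (n1 * sum((c1 - c1p)^2) + n2 * sum((c2 - c2p)^2)) / (n1 + n2)
}

# error of merging two current nodes, under the configured criterion
node_merge_error <- function(v1, v2, n1, n2, params, normalize, weighted) {
  p <- compose(v1, v2, params, normalize)
  r <- reconstruct(p, params)
  if (weighted) recon_error_weighted(v1, v2, r$c1, r$c2, n1, n2)
  else recon_error_plain(v1, v2, r$c1, r$c2)
}

new_composition_tree <- function(nodes, triplets, L) {
  root <- if (L == 1) 1L else 2L * L - 1L
  total <- if (L == 1) 0 else
    sum(vapply(nodes[(L + 1):(2 * L - 1)], `[[`, 0, "recon_error"))
  structure(list(nodes = nodes, triplets = triplets, L = L, root = root,
                 total_error = total),
            class = "composition_tree")
}

#' @export
print.composition_tree <- function(x, ...) {
  cat(sprintf("<composition_tree> %d leaves, total error %.6g\n%s\n",
              x$L, x$total_error, tree_to_string(x)))
  invisible(x)
}

#' Greedily build a composition tree
#'
#' Starting from the leaf sequence, repeatedly computes the reconstruction
#' error of every adjacent pair and merges the cheapest one (leftmost on
#' ties) until a single root remains. Node ids: leaves `1..L` in input
#' order, internal nodes `L+1 .. 2L-1` in merge order; the triplet matrix
#' rows are `(parent, left, right)` in merge (topological) order.
#'
#' @param leaves matrix with one column per leaf vector.
#' @param params an `rae_params`.
#' @param normalize unit-normalise parent vectors.
#' @param weighted use the word-count-weighted error as merge criterion
#'   (the plain form when FALSE).
#' @return object of class `composition_tree`: `nodes` (list with `vector`,
#'   `n`, `children`, `recon_error`), `triplets`, `L`, `root`,
#'   `total_error`.
#' @export
greedy_build_tree <- function(leaves, params, normalize = TRUE,
                              weighted = TRUE) {
  if (is.vector(leaves)) leaves <- matrix(leaves, ncol = 1)
  L <- ncol(leaves)
  if (L < 1) stop("at least one leaf required", call. = FALSE)
  nodes <- lapply(seq_len(L), function(i) {
    list(vector = leaves[, i], n = 1L, children = NULL, recon_error = NULL)
  })
  triplets <- matrix(integer(), 0, 3,
                     dimnames = list(NULL, c("parent", "left", "right")))
  if (L == 1) return(new_composition_tree(nodes, triplets, L))

  act <- seq_len(L)
  errs <- vapply(seq_len(L - 1), function(j) {
    node_merge_error(nodes[[act[j]]]$vector, nodes[[act[j + 1]]]$vector,
                     nodes[[act[j]]]$n, nodes[[act[j + 1]]]$n,
                     params, normalize, weighted)
  }, 0)
  for (step in seq_len(L - 1)) {
    best <- which.min(errs)          # which.min returns the first minimum
    a <- act[best]; b <- act[best + 1]
    p <- compose(nodes[[a]]$vector, nodes[[b]]$vector, params, normalize)
    r <- reconstruct(p, params)
    err <- if (weighted)
      recon_error_weighted(nodes[[a]]$vector, nodes[[b]]$vector, r$c1, r$c2,
                           nodes[[a]]$n, nodes[[b]]$n)
    else recon_error_plain(nodes[[a]]$vector, nodes[[b]]$vector, r$c1, r$c2)
    pid <- L + step
    nodes[[pid]] <- list(vector = p, n = nodes[[a]]$n + nodes[[b]]$n,
                         children = c(a, b), recon_error = err)
    triplets <- rbind(triplets, c(pid, a, b))
    act[best] <- pid
    act <- act[-(best + 1)]
    errs <- errs[-best]
    recompute <- function(j) {
      node_merge_error(nodes[[act[j]]]$vector, nodes[[act[j + 1]]]$vector,
                       nodes[[act[j]]]$n, nodes[[act[j + 1]]]$n,
                       params, normalize, weighted)
    }
    if (best > 1) errs[best - 1] <- recompute(best - 1)
    if (best <= length(errs)) errs[best] <- recompute(best)
  }
  new_composition_tree(nodes, triplets, L)
}

#' Bracketed string form of a composition tree
#'
#' @param tree a `composition_tree`.
#' @param labels optional leaf labels (default `x1..xL`).
#' @return character scalar like `"((x1 x2) x3)"`.
#' @export
tree_to_string <- function(tree, labels = paste0("x", seq_len(tree$L))) {
  rec <- function(id) {
    nd <- tree$nodes[[id]]
    if (is.null(nd$children)) return(labels[id])
    paste0("(", rec(nd$children[1]), " ", rec(nd$children[2]), ")")
  }
  rec(tree$root)
}

#' Exhaustive minimum-error composition tree (test oracle)
#'
#' Enumerates every binary bracketing of the leaf sequence (Catalan(L-1)
#' trees), evaluates each one's summed reconstruction error bottom-up, and
#' returns the minimiser. Ties are broken toward the first tree in
#' lexicographic bracketing order (splits enumerated left to right,
#' recursively). Intended as an oracle for the greedy construction; refuses
#' more than 10 leaves.
#'
#' @inheritParams greedy_build_tree
#' @return a `composition_tree` with attribute `n_trees` (number of
#'   bracketings searched).
#' @export
exhaustive_best_tree <- function(leaves, params, normalize = TRUE,
                                 weighted = TRUE) {
  if (is.vector(leaves)) leaves <- matrix(leaves, ncol = 1)
  L <- ncol(leaves)
  if (L < 1) stop("at least one leaf required", call. = FALSE)
  if (L > 10) stop("exhaustive search refuses more than 10 leaves",
                   call. = FALSE)
  # enumerate all subtrees over span [i, j]; each entry: vector, count,
  # total error, shape (nested pair of leaf ids)
  memo <- new.env(parent = emptyenv())
  span <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == j) {
      list(list(vector = leaves[, i], n = 1L, err = 0, shape = i))
    } else {
      out <- list()
      for (k in i:(j - 1)) {
        for (lt in span(i, k)) for (rt in span(k + 1, j)) {
          p <- compose(lt$vector, rt$vector, params, normalize)
          r <- reconstruct(p, params)
          e <- if (weighted)
            recon_error_weighted(lt$vector, rt$vector, r$c1, r$c2, lt$n, rt$n)
          else recon_error_plain(lt$vector, rt$vector, r$c1, r$c2)
          out[[length(out) + 1]] <- list(vector = p, n = lt$n + rt$n,
                                         err = lt$err + rt$err + e,
                                         shape = list(lt$shape, rt$shape))
        }
      }
      out
    }
    memo[[key]] <- res
    res
  }
  all_trees <- span(1, L)
  errs <- vapply(all_trees, `[[`, 0, "err")
  best <- all_trees[[which.min(errs)]]   # first minimum = lexicographic

  # materialise the winning shape as a composition_tree
  nodes <- lapply(seq_len(L), function(i) {
    list(vector = leaves[, i], n = 1L, children = NULL, recon_error = NULL)
  })
  triplets <- matrix(integer(), 0, 3,
                     dimnames = list(NULL, c("parent", "left", "right")))
  build <- function(shape) {
    if (!is.list(shape)) return(shape)  # leaf id
    a <- build(shape[[1]]); b <- build(shape[[2]])
    p <- compose(nodes[[a]]$vector, nodes[[b]]$vector, params, normalize)
    r <- reconstruct(p, params)
    e <- if (weighted)
      recon_error_weighted(nodes[[a]]$vector, nodes[[b]]$vector, r$c1, r$c2,
                           nodes[[a]]$n, nodes[[b]]$n)
    else recon_error_plain(nodes[[a]]$vector, nodes[[b]]$vector, r$c1, r$c2)
    pid <- length(nodes) + 1L
    nodes[[pid]] <<- list(vector = p, n = nodes[[a]]$n + nodes[[b]]$n,
                          children = c(a, b), recon_error = e)
    triplets <<- rbind(triplets, c(pid, a, b))
    pid
  }
  build(best$shape)
  tree <- new_composition_tree(nodes, triplets, L)
  attr(tree, "n_trees") <- length(all_trees)
  tree
}
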