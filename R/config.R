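#' Run configuration
#'
#' Bundles every tunable of the pipeline: model size, loss weights,
#' optimisation settings and preprocessing caps. All downstream functions
#' take a config object so a run is fully described by (config, seed, data).
#'
#' @param vector_dim embedding / node vector dimensionality (>= 2).
#' @param alpha weight of the reconstruction error against the cross-entropy
#'   error in the per-node loss, in `[0, 1]`.
#' @param beta weight of the listwise ranking error against the summed
#'   per-pair tree errors in the per-question loss, in `[0, 1]`.
#' @param lambda_reg L2 regularisation strength (>= 0).
#' @param learning_rate SGD step size.
#' @param epochs number of passes over the training questions.
#' @param seed integer seed controlling every stochastic step.
#' @param top_n_documents documents per question the caller is expected to
#'   supply; an input contract only -- retrieval itself is out of scope.
#' @param max_span_segments maximum number of contiguous atomic segments a
#'   candidate snippet may span.
#' @param ranking_error_variant `"relevant_index"` (literal formula: the
#'   i-th relevant candidate by descending predicted probability is divided
#'   by i) or `"global_rank"` (divided by its position in the full ranking).
#' @param normalize_parent scale every composed parent vector to unit
#'   Euclidean length (guards against the degenerate shrink-to-zero optimum
#'   of the reconstruction objective).
#' @param merge_criterion `"weighted"` (word-count-weighted reconstruction
#'   error) or `"plain"` (unweighted) as the greedy merge selection error.
#' @param fine_tune_embeddings update embedding rows during supervised
#'   training.
#' @param regularize_embeddings include embedding rows in the L2 penalty.
#' @param min_count minimum token frequency for vocabulary inclusion.
#' @param overlap_threshold fraction of a candidate's characters that must
#'   overlap a gold snippet for a positive label.
#' @param cutoff maximum number of snippets returned per question and the
#'   average-precision truncation depth.
#'
#' @return an object of class `rae_config` (a validated list).
#' @export
rae_config <- function(vector_dim = 50, alpha = 0.2, beta = 0.5,
                       lambda_reg = 1e-4, learning_rate = 0.01, epochs = 30,
                       seed = 42L, top_n_documents = 10L,
                       max_span_segments = 3L,
                       ranking_error_variant = c("relevant_index", "global_rank"),
                       normalize_parent = TRUE,
                       merge_criterion = c("weighted", "plain"),
                       fine_tune_embeddings = TRUE,
                       regularize_embeddings = FALSE,
                       min_count = 1L, overlap_threshold = 0.5,
                       cutoff = 10L) {
  ranking_error_variant <- match.arg(ranking_error_variant)
  merge_criterion <- match.arg(merge_criterion)
  stopifnot(vector_dim >= 2, alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            lambda_reg >= 0, learning_rate > 0, epochs >= 0,
            max_span_segments >= 1, overlap_threshold > 0,
            overlap_threshold <= 1, cutoff >= 1)
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  cfg <- list(vector_dim = as.integer(vector_dim), alpha = alpha, beta = beta,
              lambda_reg = lambda_reg, learning_rate = learning_rate,
              epochs = as.integer(epochs), seed = seed,
              top_n_documents = as.integer(top_n_documents),
              max_span_segments = as.integer(max_span_segments),
              ranking_error_variant = ranking_error_variant,
              normalize_parent = isTRUE(normalize_parent),
              merge_criterion = merge_criterion,
              fine_tune_embeddings = isTRUE(fine_tune_embeddings),
              regularize_embeddings = isTRUE(regularize_embeddings),
              min_count = as.integer(min_count),
              overlap_threshold = overlap_threshold,
              cutoff = as.integer(cutoff))
  structure(cfg, class = "rae_config")
}

#' @export
print.rae_config <- function(x, ...) {
  cat("<rae_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# short hash of a config for run logs (no digest dependency: sum over the
# deparse bytes is enough to spot a changed config)
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 0xFFFFFFFF)
}
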