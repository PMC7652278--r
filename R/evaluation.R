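#' @title Ranking evaluation
#' @description
#' Truncated average precision and MAP for snippet rankings, and the
#' paired-batch comparison arithmetic used on per-batch MAP tables: mean
#' paired differences, relative improvements of batch-averaged MAP, and
#' two-sided paired t-tests with effect sizes and confidence intervals.
#' @name evaluation
NULL

#' Truncated average precision
#'
#' `(1/m) * sum over relevant items at rank k <= cutoff of
#' (relevant items at ranks <= k) / k`. The divisor defaults to the gold
#' relevant count `m`, uncapped by the cutoff (trec-style); set
#' `divisor = "capped"` for `min(m, cutoff)`.
#'
#' @param ranked_labels 0/1 relevance down the ranked list.
#' @param cutoff evaluation depth (default 10).
#' @param m gold relevant count; defaults to `sum(ranked_labels)` (pass the
#'   true count when the list is already truncated).
#' @param divisor `"gold"` (default) or `"capped"`.
#' @return scalar in \[0, 1\].
#' @export
average_precision <- function(ranked_labels, cutoff = 10L, m = NULL,
                              divisor = c("gold", "capped")) {
  divisor <- match.arg(divisor)
  stopifnot(all(ranked_labels %in% c(0, 1)))
  if (is.null(m)) m <- sum(ranked_labels)
  if (m < 1) stop("average precision undefined: no relevant item (m = 0)",
                  call. = FALSE)
  top <- head(ranked_labels, cutoff)
  hits <- which(top == 1)
  denom <- if (divisor == "gold") m else min(m, cutoff)
  if (!length(hits)) return(0)
  sum(cumsum(top)[hits] / hits) / denom
}

#' Mean average precision
#'
#' @param aps per-question average precisions.
#' @return their arithmetic mean.
#' @export
mean_average_precision <- function(aps) {
  if (!length(aps)) stop("no questions", call. = FALSE)
  mean(aps)
}

# pull matched per-batch values for two systems out of an eval table
paired_maps <- function(table, system_a, system_b, years = NULL,
                        batches = NULL) {
  df <- as.data.frame(table)
  if (!is.null(years)) df <- df[df$year %in% years, , drop = FALSE]
  if (!is.null(batches)) df <- df[df$batch %in% batches, , drop = FALSE]
  a <- df[df$system == system_a, , drop = FALSE]
  b <- df[df$system == system_b, , drop = FALSE]
  key_a <- paste(a$year, a$batch)
  key_b <- paste(b$year, b$batch)
  keys <- sort(unique(paste(df$year, df$batch)))
  miss <- c(setdiff(keys, key_a), setdiff(keys, key_b))
  if (length(miss))
    stop("missing table cell(s) for batch(es): ",
         paste(unique(miss), collapse = "; "), call. = FALSE)
  list(a = a$map[match(keys, key_a)], b = b$map[match(keys, key_b)],
       keys = keys)
}

#' Mean paired MAP difference between two systems
#'
#' Mean over the matched batches of `MAP_a - MAP_b`.
#'
#' @param table an `eval_table` (see [read_eval_table()]).
#' @param system_a,system_b system names in the table.
#' @param years,batches optional filters; by default all matched batches.
#' @return scalar difference (full precision; round to 4 decimals for
#'   reporting).
#' @export
mean_paired_difference <- function(table, system_a, system_b, years = NULL,
                                   batches = NULL) {
  pm <- paired_maps(table, system_a, system_b, years, batches)
  mean(pm$a - pm$b)
}

#' Relative improvement of batch-averaged MAP
#'
#' `100 * (mean(MAP_a) / mean(MAP_b) - 1)` over the matched batches.
#'
#' @inheritParams mean_paired_difference
#' @return percentage (full precision; the convention in reports is one
#'   decimal).
#' @export
relative_improvement <- function(table, system_a, system_b, years = NULL,
                                 batches = NULL) {
  pm <- paired_maps(table, system_a, system_b, years, batches)
  mb <- mean(pm$b)
  if (mb == 0) stop("zero baseline mean MAP", call. = FALSE)
  100 * (mean(pm$a) / mb - 1)
}

#' Two-sided paired t-test between two systems
#'
#' Textbook paired t on the per-batch MAP differences: `t = dbar / (s /
#' sqrt(n))` with `s` the sample standard deviation (n - 1 divisor),
#' `df = n - 1`, two-sided p, and the 95 percent confidence interval
#' `dbar +/- t_{0.975, df} s / sqrt(n)`. The effect size is `dbar / s`.
#'
#' @inheritParams mean_paired_difference
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class `ttest_result`: `mean_diff`, `t`, `df`,
#'   `p_value`, `effect_size`, `conf_int`, `n`.
#' @export
paired_ttest <- function(table, system_a, system_b, years = NULL,
                         batches = NULL, conf_level = 0.95) {
  pm <- paired_maps(table, system_a, system_b, years, batches)
  d <- pm$a - pm$b
  n <- length(d)
  if (n < 2) stop("need at least 2 paired batches", call. = FALSE)
  s <- sd(d)
  if (s == 0) stop("zero-variance differences: t statistic undefined",
                   call. = FALSE)
  tt <- t.test(pm$a, pm$b, paired = TRUE, conf.level = conf_level)
  structure(list(mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 effect_size = mean(d) / s,
                 conf_int = unname(as.numeric(tt$conf.int)), n = n,
                 system_a = system_a, system_b = system_b),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(paste0("Paired t-test %s vs %s over %d batches:\n",
                     "  mean diff %.4f, t(%d) = %.4f, p = %.4f, ES = %.4f,",
                     " 95%% CI [%.4f, %.4f]\n"),
              x$system_a, x$system_b, x$n, x$mean_diff, x$df, x$t, x$p_value,
              x$effect_size, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Score predictions against gold questions
#'
#' Computes per-question truncated average precision of prediction records
#' against the gold snippets, using the same overlap rule as training
#' labels, and the resulting MAP.
#'
#' @param predictions list of prediction records.
#' @param questions list of `question_record` objects.
#' @param cutoff truncation depth.
#' @param threshold overlap fraction for counting a returned snippet as
#'   relevant.
#' @return list with `per_question` (data frame `question_id`, `ap`) and
#'   `map`.
#' @export
evaluate_predictions <- function(predictions, questions, cutoff = 10L,
                                 threshold = 0.5) {
  qmap <- stats::setNames(questions,
                          vapply(questions, `[[`, "", "id"))
  rows <- lapply(predictions, function(p) {
    q <- qmap[[p$question_id]]
    if (is.null(q)) stop("unknown question id ", p$question_id, call. = FALSE)
    m <- nrow(q$gold_snippets)
    if (m == 0) return(NULL)
    sn <- p$ranked_snippets
    # each gold snippet credits at most one returned snippet (the highest
    # ranked one overlapping it), so AP stays within [0, 1]
    covered <- logical(m)
    labs <- if (nrow(sn) == 0) integer() else
      vapply(seq_len(nrow(sn)), function(j) {
        cand <- list(doc_id = sn$doc_id[j], begin = sn$begin[j],
                     end = sn$end[j])
        len <- cand$end - cand$begin
        g <- q$gold_snippets
        ov <- ifelse(g$doc_id == cand$doc_id,
                     pmax(0, pmin(cand$end, g$end) - pmax(cand$begin, g$begin)),
                     0)
        hit <- which(!covered & ov / len >= threshold)
        if (length(hit)) {
          covered[hit[1]] <<- TRUE
          1L
        } else 0L
      }, 0L)
    data.frame(question_id = p$question_id,
               ap = if (length(labs)) average_precision(labs, cutoff, m) else 0,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  per_q <- do.call(rbind, rows)
  list(per_question = per_q, map = mean_average_precision(per_q$ap))
}
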