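test_that("average precision follows the truncated formula", {
  expect_equal(average_precision(c(1, 1, 0, 0), m = 2), 1.0)
  expect_equal(average_precision(c(0, 1, 0), m = 1), 0.5)
  expect_equal(average_precision(c(1, 0, 1, 0), m = 2), (1 + 2 / 3) / 2)
  # items past the cutoff never matter
  expect_equal(average_precision(c(rep(0, 10), 1), m = 1), 0)
  expect_equal(average_precision(c(1, rep(0, 10), 1), m = 2, cutoff = 10),
               average_precision(c(1, rep(0, 10), 0), m = 2, cutoff = 10))
  # swapping a relevant item downward never raises AP
  set.seed(3)
  for (i in 1:20) {
    labs <- sample(c(1, 1, 1, 0, 0, 0, 0, 0))
    k <- which(labs == 1)[1]
    if (k < length(labs) && labs[k + 1] == 0) {
      swapped <- labs
      swapped[c(k, k + 1)] <- swapped[c(k + 1, k)]
      expect_lte(average_precision(swapped, m = 3),
                 average_precision(labs, m = 3))
    }
  }
  expect_error(average_precision(c(0, 0)), "m = 0")
  # capped divisor variant
  labs <- c(rep(1, 10), rep(0, 2))
  expect_equal(average_precision(labs, m = 12, divisor = "capped"), 1.0)
})

test_that("MAP is the arithmetic mean and order-invariant", {
  expect_equal(mean_average_precision(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(mean_average_precision(c(1, 0)), 0.5)
  aps <- runif(9)
  expect_equal(mean_average_precision(aps),
               mean_average_precision(rev(aps)))
  expect_error(mean_average_precision(numeric()), "no questions")
})

test_that("mean paired differences reproduce the published comparison table", {
  tab <- read_eval_table(benchmark_table_path())
  expected <- c(CNN = 0.0249, RNN = 0.0240, LSTM = 0.0216, RAE = 0.0138,
                QL = 0.0245, SDM = 0.0217, BM25 = 0.0258)
  for (sys in names(expected)) {
    expect_equal(round(mean_paired_difference(tab, "our", sys), 4),
                 unname(expected[sys]))
  }
  # antisymmetry and the self-comparison
  expect_equal(mean_paired_difference(tab, "CNN", "our"),
               -mean_paired_difference(tab, "our", "CNN"))
  expect_equal(mean_paired_difference(tab, "our", "our"), 0)
  expect_error(mean_paired_difference(tab, "our", "nonexistent"), "missing")
})

test_that("relative improvements of batch-averaged MAP match the reports", {
  tab <- read_eval_table(benchmark_table_path())
  expect_equal(round(relative_improvement(tab, "our", "CNN", years = 2013), 1), 36.2)
  expect_equal(round(relative_improvement(tab, "our", "RNN", years = 2013), 1), 30.0)
  expect_equal(round(relative_improvement(tab, "our", "LSTM", years = 2013), 1), 26.8)
  expect_equal(round(relative_improvement(tab, "our", "RAE", years = 2013), 1), 18.6)
  expect_equal(round(relative_improvement(tab, "our", "QL", years = 2013), 1), 54.6)
  expect_equal(relative_improvement(tab, "our", "our"), 0)
})

test_that("the paired t-test follows the textbook convention", {
  mk_tab <- function(a, b) {
    df <- rbind(data.frame(system = "A", year = 2013, batch = seq_along(a),
                           map = a),
                data.frame(system = "B", year = 2013, batch = seq_along(b),
                           map = b))
    class(df) <- c("eval_table", "data.frame")
    df
  }
  # differences {1, 2, 3} (scaled by 0.1 to stay in [0, 1]):
  # dbar = 0.2, s = 0.1, t = 2 * sqrt(3)
  tt <- paired_ttest(mk_tab(c(0.4, 0.6, 0.8), c(0.3, 0.4, 0.5)), "A", "B")
  expect_equal(tt$mean_diff, 0.2)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$effect_size, 0.2 / 0.1, tolerance = 1e-12)
  expect_true(tt$conf_int[1] <= tt$mean_diff && tt$mean_diff <= tt$conf_int[2])
  # symmetric differences -> t = 0, p = 1
  tt0 <- paired_ttest(mk_tab(c(0.4, 0.5, 0.6), c(0.5, 0.5, 0.5)), "A", "B")
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p_value, 1)
  # degenerate: zero-variance differences (0.25 exactly representable)
  expect_error(paired_ttest(mk_tab(c(0.5, 0.75), c(0.25, 0.5)), "A", "B"),
               "zero-variance")
  # shared definition with the mean difference
  tab <- read_eval_table(benchmark_table_path())
  expect_equal(paired_ttest(tab, "our", "CNN")$mean_diff,
               mean_paired_difference(tab, "our", "CNN"))
})

test_that("prediction scoring applies the overlap rule against gold spans", {
  corpus <- generate_corpus(synth_config(n_questions = 6, seed = 17))
  cfg <- rae_config(epochs = 0)
  csets <- prepare_candidate_sets(corpus$questions, corpus$documents, cfg)
  # an oracle ranking (gold candidates first) must reach MAP 1
  preds <- lapply(csets, function(cs)
    rank_candidates(cs, d1 = 0.5 + 0.4 * cs$labels -
                      1e-6 * seq_len(cs$N)))
  res <- evaluate_predictions(preds, corpus$questions)
  expect_true(all(res$per_question$ap > 0))
  expect_equal(res$map, mean(res$per_question$ap))
})
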