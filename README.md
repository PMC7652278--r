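# raerank

Listwise ranking of biomedical question-snippet pairs with recursive
autoencoders.

## What it does

Biomedical question-answering benchmarks ask systems to return, per
question, up to ten *snippets* — small sequential pieces of article text
(half a sentence up to a few adjacent sentences) — that answer the
question. `raerank` treats snippet selection as classification of a latent
question–answer (Q-A) relation and ranks by the predicted probability of
that relation:

1. **Candidate extraction.** Documents are split into atomic segments on
   commas, periods, semicolons and the standalone word "and"; every
   contiguous run of up to `max_span_segments` segments in the title or
   abstract is a candidate snippet.
2. **Composition.** Each candidate is concatenated with the question into
   a Q-S pair. A recursive autoencoder greedily builds a binary tree over
   the pair's word vectors: two adjacent nodes compose as
   `p = tanh(W1 [c1; c2] + b1)`, a reconstruction layer decodes
   `[c1'; c2'] = W2 p + b2`, and at each step the adjacent pair with the
   lowest word-count-weighted reconstruction error
   `(n1 ||c1 − c1'||² + n2 ||c2 − c2'||²) / (n1 + n2)` is merged.
3. **Classification and ranking.** Every internal node is classified by
   `d = softmax(Wlabel p)` against the pair label; per-node losses blend
   reconstruction and cross-entropy error as `α·Erec + (1−α)·EcE`. On top
   of the per-pair losses, a listwise **ranking error**
   `Er = −log Σᵢ d₁⁽ⁱ⁾ / i` (sum over the relevant candidates, ordered by
   descending predicted probability) penalises orderings that put relevant
   snippets low; the per-question loss is
   `β·Er + (1−β)·Σ tree errors`, averaged over questions plus an L2 term.
   Training is per-question SGD with exact backpropagation through
   structure; ranking uses the root node's `d₁`.

The package also ships the surrounding pipeline: BioASQ-style JSON /
JSON-lines readers and writers, noun-phrase query formulation, skip-gram
embedding pretraining, a synthetic corpus generator with planted Q-A
relations, ranking metrics (truncated average precision, MAP), and
paired-batch comparison utilities (mean differences, relative
improvements, paired t-tests) with a published per-batch MAP table as a
CSV fixture.

## Worked example

Generate a synthetic corpus, train, and evaluate against a random-ranking
baseline:

```r
library(raerank)

corpus <- generate_corpus(synth_config(seed = 1))
cfg    <- rae_config(seed = 1)
csets  <- prepare_candidate_sets(corpus$questions, corpus$documents, cfg)
csets[[1]]
#> <candidate_set> question q001: N = 66 candidates, m = 6 relevant

model <- train_ranker(csets[1:40], cfg)
h <- attr(model, "history")
sprintf("objective: %.2f -> %.2f", h$objective_initial, h$objective_final)
#> "objective: 377.14 -> 66.37"

test_cs <- csets[41:60]
map <- model_map(test_cs, model)
rb  <- random_ranking_baseline(test_cs, seed = 1)
sprintf("held-out MAP: %.3f   random baseline: %.3f [%.3f, %.3f]",
        map, rb$map, rb$lower, rb$upper)
#> "held-out MAP: 0.617   random baseline: 0.049 [0.017, 0.106]"

head(rank_candidates(test_cs[[1]], model)$ranked_snippets, 3)
#>   doc_id begin end     score
#> 1 d041_3   178 263 0.2599134
#> 2 d041_3   143 263 0.1839977
#> 3 d041_3   228 263 0.1216084
```

The trained model ranks the planted relevant snippets far above chance:
held-out MAP 0.617 against a 0.049 random baseline. `begin`/`end` are
0-based end-exclusive character offsets into the document full text
(title + newline + abstract); `score` is the root node's predicted Q-A
probability.

The comparison utilities work off a per-batch MAP table:

```r
tab <- read_eval_table(system.file("extdata", "benchmark_map.csv", package = "raerank"))
mean_paired_difference(tab, "our", "CNN")
#> 0.02485385
paired_ttest(tab, "our", "CNN")
#> Paired t-test our vs CNN over 13 batches:
#>   mean diff 0.0249, t(12) = 11.0152, p = 0.0000, ES = 3.0551, 95% CI [0.0199, 0.0298]
```

A thin CLI over the same functions lives at `inst/cli/raerank.R`
(subcommands `synth`, `pretrain`, `train`, `rank`, `eval`, `ttest`).

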