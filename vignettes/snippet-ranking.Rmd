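---
title: "Ranking question-snippet pairs with recursive autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking question-snippet pairs with recursive autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Biomedical question-answering benchmarks ask systems to return, for each
question, up to ten *snippets* -- small sequential pieces of article text,
anywhere from half a sentence to a few adjacent sentences -- that answer it.
Retrieval-style scoring (term overlap between question and snippet) misses
the distinction between text that *resembles* a question and text that
*answers* it. `raerank` instead treats snippet selection as binary
classification of a latent question-answer (Q-A) relation: every candidate
snippet is concatenated with the question into a question-snippet (Q-S)
pair, a recursive autoencoder composes the pair's word vectors into a
single representation, and a softmax layer predicts whether the relation
holds. Candidates are ranked by that predicted probability.

## The model

**Composition.** Given word vectors of dimension $n$, two adjacent nodes
$c_1, c_2$ are composed as

$$p = \tanh(W^{(1)} [c_1; c_2] + b^{(1)}),$$

and decoded back through the reconstruction layer
$[c_1'; c_2'] = W^{(2)} p + b^{(2)}$. The merge is scored by reconstruction
error: the plain form $\tfrac12 \lVert [c_1;c_2] - [c_1';c_2'] \rVert^2$
and, for tree construction and training, the word-count-weighted form

$$E_{rec} = \frac{n_1 \lVert c_1 - c_1' \rVert^2 + n_2 \lVert c_2 - c_2'
\rVert^2}{n_1 + n_2},$$

where $n_1, n_2$ count the words under each child, so subtrees carrying
more of the pair's meaning weigh more. Both forms are implemented exactly
as written -- the plain form carries the $\tfrac12$, the weighted form does
not.

**Greedy trees.** The tree over a token sequence is built greedily: the
reconstruction error of every adjacent pair in the current sequence is
evaluated, the cheapest pair (leftmost on ties) is replaced by its parent,
and the process repeats until a single root remains. The binary tree is
deliberately *not* a parse tree: the network chooses its own bracketing,
and merges freely cross the question/snippet boundary, which is exactly
where the Q-A relation lives. An exhaustive-enumeration oracle
(`exhaustive_best_tree`, Catalan-bounded to ten leaves) exists for testing.

**Classification and the listwise ranking error.** Every internal node $p$
is classified by $d = \mathrm{softmax}(W_{label}\, p)$, with $d_1$ the
predicted probability of a Q-A relation, and scored against the pair-level
label by cross-entropy. The per-node loss is the blend $\alpha E_{rec} +
(1-\alpha) E_{cE}$, summed over the tree.

Classification accuracy alone does not order candidates well: a classifier
scoring a relevant/irrelevant pair $(0.51, 0.52)$ and one scoring
$(1.00, 0.99)$ make the same binary decisions, but only the latter ranks
the relevant snippet first. The listwise *ranking error* penalises exactly
this. For one question with $m$ relevant candidates whose predicted
probabilities, sorted descending, are $d_1^{(1)} \ge \dots \ge d_1^{(m)}$:

$$E_r = -\log \sum_{i=1}^{m} \frac{d_1^{(i)}}{i}.$$

This is the negative logarithm of a MAP-like sum. Implemented literally it
has no $1/m$ factor, so the inner sum can exceed 1 and $E_r$ can go
negative for $m \ge 2$; it still decreases monotonically as the relevant
probabilities rise, which is all gradient descent needs. The
`global_rank` variant divides by the candidate's position in the *full*
ranking instead; the literal form is the default
(`ranking_error_variant = "relevant_index"`).

**Objective.** The per-question loss is $\beta E_r + (1-\beta) \sum_{pairs}
E_{tree}$, and the objective averages over questions and adds
$\tfrac{\lambda}{2}\lVert\theta\rVert^2$. Questions with no relevant
candidate are skipped (their ranking error is undefined).

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `vector_dim` | 50 | embedding / node dimensionality; standard for desk-scale recursive autoencoders |
| `alpha` | 0.2 | reconstruction weight per node; kept small so classification dominates, as in prior semi-supervised RAE practice |
| `beta` | 0.5 | ranking-error weight per question |
| `lambda_reg` | 1e-4 | L2 strength; embedding rows excluded unless `regularize_embeddings` |
| `learning_rate`, `epochs` | 0.01, 30 | per-question SGD |
| `max_span_segments` | 3 | snippet cap in atomic segments: snippets range from half a sentence to about two sentences, and the cap bounds the quadratic candidate blow-up |
| `overlap_threshold` | 0.5 | fraction of a candidate's characters that must overlap a gold span to count as relevant |
| `normalize_parent` | TRUE | see below |
| `cutoff` | 10 | benchmark submission cap and AP truncation depth |

## Design choices where the design was open

* **Parent normalisation** (default on): the raw reconstruction objective
  has a degenerate optimum where all node vectors shrink toward zero,
  making reconstruction trivially cheap. Scaling every composed parent to
  unit length removes it. The literal un-normalised variant remains
  available as a flag.
* **Greedy merge criterion**: the weighted error is used for merge
  selection (it is the form the training loss uses); `merge_criterion =
  "plain"` gives the alternative.
* **Per-node targets**: every internal node of a pair's tree inherits the
  pair-level label -- the tree error is a sum of node errors against a
  single target.
* **Pair construction**: the pair's token sequence is question tokens
  followed by snippet tokens with *no* separator token, since the greedy
  composition is meant to cross that boundary anyway. Question tokens are
  not noun-phrase-filtered for pair construction; the filter is a
  *retrieval-query* device only.
* **Inference**: a pair's predicted probability is the *root* node's
  $d_1$; per-node distributions are retained for diagnostics only.
* **Embedding fine-tuning** (default on): pretraining is a coarse
  initialisation; the embedding rows are part of $\theta$ during
  supervised training, with a flag to freeze them.

## Preprocessing

Tokenisation is lowercase alphanumeric-run extraction, no stemming --
the simplest reproducible convention. Retrieval queries keep only
noun-phrase tokens: a rule-based tagger (closed-class lexicons for
determiners, pronouns, prepositions, conjunctions, auxiliaries and common
verbs/adverbs; adjectival suffix rules; noun as the default tag) feeds the
chunk grammar *determiner? adjective\* noun+*. Noun as default is the
right bias for biomedical text, where unknown open-class words are
overwhelmingly nouns ("mononucleosis"). With no noun phrase at all, the
fallback is the stopword-filtered token list, with a warning.

Documents split into *atomic segments* on commas, periods, semicolons and
the standalone word "and"; candidates are every contiguous run of one to
`max_span_segments` segments within a single field (title or abstract).
Offsets are 0-based, end-exclusive characters into the document full text,
defined as title + newline + abstract. A candidate is labelled relevant
when its character overlap with some gold snippet of the same document
reaches half the candidate's length -- the benchmark provides gold spans
but no matching rule, so one had to be fixed.

Document retrieval itself is out of scope: the package ranks candidates
from caller-supplied documents (`top_n_documents` is an input contract).

## Embeddings

`pretrain_skipgram` is a single-threaded, seed-deterministic skip-gram
with negative sampling (window 4, five negatives, unigram$^{0.75}$ noise)
-- a desk-scale stand-in for large-corpus word2vec pretraining. Vectors
start from the uniform $[-0.1, 0.1]$ random initialisation, so zero
epochs reproduce `init_embeddings` exactly. Unknown tokens map to a
dedicated row; lookups never fail.

## Training and gradients

Training is per-question SGD: each epoch reshuffles the questions
(seeded), rebuilds every pair's greedy tree and the ranking order at the
current parameters, and steps against the per-question gradient plus the
L2 term. Tree structures and ranking order are discrete, so they are
treated as piecewise constant during differentiation -- recomputed before
each step, held fixed within it. The backward pass is exact
backpropagation through structure: gradients flow through the softmax
layers, the reconstruction layers (including into each child as a
reconstruction *target*), the unit-normalisation Jacobian
$(I - pp^\top)/\lVert h\rVert$, and the $\tanh$, down to the embedding
rows.

Numerical choices: cross-entropy clips probabilities at $10^{-12}$ with a
warning; training aborts with diagnostics if a loss goes non-finite; the
greedy tie-break is leftmost-minimum, making construction deterministic.
The finite-difference gradient checks draw their random parameter points
at unit-scale embeddings: close to the normalisation singularity
($\lVert\tanh(z)\rVert \to 0$, which tiny embeddings induce) the numeric
oracle's truncation error at $\varepsilon = 10^{-5}$ exceeds the
comparison threshold even for an exact gradient.

**A known limitation of greedy construction**: greedy scores only the
next merge. Already at three leaves, minimising the first merge error
does not minimise the two-merge total, so greedy and the exhaustive
oracle regularly choose different bracketings there; the oracle's total
error is a lower bound on greedy's (verified over random inputs), with
equality guaranteed only at two leaves.

## The synthetic corpus

The generator emulates the benchmark's shape -- questions with gold
snippet spans, candidate documents with title and abstract, planted
relevant segments among distractor clauses -- with purely synthetic
tokens. Each question draws from one of 8 topics (30 tokens each, of
which 8 are *answer tokens*) plus a 50-token shared pool; its 3 documents
each carry 8 abstract segments; 1-3 segments per question are relevant.
A relevant segment's token slots carry answer tokens of the question's
topic with probability `answer_overlap` (default 0.9) and distractor text
otherwise; distractor segments mix off-topic general vocabulary and
shared tokens and never contain answer tokens. The modelling stance:
answer phrases in real abstracts are specific mentions (treatments,
genes) that occur in answering statements, while off-topic prose is
generic -- what the generator preserves is the lexical-overlap structure
the composition model can exploit, not linguistic realism. At
`answer_overlap = 1` the corpus is (near-)perfectly separable; at 0
relevant segments are statistically identical to distractors, and a
trained model's MAP should fall inside the random baseline's permutation
interval -- a sanity check of both the generator and the learner.

What passing tests on this corpus do **not** show: robustness to
morphology, synonymy, discourse structure, or class imbalance at
literature scale; the benchmark's own MAP levels are not reproducible
without the full literature collection, so training quality is accepted
via recovery properties (trained MAP against a seeded
random-permutation baseline on held-out questions, 40 train / 20 test)
rather than absolute values.

## Evaluation conventions

Average precision is truncated at the submission cutoff (10) and divided
by the gold relevant count $m$ uncapped (trec-style); `divisor =
"capped"` gives the $\min(m, \mathrm{cutoff})$ alternative. The
paired-comparison utilities consume a per-batch MAP table
(`system,year,batch,map`); the shipped `benchmark_map.csv` fixture is a
transcription of published per-batch MAP values for one benchmark run and
seven baselines over 13 batches. Mean paired differences and
year-averaged relative improvements reproduce the published comparison
figures; the paired t-test follows the textbook convention ($n-1$
divisor, $t = \bar d/(s/\sqrt n)$, two-sided $p$, effect size $\bar
d/s$), under which the published $t$ statistics themselves are not
reproducible from the table -- only the mean differences are treated as
reproduction targets. One published improvement figure (the 2014
convolutional baseline) is likewise inconsistent with the table under
either averaging convention and is excluded.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
the default 60-question corpus (about 66 candidates per question) for
recovery experiments, a 20-question corpus for training-curve properties,
5-dimensional models on 2-question instances for full-coordinate gradient
checks, and 5-7 leaf sequences for tree-search comparisons. A full
recovery run (generate, preprocess, train 30 epochs on 40 questions,
rank, evaluate) takes well under a minute on one CPU.
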