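#' @title Synthetic corpora with planted question-answer relations
#' @description
#' Generates desk-scale corpora so the whole pipeline is trainable and
#' testable without downloads. Tokens are synthetic strings carrying topic
#' structure only: each question draws from one topic's vocabulary, its
#' candidate documents contain planted relevant segments plus distractor
#' clauses, and relevance is encoded lexically -- relevant segments carry
#' topic-specific answer tokens at a configurable rate. No natural-language
#' realism is attempted; what matters is the lexical-overlap structure the
#' composition model can exploit.
#' @name synthetic_data
NULL

#' Synthetic corpus configuration
#'
#' @param n_topics number of topics.
#' @param vocab_per_topic tokens per topic, of which
#'   `answer_tokens_per_topic` are answer tokens (they appear only inside
#'   relevant segments; the rest is general topic vocabulary).
#' @param answer_tokens_per_topic see above.
#' @param shared_vocab_size topic-neutral tokens mixed into questions and
#'   distractors.
#' @param n_questions questions to generate.
#' @param docs_per_question candidate documents per question.
#' @param segments_per_doc abstract segments per document.
#' @param relevant_range integer range (min, max) of relevant segments
#'   planted per question.
#' @param question_len integer range of question token counts.
#' @param segment_len integer range of segment token counts.
#' @param answer_overlap probability that a relevant-segment token slot
#'   carries an answer token of the question's topic; the remaining slots
#'   are filled like distractor text. At 1 the corpus is (near-)perfectly
#'   separable, at 0 relevant segments are statistically identical to
#'   distractors.
#' @param seed integer seed; the same seed always yields the identical
#'   corpus.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_topics = 8L, vocab_per_topic = 30L,
                         answer_tokens_per_topic = 8L,
                         shared_vocab_size = 50L, n_questions = 60L,
                         docs_per_question = 3L, segments_per_doc = 8L,
                         relevant_range = c(1L, 3L),
                         question_len = c(4L, 8L), segment_len = c(4L, 8L),
                         answer_overlap = 0.9, seed = 1L) {
  stopifnot(n_topics >= 1, vocab_per_topic >= 2,
            answer_tokens_per_topic >= 1,
            answer_tokens_per_topic < vocab_per_topic,
            shared_vocab_size >= 1, n_questions >= 1,
            docs_per_question >= 1, segments_per_doc >= 1,
            length(relevant_range) == 2, relevant_range[1] >= 1,
            relevant_range[1] <= relevant_range[2],
            answer_overlap >= 0, answer_overlap <= 1)
  if (relevant_range[2] > docs_per_question * segments_per_doc)
    stop("infeasible config: segment budget (", docs_per_question *
           segments_per_doc, ") < maximum relevant count (",
         relevant_range[2], ")", call. = FALSE)
  structure(list(n_topics = as.integer(n_topics),
                 vocab_per_topic = as.integer(vocab_per_topic),
                 answer_tokens_per_topic = as.integer(answer_tokens_per_topic),
                 shared_vocab_size = as.integer(shared_vocab_size),
                 n_questions = as.integer(n_questions),
                 docs_per_question = as.integer(docs_per_question),
                 segments_per_doc = as.integer(segments_per_doc),
                 relevant_range = as.integer(relevant_range),
                 question_len = as.integer(question_len),
                 segment_len = as.integer(segment_len),
                 answer_overlap = answer_overlap, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic corpus
#'
#' Each question is assigned a topic; its body mixes general topic tokens
#' with shared tokens. Its documents consist of a distractor title and
#' `segments_per_doc` abstract segments joined by ". "; the planted
#' relevant segments draw answer tokens of the question's topic at rate
#' `answer_overlap`, all other segment slots draw from other topics'
#' general vocabulary and the shared pool. Gold snippet offsets are exact
#' substrings of the document full text (title, newline, abstract).
#'
#' @param config a [synth_config()].
#' @return object of class `synth_corpus`: `questions` (list of
#'   `question_record`), `documents` (named list of `document_record`),
#'   `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  cf <- config
  topic_general <- lapply(seq_len(cf$n_topics), function(t)
    sprintf("t%02d_w%d", t,
            seq_len(cf$vocab_per_topic - cf$answer_tokens_per_topic)))
  topic_answer <- lapply(seq_len(cf$n_topics), function(t)
    sprintf("t%02d_a%d", t, seq_len(cf$answer_tokens_per_topic)))
  shared <- sprintf("shared_w%d", seq_len(cf$shared_vocab_size))

  with_seed(cf$seed, {
    distractor_tokens <- function(len, topic) {
      # off-topic general vocabulary (70%) and shared tokens (30%)
      vapply(seq_len(len), function(i) {
        if (runif(1) < 0.3 || cf$n_topics == 1) sample(shared, 1)
        else sample(unlist(topic_general[-topic]), 1)
      }, "")
    }
    questions <- vector("list", cf$n_questions)
    documents <- list()
    for (qi in seq_len(cf$n_questions)) {
      topic <- sample.int(cf$n_topics, 1)
      qlen <- sample(cf$question_len[1]:cf$question_len[2], 1)
      qtoks <- vapply(seq_len(qlen), function(i) {
        if (runif(1) < 0.3) sample(shared, 1)
        else sample(topic_general[[topic]], 1)
      }, "")
      n_rel <- sample(cf$relevant_range[1]:cf$relevant_range[2], 1)
      slots <- expand.grid(doc = seq_len(cf$docs_per_question),
                           seg = seq_len(cf$segments_per_doc))
      rel_slots <- slots[sample.int(nrow(slots), n_rel), , drop = FALSE]

      gold <- empty_gold()
      doc_ids <- character(cf$docs_per_question)
      for (di in seq_len(cf$docs_per_question)) {
        doc_id <- sprintf("d%03d_%d", qi, di)
        doc_ids[di] <- doc_id
        title <- paste(distractor_tokens(4, topic), collapse = " ")
        segs <- character(cf$segments_per_doc)
        rel_here <- rel_slots$seg[rel_slots$doc == di]
        for (si in seq_len(cf$segments_per_doc)) {
          slen <- sample(cf$segment_len[1]:cf$segment_len[2], 1)
          segs[si] <- if (si %in% rel_here) {
            paste(vapply(seq_len(slen), function(i) {
              if (runif(1) < cf$answer_overlap)
                sample(topic_answer[[topic]], 1)
              else distractor_tokens(1, topic)
            }, ""), collapse = " ")
          } else {
            paste(distractor_tokens(slen, topic), collapse = " ")
          }
        }
        abstract <- paste0(paste(segs, collapse = ". "), ".")
        doc <- structure(list(doc_id = doc_id, title = title,
                              abstract = abstract),
                         class = "document_record")
        documents[[doc_id]] <- doc
        # gold offsets in document full-text coordinates
        base <- nchar(title) + 1L
        pos <- 0L
        for (si in seq_len(cf$segments_per_doc)) {
          b <- pos
          e <- pos + nchar(segs[si])
          if (si %in% rel_here)
            gold <- rbind(gold, data.frame(doc_id = doc_id,
                                           begin = base + b, end = base + e,
                                           text = segs[si],
                                           stringsAsFactors = FALSE))
          pos <- e + 2L   # ". " separator
        }
      }
      questions[[qi]] <- new_question_record(sprintf("q%03d", qi),
                                             paste(qtoks, collapse = " "),
                                             gold, doc_ids)
    }
    structure(list(questions = questions, documents = documents,
                   config = cf), class = "synth_corpus")
  })
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(sprintf("<synth_corpus> %d questions, %d documents, %d topics, seed %d\n",
              length(x$questions), length(x$documents), x$config$n_topics,
              x$config$seed))
  invisible(x)
}

#' Token sentences of a corpus (for embedding pretraining)
#'
#' Question bodies and document title/abstract segments as token vectors.
#'
#' @param corpus a `synth_corpus` (or list with `questions`, `documents`).
#' @return list of character token vectors.
#' @export
corpus_sentences <- function(corpus) {
  qs <- lapply(corpus$questions, function(q) tokenize_text(q$body))
  ds <- unlist(lapply(corpus$documents, function(d) {
    segs <- c(d$title, segment_atoms(d$abstract)$text)
    lapply(segs, tokenize_text)
  }), recursive = FALSE)
  c(qs, ds)
}

#' Random-permutation ranking baseline
#'
#' MAP of uniformly random candidate orderings: each permutation ranks
#' every question's candidates at random; the per-permutation MAPs give
#' the null distribution of the evaluation metric.
#'
#' @param csets list of `candidate_set` objects (questions with `m = 0`
#'   are excluded).
#' @param seed integer seed.
#' @param n_perm permutations (default 100).
#' @param cutoff truncation depth.
#' @return list with `map` (mean over permutations), `per_perm` (vector of
#'   per-permutation MAPs), `lower`/`upper` (2.5 and 97.5 percent
#'   quantiles).
#' @export
random_ranking_baseline <- function(csets, seed = 1L, n_perm = 100L,
                                    cutoff = 10L) {
  csets <- csets[vapply(csets, function(cs) cs$m > 0, TRUE)]
  if (!length(csets)) stop("no candidate set with relevant items", call. = FALSE)
  per_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      aps <- vapply(csets, function(cs) {
        ord <- sample.int(cs$N)
        average_precision(cs$labels[ord], cutoff = cutoff, m = cs$m)
      }, 0)
      mean(aps)
    }, 0)
  })
  list(map = mean(per_perm), per_perm = per_perm,
       lower = unname(stats::quantile(per_perm, 0.025)),
       upper = unname(stats::quantile(per_perm, 0.975)))
}
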