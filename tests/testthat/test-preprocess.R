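test_that("query formulation keeps noun-phrase tokens in order", {
  expect_equal(formulate_query("How to treat infectious mononucleosis"),
               c("infectious", "mononucleosis"))
  expect_warning(fb <- formulate_query("Go away!"), "no noun phrase")
  expect_equal(fb, c("go", "away"))
  expect_error(formulate_query("   "), "nonempty")
})

test_that("query tokens are always a subsequence of the question tokens", {
  set.seed(42)
  vocabulary <- c("the", "a", "infectious", "chronic", "mononucleosis",
                  "treatment", "gene", "mutation", "is", "what", "causes",
                  "protein", "common", "disease", "in", "of", "humans")
  for (i in 1:200) {
    body <- paste(sample(vocabulary, sample(3:9, 1), replace = TRUE),
                  collapse = " ")
    toks <- tokenize_text(body)
    q <- suppressWarnings(formulate_query(body))
    # subsequence check: match q into toks left to right
    j <- 1
    for (tk in q) {
      while (j <= length(toks) && toks[j] != tk) j <- j + 1
      expect_lte(j, length(toks))
      j <- j + 1
    }
  }
})

test_that("atomic segmentation splits on the clause separators", {
  expect_equal(segment_atoms("Chloroquine and steroids are worth attempting.")$text,
               c("Chloroquine", "steroids are worth attempting"))
  expect_equal(segment_atoms("")$text, character())
  expect_equal(segment_atoms("A, B; C.")$text, c("A", "B", "C"))
  # "and" only as a standalone word, not inside words
  expect_equal(segment_atoms("sandy islands")$text, "sandy islands")
  # spans index into the original text (0-based, end-exclusive)
  txt <- "Hello there, my friend; ok."
  s <- segment_atoms(txt)
  expect_equal(substr(rep(txt, nrow(s)), s$begin + 1, s$end), s$text)
})

test_that("segmentation is idempotent on its own outputs", {
  texts <- c("a, b and c; d. e", "Chloroquine and steroids, or not.",
             "one. two. three and four")
  for (txt in texts) {
    for (seg in segment_atoms(txt)$text) {
      again <- segment_atoms(seg)
      expect_equal(again$text, seg)
    }
  }
})

test_that("candidate enumeration matches the closed-form count", {
  make_doc <- function(S) {
    structure(list(doc_id = "d", title = "",
                   abstract = paste0(paste(sprintf("seg %d", seq_len(S)),
                                           collapse = ". "), ".")),
              class = "document_record")
  }
  for (S in c(1, 2, 3, 5, 8, 13, 20)) {
    for (K in 1:5) {
      expected <- sum(vapply(seq_len(min(K, S)), function(k) S - k + 1, 0))
      expect_length(enumerate_snippets(make_doc(S), K), expected)
    }
  }
  # worked case: 4 abstract segments, cap 3 -> 4 + 3 + 2 = 9
  expect_length(enumerate_snippets(make_doc(4), 3), 9)
})

test_that("candidates never cross the title/abstract boundary and spans match", {
  corpus <- generate_corpus(synth_config(n_questions = 5, seed = 3))
  for (doc in corpus$documents[1:6]) {
    txt <- document_text(doc)
    for (cand in enumerate_snippets(doc, 3)) {
      expect_equal(substr(txt, cand$begin + 1, cand$end), cand$text)
      # no candidate contains the field-separating newline
      expect_false(grepl("\n", cand$text, fixed = TRUE))
    }
  }
})

test_that("overlap labelling applies the 0.5 threshold", {
  gold <- data.frame(doc_id = "d", begin = 100L, end = 200L, text = NA)
  exact <- list(doc_id = "d", begin = 100, end = 200)
  expect_equal(label_pair(exact, gold), 1L)
  none <- list(doc_id = "d", begin = 300, end = 400)
  expect_equal(label_pair(none, gold), 0L)
  other_doc <- list(doc_id = "e", begin = 100, end = 200)
  expect_equal(label_pair(other_doc, gold), 0L)
  # candidate of length 100 overlapping 40 characters -> below threshold
  forty <- list(doc_id = "d", begin = 160, end = 260)
  expect_equal(label_pair(forty, gold), 0L)
  # exactly half the candidate overlaps -> at threshold, relevant
  fifty <- list(doc_id = "d", begin = 150, end = 250)
  expect_equal(label_pair(fifty, gold), 1L)
})

test_that("pair assembly concatenates question and snippet tokens and counts m", {
  corpus <- generate_corpus(synth_config(n_questions = 50, seed = 9))
  cfg <- rae_config()
  csets <- prepare_candidate_sets(corpus$questions, corpus$documents, cfg)
  for (i in seq_along(csets)) {
    cs <- csets[[i]]
    q <- corpus$questions[[i]]
    qtoks <- tokenize_text(q$body)
    # brute-force label recount
    docs <- corpus$documents[q$doc_ids]
    cands <- unlist(lapply(docs, enumerate_snippets,
                           max_span_segments = cfg$max_span_segments),
                    recursive = FALSE)
    m_brute <- sum(vapply(cands, label_pair, 0L,
                          gold_snippets = q$gold_snippets))
    expect_equal(cs$m, m_brute)
    expect_equal(cs$m, sum(cs$labels))
    for (p in cs$pairs) {
      expect_equal(p$tokens[seq_along(qtoks)], qtoks)
      expect_equal(length(p$tokens),
                   length(qtoks) + length(tokenize_text(p$text)))
    }
  }
  # planted relevant segments guarantee at least one positive pair
  expect_true(all(vapply(csets, `[[`, 0L, "m") >= 1))
})

test_that("pair assembly rejects an empty candidate list", {
  q <- generate_corpus(synth_config(n_questions = 1, seed = 1))$questions[[1]]
  expect_error(build_pairs(q, list()), "no candidates")
})
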