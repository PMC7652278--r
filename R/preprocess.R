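#' @title Preprocessing: queries, segments, candidates, pairs
#' @description
#' Turns raw questions and documents into question-snippet (Q-S) pairs:
#' noun-phrase query formulation, atomic-segment splitting on clause
#' separators, enumeration of contiguous segment runs as candidate
#' snippets, overlap-based labelling against gold snippets, and assembly of
#' the per-question candidate set.
#' @name preprocess
NULL

#' Tokenize text
#'
#' Lowercases and extracts maximal runs of letters, digits and underscores;
#' punctuation is dropped. No stemming.
#'
#' @param text character scalar.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  m <- gregexpr("[a-z0-9_]+", tolower(text))[[1]]
  if (m[1] == -1) return(character())
  regmatches(tolower(text), list(m))[[1]]
}

# --- rule-based part-of-speech tagging -------------------------------------
# Small closed-class lexicons; anything unlisted defaults to noun, which is
# the right bias for biomedical question text where the open-class content
# words are overwhelmingly nouns.
.pos_det <- c("the", "a", "an", "this", "that", "these", "those", "some",
              "any", "each", "every", "no", "all", "both", "either",
              "neither", "my", "your", "his", "her", "its", "our", "their")
.pos_wh <- c("what", "which", "who", "whom", "whose", "when", "where", "why",
             "how")
.pos_pron <- c("i", "you", "he", "she", "it", "we", "they", "me", "him",
               "them", "us", "itself", "themselves")
.pos_prep <- c("of", "in", "on", "at", "by", "for", "with", "about",
               "against", "between", "into", "through", "during", "before",
               "after", "above", "below", "to", "from", "up", "down",
               "over", "under", "within", "without", "via", "per", "as")
.pos_conj <- c("and", "or", "but", "nor", "so", "yet", "if", "because",
               "while", "whereas", "although", "than", "whether")
.pos_verb <- c("is", "are", "was", "were", "be", "been", "being", "am",
               "do", "does", "did", "done", "have", "has", "had", "having",
               "can", "could", "may", "might", "must", "shall", "should",
               "will", "would", "treat", "treats", "treated", "treating",
               "cause", "causes", "caused", "causing", "use", "used",
               "using", "uses", "affect", "affects", "affected", "involve",
               "involves", "involved", "occur", "occurs", "occurred",
               "go", "goes", "went", "gone", "get", "gets", "got", "make",
               "makes", "made", "take", "takes", "taken", "give", "gives",
               "given", "know", "known", "play", "plays", "described",
               "associated", "linked", "related", "found", "identified",
               "reported", "shown", "defined", "diagnose", "diagnosed",
               "prevent", "prevents", "prevented", "work", "works")
.pos_adv <- c("not", "also", "very", "only", "just", "often", "usually",
              "commonly", "mainly", "mostly", "away", "here", "there",
              "now", "then", "well", "still", "even", "again", "most",
              "more", "less", "least")
.pos_adj <- c("common", "rare", "several", "many", "few", "new", "main",
              "major", "minor", "high", "low", "large", "small", "human",
              "normal", "abnormal", "acute", "chronic", "severe", "mild",
              "effective", "available", "responsible", "important", "other",
              "first", "second", "different", "similar", "specific",
              "possible", "worth")
.adj_suffix <- "(ous|ive|ic|ical|al|ary|ful|less|able|ible|ant|ent)$"

pos_tag <- function(tokens) {
  vapply(tokens, function(tk) {
    if (tk %in% .pos_det) return("DET")
    if (tk %in% .pos_wh) return("WH")
    if (tk %in% .pos_pron) return("PRON")
    if (tk %in% .pos_prep) return("PREP")
    if (tk %in% .pos_conj) return("CONJ")
    if (tk %in% .pos_verb) return("VERB")
    if (tk %in% .pos_adv) return("ADV")
    if (tk %in% .pos_adj) return("ADJ")
    if (grepl(.adj_suffix, tk) && nchar(tk) > 4) return("ADJ")
    "NOUN"
  }, "", USE.NAMES = FALSE)
}

.stopwords <- unique(c(.pos_det, .pos_wh, .pos_pron, .pos_prep, .pos_conj,
                       "is", "are", "was", "were", "be", "been", "being",
                       "am", "do", "does", "did", "have", "has", "had",
                       "not", "it", "its"))

#' Formulate a retrieval query from a question
#'
#' Keeps only the tokens belonging to noun-phrase chunks (chunk grammar:
#' optional determiner, any adjectives, one or more nouns), in their
#' original order, lowercased. Tagging is rule-based: small closed-class
#' lexicons plus adjectival suffix rules, with noun as the default tag. If
#' the question contains no noun phrase, all non-stopword tokens are
#' returned with a warning.
#'
#' @param question_body nonempty question text.
#' @return character vector of query tokens.
#' @export
formulate_query <- function(question_body) {
  if (!is.character(question_body) || length(question_body) != 1 ||
      !nzchar(trimws(question_body)))
    stop("question body must be nonempty text", call. = FALSE)
  toks <- tokenize_text(question_body)
  tags <- pos_tag(toks)
  keep <- logical(length(toks))
  i <- 1
  while (i <= length(toks)) {
    j <- i
    start <- j
    if (j <= length(toks) && tags[j] == "DET") j <- j + 1
    while (j <= length(toks) && tags[j] == "ADJ") j <- j + 1
    k <- j
    while (k <= length(toks) && tags[k] == "NOUN") k <- k + 1
    if (k > j) {            # at least one noun: accept chunk [start, k)
      keep[start:(k - 1)] <- TRUE
      i <- k
    } else {
      i <- i + 1
    }
  }
  if (!any(keep)) {
    warning("no noun phrase found; falling back to non-stopword tokens")
    return(toks[!(toks %in% .stopwords)])
  }
  toks[keep]
}

#' Split text into atomic segments
#'
#' Splits on commas, periods, semicolons and the standalone word "and";
#' separators are not part of any segment, whitespace is trimmed and empty
#' segments dropped. Spans are 0-based, end-exclusive character offsets
#' into the input text.
#'
#' @param text character scalar (may be empty).
#' @return data frame with columns `text`, `begin`, `end`.
#' @export
segment_atoms <- function(text) {
  empty <- data.frame(text = character(), begin = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[,.;]|(?<![A-Za-z0-9_])[Aa][Nn][Dd](?![A-Za-z0-9_])", text,
                perl = TRUE)[[1]]
  cuts <- if (m[1] == -1) integer() else
    cbind(start = as.integer(m), len = attr(m, "match.length"))
  bounds_begin <- c(1L, if (length(cuts)) cuts[, 1] + cuts[, 2])
  bounds_end <- c(if (length(cuts)) cuts[, 1] - 1L, nchar(text))
  rows <- lapply(seq_along(bounds_begin), function(i) {
    b <- bounds_begin[i]; e <- bounds_end[i]
    if (b > e) return(NULL)
    seg <- substr(text, b, e)
    # trim, keeping offsets aligned
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    b2 <- b + lead; e2 <- e - trail
    if (b2 > e2) return(NULL)
    data.frame(text = substr(text, b2, e2), begin = b2 - 1L, end = e2,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full text of a document
#'
#' The offset coordinate system for gold snippets and candidates: `title`,
#' a single newline, then `abstract`.
#'
#' @param doc a `document_record`.
#' @return character scalar.
#' @export
document_text <- function(doc) {
  paste(doc$title, doc$abstract, sep = "\n")
}

#' Enumerate candidate snippets of a document
#'
#' Every contiguous run of 1..`max_span_segments` atomic segments within a
#' single field (title or abstract) becomes one candidate; candidates never
#' cross the title/abstract boundary. For a field with S segments and cap K
#' this yields sum over k = 1..K of (S - k + 1) candidates.
#'
#' @param doc a `document_record`.
#' @param max_span_segments cap on segments per candidate.
#' @return list of candidates, each a list with `doc_id`, `field`,
#'   `seg_from`, `seg_to`, `text`, `begin`, `end` (offsets into the
#'   document full text, 0-based end-exclusive).
#' @export
enumerate_snippets <- function(doc, max_span_segments = 3L) {
  out <- list()
  for (field in c("title", "abstract")) {
    ftext <- if (field == "title") doc$title else doc$abstract
    offset <- if (field == "title") 0L else nchar(doc$title) + 1L
    segs <- segment_atoms(ftext)
    S <- nrow(segs)
    if (S == 0) next
    for (k in seq_len(min(max_span_segments, S))) {
      for (i in seq_len(S - k + 1)) {
        j <- i + k - 1
        b <- segs$begin[i]; e <- segs$end[j]
        out[[length(out) + 1]] <- list(
          doc_id = doc$doc_id, field = field, seg_from = i, seg_to = j,
          text = substr(ftext, b + 1, e),
          begin = b + offset, end = e + offset)
      }
    }
  }
  out
}

#' Label one candidate against gold snippets
#'
#' A candidate is relevant (target distribution (1, 0)) when the character
#' overlap with some gold snippet of the same document, divided by the
#' candidate's length, reaches `threshold`; otherwise irrelevant ((0, 1)).
#'
#' @param candidate a candidate as produced by [enumerate_snippets()].
#' @param gold_snippets data frame with columns `doc_id`, `begin`, `end`.
#' @param threshold overlap fraction for a positive label (default 0.5).
#' @return 1L (relevant) or 0L (irrelevant).
#' @export
label_pair <- function(candidate, gold_snippets, threshold = 0.5) {
  if (is.null(gold_snippets) || nrow(gold_snippets) == 0) return(0L)
  g <- gold_snippets[gold_snippets$doc_id == candidate$doc_id, , drop = FALSE]
  if (nrow(g) == 0) return(0L)
  len <- candidate$end - candidate$begin
  ov <- pmax(0, pmin(candidate$end, g$end) - pmax(candidate$begin, g$begin))
  if (any(ov / len >= threshold)) 1L else 0L
}

#' Build the question-snippet pair set for one question
#'
#' Each candidate is concatenated with the question: the pair's token
#' sequence is the question tokens followed by the snippet tokens, with no
#' separator token. Labels come from [label_pair()]; `m` is the count of
#' relevant pairs.
#'
#' @param question a `question_record`.
#' @param candidates nonempty list of candidates from [enumerate_snippets()].
#' @param threshold overlap threshold passed to [label_pair()].
#' @return an object of class `candidate_set`: `question_id`, `pairs` (each
#'   with `tokens`, `q_len`, `doc_id`, `begin`, `end`, `text`, `relevant`),
#'   `labels`, `N`, `m`.
#' @export
build_pairs <- function(question, candidates, threshold = 0.5) {
  if (length(candidates) == 0)
    stop("no candidates for question ", question$id, call. = FALSE)
  qtoks <- tokenize_text(question$body)
  pairs <- lapply(candidates, function(cand) {
    stoks <- tokenize_text(cand$text)
    rel <- label_pair(cand, question$gold_snippets, threshold)
    list(tokens = c(qtoks, stoks), q_len = length(qtoks),
         doc_id = cand$doc_id, begin = cand$begin, end = cand$end,
         text = cand$text, relevant = rel)
  })
  keep <- vapply(pairs, function(p) length(p$tokens) > 0, TRUE)
  pairs <- pairs[keep]
  if (!length(pairs))
    stop("all candidate pairs empty after tokenization for question ",
         question$id, call. = FALSE)
  labels <- vapply(pairs, `[[`, 0L, "relevant")
  structure(list(question_id = question$id, pairs = pairs, labels = labels,
                 N = length(pairs), m = sum(labels)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> question %s: N = %d candidates, m = %d relevant\n",
              x$question_id, x$N, x$m))
  invisible(x)
}

#' Preprocess questions and documents into candidate sets
#'
#' Runs [enumerate_snippets()] on every candidate document of each question
#' and assembles labelled Q-S pairs. A question's candidate documents are
#' those listed in its `doc_ids` field when present, otherwise the whole
#' collection.
#'
#' @param questions list of `question_record` objects.
#' @param documents named list of `document_record` objects.
#' @param config an [rae_config()] (supplies `max_span_segments` and
#'   `overlap_threshold`).
#' @return list of `candidate_set` objects, one per question.
#' @export
prepare_candidate_sets <- function(questions, documents, config = rae_config()) {
  lapply(questions, function(q) {
    ids <- if (!is.null(q$doc_ids) && length(q$doc_ids)) q$doc_ids
           else names(documents)
    miss <- setdiff(ids, names(documents))
    if (length(miss))
      stop("question ", q$id, ": unknown document id(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    cands <- unlist(lapply(documents[ids], enumerate_snippets,
                           max_span_segments = config$max_span_segments),
                    recursive = FALSE)
    build_pairs(q, cands, threshold = config$overlap_threshold)
  })
}
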