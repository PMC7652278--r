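#' @title On-disk formats
#' @description
#' The package exchanges four plain-text artifacts:
#' * questions: a JSON object `{"questions": [...]}` whose records carry
#'   `id`, `body` and gold `snippets` (`document`, `offsetInBeginSection`,
#'   `offsetInEndSection`, `text`); section-name fields are accepted and
#'   ignored so BioASQ files load unchanged.
#' * documents: JSON-lines, one `{"doc_id", "title", "abstract"}` per line.
#' * predictions: the question JSON layout with a `score` per snippet.
#' * word vectors: one token per line followed by `vector_dim` floats.
#'
#' Character offsets are 0-based and end-exclusive into the document's full
#' text, defined as `title` + `"\n"` + `abstract`.
#' @name io_formats
NULL

stop_schema <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# readLines tolerant of CRLF files
read_lines_lf <- function(path) {
  sub("\r$", "", readLines(path, warn = FALSE))
}

new_question_record <- function(id, body, gold_snippets, doc_ids = character()) {
  structure(list(id = id, body = body, gold_snippets = gold_snippets,
                 doc_ids = doc_ids),
            class = "question_record")
}

empty_gold <- function() {
  data.frame(doc_id = character(), begin = integer(), end = integer(),
             text = character(), stringsAsFactors = FALSE)
}

#' Read a question file
#'
#' @param path path to a question JSON file.
#' @return a list of `question_record` objects, each with fields `id`,
#'   `body` and `gold_snippets` (a data frame with columns `doc_id`,
#'   `begin`, `end`, `text`; offsets 0-based, end-exclusive).
#' @export
read_questions <- function(path) {
  if (!file.exists(path)) stop_schema("question file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  recs <- obj[["questions"]]
  if (is.null(recs)) stop_schema("missing top-level 'questions' array")
  out <- vector("list", length(recs))
  ids <- character(length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    for (f in c("id", "body")) {
      if (is.null(r[[f]]) || !nzchar(as.character(r[[f]])[1]))
        stop_schema("question record %d: missing required field '%s'", i, f)
    }
    sn <- r[["snippets"]]
    gold <- if (length(sn) == 0) empty_gold() else {
      rows <- lapply(seq_along(sn), function(j) {
        s <- sn[[j]]
        for (f in c("document", "offsetInBeginSection", "offsetInEndSection"))
          if (is.null(s[[f]]))
            stop_schema("question record %d snippet %d: missing field '%s'",
                        i, j, f)
        b <- as.integer(s[["offsetInBeginSection"]])
        e <- as.integer(s[["offsetInEndSection"]])
        if (is.na(b) || is.na(e) || b < 0 || b >= e)
          stop_schema("question record %d snippet %d: bad offsets [%s, %s)",
                      i, j, s[["offsetInBeginSection"]],
                      s[["offsetInEndSection"]])
        data.frame(doc_id = as.character(s[["document"]]), begin = b, end = e,
                   text = if (is.null(s[["text"]])) NA_character_ else
                            as.character(s[["text"]]),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    ids[i] <- as.character(r[["id"]])
    doc_ids <- if (is.null(r[["documents"]])) character() else
      vapply(r[["documents"]], as.character, "")
    out[[i]] <- new_question_record(ids[i], as.character(r[["body"]]), gold,
                                    doc_ids)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_schema("duplicate question id(s): %s", paste(unique(dup), collapse = ", "))
  out
}

#' Write a question file
#'
#' @param questions list of `question_record` objects.
#' @param path output path.
#' @export
write_questions <- function(questions, path) {
  recs <- lapply(questions, function(q) {
    sn <- q$gold_snippets
    snippets <- lapply(seq_len(nrow(sn)), function(j) {
      list(document = sn$doc_id[j],
           offsetInBeginSection = sn$begin[j],
           offsetInEndSection = sn$end[j],
           text = sn$text[j])
    })
    rec <- list(id = q$id, body = q$body, snippets = snippets)
    if (!is.null(q$doc_ids) && length(q$doc_ids))
      rec$documents <- as.list(q$doc_ids)
    rec
  })
  jsonlite::write_json(list(questions = recs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a document collection
#'
#' JSON-lines, one record per line with fields `doc_id`, `title`,
#' `abstract`. Empty lines are skipped with a warning.
#'
#' @param path path to the JSONL file.
#' @return a named list of `document_record` objects keyed by `doc_id`.
#' @export
read_documents <- function(path) {
  if (!file.exists(path)) stop_schema("document file not found: %s", path)
  lines <- read_lines_lf(path)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning(sprintf("skipped %d empty line(s) in %s", sum(blank), path))
    lines <- lines[!blank]
  }
  recs <- lapply(seq_along(lines), function(i) {
    r <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    if (is.null(r[["doc_id"]]))
      stop_schema("document line %d: missing required field 'doc_id'", i)
    title <- if (is.null(r[["title"]])) "" else as.character(r[["title"]])
    abstract <- if (is.null(r[["abstract"]])) "" else as.character(r[["abstract"]])
    if (!nzchar(title) && !nzchar(abstract))
      stop_schema("document line %d: title and abstract both empty", i)
    structure(list(doc_id = as.character(r[["doc_id"]]), title = title,
                   abstract = abstract), class = "document_record")
  })
  ids <- vapply(recs, `[[`, "", "doc_id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_schema("duplicate doc_id(s): %s", paste(unique(dup), collapse = ", "))
  names(recs) <- ids
  recs
}

#' Write a document collection
#'
#' @param documents named list of `document_record` objects.
#' @param path output JSONL path.
#' @export
write_documents <- function(documents, path) {
  lines <- vapply(documents, function(d) {
    jsonlite::toJSON(list(doc_id = d$doc_id, title = d$title,
                          abstract = d$abstract), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write ranked snippet predictions
#'
#' At most `max_snippets` snippets are written per question (the benchmark
#' submission cap); longer lists are truncated with a warning. Scores must
#' be non-increasing down each list.
#'
#' @param records list of prediction records, each a list with `question_id`
#'   and `ranked_snippets` (data frame with columns `doc_id`, `begin`,
#'   `end`, `score`).
#' @param path output JSON path.
#' @param max_snippets per-question cap (default 10).
#' @export
write_predictions <- function(records, path, max_snippets = 10L) {
  recs <- lapply(records, function(p) {
    sn <- p$ranked_snippets
    if (nrow(sn) > 1 && any(diff(sn$score) > 1e-12))
      stop_schema("question %s: snippet scores are not non-increasing",
                  p$question_id)
    if (any(sn$score < 0 | sn$score > 1))
      stop_schema("question %s: scores outside [0, 1]", p$question_id)
    if (nrow(sn) > max_snippets) {
      warning(sprintf("question %s: truncating %d snippets to %d",
                      p$question_id, nrow(sn), max_snippets))
      sn <- sn[seq_len(max_snippets), , drop = FALSE]
    }
    list(id = p$question_id,
         snippets = lapply(seq_len(nrow(sn)), function(j) {
           list(document = sn$doc_id[j], offsetInBeginSection = sn$begin[j],
                offsetInEndSection = sn$end[j], score = sn$score[j])
         }))
  })
  jsonlite::write_json(list(questions = recs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read ranked snippet predictions
#'
#' @param path prediction JSON path (as written by [write_predictions()]).
#' @return list of prediction records.
#' @export
read_predictions <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj[["questions"]], function(r) {
    sn <- r[["snippets"]]
    df <- if (length(sn) == 0) {
      data.frame(doc_id = character(), begin = integer(), end = integer(),
                 score = numeric(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(sn, function(s) {
        data.frame(doc_id = as.character(s[["document"]]),
                   begin = as.integer(s[["offsetInBeginSection"]]),
                   end = as.integer(s[["offsetInEndSection"]]),
                   score = as.numeric(s[["score"]]), stringsAsFactors = FALSE)
      }))
    }
    list(question_id = as.character(r[["id"]]), ranked_snippets = df)
  })
}

#' Read a word-vector text file
#'
#' One token per line followed by the vector entries, whitespace separated.
#'
#' @param path path to the vector file.
#' @return list with `tokens` (character) and `vectors` (matrix, one column
#'   per token).
#' @export
read_word_vectors <- function(path) {
  lines <- read_lines_lf(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  tokens <- vapply(parts, `[[`, "", 1)
  vecs <- lapply(parts, function(p) as.numeric(p[-1]))
  dims <- lengths(vecs)
  if (length(unique(dims)) != 1)
    stop_schema("inconsistent vector dimensions in %s", path)
  m <- matrix(unlist(vecs), nrow = dims[1],
              dimnames = list(NULL, tokens))
  if (any(!is.finite(m))) stop_schema("non-finite vector entries in %s", path)
  list(tokens = tokens, vectors = m)
}

#' Write a word-vector text file
#'
#' @param tokens character vector of tokens.
#' @param vectors matrix with one column per token.
#' @param path output path.
#' @param digits significant digits written (default 17: round-trip exact
#'   for doubles).
#' @export
write_word_vectors <- function(tokens, vectors, path, digits = 17) {
  stopifnot(length(tokens) == ncol(vectors))
  lines <- vapply(seq_along(tokens), function(i) {
    paste(c(tokens[i], formatC(vectors[, i], digits = digits, format = "g")),
          collapse = " ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-batch MAP evaluation table
#'
#' CSV with header `system,year,batch,map`; one row per (system, year,
#' batch) cell. Used by [mean_paired_difference()], [relative_improvement()]
#' and [paired_ttest()].
#'
#' @param path CSV path.
#' @return a data frame of class `eval_table`.
#' @export
read_eval_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("system", "year", "batch", "map")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_schema("eval table missing column(s): %s", paste(miss, collapse = ", "))
  key <- paste(df$system, df$year, df$batch)
  if (anyDuplicated(key))
    stop_schema("duplicate (system, year, batch) rows in %s", path)
  if (any(df$map < 0 | df$map > 1))
    stop_schema("MAP values outside [0, 1] in %s", path)
  class(df) <- c("eval_table", "data.frame")
  df
}
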