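# KWIC concordances, exact phrase frequencies, modifier profiles.

# validate a phrase query: >= 1 non-empty word norms, no punctuation
.check_query <- function(query) {
  if (length(query) < 1L || !is.character(query) || any(!nzchar(query))) {
    stop("phrase query must contain at least one non-empty word", call. = FALSE)
  }
  query <- tolower(query)
  if (any(!grepl("[\\p{L}\\p{N}]", query, perl = TRUE))) {
    stop("phrase query must not contain punctuation tokens", call. = FALSE)
  }
  query
}

# All contiguous matches of the query norms. Returns a data frame with
# columns doc (document number), start, end (0-based token offsets of the
# first and last node token). With skip_punct, matching runs over the
# subsequence of word tokens, so "gout , flares" matches [gout, flares].
.phrase_matches <- function(index, query, skip_punct = TRUE) {
  L <- length(query)
  hits <- list()
  for (di in seq_along(index$documents)) {
    d <- index$documents[[di]]
    if (skip_punct) {
      tokpos <- which(d$kind == "word")
      seqn <- d$norm[tokpos]
    } else {
      tokpos <- seq_along(d$norm)
      seqn <- d$norm
    }
    n <- length(seqn)
    if (n < L) next
    ok <- seqn[seq_len(n - L + 1L)] == query[1L]
    if (L > 1L) {
      for (k in 2L:L) {
        ok <- ok & seqn[k:(n - L + k)] == query[k]
      }
    }
    st <- which(ok)
    if (!length(st)) next
    hits[[length(hits) + 1L]] <- data.frame(
      doc = di,
      start = tokpos[st] - 1L,
      end = tokpos[st + L - 1L] - 1L)
  }
  if (!length(hits)) {
    return(data.frame(doc = integer(), start = integer(), end = integer()))
  }
  do.call(rbind, hits)
}

#' Keyword-in-context concordance
#'
#' Lists every occurrence of a word or phrase with its surrounding text,
#' the classic concordance view used for qualitative analysis of how an
#' expression is used. Matching is case-insensitive on normalized tokens;
#' by default punctuation tokens between the query words are skipped
#' during matching (so a comma does not break a two-word phrase), which
#' can be disabled.
#'
#' @param index A \code{corpus_index}.
#' @param query Character vector of word norms forming the phrase
#'   (length >= 1, no punctuation).
#' @param context Number of tokens of context shown on each side
#'   (truncated at document edges).
#' @param skip_punct Skip intervening punctuation while matching.
#' @return An object of class \code{kwic}: a data frame with columns
#'   \code{doc_id}, \code{start} (0-based offset of the first node token),
#'   \code{left}, \code{node}, \code{right} (surface text), sorted by
#'   (doc_id, start).
#' @examples
#' idx <- build_index(list(
#'   new_document_from_text("d1", "Severe gout flares need urgent care.")))
#' kwic(idx, "gout", context = 2)
#' @export
kwic <- function(index, query, context = 10L, skip_punct = TRUE) {
  stopifnot(inherits(index, "corpus_index"), context >= 0L)
  query <- .check_query(query)
  m <- .phrase_matches(index, query, skip_punct = skip_punct)

  out <- data.frame(doc_id = character(nrow(m)), start = integer(nrow(m)),
                    left = character(nrow(m)), node = character(nrow(m)),
                    right = character(nrow(m)), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    d <- index$documents[[m$doc[i]]]
    len <- length(d$surface)
    s <- m$start[i]; e <- m$end[i]
    lo <- max(0L, s - context)
    hi <- min(len - 1L, e + context)
    out$doc_id[i] <- d$doc_id
    out$start[i] <- s
    out$left[i] <- if (s > lo) paste(d$surface[(lo + 1L):s], collapse = " ") else ""
    out$node[i] <- paste(d$surface[(s + 1L):(e + 1L)], collapse = " ")
    out$right[i] <- if (hi > e) paste(d$surface[(e + 2L):(hi + 1L)], collapse = " ") else ""
  }
  out <- out[order(out$doc_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("kwic", "data.frame"),
            query = query, context = as.integer(context))
}

#' @export
print.kwic <- function(x, max_rows = 25L, ...) {
  cat(sprintf("KWIC concordance for \"%s\": %d occurrence%s\n",
              paste(attr(x, "query"), collapse = " "), nrow(x),
              if (nrow(x) == 1L) "" else "s"))
  if (!nrow(x)) return(invisible(x))
  shown <- utils::head(x, max_rows)
  wl <- max(nchar(shown$left)); wn <- max(nchar(shown$node))
  for (i in seq_len(nrow(shown))) {
    cat(sprintf("%s  [%s]  %s    (%s:%d)\n",
                formatC(shown$left[i], width = wl, flag = " "),
                formatC(shown$node[i], width = wn),
                shown$right[i], shown$doc_id[i], shown$start[i]))
  }
  if (nrow(x) > max_rows) cat(sprintf("  ... %d more lines\n", nrow(x) - max_rows))
  invisible(x)
}

#' Write a concordance as TSV
#'
#' @param x A \code{kwic} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_kwic <- function(x, path) {
  stopifnot(inherits(x, "kwic"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Exact phrase frequency
#'
#' Counts every starting position at which the phrase matches
#' (overlapping matches all count) and the number of distinct documents
#' with at least one match.
#'
#' @inheritParams kwic
#' @return A list with \code{occurrences} and \code{n_docs}.
#' @examples
#' idx <- build_index(list(
#'   new_document_from_text("d1", "acute gout and acute gout again")))
#' phrase_count(idx, c("acute", "gout"))
#' @export
phrase_count <- function(index, query, skip_punct = TRUE) {
  stopifnot(inherits(index, "corpus_index"))
  query <- .check_query(query)
  m <- .phrase_matches(index, query, skip_punct = skip_punct)
  list(occurrences = nrow(m), n_docs = length(unique(m$doc)))
}

#' Default function-word stoplist
#'
#' Determiners, prepositions, conjunctions, pronouns and auxiliaries that
#' are excluded from modifier profiles when no part-of-speech tags are
#' available.
#'
#' @return A character vector of normalized function words.
#' @export
default_stoplist <- function() {
  c("a", "an", "the", "this", "that", "these", "those", "some", "any",
    "each", "every", "no", "either", "neither", "such", "both", "all",
    "of", "in", "on", "at", "by", "for", "with", "without", "from", "to",
    "into", "onto", "over", "under", "about", "against", "between",
    "among", "through", "during", "before", "after", "above", "below",
    "up", "down", "out", "off", "than", "as", "like",
    "and", "or", "but", "nor", "so", "yet", "if", "because", "while",
    "although", "though", "whereas", "since", "until", "unless", "when",
    "where", "whether",
    "i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
    "us", "them", "my", "your", "his", "its", "our", "their", "mine",
    "yours", "hers", "ours", "theirs", "who", "whom", "whose", "which",
    "what", "there", "here", "one", "ones",
    "is", "are", "was", "were", "be", "been", "being", "am",
    "have", "has", "had", "having", "do", "does", "did", "doing",
    "not", "also", "only", "very", "more", "most", "other", "another")
}

#' Profile the modifiers of a head word
#'
#' A modifier is the word token immediately preceding an occurrence of
#' the head within the same document, with no intervening punctuation.
#' Function words (a bundled stoplist of determiners, prepositions,
#' conjunctions and pronouns) are excluded; when part-of-speech tags are
#' present on a document, only tokens tagged adjective or noun qualify
#' and the tag filter supersedes the stoplist.
#'
#' @param index A \code{corpus_index}.
#' @param head Normalized head word.
#' @param min_count Keep modifiers occurring at least this often.
#' @param stoplist Character vector of norms to exclude (defaults to
#'   [default_stoplist()]).
#' @return A data frame (modifier, count) sorted by count descending,
#'   ties broken alphabetically.
#' @examples
#' idx <- build_index(list(new_document_from_text("d1",
#'   "chronic gout, tophaceous gout and the gout of kings: chronic gout.")))
#' modifier_profile(idx, "gout", min_count = 1)
#' @export
modifier_profile <- function(index, head, min_count = 20L,
                             stoplist = default_stoplist()) {
  stopifnot(inherits(index, "corpus_index"), min_count >= 1L)
  head <- tolower(head)
  stoplist <- tolower(stoplist)
  ix <- index$postings[[head]]
  empty <- data.frame(modifier = character(), count = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(ix)) return(empty)

  mods <- character(0)
  for (i in ix) {
    pos <- index$tok_pos[i]
    if (pos == 0L) next
    d <- index$documents[[index$tok_doc[i]]]
    j <- pos              # 1-based index of preceding token
    if (d$kind[j] != "word") next
    if (!is.null(d$tag) && !is.na(d$tag[j]) && nzchar(d$tag[j])) {
      if (!grepl("^(JJ|NN)", d$tag[j])) next        # adjectives and nouns only
    } else if (d$norm[j] %in% stoplist) {
      next
    }
    mods <- c(mods, d$norm[j])
  }
  if (!length(mods)) return(empty)
  tab <- table(mods)
  out <- data.frame(modifier = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$count >= min_count, , drop = FALSE]
  out <- out[order(-out$count, out$modifier), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.kwic <- function(x, ...) {
  attr(x, "query") <- NULL
  attr(x, "context") <- NULL
  class(x) <- "data.frame"
  x
}
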