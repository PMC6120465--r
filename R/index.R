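# Positional corpus index: documents, vocabulary, postings.

#' Build a positional corpus index
#'
#' Assembles tokenized documents into an immutable index holding the
#' vocabulary frequency table and, for every normalized token type, the
#' sorted postings list of (document, offset) positions. All downstream
#' queries — collocation scoring, concordances, phrase counts, modifier
#' profiles — run against this index. The total token count \eqn{N}
#' includes punctuation tokens.
#'
#' @param documents A list of \code{corpus_document} objects.
#' @param require_terms Optional character vector of normalized terms;
#'   documents containing none of them are dropped, mirroring a Boolean
#'   inclusion filter on the collection.
#' @return A \code{corpus_index} with fields \code{documents},
#'   \code{n_docs}, \code{n_tokens}, \code{vocab} (named integer vector of
#'   corpus frequencies) and \code{postings} (for each norm, integer
#'   indices into the flattened token stream; document and offset are
#'   recovered from \code{tok_doc} / \code{tok_pos}).
#' @examples
#' docs <- list(new_document_from_text("d1", "acute gout flares occur."),
#'              new_document_from_text("d2", "chronic tophaceous gout."))
#' idx <- build_index(docs)
#' idx$vocab[["gout"]]
#' @export
build_index <- function(documents, require_terms = NULL) {
  stopifnot(is.list(documents))
  ok <- vapply(documents, inherits, logical(1), "corpus_document")
  if (!all(ok)) stop("all elements of 'documents' must be corpus_document objects")

  ids <- vapply(documents, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.null(require_terms)) {
    require_terms <- tolower(require_terms)
    keep <- vapply(documents, function(d) any(require_terms %in% d$norm),
                   logical(1))
    documents <- documents[keep]
    ids <- ids[keep]
  }

  lens <- vapply(documents, function(d) length(d$norm), integer(1))
  norm <- unlist(lapply(documents, `[[`, "norm"), use.names = FALSE)
  if (is.null(norm)) norm <- character()
  tok_doc <- rep.int(seq_along(documents), lens)        # document number
  tok_pos <- unlist(lapply(lens, function(n) seq_len(n) - 1L), use.names = FALSE)
  if (is.null(tok_pos)) tok_pos <- integer()

  # postings[[w]]: indices into the flat stream, already sorted by
  # (document, offset) because documents are concatenated in order
  postings <- split(seq_along(norm), norm)

  vocab <- lengths(postings)
  structure(
    list(documents = documents,
         doc_ids = ids,
         doc_lengths = lens,
         n_docs = length(documents),
         n_tokens = length(norm),
         vocab = vocab,
         postings = postings,
         tok_norm = norm,
         tok_doc = tok_doc,
         tok_pos = tok_pos),
    class = "corpus_index"
  )
}

#' Construct a document directly from a text string
#'
#' Convenience constructor used in examples, tests and the synthetic
#' corpus generator.
#'
#' @param doc_id Document identifier.
#' @param text Raw text to tokenize.
#' @param tag Optional character vector of part-of-speech tags, one per
#'   token (pass-through metadata; nothing in the scoring requires tags).
#' @return A \code{corpus_document}.
#' @export
new_document_from_text <- function(doc_id, text, tag = NULL) {
  new_document(doc_id, "plaintext", tokenize(text), tag = tag)
}

#' @export
print.corpus_index <- function(x, ...) {
  cat(sprintf("<corpus index> %d documents, %s tokens, %s types\n",
              x$n_docs, format(x$n_tokens, big.mark = ","),
              format(length(x$vocab), big.mark = ",")))
  invisible(x)
}

#' @export
summary.corpus_index <- function(object, n = 10L, ...) {
  cat(sprintf("Corpus index: %d documents, %s tokens (%s word, %s punct), %s types\n",
              object$n_docs,
              format(object$n_tokens, big.mark = ","),
              format(sum(unlist(lapply(object$documents,
                                       function(d) sum(d$kind == "word")))),
                     big.mark = ","),
              format(sum(unlist(lapply(object$documents,
                                       function(d) sum(d$kind == "punct")))),
                     big.mark = ","),
              format(length(object$vocab), big.mark = ",")))
  if (length(object$vocab)) {
    top <- vocabulary_stats(object)
    cat("Most frequent types:\n")
    print(utils::head(top, n), row.names = FALSE)
  }
  invisible(object)
}

#' Vocabulary frequency table
#'
#' @param index A \code{corpus_index}.
#' @param min_freq Keep types with corpus frequency at least this.
#' @return A data frame (norm, frequency, n_docs) sorted by frequency
#'   descending, ties broken alphabetically. \code{n_docs} is the number
#'   of distinct documents containing the type.
#' @export
vocabulary_stats <- function(index, min_freq = 1L) {
  stopifnot(inherits(index, "corpus_index"), min_freq >= 1L)
  keep <- index$vocab >= min_freq
  norms <- names(index$vocab)[keep]
  freq <- unname(index$vocab[keep])
  ndoc <- vapply(index$postings[norms],
                 function(ix) length(unique(index$tok_doc[ix])), integer(1))
  out <- data.frame(norm = norms, frequency = freq, n_docs = unname(ndoc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$norm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- on-disk layout: manifest.tsv + one token TSV per document -------------

#' Serialize a corpus index to a directory
#'
#' Writes a \code{manifest.tsv} (doc_id, file, source, n_tokens) and one
#' token table per document (columns pos, surface, kind and, if present,
#' tag), all tab-separated UTF-8 text. [read_corpus_index()] rebuilds an
#' identical index from this layout.
#'
#' @param index A \code{corpus_index}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_corpus_index <- function(index, dir) {
  stopifnot(inherits(index, "corpus_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("doc%05d.tsv", seq_along(index$documents))
  for (i in seq_along(index$documents)) {
    d <- index$documents[[i]]
    tab <- as.data.frame(d)
    tab$doc_id <- NULL
    utils::write.table(tab, file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  manifest <- data.frame(
    doc_id = index$doc_ids,
    file = files,
    source = vapply(index$documents, `[[`, character(1), "source"),
    n_tokens = index$doc_lengths,
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' Load a corpus index from its on-disk layout
#'
#' @param dir Directory written by [write_corpus_index()].
#' @return A \code{corpus_index}.
#' @export
read_corpus_index <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.tsv under '", dir, "'", call. = FALSE)
  }
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE,
                                colClasses = "character")
  docs <- lapply(seq_len(nrow(manifest)), function(i) {
    tab <- utils::read.delim(file.path(dir, manifest$file[i]),
                             stringsAsFactors = FALSE,
                             quote = "", colClasses = "character",
                             na.strings = NULL, fileEncoding = "UTF-8")
    toks <- data.frame(surface = tab$surface, norm = tolower(tab$surface),
                       kind = tab$kind, stringsAsFactors = FALSE)
    d <- new_document(manifest$doc_id[i], manifest$source[i], toks,
                      tag = tab$tag)
    d
  })
  build_index(docs)
}
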