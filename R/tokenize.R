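# Tokenization: words and punctuation marks.

# A word token is a maximal run of letters/digits, optionally containing
# internal hyphens or apostrophes ("anti-inflammatory", "Lesch-Nyhan",
# "patient's"); every other non-whitespace character is a single-character
# punctuation token. Whitespace only separates.
.token_regex <- "[\\p{L}\\p{N}]+(?:[-'’][\\p{L}\\p{N}]+)*|[^\\p{L}\\p{N}\\s]"

#' Tokenize raw text into words and punctuation marks
#'
#' Splits text into a sequence of tokens: word tokens are maximal runs of
#' letters and digits (hyphens and apostrophes internal to a word do not
#' split it, so clinical compounds such as \code{anti-inflammatory} stay
#' whole); every other non-whitespace character becomes a single-character
#' punctuation token. Whitespace produces no tokens.
#'
#' @param text A character scalar (may be empty). Longer vectors are
#'   collapsed with newlines.
#' @return A data frame with one row per token and columns
#'   \describe{
#'     \item{surface}{the token as it appeared in the text}
#'     \item{norm}{the lower-cased surface, used for all counting}
#'     \item{kind}{\code{"word"} or \code{"punct"}; a token is punctuation
#'       iff its surface contains no letter or digit}
#'   }
#'   Row \code{i} is the token at 0-based offset \code{i - 1}.
#' @examples
#' tokenize("Acute gout flares occur.")
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) text <- ""
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(surface = character(), norm = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), norm = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  surface <- regmatches(text, list(m))[[1]]
  kind <- ifelse(grepl("[\\p{L}\\p{N}]", surface, perl = TRUE), "word", "punct")
  data.frame(surface = surface, norm = tolower(surface), kind = kind,
             stringsAsFactors = FALSE)
}

#' @keywords internal
new_document <- function(doc_id, source, tokens, tag = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!is.null(tag)) stopifnot(length(tag) == nrow(tokens))
  structure(
    list(doc_id = doc_id, source = source,
         surface = tokens$surface, norm = tokens$norm, kind = tokens$kind,
         tag = tag),
    class = "corpus_document"
  )
}

#' @export
print.corpus_document <- function(x, ...) {
  cat(sprintf("<document '%s'> %d tokens (%s)\n",
              x$doc_id, length(x$norm), x$source))
  invisible(x)
}

#' Token table of a document
#'
#' @param x A document as returned by [read_jats()], [read_plaintext()] or
#'   [generate_corpus()].
#' @param ... Unused.
#' @return A data frame with columns \code{doc_id}, \code{pos} (0-based
#'   token offset), \code{surface}, \code{norm}, \code{kind} and, when
#'   part-of-speech tags were supplied, \code{tag}.
#' @export
as.data.frame.corpus_document <- function(x, ...) {
  n <- length(x$norm)
  out <- data.frame(doc_id = rep(x$doc_id, n),
                    pos = seq_len(n) - 1L,
                    surface = x$surface, norm = x$norm, kind = x$kind,
                    stringsAsFactors = FALSE)
  if (!is.null(x$tag)) out$tag <- x$tag
  out
}
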