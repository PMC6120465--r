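# Windowed co-occurrence counting and the Dunning log-likelihood (G2)
# association statistic.

#' Tabulate windowed co-occurrence around a target term
#'
#' Retrieves every occurrence of the target and counts each token whose
#' offset lies within \code{left} tokens before or \code{right} tokens
#' after it, excluding the target position itself. Windows truncate at
#' document boundaries. Counting is per occurrence: a token inside the
#' windows of two target occurrences contributes twice, and other
#' occurrences of the target itself inside a window do count (a frequent
#' word is typically its own collocate). Punctuation tokens contribute to
#' the context mass \code{W} and may appear in the counts; they are
#' filtered at reporting time, not here, so that \code{W} stays on the
#' same scale as a total token count \code{N} that includes punctuation.
#'
#' @param index A \code{corpus_index}.
#' @param target Normalized (lower-case) target term.
#' @param left,right Window radius in tokens on each side; default a
#'   10-token span either side.
#' @return A list of class \code{window_counts}: \code{target}, \code{W}
#'   (total context-token mass over all occurrences), \code{counts}
#'   (named integer vector of observed co-occurrence per norm),
#'   \code{doc_counts} (distinct documents with at least one
#'   co-occurrence, per norm), \code{n_target_occurrences}.
#' @export
window_counts <- function(index, target, left = 10L, right = 10L) {
  stopifnot(inherits(index, "corpus_index"),
            is.character(target), length(target) == 1L, nzchar(target),
            left >= 0L, right >= 0L, left + right >= 1L)
  target <- tolower(target)

  empty <- structure(list(target = target, W = 0L,
                          counts = integer(0), doc_counts = integer(0),
                          n_target_occurrences = 0L,
                          left = as.integer(left), right = as.integer(right)),
                     class = "window_counts")
  ix <- index$postings[[target]]
  if (is.null(ix)) return(empty)

  offs <- c(if (left > 0L) -(left:1L), if (right > 0L) seq_len(right))
  counts <- integer(0)
  doc_counts <- integer(0)
  W <- 0L

  for (di in unique(index$tok_doc[ix])) {
    d <- index$documents[[di]]
    len <- length(d$norm)
    p <- index$tok_pos[ix[index$tok_doc[ix] == di]]       # 0-based offsets
    ctx <- outer(p, offs, `+`)
    ctx <- ctx[ctx >= 0L & ctx < len]
    if (!length(ctx)) next
    W <- W + length(ctx)
    tab <- table(d$norm[ctx + 1L])
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    counts <- .merge_counts(counts, cnt)
    seen <- names(tab)
    one <- rep.int(1L, length(seen))
    names(one) <- seen
    doc_counts <- .merge_counts(doc_counts, one)
  }

  structure(list(target = target, W = W, counts = counts,
                 doc_counts = doc_counts,
                 n_target_occurrences = length(ix),
                 left = as.integer(left), right = as.integer(right)),
            class = "window_counts")
}

# add two named integer count vectors
.merge_counts <- function(a, b) {
  if (!length(a)) return(b)
  new <- setdiff(names(b), names(a))
  if (length(new)) {
    a <- c(a, structure(integer(length(new)), names = new))
  }
  a[names(b)] <- a[names(b)] + b
  a
}

#' Expected co-occurrence frequency under independence
#'
#' The number of times a word of corpus frequency \code{corpus_freq} is
#' expected to fall inside a context mass of \code{W} tokens if it were
#' distributed at random over a corpus of \code{N} tokens:
#' \eqn{E = W f / N}.
#'
#' @param W Context-token mass (see [window_counts()]).
#' @param corpus_freq Corpus frequency of the candidate collocate.
#' @param N Total number of tokens in the corpus.
#' @return The expected co-occurrence count (vectorized).
#' @export
expected_frequency <- function(W, corpus_freq, N) {
  if (any(N <= 0)) stop("N must be positive", call. = FALSE)
  stopifnot(all(corpus_freq >= 0), all(corpus_freq <= N),
            all(W >= 0), all(W <= N))
  W * corpus_freq / N
}

#' Build the 2x2 co-occurrence contingency table
#'
#' Cross-classifies every token of the corpus by (inside a context window
#' vs. outside) and (is the candidate collocate vs. any other word):
#' \code{o11 = observed}, \code{o12 = W - observed},
#' \code{o21 = corpus_freq - observed},
#' \code{o22 = N - W - corpus_freq + observed}.
#'
#' @param observed Observed co-occurrence count of the candidate inside
#'   the windows.
#' @param W Context-token mass.
#' @param corpus_freq Corpus frequency of the candidate.
#' @param N Total tokens in the corpus.
#' @return A 2x2 integer-valued matrix of class \code{contingency_table}.
#' @export
contingency_table <- function(observed, W, corpus_freq, N) {
  stopifnot(length(observed) == 1L, observed >= 0,
            observed <= W, observed <= corpus_freq,
            W + corpus_freq - observed <= N)
  m <- matrix(c(observed, corpus_freq - observed,
                W - observed, N - W - corpus_freq + observed),
              nrow = 2L,
              dimnames = list(context = c("window", "rest"),
                              word = c("collocate", "other")))
  class(m) <- c("contingency_table", class(m))
  m
}

# vectorized G2 over cell vectors; 0 * log(0) := 0
.g2_cells <- function(o11, o12, o21, o22) {
  N <- o11 + o12 + o21 + o22
  r1 <- o11 + o12; r2 <- o21 + o22
  c1 <- o11 + o21; c2 <- o12 + o22
  term <- function(o, e) {
    out <- numeric(length(o))
    i <- o > 0
    out[i] <- o[i] * log(o[i] / e[i])
    out
  }
  g <- 2 * (term(o11, r1 * c1 / N) + term(o12, r1 * c2 / N) +
            term(o21, r2 * c1 / N) + term(o22, r2 * c2 / N))
  pmax(g, 0)   # clamp tiny negative floating error at independence
}

#' Dunning log-likelihood statistic for a 2x2 table
#'
#' The likelihood-ratio statistic
#' \eqn{G^2 = 2 \sum_{ij} O_{ij} \ln(O_{ij}/E_{ij})} with expected cells
#' \eqn{E_{ij}} from the row and column marginals, and the convention
#' \eqn{0 \ln 0 = 0}. No continuity correction or smoothing is applied.
#' Under independence \eqn{G^2} is asymptotically chi-square with one
#' degree of freedom.
#'
#' @param table A 2x2 table: a \code{contingency_table}, any 2x2 matrix,
#'   or a numeric vector \code{c(o11, o12, o21, o22)}.
#' @return The G2 statistic (non-negative).
#' @examples
#' g2_log_likelihood(contingency_table(20, 20, 20, 100))
#' @export
g2_log_likelihood <- function(table) {
  cells <- if (is.matrix(table)) {
    stopifnot(all(dim(table) == 2L))
    c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  } else {
    stopifnot(is.numeric(table), length(table) == 4L)
    table
  }
  if (any(cells < 0)) stop("contingency cells must be non-negative", call. = FALSE)
  if (sum(cells) <= 0) stop("empty contingency table", call. = FALSE)
  .g2_cells(cells[1], cells[2], cells[3], cells[4])
}

#' Upper-tail p-value for a G2 score
#'
#' Reference distribution is chi-square with one degree of freedom, the
#' asymptotic null law of the Dunning statistic.
#'
#' @param g2 G2 score(s), non-negative.
#' @return \eqn{P(\chi^2_1 > g2)} (vectorized).
#' @export
g2_pvalue <- function(g2) {
  if (any(g2 < 0)) stop("g2 must be non-negative", call. = FALSE)
  stats::pchisq(g2, df = 1L, lower.tail = FALSE)
}

#' Extract and score the collocates of a target term
#'
#' The main analysis. Tabulates windowed co-occurrence around the target
#' once, keeps candidate words co-occurring at least \code{min_cooccur}
#' times in context and occurring at least \code{min_corpus} times in the
#' whole corpus, builds each candidate's 2x2 contingency table and scores
#' it with [g2_log_likelihood()]. Candidates are ranked by score; words
#' with the highest scores are those most strongly associated with the
#' target.
#'
#' @param index A \code{corpus_index}.
#' @param target Normalized target term.
#' @param left,right Window radius in tokens (default 10 each side).
#' @param min_cooccur Minimum observed co-occurrence with the target.
#' @param min_corpus Minimum corpus frequency.
#' @param exclude_punct Drop punctuation tokens from the report (they
#'   still contribute to the context mass \code{W}).
#' @param top_k Optionally truncate to the top \code{k} records.
#' @return An object of class \code{collocations}: a data frame with one
#'   row per collocate and columns \code{rank}, \code{word},
#'   \code{corpus_freq}, \code{expected}, \code{observed}, \code{n_texts},
#'   \code{log_likelihood}, sorted by score descending (ties: corpus
#'   frequency descending, then alphabetical). Attributes carry the
#'   target, window, context mass \code{W}, corpus size \code{N} and the
#'   number of target occurrences.
#' @examples
#' docs <- lapply(1:3, function(i)
#'   new_document_from_text(paste0("d", i),
#'     strrep("acute gout flares hurt . filler words here ", 20)))
#' collocates(build_index(docs), "gout", min_cooccur = 2, min_corpus = 2)
#' @export
collocates <- function(index, target, left = 10L, right = 10L,
                       min_cooccur = 10L, min_corpus = 50L,
                       exclude_punct = TRUE, top_k = NULL) {
  stopifnot(min_cooccur >= 1L, min_corpus >= 1L)
  wc <- window_counts(index, target, left = left, right = right)
  N <- index$n_tokens

  words <- names(wc$counts)
  if (length(words) && exclude_punct) {
    words <- words[grepl("[\\p{L}\\p{N}]", words, perl = TRUE)]
  }
  observed <- unname(wc$counts[words])
  corpus_freq <- unname(index$vocab[words])
  keep <- which(observed >= min_cooccur & corpus_freq >= min_corpus)

  out <- data.frame(
    rank = integer(0), word = character(0), corpus_freq = integer(0),
    expected = numeric(0), observed = integer(0), n_texts = integer(0),
    log_likelihood = numeric(0), stringsAsFactors = FALSE)

  if (length(keep)) {
    words <- words[keep]; observed <- observed[keep]
    corpus_freq <- corpus_freq[keep]
    # per-occurrence counting can, in very dense corpora, push observed
    # above corpus_freq (a token inside two overlapping windows counts
    # twice); the outside-window cells are floored at zero so the table
    # stays valid, which scores such words as maximally associated
    o21 <- pmax(0L, corpus_freq - observed)
    ll <- .g2_cells(observed, wc$W - observed, o21, N - wc$W - o21)
    out <- data.frame(
      rank = NA_integer_, word = words, corpus_freq = corpus_freq,
      expected = expected_frequency(wc$W, corpus_freq, N),
      observed = observed,
      n_texts = unname(wc$doc_counts[words]),
      log_likelihood = ll, stringsAsFactors = FALSE)
    out <- out[order(-out$log_likelihood, -out$corpus_freq, out$word), ,
               drop = FALSE]
    if (!is.null(top_k)) out <- utils::head(out, top_k)
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
  }

  structure(out,
            class = c("collocations", "data.frame"),
            target = wc$target, left = wc$left, right = wc$right,
            W = wc$W, N = N,
            n_target_occurrences = wc$n_target_occurrences,
            min_cooccur = min_cooccur, min_corpus = min_corpus)
}

#' @export
print.collocations <- function(x, digits = 3L, max_rows = 25L, ...) {
  cat(sprintf("Collocates of '%s' (window %d left / %d right)\n",
              attr(x, "target"), attr(x, "left"), attr(x, "right")))
  cat(sprintf("  target occurrences: %s; context mass W = %s; corpus N = %s\n",
              format(attr(x, "n_target_occurrences"), big.mark = ","),
              format(attr(x, "W"), big.mark = ","),
              format(attr(x, "N"), big.mark = ",")))
  if (nrow(x) == 0L) {
    cat("  (no collocate passed the frequency thresholds)\n")
    return(invisible(x))
  }
  shown <- utils::head(as.data.frame(x), max_rows)
  shown$expected <- formatC(shown$expected, format = "f", digits = digits)
  shown$log_likelihood <- formatC(shown$log_likelihood, format = "f",
                                  digits = digits)
  print(shown, row.names = FALSE)
  if (nrow(x) > max_rows) cat(sprintf("  ... %d more rows\n", nrow(x) - max_rows))
  invisible(x)
}

#' @export
summary.collocations <- function(object, ...) {
  cat(sprintf(
    "Collocation analysis of '%s': %d collocates passed thresholds (observed >= %d, corpus >= %d)\n",
    attr(object, "target"), nrow(object),
    attr(object, "min_cooccur"), attr(object, "min_corpus")))
  if (nrow(object)) {
    cat(sprintf("  top collocate: '%s' (G2 = %.3f, observed %d vs expected %.3f)\n",
                object$word[1], object$log_likelihood[1],
                object$observed[1], object$expected[1]))
    cat(sprintf("  G2 range: %.3f .. %.3f\n",
                min(object$log_likelihood), max(object$log_likelihood)))
  }
  invisible(object)
}

#' Write a collocation table as TSV
#'
#' Emits the six reporting columns (word, corpus_freq, expected, observed,
#' n_texts, log_likelihood) with a header row; real-valued columns are
#' formatted to a fixed number of decimals.
#'
#' @param x A \code{collocations} object.
#' @param path Output file path.
#' @param digits Decimal places for \code{expected} and
#'   \code{log_likelihood}.
#' @return \code{path}, invisibly.
#' @export
write_collocates <- function(x, path, digits = 3L) {
  stopifnot(inherits(x, "collocations"))
  tab <- as.data.frame(x)[, c("word", "corpus_freq", "expected", "observed",
                              "n_texts", "log_likelihood"), drop = FALSE]
  tab$expected <- formatC(tab$expected, format = "f", digits = digits)
  tab$log_likelihood <- formatC(tab$log_likelihood, format = "f", digits = digits)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
as.data.frame.collocations <- function(x, ...) {
  for (a in c("target", "left", "right", "W", "N", "n_target_occurrences",
              "min_cooccur", "min_corpus")) attr(x, a) <- NULL
  class(x) <- "data.frame"
  x
}
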