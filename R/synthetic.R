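# Synthetic corpora with known collocational structure: Zipfian
# background, planted target word, associates inserted into windows at
# controlled strengths.

#' Configuration for the synthetic corpus generator
#'
#' @param vocab_size Number of background word types (Zipf-ranked).
#' @param zipf_exponent Exponent of the rank-frequency law; background
#'   word of rank r is drawn with probability proportional to
#'   \eqn{r^{-s}}. A Zipfian (not uniform) background ensures
#'   corpus-frequency thresholds are meaningfully exercised.
#' @param n_docs Number of documents.
#' @param doc_length Tokens per document: a single number, or a
#'   length-two range from which each document's length is drawn
#'   uniformly.
#' @param target The planted target word.
#' @param target_rate Probability that any token position is the target.
#' @param associates A list of \code{list(word=, strength=, max_offset=)}
#'   entries: for each target occurrence, with probability
#'   \code{strength} one occurrence of \code{word} is written into a
#'   uniformly chosen free offset within \code{max_offset} tokens of the
#'   target.
#' @param punct_rate Probability that a non-target position is a
#'   punctuation token.
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return A validated list of class \code{synthetic_corpus_config}.
#' @export
synthetic_corpus_config <- function(vocab_size = 500L, zipf_exponent = 1.0,
                                    n_docs = 20L, doc_length = 500L,
                                    target = "gout", target_rate = 0.01,
                                    associates = list(), punct_rate = 0.1,
                                    seed = 1L) {
  stopifnot(vocab_size >= 10L, zipf_exponent > 0, n_docs >= 1L,
            length(doc_length) %in% c(1L, 2L), all(doc_length >= 20L),
            is.character(target), nzchar(target),
            target_rate >= 0, target_rate <= 1,
            punct_rate >= 0, punct_rate <= 1)
  target <- tolower(target)
  words <- vapply(associates, function(a) tolower(a$word), character(1))
  if (length(words)) {
    for (a in associates) {
      stopifnot(is.numeric(a$strength), a$strength >= 0, a$strength <= 1,
                is.numeric(a$max_offset), a$max_offset >= 1)
    }
    if (anyDuplicated(words) || target %in% words) {
      stop("associate words must be distinct from each other and from the target",
           call. = FALSE)
    }
  }
  structure(list(vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent,
                 n_docs = as.integer(n_docs),
                 doc_length = as.integer(doc_length),
                 target = target, target_rate = target_rate,
                 associates = lapply(associates, function(a)
                   list(word = tolower(a$word), strength = a$strength,
                        max_offset = as.integer(a$max_offset))),
                 punct_rate = punct_rate, seed = as.integer(seed)),
            class = "synthetic_corpus_config")
}

# run code with a private RNG stream, restoring global state afterwards
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Generate a synthetic corpus with planted collocations
#'
#' Background tokens are drawn i.i.d. from a Zipf-like rank-frequency
#' distribution, with punctuation interleaved at \code{punct_rate}; each
#' position becomes the target with probability \code{target_rate}. For
#' each target occurrence and each configured associate, with the
#' configured probability one occurrence of the associate is written over
#' a uniformly chosen free background position within \code{max_offset}
#' tokens of the target (never over the target itself or an earlier
#' insertion); infeasible insertions are skipped and recorded. Insertions
#' overwrite rather than lengthen, keeping document lengths exact. The
#' returned ledger — not the sampling intention — is the ground truth of
#' how many co-occurrences were planted.
#'
#' @param config A [synthetic_corpus_config()].
#' @return A list of class \code{synthetic_corpus}: \code{documents}
#'   (list of \code{corpus_document}), \code{ledger} (data frame
#'   \code{doc_id}, \code{word}, \code{inserted}, \code{skipped}),
#'   \code{config}.
#' @examples
#' cfg <- synthetic_corpus_config(n_docs = 2, doc_length = 50,
#'   target_rate = 0.05,
#'   associates = list(list(word = "flares", strength = 0.9, max_offset = 5)),
#'   seed = 42)
#' corp <- generate_corpus(cfg)
#' corp$ledger
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_corpus_config"))
  .with_seed(config$seed, {
    V <- config$vocab_size
    bg <- sprintf("w%04d", seq_len(V))
    p_bg <- seq_len(V)^(-config$zipf_exponent)
    p_bg <- p_bg / sum(p_bg)
    puncts <- c(".", ",")
    assoc_words <- vapply(config$associates, `[[`, character(1), "word")

    docs <- vector("list", config$n_docs)
    ledger <- list()
    for (di in seq_len(config$n_docs)) {
      n <- if (length(config$doc_length) == 2L) {
        sample(config$doc_length[1]:config$doc_length[2], 1L)
      } else config$doc_length
      tok <- sample(bg, n, replace = TRUE, prob = p_bg)
      is_p <- stats::runif(n) < config$punct_rate
      if (any(is_p)) tok[is_p] <- sample(puncts, sum(is_p), replace = TRUE)
      is_t <- stats::runif(n) < config$target_rate
      tok[is_t] <- config$target
      tpos <- which(is_t)

      used <- logical(n)          # positions consumed by an insertion
      ins <- skip <- structure(integer(length(assoc_words)), names = assoc_words)
      for (p in tpos) {
        for (a in config$associates) {
          if (stats::runif(1) >= a$strength) next
          lo <- max(1L, p - a$max_offset)
          hi <- min(n, p + a$max_offset)
          free <- setdiff(lo:hi, p)
          free <- free[!is_t[free] & !used[free]]
          if (!length(free)) {
            skip[a$word] <- skip[a$word] + 1L
            next
          }
          q <- if (length(free) == 1L) free else sample(free, 1L)
          tok[q] <- a$word
          used[q] <- TRUE
          ins[a$word] <- ins[a$word] + 1L
        }
      }

      doc_id <- sprintf("doc%04d", di)
      kind <- ifelse(tok %in% puncts, "punct", "word")
      docs[[di]] <- new_document(doc_id, "plaintext",
                                 data.frame(surface = tok, norm = tok,
                                            kind = kind,
                                            stringsAsFactors = FALSE))
      if (length(assoc_words)) {
        ledger[[di]] <- data.frame(doc_id = doc_id, word = assoc_words,
                                   inserted = unname(ins),
                                   skipped = unname(skip),
                                   stringsAsFactors = FALSE)
      }
    }
    ledger <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(doc_id = character(), word = character(),
                 inserted = integer(), skipped = integer(),
                 stringsAsFactors = FALSE)
    rownames(ledger) <- NULL
    structure(list(documents = docs, ledger = ledger, config = config),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic corpus> %d documents, target '%s', %d associate(s), seed %d\n",
              length(x$documents), x$config$target,
              length(x$config$associates), x$config$seed))
  if (nrow(x$ledger)) {
    tot <- stats::aggregate(cbind(inserted, skipped) ~ word, x$ledger, sum)
    print(tot, row.names = FALSE)
  }
  invisible(x)
}

#' Write a synthetic corpus to plain-text files
#'
#' One text file per document (tokens joined by single spaces — the
#' tokenizer recovers the exact token sequence) plus \code{ledger.tsv},
#' so the generated corpus can be re-ingested through the ordinary
#' plain-text reader.
#'
#' @param corpus A \code{synthetic_corpus}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in corpus$documents) {
    writeLines(paste(d$surface, collapse = " "),
               file.path(dir, paste0(d$doc_id, ".txt")), useBytes = TRUE)
  }
  utils::write.table(corpus$ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' Draw a null 2x2 co-occurrence table
#'
#' Under the null of no association, the count of a word with corpus
#' frequency \code{corpus_freq} falling inside a context mass of \code{W}
#' tokens out of \code{N} is hypergeometric (population \code{N},
#' successes \code{corpus_freq}, draws \code{W}). Used to calibrate the
#' type-I error of the G2 statistic.
#'
#' @param W Context-token mass.
#' @param corpus_freq Corpus frequency of the candidate word.
#' @param N Total tokens.
#' @param seed Optional seed; consecutive seeds give i.i.d. tables.
#' @return A \code{contingency_table}.
#' @export
sample_null_contingency <- function(W, corpus_freq, N, seed = NULL) {
  stopifnot(N > 0, corpus_freq >= 0, corpus_freq <= N, W >= 0, W <= N)
  draw <- function() {
    o11 <- stats::rhyper(1L, m = corpus_freq, n = N - corpus_freq, k = W)
    contingency_table(o11, W, corpus_freq, N)
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Sample the null distribution of G2
#'
#' Convenience wrapper drawing many independent null tables and scoring
#' each, for calibration against the chi-square(1) reference.
#'
#' @param n_draws Number of tables.
#' @inheritParams sample_null_contingency
#' @param seed Seed for the whole sample.
#' @return Numeric vector of G2 scores of length \code{n_draws}.
#' @export
sample_null_g2 <- function(n_draws, W, corpus_freq, N, seed = 1L) {
  stopifnot(n_draws >= 1L, N > 0, corpus_freq >= 0, corpus_freq <= N,
            W >= 0, W <= N)
  .with_seed(seed, {
    o11 <- stats::rhyper(n_draws, m = corpus_freq, n = N - corpus_freq, k = W)
    .g2_cells(o11, W - o11, corpus_freq - o11, N - W - corpus_freq + o11)
  })
}
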