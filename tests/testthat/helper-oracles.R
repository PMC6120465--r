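# Independent naive-scan oracles. These deliberately share no code with
# the package internals: windows are materialized as explicit token
# lists, phrase matching walks token by token, and G2 is computed from
# the two-binomial likelihood-ratio formulation rather than the
# observed/expected cell sum.

# G2 as 2*[logL(p1;k1,n1) + logL(p2;k2,n2) - logL(p;k1,n1) - logL(p;k2,n2)]
oracle_g2 <- function(o11, o12, o21, o22) {
  ll <- function(k, n, p) {
    t <- 0
    if (k > 0) t <- t + k * log(p)
    if (n - k > 0) t <- t + (n - k) * log(1 - p)
    t
  }
  k1 <- o11; n1 <- o11 + o12
  k2 <- o21; n2 <- o21 + o22
  if (n1 + n2 == 0) return(0)
  p <- (k1 + k2) / (n1 + n2)
  p1 <- if (n1 > 0) k1 / n1 else 0
  p2 <- if (n2 > 0) k2 / n2 else 0
  2 * (ll(k1, n1, p1) + ll(k2, n2, p2) - ll(k1, n1, p) - ll(k2, n2, p))
}

# every (occurrence, offset) pair enumerated one by one
oracle_window_counts <- function(docs, target, left, right) {
  ctx <- character(0)
  ctx_doc <- character(0)
  n_occ <- 0L
  for (d in docs) {
    len <- length(d$norm)
    for (pos in which(d$norm == target)) {     # 1-based
      n_occ <- n_occ + 1L
      for (off in seq(-left, right)) {
        if (off == 0L) next
        q <- pos + off
        if (q < 1L || q > len) next
        ctx <- c(ctx, d$norm[q])
        ctx_doc <- c(ctx_doc, d$doc_id)
      }
    }
  }
  counts <- table(ctx)
  doc_counts <- vapply(names(counts),
                       function(w) length(unique(ctx_doc[ctx == w])),
                       integer(1))
  list(W = length(ctx),
       counts = structure(as.integer(counts), names = names(counts)),
       doc_counts = doc_counts,
       n_target_occurrences = n_occ)
}

oracle_collocates <- function(docs, target, left = 10L, right = 10L,
                              min_cooccur = 10L, min_corpus = 50L,
                              exclude_punct = TRUE) {
  all_norms <- unlist(lapply(docs, `[[`, "norm"))
  N <- length(all_norms)
  vocab <- table(all_norms)
  wc <- oracle_window_counts(docs, target, left, right)
  words <- names(wc$counts)
  if (exclude_punct) words <- words[grepl("[[:alnum:]]", words)]
  rows <- list()
  for (w in words) {
    O <- wc$counts[[w]]
    f <- as.integer(vocab[[w]])
    if (O < min_cooccur || f < min_corpus) next
    o21 <- max(0L, f - O)   # same outside-cell floor as the implementation
    rows[[w]] <- data.frame(
      word = w, corpus_freq = f, expected = wc$W * f / N, observed = O,
      n_texts = wc$doc_counts[[w]],
      log_likelihood = oracle_g2(O, wc$W - O, o21, N - wc$W - o21),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(word = character(), corpus_freq = integer(),
                      expected = numeric(), observed = integer(),
                      n_texts = integer(), log_likelihood = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$log_likelihood, -out$corpus_freq, out$word), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# token-by-token walk; returns (doc_id, start, end), 0-based offsets
oracle_phrase_matches <- function(docs, query, skip_punct = TRUE) {
  hits <- data.frame(doc_id = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
  for (d in docs) {
    len <- length(d$norm)
    for (i in seq_len(len)) {
      if (skip_punct) {
        if (d$kind[i] != "word") next
        j <- i
        matched <- TRUE
        for (k in seq_along(query)) {
          while (j <= len && d$kind[j] != "word") j <- j + 1L
          if (j > len || d$norm[j] != query[k]) {
            matched <- FALSE
            break
          }
          last <- j
          j <- j + 1L
        }
      } else {
        last <- i + length(query) - 1L
        if (last > len) next
        matched <- all(d$norm[i:last] == query)
      }
      if (matched) {
        hits <- rbind(hits, data.frame(doc_id = d$doc_id, start = i - 1L,
                                       end = last - 1L,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  hits
}

oracle_phrase_count <- function(docs, query, skip_punct = TRUE) {
  m <- oracle_phrase_matches(docs, query, skip_punct)
  list(occurrences = nrow(m), n_docs = length(unique(m$doc_id)))
}

oracle_kwic <- function(docs, query, context = 10L) {
  m <- oracle_phrase_matches(docs, query, TRUE)
  by_id <- stats::setNames(docs, vapply(docs, `[[`, character(1), "doc_id"))
  out <- m[order(m$doc_id, m$start), , drop = FALSE]
  lines <- data.frame(doc_id = character(0), start = integer(0),
                      left = character(0), node = character(0),
                      right = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    d <- by_id[[out$doc_id[i]]]
    len <- length(d$surface)
    s <- out$start[i]; e <- out$end[i]
    left <- if (s > 0) paste(d$surface[max(1L, s - context + 1L):s],
                             collapse = " ") else ""
    right <- if (e < len - 1L) {
      paste(d$surface[(e + 2L):min(len, e + 1L + context)], collapse = " ")
    } else ""
    lines <- rbind(lines, data.frame(
      doc_id = out$doc_id[i], start = s, left = left,
      node = paste(d$surface[(s + 1L):(e + 1L)], collapse = " "),
      right = right, stringsAsFactors = FALSE))
  }
  rownames(lines) <- NULL
  lines
}

oracle_modifiers <- function(docs, head, min_count = 1L,
                             stoplist = default_stoplist()) {
  mods <- character(0)
  for (d in docs) {
    for (pos in which(d$norm == head)) {
      if (pos == 1L) next
      prev <- pos - 1L
      if (d$kind[prev] != "word") next
      if (!is.null(d$tag) && !is.na(d$tag[prev]) && nzchar(d$tag[prev])) {
        if (!grepl("^(JJ|NN)", d$tag[prev])) next
      } else if (d$norm[prev] %in% stoplist) next
      mods <- c(mods, d$norm[prev])
    }
  }
  tab <- table(mods)
  out <- data.frame(modifier = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$count >= min_count, , drop = FALSE]
  out <- out[order(-out$count, out$modifier), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# small random corpora for oracle-equivalence checks
random_test_corpus <- function(seed, n_docs = 8L, doc_length = 150L,
                               target_rate = 0.03) {
  cfg <- synthetic_corpus_config(
    vocab_size = 40L + (seed %% 30L), zipf_exponent = 1.0,
    n_docs = n_docs, doc_length = doc_length,
    target = "gout", target_rate = target_rate,
    associates = list(
      list(word = "flares", strength = 0.7, max_offset = 8L),
      list(word = "chronic", strength = 0.3, max_offset = 5L)),
    punct_rate = 0.12, seed = seed)
  generate_corpus(cfg)
}
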