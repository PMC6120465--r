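# Windowed co-occurrence counting and the G2 statistic.

test_that("window counting follows the per-occurrence rule with truncation", {
  idx <- build_index(list(new_document_from_text("d", "a b T c d")))
  wc <- window_counts(idx, "t", 2, 2)
  expect_equal(wc$W, 4L)
  expect_equal(wc$counts[c("a", "b", "c", "d")],
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(wc$n_target_occurrences, 1L)

  # left window truncated at document start
  wc2 <- window_counts(build_index(list(new_document_from_text("d", "T c"))),
                       "t", 10, 10)
  expect_equal(wc2$W, 1L)
  expect_equal(wc2$counts, c(c = 1L))

  # self-collocation and per-occurrence counting: in "T a T" each target
  # occurrence sees the other one plus 'a' inside a 2-token window
  wc3 <- window_counts(build_index(list(new_document_from_text("d", "T a T"))),
                       "t", 2, 2)
  expect_equal(wc3$W, 4L)
  expect_equal(wc3$counts[c("a", "t")], c(a = 2L, t = 2L))
  # the target position itself is always excluded from its own window
  wc3b <- window_counts(build_index(list(new_document_from_text("d", "T a T"))),
                        "t", 1, 1)
  expect_equal(wc3b$W, 2L)
  expect_equal(wc3b$counts, c(a = 2L))

  # absent target is not an error
  wc4 <- window_counts(idx, "absent", 10, 10)
  expect_equal(wc4$W, 0L)
  expect_equal(length(wc4$counts), 0L)
})

test_that("window counts match the brute-force (occurrence, offset) oracle", {
  for (seed in c(2, 21, 33)) {
    corp <- random_test_corpus(seed, n_docs = 5L, doc_length = 120L)
    idx <- build_index(corp$documents)
    for (target in c("gout", "flares", "w0001")) {
      wc <- window_counts(idx, target, 10, 10)
      ora <- oracle_window_counts(corp$documents, target, 10, 10)
      expect_equal(wc$W, ora$W)
      expect_equal(wc$n_target_occurrences, ora$n_target_occurrences)
      expect_equal(wc$counts[order(names(wc$counts))],
                   ora$counts[order(names(ora$counts))])
      expect_equal(wc$doc_counts[order(names(wc$doc_counts))],
                   ora$doc_counts[order(names(ora$doc_counts))])
    }
    # asymmetric and degenerate windows
    wc <- window_counts(idx, "gout", 0, 3)
    ora <- oracle_window_counts(corp$documents, "gout", 0, 3)
    expect_equal(wc$W, ora$W)
    expect_equal(wc$counts[order(names(wc$counts))],
                 ora$counts[order(names(ora$counts))])
  }
})

test_that("window counts satisfy their mass invariants", {
  corp <- random_test_corpus(8)
  idx <- build_index(corp$documents)
  wc <- window_counts(idx, "gout", 10, 10)
  expect_equal(sum(wc$counts), wc$W)
  expect_true(all(wc$counts <= wc$W))
  expect_true(all(wc$doc_counts <= pmin(wc$counts, idx$n_docs)))
  expect_lte(wc$W, 20L * wc$n_target_occurrences)
})

test_that("expected frequency is W*f/N with its edge cases", {
  expect_equal(expected_frequency(100, 50, 1000), 5)
  expect_equal(expected_frequency(100, 0, 1000), 0)
  expect_equal(expected_frequency(1000, 37, 1000), 37)  # window covers corpus
  expect_error(expected_frequency(10, 5, 0), "positive")
})

test_that("G2 matches closed forms and the independent binomial formulation", {
  # exact independence
  expect_equal(g2_log_likelihood(c(10, 10, 10, 10)), 0)
  # perfect association: 80 * ln 2
  expect_equal(g2_log_likelihood(contingency_table(20, 20, 20, 40)),
               80 * log(2), tolerance = 1e-12)
  # zero marginal
  expect_equal(g2_log_likelihood(c(0, 0, 5, 7)), 0)
  # symmetry under transposition
  m <- matrix(c(12, 3, 40, 200), 2)
  expect_equal(g2_log_likelihood(m), g2_log_likelihood(t(m)))

  set.seed(42)
  for (i in 1:30) {
    cells <- rpois(4, lambda = sample(c(3, 20, 400), 1)) + sample(0:1, 4, TRUE)
    expect_equal(g2_log_likelihood(cells),
                 oracle_g2(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }

  expect_error(g2_log_likelihood(c(-1, 2, 3, 4)), "non-negative")
})

test_that("G2 is monotone as o11 departs its expectation with fixed marginals", {
  W <- 500; f <- 300; N <- 10000
  e11 <- W * f / N   # 15
  o <- 0:200
  feasible <- o <= W & o <= f
  g <- vapply(o[feasible], function(x)
    g2_log_likelihood(contingency_table(x, W, f, N)), numeric(1))
  ov <- o[feasible]
  expect_true(all(diff(g[ov > ceiling(e11)]) > 0))
  expect_true(all(diff(g[ov < floor(e11)]) < 0))
})

test_that("g2_pvalue is the chi-square(1) upper tail", {
  expect_equal(g2_pvalue(0), 1)
  expect_equal(g2_pvalue(qchisq(0.95, 1)), 0.05, tolerance = 1e-6)
  expect_lt(g2_pvalue(6183.6), 1e-300)
  expect_true(all(diff(g2_pvalue(c(0, 1, 5, 50))) < 0))
  expect_error(g2_pvalue(-1), "non-negative")
})

test_that("collocates ranks a strongly planted associate first", {
  cfg <- synthetic_corpus_config(
    vocab_size = 50L, n_docs = 10L, doc_length = 400L,
    target = "gout", target_rate = 0.02,
    associates = list(list(word = "flares", strength = 0.9, max_offset = 8L)),
    punct_rate = 0.1, seed = 99L)
  corp <- generate_corpus(cfg)
  idx <- build_index(corp$documents)
  res <- collocates(idx, "gout", min_cooccur = 5, min_corpus = 5)
  expect_equal(res$word[1], "flares")
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(all(diff(res$log_likelihood) <= 0))
  expect_true(all(res$observed <= attr(res, "W")))
  expect_equal(res$expected,
               expected_frequency(attr(res, "W"), res$corpus_freq, attr(res, "N")))
})

test_that("collocates filters, excludes punctuation, and handles absent targets", {
  corp <- random_test_corpus(4)
  idx <- build_index(corp$documents)
  res <- collocates(idx, "gout", min_cooccur = 2, min_corpus = 2)
  expect_false(any(res$word %in% c(".", ",")))
  withp <- collocates(idx, "gout", min_cooccur = 2, min_corpus = 2,
                      exclude_punct = FALSE)
  expect_true(any(withp$word %in% c(".", ",")))

  # thresholds above every count -> empty, absent target -> empty
  expect_equal(nrow(collocates(idx, "gout", min_cooccur = 10000)), 0L)
  expect_equal(nrow(collocates(idx, "notaword")), 0L)

  expect_named(res, c("rank", "word", "corpus_freq", "expected", "observed",
                      "n_texts", "log_likelihood"))
})

test_that("scores are invariant under word renaming and document permutation", {
  corp <- random_test_corpus(12, n_docs = 6L, doc_length = 100L)
  idx <- build_index(corp$documents)
  base <- collocates(idx, "gout", min_cooccur = 2, min_corpus = 2)

  # permute document order
  perm <- rev(corp$documents)
  res_p <- collocates(build_index(perm), "gout", min_cooccur = 2, min_corpus = 2)
  expect_equal(as.data.frame(res_p), as.data.frame(base))

  # bijectively rename every word: scores unchanged, words mapped
  rename <- function(w) paste0("x", w)
  renamed <- lapply(corp$documents, function(d) {
    keep <- d$kind == "word"
    surf <- d$surface
    surf[keep] <- rename(surf[keep])
    new_document_from_text(d$doc_id, paste(surf, collapse = " "))
  })
  res_r <- collocates(build_index(renamed), rename("gout"),
                      min_cooccur = 2, min_corpus = 2)
  expect_equal(res_r$log_likelihood, base$log_likelihood)
  expect_equal(res_r$word, rename(base$word))
  expect_equal(res_r$observed, base$observed)
})

test_that("the collocation TSV writer emits the six reporting columns", {
  corp <- random_test_corpus(6)
  res <- collocates(build_index(corp$documents), "gout",
                    min_cooccur = 2, min_corpus = 2)
  path <- tempfile(fileext = ".tsv")
  write_collocates(res, path)
  tab <- read.delim(path)
  expect_named(tab, c("word", "corpus_freq", "expected", "observed",
                      "n_texts", "log_likelihood"))
  expect_equal(nrow(tab), nrow(res))
  # 3-decimal fixed formatting
  raw <- readLines(path)[2]
  expect_match(raw, "\t[0-9]+\\.[0-9]{3}\t")
})
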