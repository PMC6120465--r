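# collocr

Windowed collocation and concordance analysis for text corpora, aimed at
computational-lexicography studies of specialist language — for example,
profiling how a clinical research community actually uses a disease term
across ten years of full-text articles. The package is for linguists,
clinicians and text-mining researchers who want the classic corpus-query
toolkit (collocates, concordances, phrase frequencies, modifier
profiles) as plain R functions over a reproducible positional index.

## What it computes

The quantitative core is the **Dunning log-likelihood (G²) association
measure** over windowed co-occurrence. For a target word (e.g. *gout*),
every token within a fixed span of *L* tokens to the left and *R* to the
right of each occurrence (default 10/10) counts as context. For a
candidate collocate with corpus frequency *f*, observed co-occurrence
*O*, context mass *W* (total context tokens over all target occurrences,
after truncation at document boundaries) and corpus size *N*, the
expected co-occurrence under independence is

    E = W · f / N

and the association score is the likelihood-ratio statistic over the
2×2 table cross-classifying tokens by (inside window / outside) ×
(candidate / other):

    G² = 2 Σᵢⱼ Oᵢⱼ ln(Oᵢⱼ / Eᵢⱼ),   0·ln 0 ≡ 0

which is asymptotically χ²₁ under independence. Candidates must co-occur
at least 10 times with the target and at least 50 times in the corpus
(both configurable); survivors are ranked by G². High-scoring collocates
are the words most strongly associated with the target and the best
indication of its contextual meaning.

Around that sit: a tokenizer (words and single-character punctuation
marks; internal hyphens/apostrophes do not split words), JATS/NLM XML
and plain-text readers, a positional corpus index with a documented TSV
on-disk layout, keyword-in-context (KWIC) concordances, exact phrase
counts, modifier profiles, and a synthetic-corpus generator (Zipfian
background, planted target and associates at controlled strengths) used
to validate and calibrate every stage offline.

## Worked example

Generate a corpus with two planted collocates of *gout* (strengths 0.7
and 0.25), index it, and score:

```r
library(collocr)

cfg <- synthetic_corpus_config(
  vocab_size = 200, n_docs = 20, doc_length = 800,
  target = "gout", target_rate = 0.008,
  associates = list(list(word = "flares",     strength = 0.70, max_offset = 10),
                    list(word = "tophaceous", strength = 0.25, max_offset = 10)),
  punct_rate = 0.1, seed = 42)
corp <- generate_corpus(cfg)
idx <- build_index(corp$documents)

collocates(idx, "gout", min_cooccur = 5, min_corpus = 10)
#> Collocates of 'gout' (window 10 left / 10 right)
#>   target occurrences: 150; context mass W = 2,972; corpus N = 16,000
#>  rank       word corpus_freq expected observed n_texts log_likelihood
#>     1     flares          97   18.018      108      20        366.847
#>     2 tophaceous          36    6.687       39      16        131.720
#>     3      w0097          22    4.087       11       6         11.076
#>     ...
```

The two planted associates surface as ranks 1 and 2, in strength order:
*flares* occurs 108 times in gout windows where 18 would be expected at
random, and the Zipfian background words score an order of magnitude
lower. The same index answers qualitative queries:

```r
kwic(idx, "flares", context = 3)
#> KWIC concordance for "flares": 97 occurrences
#> w0005 w0021 w0073  [flares]  w0006 w0016 w0018    (doc0001:120)
#>  w0003 gout w0011  [flares]  w0093 w0002 w0129    (doc0001:265)
#> ...

phrase_count(idx, c("gout", "flares"))   # exact contiguous phrase
#> $occurrences
#> [1] 4
#> $n_docs
#> [1] 4
```

Real collections enter through `read_jats()` (title + abstract + body
paragraphs; reference lists, tables and figure captions excluded by
default) or `read_plaintext()`, with `build_index(docs, require_terms =
c("gout", "hyperuricemia"))` mirroring a Boolean inclusion filter. A
command-line wrapper (`inst/cli/collocr`, or `collocr_cli()` from R)
chains ingest → collocates / kwic / phrases / modifiers / simulate with
TSV outputs.

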