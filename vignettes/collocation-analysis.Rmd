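---
title: "Windowed collocation analysis: model, conventions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed collocation analysis: model, conventions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collocr)
```

## The problem

Specialist communities develop characteristic ways of using words, and
those habits can be read off a corpus: words that systematically occur
near a term of interest — its *collocates* — are the best statistical
indication of what the community means by it. In clinical language
around gout, for instance, the neighbourhood of the disease term
(flare/attack vocabulary versus urate-burden vocabulary) reveals whether
authors treat the condition as an intermittent event or a chronic
metabolic disease. `collocr` implements the standard corpus-linguistics
machinery for such studies: a positional index over tokenized articles,
windowed collocation scoring, and the qualitative companions
(concordances, phrase counts, modifier profiles).

## The association model

Fix a target word and a window of `left` tokens before and `right`
tokens after each of its occurrences (defaults 10/10, the conventional
"10-word span"). Every token whose offset falls in the window — excluding
the target position itself, truncated at document boundaries — is a
*context token*. Summed over all occurrences this gives the context mass
$W$. For a candidate word with corpus frequency $f$ in a corpus of $N$
tokens, the co-occurrence count expected under independence is

$$E = \frac{W f}{N},$$

and the observed count $O$ is assessed with Dunning's likelihood-ratio
statistic on the 2×2 table cross-classifying all $N$ tokens by
window-membership and word-identity
($o_{11}=O$, $o_{12}=W-O$, $o_{21}=f-O$, $o_{22}=N-W-f+O$):

$$G^2 = 2\sum_{ij} O_{ij}\,\ln\frac{O_{ij}}{E_{ij}},
  \qquad E_{ij} = \frac{r_i c_j}{N},\qquad 0\ln 0 \equiv 0.$$

$G^2$ is asymptotically $\chi^2_1$ under independence; unlike the plain
chi-square statistic it remains well-behaved for the rare events that
dominate word statistics. No continuity correction or smoothing is
applied, because the plain statistic is what reproduces published
scores computed this way.

### Counting conventions

These conventions are deliberate and tested; all were chosen so that the
arithmetic $E = Wf/N$ closes against a corpus-level $N$ that counts
words *and* punctuation:

* **Punctuation in the mass, not in the report.** Punctuation tokens
  occupy window offsets and contribute to $W$ (and to $N$), but
  punctuation norms are dropped from the collocation report by default.
  Skipping punctuation while *counting the span* is exposed as nothing —
  windows are over the raw token stream — because the recovered context
  mass of the reference table ($W \approx 417{,}175$ for $20{,}869$
  target occurrences, i.e. slightly under $20$ per occurrence) is
  consistent with boundary truncation over a punctuation-inclusive
  stream.
* **Per-occurrence counting.** A token inside the windows of two nearby
  target occurrences counts once per occurrence. Other occurrences of
  the target itself inside a window count too, which is why a frequent
  target appears among its own collocates with observed count well below
  its corpus frequency.
* **Truncation at document boundaries**, never at sentence boundaries.
* **Thresholds.** Candidates need $O \ge 10$ and $f \ge 50$ by default —
  the standard guard against unstable scores for rare words.
* **Determinism.** Ties in $G^2$ are broken by corpus frequency
  (descending), then alphabetically.

### Degenerate inputs

In very dense corpora (target rate of a few percent, as synthetic
stress tests produce) per-occurrence counting can push $O$ above $f$:
the same physical token is counted from two overlapping windows. The
2×2 table then has a negative outside-window cell; `collocates()`
floors $o_{21}$ (and correspondingly $o_{22}$) at zero, which scores
such words as maximally associated. At realistic literature densities
(target well under 1% of tokens) this never triggers. A $G^2$ evaluated
at exact independence can go microscopically negative in floating
arithmetic and is clamped to zero. An absent target yields an empty
(not erroneous) result throughout.

## Tokenization and ingestion

A word token is a maximal run of letters/digits, with hyphens and
apostrophes internal to a word preserved (`anti-inflammatory`,
`patient's`) — clinical compounds stay whole; every other non-whitespace
character is a single-character punctuation token. Counting is on
lower-cased norms; surfaces are preserved for display. Part-of-speech
tags are optional pass-through metadata: nothing in the scoring needs
them, so no tagger is bundled.

JATS/NLM XML articles contribute title, abstract and body paragraphs in
document order. Reference lists, tables, figure captions and inline
citation markers are excluded by default — reference lists would flood
collocation windows with bibliographic boilerplate — and can be widened
per call. The corpus filter `require_terms` drops documents containing
none of the given terms, mirroring the Boolean search that typically
defines such collections.

## Concordance-side conventions

* **KWIC / phrase matching** is case-insensitive over word norms;
  intervening punctuation is skipped by default (so `"gout, flares"`
  still matches the query `gout flares`), switchable off — with skipping
  disabled, a single-word phrase count equals the word's vocabulary
  frequency exactly, a tested identity.
* **Overlapping matches all count** (`gout gout gout` contains the
  bigram `gout gout` twice). Self-overlap is vanishingly rare in prose;
  counting all starting positions keeps the count deterministic.
* **Modifiers** are the word tokens immediately preceding a head with no
  intervening punctuation — the weakest defensible reading of
  "modifier", chosen because adjacency needs no parser and is auditable
  in the concordance. Without tags, a bundled function-word stoplist
  filters determiners, prepositions, conjunctions and pronouns; when
  tags are present only adjective/noun tags (`JJ*`, `NN*`) qualify and
  the tag filter supersedes the stoplist.

## The synthetic corpus generator

`generate_corpus()` produces corpora with known structure: background
tokens drawn i.i.d. from a Zipf rank-frequency law (exponent 1 by
default — a Zipfian rather than uniform background so the
corpus-frequency threshold meaningfully partitions the vocabulary),
punctuation interleaved at a configurable rate (default 0.1, roughly
prose-like), a target planted per-position with probability
`target_rate`, and associates written into a uniformly chosen free
offset within `max_offset` of each target occurrence with configured
probability. Insertions overwrite background tokens rather than
lengthening the document, so document lengths stay exact; the returned
ledger records every insertion and every infeasible skip per document,
and *the ledger, not the sampling intention, is the ground truth*. All
randomness derives from one seed; regeneration is byte-identical, and
the generator restores the caller's RNG state.

What it emulates: frequency structure, planted association strength,
document segmentation. What it does not: syntax, sentence structure,
discourse, JATS markup, or realistic type-token growth. Passing tests
on synthetic corpora therefore validate the *counting and scoring
machinery* — not linguistic claims about real literature, and corpus
-dependent published quantities (article counts, absolute phrase
frequencies) are not reproducible from synthetic data by design.

## Calibration and verification

The test suite verifies the package at four levels, at problem sizes
chosen to keep the whole suite under a minute or two:

* **Published-table arithmetic.** The ten-row reference collocation
  table for the target *gout* prints $E$, $f$, $O$ and $G^2$ but not
  $W$; inverting $E = Wf/N$ on the target's self-collocation row
  recovers a single $W$ that is constant across all rows to ±3.5 and
  reproduces every printed $G^2$ to within 0.02 — strong evidence the
  implemented statistic is the one used to produce the table.
* **Oracle equivalence.** On 50 generated corpora (≤10⁴ tokens each)
  collocation tables, phrase counts, concordances and modifier profiles
  are compared, exactly, against deliberately naive reimplementations:
  windows materialized as explicit token lists, phrase matching by
  token-by-token walking, and $G^2$ via the independent two-binomial
  likelihood formulation.
* **Null calibration.** Under no association, $O$ is hypergeometric
  (population $N$, successes $f$, draws $W$); 10,000 such tables at
  reference-corpus scale ($N \approx 1.2\times 10^7$, smallest expected
  cell ≈ 1,658) give an empirical type-I error at the 3.8415 cutoff
  within [0.04, 0.06] and a Kolmogorov–Smirnov distance to $\chi^2_1$
  below 0.05. The hypergeometric's discreteness makes the KS distance
  floor scale like the largest point mass, so calibration is checked in
  the large-expected-cell regime where the asymptotic reference is
  meaningful.
* **Planted-signal recovery.** Across 100 seeded replicates (35,000
  tokens, ~350 target occurrences each) an associate planted at
  strength 0.8 outranks one at 0.2 in at least 99 runs; and in a sparse
  800,000-token corpus (target rate $5\times10^{-4}$, so overlapping
  windows are negligible) the empirical co-occurrence ratio recovers
  the planted strength within three binomial standard errors. Strength
  recovery is checked in the sparse regime deliberately: per-occurrence
  counting inflates the ratio by roughly $(L+R)\cdot\text{target rate}$
  when windows overlap, which is a property of the estimand, not an
  estimation error.

## Limitations

Single-token collocation targets only (phrase-level neighbourhoods are
served by `kwic()`/`phrase_count()`); no dependency parsing, so
"modifier" means adjacency; no sentence segmentation; no alternative
association measures (MI, t-score, Dice) — the log-likelihood ratio is
the measure this toolkit is built around; no retrieval — articles are
supplied as files. Absolute counts from any particular published corpus
require that corpus; what the package guarantees is that, given the
same tokens and the same conventions, the arithmetic reproduces.
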