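---
title: "Open literature-based discovery with linking-term-count ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open literature-based discovery with linking-term-count ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcdiscovery)
```

## The model

Literature-based discovery (LBD) generates hypotheses by combining
fragments of knowledge that are individually published but never
connected. The package implements the classic open-discovery ABC
co-occurrence model: a start concept *A* (here, a disease of interest such
as cardiac arrest) is connected to candidate target concepts *C* through
shared linking concepts *B* (here, metabolites identified as significant in
a laboratory experiment). An *A–B* relationship and a *B–C* relationship
are each attested by textual co-occurrence; the *A–C* connection need not
appear in any single document, which is exactly what makes the output a
*hypothesis* rather than a retrieval result.

All text is assumed to be pre-mapped to UMLS-style Concept Unique
Identifiers (CUIs, `C` + 7 digits). This buys two things for free:
stopwords vanish (they map to no concept) and synonyms collapse to one
identifier, so co-occurrence counts aggregate over surface variation.

The pipeline has four stages, each an exported function composed by
`run_discovery()`:

1. **Linking** (`link_b_terms`): a candidate *B* links to *A* iff their
   co-occurrence count is at least `min_ab_count` (default 1 — any
   co-occurrence constitutes a relationship). Candidates below threshold
   are reported as excluded, not silently dropped, because "this metabolite
   has *never* been reported with the disease" is itself a finding.
2. **Expansion** (`generate_c_candidates`): every concept co-occurring
   with at least one linked *B* becomes a candidate *C*, including *A*
   itself.
3. **Filtering** (`apply_filters`): *B–C* edges with count below
   `min_bc_count` (default 2) are removed — a single co-occurrence is too
   weak to constitute evidence; then candidates carrying none of the
   queried semantic types (default `T047`, Disease or Syndrome) are
   removed. Concepts absent from the vocabulary cannot pass a
   type-membership test and are removed by the same rule. Targets directly
   co-occurring with *A* are kept by default (`keep_direct = TRUE`): they
   validate the ranking at a glance, and what is old to science may still
   be new to the investigator.
4. **Ranking** (`rank_by_ltc`): the Linking Term Count (LTC) of a target
   is the number of unique *B* terms connecting it to *A*. It needs no
   direct *A–C* evidence, is trivially interpretable, and with a
   restricted *B* set of size *k* is bounded by *k*.

## Counting co-occurrences

`count_cooccurrences()` slides a symmetric window over each document's
concept stream: tokens at positions *i* < *j* co-occur when *j − i* ≤
`window_size`. The default window of 8 concepts approximates the average
concept-length of a sentence, balancing the noise of a too-wide window
against the misses of a too-narrow one; sentence boundaries are ignored
but windows never cross document boundaries, since the unit of processing
is one citation's title+abstract stream.

Three counting conventions are fixed deliberately:

* **Each unordered position pair counts once.** A focus-token ("sliding")
  description visits every pair twice; counting pairs with *i* < *j* once
  is symmetric, non-redundant, and equal to the symmetric sliding-window
  count.
* **No diagonal.** The same CUI at two positions is not a co-occurrence;
  self-pairs are meaningless for ABC linking, and `pair_count(m, x, x)` is
  an error rather than a number.
* **Duplicate tokens count per position pair.** `[X, Y, X]` yields
  count(X,Y) = 2: positions, not types, are the counting unit.

The matrix serializes to a flat text file (two metadata header lines, then
normalized sorted `cui_a TAB cui_b TAB count` lines). Sorting uses radix
order so output is byte-identical across locales; the write→read→write
composition is the identity.

## Determinism and tie-breaking

The original workflow left display order of tied terms to chance. Chance
ordering makes results irreproducible, so the package imposes a total
order everywhere: hypotheses sort by LTC descending then CUI ascending,
and within a hypothesis the linking-term breakdown sorts by count
descending then CUI ascending. This is a deliberate, documented divergence
from the source workflow's behaviour; it never changes which terms appear,
only the order of exact ties.

## The synthetic generator

Real concept-mapped citation corpora are licensed and enormous, so the
package tests itself on corpora whose ground truth is known by
construction. A `plant_spec()` prescribes exact pairwise counts; the
generator emits, for each pair (x, y) with target k, k minimal two-token
documents `[x, y]`. Because windows never span documents, recounting at
any window ≥ 1 recovers exactly k, and two-token documents cannot create
unplanted pairs. Background noise documents sample uniformly from a
reserved identifier range (`C99·····`) disjoint from plantable CUIs, so
noise can never contaminate a planted count. Document order is shuffled by
the plant's seed; all randomness flows through explicit seeds, and the
generator restores the caller's RNG state.

What the generator deliberately does **not** emulate: realistic document
lengths and concept frequencies (Zipfian vocabularies), concept-mapping
errors, or correlated topical structure. Passing the planted-recovery
suites therefore demonstrates the *counting and ranking machinery* is
exact, not that the pipeline is robust to mapping noise in real corpora.
`plant_abc_scenario()` builds full open-discovery instances (A, n
linking terms, targets with a prescribed link profile, each planted edge
at count 2 so it survives the default filter), where each target's LTC is
known in advance; these drive end-to-end ranking tests with and without
direct A–C edges.

## The packaged worked example

The package ships a small fixture encoding a published worked example from
a metabolomics study of cardiac arrest: a vocabulary of 40 concepts (the
start term, 19 metabolite CUIs, 20 disease CUIs) and the complete printed
B–C edge lists for the two showcased targets, fish-eye disease (C0342895,
15 edges, strongest: docosahexaenoic acid at 503) and Wiskott-Aldrich
syndrome (C0043194, 14 edges, strongest: histidine at 508). Two
metabolites (C2348307, C0069409) carry no edge to the start term and are
excluded at linking time, leaving the 17-member linked set.

The study's corpus-scale numbers cannot be regenerated without the
licensed source corpus, so the fixture treats the printed edge lists as
inputs and the package reproduces every piece of arithmetic on top of
them: LTC 15 for fish-eye disease, 14 for Wiskott-Aldrich, their relative
order, the 17-member linked set, and — from the published per-score
distribution over 55,376 disease concepts — the cumulative histogram
counts (3,122 diseases share at least one linking term; 21 score ≥ 10).

One value in the fixture is constructed rather than printed: the study
reports only that the 17 A–B links exist, not their counts.
`fixture_matrix(ab_count = 2)` defaults them to 2 so that the B→A edges
also clear the default `min_bc_count = 2` filter and the start term
appears in its own ranked output with LTC 17, as in the published listing.
LTC depends only on edge existence above threshold, so no other fixture
quantity is affected; the parameter is exposed for sensitivity checks.

```{r worked-example}
fx <- fixture_matrix()
res <- run_discovery(fixture_query(), fx$matrix, fx$vocab)
threshold_listing(res, fx$vocab, min_ltc = 10)
```

## Degenerate inputs and edge policies

* Empty corpus → empty matrix; empty matrix → empty result (no error).
* A start term absent from the vocabulary is a warning with an empty
  result — exploratory queries are legitimate — while structural errors
  (duplicate document ids, duplicate matrix pairs, malformed headers) are
  always fatal.
* Corpus reading has a lenient mode that drops malformed tokens and
  reports a tally, mirroring how a concept mapper tolerates unmappable
  phrases; kept + dropped always equals the token count in the file.
* The histogram's score-0 row cannot be derived from a result (zero-scored
  targets never enter it), so `ltc_histogram()` takes the target-universe
  size explicitly — in a real run, the number of vocabulary entries
  carrying a queried semantic type.

## Design choices made where the design was open

* **Edge-count filter placement.** The singleton-co-occurrence filter is
  applied to B–C edges (`min_bc_count = 2`) while A–B linking accepts any
  nonzero count (`min_ab_count = 1`): the published listings retain B–C
  edges of count 2 and admit linking terms on any A co-occurrence. Both
  thresholds are query parameters, and whether the original workflow also
  pruned count-1 A–B edges is unknowable from the printed output.
* **General-term removal is manual.** Overly general targets ("disease,
  NOS") are left in the output for expert review rather than filtered by
  hierarchy depth; automating that filter is future work.
* **One document = one stream.** Whether titles and abstracts were
  windowed jointly or separately is not recoverable; the format carries
  one stream per document and the counter treats it as one window domain.
* **Unknown-vocabulary targets fail the semantic filter** rather than
  passing it: the filter is defined by type membership, and an unknown
  concept has no types.

## Problem sizes

The test suite and reproduction script run on deliberately small
instances: random corpora of ≤ 10 documents × ≤ 30 tokens over 8-concept
alphabets for the oracle-equivalence suites (200 corpora), 50 random plant
specifications × 3 seeds for generator recovery, and planted scenarios
with ≤ 6 linking terms. These sizes were chosen because exhaustive
brute-force oracles stay trivially cheap there while still exercising
every code path (duplicates, window truncation, noise, ties); the
counting core itself is vectorized per offset and handles much larger
corpora without modification.

## Known limitations

* LTC is the only ranking measure implemented; association-strength
  measures over indirect paths are out of scope.
* Closed-discovery mode (explaining a fixed A–C pair) is not implemented.
* The concept-stream format carries exactly one CUI per token; many-to-one
  mapping ambiguity must be resolved upstream.
* Fixture-based reproduction validates the arithmetic on printed inputs;
  it cannot validate corpus construction against the original licensed
  corpus.
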