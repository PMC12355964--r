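---
title: "Mining, curating and validating enzyme kinetic constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining, curating and validating enzyme kinetic constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzkinex)
```

## The problem

Quantitative enzyme kinetics — turnover numbers $k_{cat}$ and Michaelis
constants $K_m$, tied to an enzyme sequence, a substrate structure and assay
conditions — are published mostly as tables in papers, not as structured
records. Extracting them at scale runs into a characteristic set of failure
modes: heterogeneous unit dialects, the visually confusable micro/milli
prefix glyphs whose confusion shifts a concentration by exactly $10^3$,
scientific notation whose exponent sign is easily mistranscribed, and —
when a generative language model does the reading — values that were never
in the source text at all. `enzkinex` implements the deterministic stages
around such an extractor: canonicalization, quality filtering, entity
resolution, benchmark validation and concordance analysis, together with a
synthetic corpus generator so that every stage is testable without any
proprietary model or harvested literature.

## The record model

One measurement is one row: enzyme name, organism, optional point-mutation
descriptor, substrate name and optional SMILES, the two kinetic quantities
with printed value, raw unit string and canonical value, pH, temperature,
optional database identifiers (UniProt, NCBI, PDB, EC), a sequence,
a confidence tier, five quality flags, and provenance (document id, source
format, table id, row index). Records serialize to a flat JSON-Lines
schema; canonical values are derived columns recomputed on load.

Validation is deliberately two-tier: positivity of canonical values, pH in
[0, 14] and temperature in [−20, 150] °C are hard errors, while
temperatures outside 0–100 °C — the span actually observed in curated
kinetics corpora — are warnings only, because an observed range is not a
validity bound.

The matching key lower-cases, NFKC-normalizes (so the micro sign U+00B5 and
Greek mu U+03BC coincide), collapses whitespace and strips flanking
punctuation; mutation codes like "a 123 g" normalize to `A123G`, anything
not matching the single-substitution grammar passes through verbatim, since
no general mutation grammar exists in the wild. NFKC matters here: without
it, the 90% similarity threshold (below) would silently fail on
typographic variants of the same Greek letter.

## Unit engine

Rates canonicalize to $s^{-1}$ (per-minute divided by exactly 60),
concentrations to molar, with prefixes
$\{m, \mu, n, k\}$. The glyph-ambiguity flag marks any prefix drawn from
the confusable set $\{m, \mu, µ, u\}$ — deliberately including `m` itself,
because a printed "m" may be a misrendered µ; downstream concordance
analysis is what decides whether a 1000-fold systematic shift is present.
Scientific notation (e-notation, `× 10^k`, superscript exponents) is parsed
at face value and flagged rather than dropped: exclusion is a curation
decision, not a parsing one. Decimal commas are unsupported; thousands
separators are stripped. Quantities per milligram of protein (specific
activities) are out of the two canonical kinds and stay `unknown`, which
`canonicalize()` refuses loudly. We canonicalize $K_m$ to molar rather than
the also-defensible millimolar; the choice is recorded in the schema
documentation and affects nothing downstream, since all comparisons happen
in log space.

## Quality filters

Three flags, mirroring the failure modes above:

* **Hallucination** (document-level): the fraction of extracted kinetic
  value strings locatable verbatim in the document text, by a
  word-boundary numeric search ("4.2" does not match inside "14.25";
  thousands commas normalized on both sides). Flagged when strictly below
  0.5. The search uses the value exactly as printed, before
  canonicalization — the check targets transcription fidelity, not unit
  algebra.
* **Repetition** (document-level): fraction of distinct kinetic value
  strings, flagged strictly below 0.3.
* **Scientific notation** (row-level), taken from the parsed quantities.

Neither threshold has a published value; 0.5 and 0.3 are package defaults
chosen so that a clean synthetic corpus is never flagged while fully
corrupted documents always are, and both are `qc_config()` parameters. The
curation pipeline is ordered: exact duplicates, then pdf/xml
double-ingestion (the native-markup XML form wins), then empty rows, then
flags, then exclusion. Flag categories may overlap and are tallied
independently; the report's ledger accounts for every input row exactly
once, which makes curation idempotent — a property the tests enforce.

## Resolution and confidence tiers

Sequence retrieval is identifier-first (UniProt, then NCBI, then PDB — the
first identifier that resolves wins), falling back to a combined
name+organism search whose top-ranked hit is taken. Substrate names are
expanded through an abbreviation table before lookup, and generic polymeric
names (DNA, RNA, protein, starch — configurable) are refused outright
because they have no defined structure. All lookups are offline TSV
fixtures implementing a two-function contract (`by_identifier`,
`by_name_organism`); a live web client could implement the same contract,
but web queries are irreproducible and deliberately out of scope. The
confidence tier counts non-empty metadata fields among {enzyme name,
organism, UniProt, NCBI, PDB}: ≥3 high, 2 medium, 1 low. Records with zero
fields are "unmapped" — below the lowest published tier — and are excluded
from the sequence-mapped database subset while remaining in the crude
table.

## Benchmark validation

Alignment is three-step: (1) enzyme and organism names must each reach 90%
similarity, where similarity is $1 - d(a,b)/\max(|a|,|b|)$ on
key-normalized strings with $d$ the unit-cost edit distance (the metric is
injectable; normalized edit distance is the natural reading of "string
similarity" and is what the tests cross-check against a DP oracle);
(2) substrates must match exactly by normalized name or byte-identical
SMILES; mutation strings must also agree, since the key includes the
mutation; (3) only then are values compared. Among admissible pairs a
one-to-one assignment maximizing the summed mean of enzyme and organism
similarities is computed as a maximum-weight bipartite matching
(`igraph`); property tests verify optimality against brute-force
enumeration on instances up to 6×6.

Classification: a matched pair with both canonical values within 1%
relative (compared as $|\log_{10}(p/t)| \le \log_{10} 1.01$, absorbing
printed rounding) is a TP; a missing predicted value is an FN; a mismatch
is an FP and is additionally tallied off-by-$10^k$ when $|\log_{10}(p/t)|$
lies within 0.05 of $k \in \{1,2,3\}$ — in either direction, since a unit
error can inflate or deflate. Ground-truth entries with no admissible
partner are *Unresolved* and excluded from both metric denominators;
predictions with no admissible partner count as FP. Off-by counts are a
subset of FP. Then accuracy $= TP/(TP+FP+FN)$ and precision
$= TP/(TP+FP)$; accuracy never exceeds precision (same numerator, larger
or equal denominator), and the randomized tests assert it.

## Concordance

Two sources of the same kinetic constants are compared in $\log_{10}$
space: Pearson $R$, Spearman $\rho$ (mid-ranks on ties), $R^2$, mean
absolute deviation and root-mean-square deviation of the differences, with
MAD ≤ RMSD guaranteed by the power-mean inequality. Systematic unit errors
appear as off-diagonal clusters at fixed offsets; `detect_offset_clusters`
tests candidate offsets $\pm\log_{10}60$ (s⁻¹ vs min⁻¹) and $\pm 3$
(µ vs m) with a membership half-width of 0.15 log units and a minimum
cluster size of 5 — both unpublished anywhere, both configurable — and tags
members for manual review.

## Glyph classifier

The disambiguator is trained on synthetic glyphs: parametric stroke
templates for "m", "µ" and a confusable *other* class (u, n, rn — the
composition of the negative class in scanned literature is unknowable, so
ours is an explicit guess), rendered at 32×32 under four "fonts" (stroke
width / slant / proportion parameter sets), ±5° rotation, sub-pixel jitter
and Gaussian noise. The classifier is a single-hidden-layer network (64
units, ReLU, softmax) trained with minibatch Adam — epochs, learning rate
and seed are the training contract — because no deep-learning framework is
part of this package's R dependency set and a desk-scale CPU model
suffices: the synthetic benchmark (1500 training, 600 held-out samples) is
solved at ≥99% accuracy in seconds. The architecture is injectable for
anyone wanting a convolutional model. The renderer and dataset are
synthetic stand-ins and say nothing about scanned-PDF performance; the
pipeline consumes the classifier only through the glyph-ambiguity pathway,
so it is optional at runtime.

## Synthetic corpus

Each generated document is narrative filler plus one pipe-delimited
kinetics table (enzyme/organism/mutation/substrate/k~cat~/K~m~/pH/T), with
unit dialects sampled per document, units embedded in cells or headers, and
enzyme/organism optionally stated in the narrative instead of columns.
Log-values draw from truncated normals matching the ranges reported for
large literature corpora — $\log_{10}k_{cat} \in [-5.8, 5.3]$,
$\log_{10}K_m(M) \in [-5.5, 4.5]$ — with means (0.8, −4.2) and SDs
(1.5, 1.2) chosen once for plausibility, as the published information is a
range and an approximately Gaussian shape. pH and temperature draw from
clipped normals around 7.2 and 25.9 °C. Ground truth is re-parsed from the
printed strings, so a clean corpus round-trips bit-exactly.

Corruptions operate on two channels. *Printed-text* corruptions alter the
document and its table consistently: glyph swap (µ↔m in a K~m~ unit,
producing exactly 1000-fold canonical shifts), rate-unit relabeling
(s⁻¹↔min⁻¹ without rescaling, a 60-fold shift) and scientific-notation
reformatting. *Extraction-channel* corruptions alter only the structured
table the extractor reads while the document text keeps the original
values — this is precisely what "hallucinated" means, and it is the one
place the invariant "full text contains every table's rendered text" is
deliberately broken. Hallucination and repetition are injected per
document (all of a document's values perturbed, or one value copied
everywhere), because the QC flags that must recover them are
document-level; glyph/rate/notation corruptions are injected per row. The
default K~m~ dialect set contains only µ/m-prefixed units so the glyph
swap is always applicable. Corruption decisions draw from an RNG stream
separate from content generation, so the same seed with rates zeroed
yields byte-identical underlying documents; the corruption log records
every original and corrupted cell and suffices to undo every corruption,
which the tests verify byte-for-byte. Name typos (single-character edits at
a configurable per-document rate, default 0) exercise the 90%-similarity
pathway; all packaged names are ≥10 characters so one edit stays above
threshold.

What the generator does *not* emulate: PDF layout and OCR noise, multi-table
documents, free-text (non-tabular) kinetics, conflicting re-measurements of
the same key, real substrate synonymy. Passing on synthetic corpora
therefore demonstrates the correctness of the deterministic pipeline
stages, not end-to-end extraction quality on real literature.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale corpora — 50 clean
documents (≈250–300 rows) for round-trip checks, ~170 documents (≥1000
rows) for binomial rate-recovery checks at 3σ, 15–20 documents for
corruption-specific checks, and 1500/600 train/test glyphs — sizes at
which every documented property is decidable in seconds while behaviour is
identical to larger runs. Value equality uses the 1% relative tolerance in
log space; off-by detection uses ±0.05 log units; floating-point decade
arithmetic (e.g. the 1000-fold µ/m ratio) is exact only to double
precision, and tests compare accordingly. Assignment scores lie in
[0.9, 1], so maximum-weight matching never leaves an admissible pair
both-unmatched. Correlations on fewer than two pairs or constant vectors
are reported `NA` rather than fabricated.

## Known limitations

Mutation handling is string-normalization only — no application to
sequences, no verification that a retrieved sequence matches the assayed
construct. One substrate and one mutation per record. No reconciliation of
conflicting values for the same key within a paper: the reference extractor
emits all rows and leaves the decision to curation. EC numbers are passed
through from extraction metadata, never inferred from enzyme names. The
"Unresolved" category counts ground-truth entries only; key-less
predictions are FPs — with asymmetric benchmark sets the two conventions
differ, and ours is stated here so reports are comparable.
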