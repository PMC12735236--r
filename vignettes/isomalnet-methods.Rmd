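---
title: "Methods: mass arithmetic, neutral-loss annotation, molecular networking and chemometrics in isomalnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass arithmetic, neutral-loss annotation, molecular networking and chemometrics in isomalnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomalnet)
```

`isomalnet` re-implements, as plain R over small explicit data structures, the
computational chain used to chemotype sponge extracts by their isomalabaricane
content: exact-mass arithmetic for negative-mode ions, a diagnostic
neutral-loss rule engine, feature-based molecular networking, and a
normalization → PCA/HCA chemometrics stage. This vignette documents the models
behind each stage, every tunable that matters, the numerical choices made
where the design was genuinely open, and what the synthetic test corpus does
and does not establish about real data.

## Mass and formula arithmetic

All masses are monoisotopic, built from IUPAC atomic masses hard-coded to at
least nine decimal places (C 12 exactly, H 1.0078250319, N 14.0030740052,
O 15.9949146221, P 30.9737615120, S 31.9720706912) and the electron mass
5.4857990907×10⁻⁴ Da. Element support is restricted to CHNOPS, which covers
every composition this chemistry produces (triterpenoids, their glycosides,
nitrogenous congeners, and lysophosphatidylinositol lipids).

Two conventions matter and are applied consistently:

* **Anion masses include the electron.** The m/z of a singly charged
  deprotonated ion is `mass(M) − mass(H) + mₑ`. Omitting the electron term
  shifts the fourth decimal place — `mz_deprotonated("C30H40O4")` returns
  463.2854 only because the term is present.
* **Nominal mass is half-up integer rounding** of the monoisotopic value,
  because fragment ions in this literature are quoted at integer m/z
  (`nominal_mass(anion_mz("C8H12NO5"))` is 202). R's banker's rounding is
  deliberately avoided.

Ring-and-double-bond equivalents use RDBE = C − H/2 + N/2 + P/2 + 1, treating
phosphorus as trivalent and ignoring O and S. RDBE is defined here for
*neutral* even-electron formulas only; anion compositions are never passed to
it inside the package.

`infer_delta_formula()` does an exhaustive search over the bounded element
lattice (all count vectors up to the per-element maxima), keeps candidates
within a ppm tolerance (default 10 ppm, the customary high-resolution
formula-assignment window), and orders them by |ppm error| with ties broken by
the formula string. Exhaustive enumeration is the point: at the bounded sizes
used for neutral-loss deltas (≤ 10⁵–10⁶ lattice points) it is instantaneous
and trivially correct, and the test suite verifies it against an independent
nested-loop enumeration.

## The neutral-loss rule engine

Structural classes are described declaratively in
`inst/extdata/class_rules.json` — chemists can edit loss chains, ion series
and weights without touching code. Four rule types exist:

* **loss** — a chain of neutral formulas subtracted from the precursor
  (e.g. `[CO2, CH4]` targets m/z `precursor − 43.9898 − 16.0313`). The match
  is the most intense peak within the fragment tolerance.
* **series** — a set of nominal fragment m/z values with a minimum hit count.
  A peak hits a nominal target when it rounds to it *and* lies within a
  ±0.3 Da guard of the integer, which excludes mid-decade artifacts.
* **parallel_series** — counts peak pairs separated by a fixed neutral offset
  (default C₂H₄O, 44.0262 Da), the operational reading of "two parallel
  fragmentation series separated by 44 Da" for 3-O-acetyl compounds. The
  enumeration of that observation is not published peak-by-peak, so the
  detector requires ≥ 3 such pairs; this is an operationalization and is
  flagged as such here.
* **parity** — the anion nitrogen rule: an even nominal [M−H]⁻ mass implies
  an odd nitrogen count for CHNO compounds. A supplied neutral formula
  containing N satisfies the rule directly.

Scoring: per class, the weights of its scoring rules sum to 1 (validated at
load). A class scores the weight-sum of its satisfied rules; any fired
*forbidden* rule or failed *required* rule zeroes it. Hypotheses at or above
0.5 are reported, ranked by score then class id. Scores are evidence
fractions, not probabilities — no error model is implied, and none is
published for this chemistry. Three further numerical choices:

* **Intensity floor**: any diagnostic match must reach 1% of the base peak, so
  noise grass cannot carry evidence.
* **"Dominated by"**: the 3-hydroxy-4-carboxy core class requires its
  CO₂+H₂O-loss ion to rank within the top 3 peaks by intensity. No threshold
  is published; top-3 separates that class from spectra that merely *contain*
  the ion.
* **Tie-breaking is chemically loaded.** The neutral-loss pair CO₂+CH₄ and a
  single C₂H₄O₂ (acetic acid) loss are the *same* elemental composition
  (60.0211 Da), so every side-chain acid also part-scores the acetoxy class at
  0.5. Ranking is deterministic (score descending, class id ascending) and the
  full-score class always outranks the shadow; the 0.5-score acetoxy
  hypothesis is reported honestly rather than suppressed, because on mass
  evidence alone the two are indistinguishable.

Scores are rounded to 9 decimals before ranking so that weight sums like
0.3 + 0.35 + 0.35 compare equal to 1 exactly.

`pair_analogs()` types composition differences between features:
+C₂H₄O with a retention shift inside [2.5, 3.5] min is acetylation of a keto
compound (+C₂H₂O of a hydroxy compound), +H₂ is double-bond reduction at any
retention shift, +H₂O is hydration or an extra hydroxyl, and an identical
formula at a distinct retention time is an isomer pair. The acetylation window
brackets the single printed exemplar shift (≈3.2 min) and is configurable; the
observed elution order of geometric isomers is deliberately *not* encoded as a
rule, since there is no evidence it generalizes.

## Modified cosine and molecular networking

The networking kernel scores two spectra by a modified cosine: each spectrum's
intensities are square-root scaled and L2-normalized; peaks of `a` may pair
with peaks of `b` at offset 0 or at the precursor difference Δ; each peak is
used at most once; the score is the sum of matched products. Design decisions:

* **Greedy pairing** in order of decreasing intensity product (ties: lower m/z
  in `a`, then in `b`), as in standard networking implementations. Greedy can
  in principle fall below the optimal assignment; the test suite compares it
  against an exhaustive maximum-weight matching oracle on 1000 seeded random
  pairs of ≤ 8-peak spectra and fails the build on any discrepancy above
  10⁻⁹.
* **The parent-mass tolerance gates the shift channel**: when |Δ| ≤ 0.01 Da
  the precursors are treated as equal and only direct matching applies.
  Defaults are 0.02 Da fragment and 0.01 Da parent tolerance, the standard
  workflow settings for this data type.
* Empty peak lists are a domain error for the kernel; `build_network()` skips
  such spectra (they become singletons), mirroring how uninformative spectra
  behave in practice.

`build_network()` then applies, in order: the edge thresholds (cosine strictly
above 0.7 — "above", not "at" — and ≥ 5 matched peaks, reading "more than
four" literally; both configurable because deployed workflows vary); the
mutual top-K filter (an edge survives only if each endpoint ranks within the
other's top 10 neighbours by cosine, ties broken by id); and the family-size
cap (while any connected component exceeds 100 nodes, the lowest-cosine edge
inside an oversized component is deleted, ties broken by the lexicographically
smallest id pair). Every step is deterministic; two runs on identical input
produce byte-identical edge lists and GraphML.

Connected components are computed with `igraph`; the test suite re-derives
component statistics with an independently written union-find and re-checks
the mutual top-K property by direct re-ranking.

## Chemometrics

`normalize_table()` applies the fixed chain sum-normalize → log-transform →
auto-scale: each sample column is scaled to unit total (a composition-style
correction for extract loading), zeros are replaced by half the smallest
positive value in the table before log₁₀ (the conventional half-minimum
pseudo-replacement; the log base is a choice, since only "log-transformed" is
specified), and each feature row is centred and scaled to unit variance.
Zero-variance rows are dropped with a message; an all-zero sample column is an
error naming the sample.

PCA is the SVD of the samples × features matrix. Auto-scaling already centres
every feature, so the SVD is classical centred PCA and the explained-variance
percentages sum to 100 across all components. Sign indeterminacy is resolved
by forcing the largest-magnitude loading of each component positive, making
score plots reproducible run-to-run. Full-rank reconstruction
(`scores %*% t(loadings)`) reproduces the normalized matrix to 10⁻⁹.

Hierarchical clustering defaults to Ward linkage (`ward.D2`) on Euclidean
distances — the customary pairing for auto-scaled metabolomics tables; both
are configurable since neither is prescribed for this data. Dendrograms are
exported as Newick via `ape`. On the packaged 16-standard × 9-specimen
relative-content table, cutting at k = 2 isolates exactly the three Phan Thiet
specimens (PIBOC O66-089/-092/-109) — the same qualitative chemotype split the
full-featured study data show, though it is worth noting the published
clustering used the full >1500-feature table, not the 16-standard subset.

## The synthetic corpus: what it emulates, and what it does not

Instrument-scale raw data for this study are not redistributable, so the
pipeline is validated on a seeded generator (`generate_corpus()`) that
reproduces the *structure* the analysis assumes:

* nine samples split 6/3 into chemotypes A and B;
* 42 features (default) drawn from seven structural-class templates, with
  class-appropriate precursor formulas taken from printed compositions of real
  compounds (C₂₅H₃₄O₄, C₃₀H₄₀O₄, C₄₄H₇₃NO₁₄, C₂₇H₃₆O₅, C₃₂H₄₄O₅, …), so
  precursors fall in the characteristic m/z 300–550 window;
* MS/MS peaks computed *exactly* from each class's loss chains and fragment
  compositions via the package's own mass arithmetic, then degraded with
  m/z jitter (N(0, 0.005 Da)), ±20% log-normal intensity noise, and five
  uniform noise peaks per spectrum capped at 5% of the base peak — below that
  cap, noise peaks can clear the 1% evidence floor only by rare coincidence;
* per-sample abundances from a log-normal model (base log₁₀ level
  N(6, 0.2), within-group SD 0.25 log₁₀ units) with a 1.5 log₁₀-unit mean
  shift for chemotype-enriched classes — side-chain acids, RAA-type cores,
  glycosides and nitrogenous congeners enriched in chemotype A;
  3-hydroxy-4-carboxy cores and acetates in chemotype B; lyso-PI lipids
  even — mirroring the direction of the published group contrasts.

The generator is a pure function of its configuration including the seed;
identical configurations give byte-identical MGF/CSV/JSON output.

Passing tests on this corpus show that the engine recovers the generating
class of every noiseless spectrum, at least 95% under the default noise model
(in practice 100% at the shipped defaults), and that PCA/HCA recover the
chemotype partition exactly at the default effect size. They do **not** show
performance on real extracts: the generator makes no attempt at
chromatographic peak shapes, isotope envelopes, in-source fragmentation,
co-eluting isomers sharing one feature, or the long tail of low-quality
spectra that dominates real singleton counts. Published dataset-level numbers
(total feature counts, singleton fractions, explained-variance percentages)
depend on those properties and on the unavailable raw data, and are therefore
explicitly out of reach of the synthetic validation.

Problem sizes used by the automated tests — a 42-feature default corpus, a
200-feature corpus for the I/O roundtrip, 1000 random ≤ 8-peak pairs for the
kernel oracle — were chosen as the smallest sizes at which every code path is
exercised, and run in well under a minute.

## Known limitations

* Only [M−H]⁻ singly charged ions; no adducts, multimers, multiple charging,
  or isotope-pattern scoring.
* The formula search is bounded brute force — appropriate for neutral-loss
  deltas, not for assigning formulas to large intact masses with wide bounds.
* Class scores are heuristic evidence fractions; no FDR or probability
  calibration is attempted.
* The published Y-ion annotation of the glycoside standard writes one loss
  composition inconsistently with its own ion series; the engine implements
  the chemically consistent sequential HexNAc-then-Hex losses.
* `hclust` tie-breaking can make clustering order-sensitive on degenerate
  (exactly tied) distance matrices; on real-valued normalized data ties have
  measure zero.
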