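---
title: "Models and methods behind gambi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gambi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gambi)
```

## The biotic index

The AZTI Marine Biotic Index summarizes a soft-bottom macroinvertebrate
sample as the weighted mean pollution tolerance of its fauna. Each species
carries one of five ecological groups: GI, very sensitive to organic
enrichment; GII, indifferent; GIII, tolerant; GIV, second-order opportunist;
GV, first-order opportunist. With `%G1..%G5` the percentages of individuals
(abundance mode) or of species present (presence mode, the "p/a" variant) in
each group,

```
index = (0*%G1 + 1.5*%G2 + 3*%G3 + 4.5*%G4 + 6*%G5) / 100
```

so a non-azoic sample lies in [0, 6]: 0 when every assigned individual is
GI, 6 when every one is GV. Note the division applies to the whole weighted
sum — the only reading compatible with the 0–7 class scale; distributing the
divisor over a single term would produce values two orders of magnitude too
large.

**Quality classes.** Values bin into five pollution levels at 1.2, 3.3, 5
and 6. The published thresholds appear gapped (1.2 then 1.3) only because
index values are conventionally reported to one decimal; `classify_pollution()`
therefore bins the *unrounded* value with half-open intervals (`<= 1.2`
unpolluted, `(1.2, 3.3]` slightly polluted, and so on). One-decimal rounding
is a display concern only.

**Azoic samples.** A sample with zero individuals has no defined group
percentages. Monitoring practice assigns azoic sediment the scale maximum;
`compute_index()` returns value 7 / "extremely polluted" with the `azoic`
flag set, and all agreement analyses exclude azoic stations pairwise by
default, as analyses of real monitoring series conventionally drop them.

**Unassigned species.** Species missing from the group list, or listed
without a group, are excluded from both numerator and denominator. The
excluded fraction is reported (`unassigned_fraction`), a warning fires above
20% (configurable), and only a sample with *no* assigned taxa is an error.
Species names are matched after trimming, whitespace collapsing and case
folding — never fuzzily, so a misspelling surfaces as "unassigned" rather
than silently mapping to the wrong species. A warning (no correction) is
emitted below 4 assigned taxa; whether dedicated low-richness corrections
should apply is left to the caller, as standard practice varies.

**Why species-level identification matters.** `eg_heterogeneity_by_rank()`
tabulates, per taxonomic rank, how many distinct groups the species of each
taxon span. On realistic lists even congeneric species split across groups,
so no rank above species supports reliable group assignment — the package
exposes this as data rather than assertion.

## Agreement between classifications

Two classifications of the same stations (e.g. abundance vs presence mode,
or full vs restricted species set) are compared with unweighted Cohen's
kappa on the 5x5 confusion matrix: `kappa = (p_o - p_e) / (1 - p_e)` with
`p_o` the observed agreement and `p_e` the expected agreement under
independent raters with the observed marginals. Unweighted is the right
choice here because the source analysis cites the original (unweighted)
statistic and gives no distance weights. When both raters are constant and
identical (`p_e = 1`, `p_o = 1`) kappa is defined as 1. Verbal
interpretation follows the Monserud–Leemans ranges with lower-inclusive
half-open bins (the printed ranges share endpoints, e.g. "0.20–0.40 poor;
0.40–0.55 fair"; exactly 0.40 is read as "fair"). Per-class agreement is the
diagonal cell over its row total, undefined (NA) for an empty row.

## Species subsets and the resampling null

A metabarcoding index can only see species with reference barcodes. The
subset machinery asks how much classification is lost:

1. `species_frequency_ranking()` ranks species by the number of stations
   where they occur (ties broken alphabetically, so ranks are
   deterministic).
2. `subset_agreement()` computes the p/a AMBI classes on the full species
   set and on a restricted set, excluding pairwise the stations the
   restriction empties, and returns their kappa.
3. `random_subset_null()` repeats this for `n` (default 100) random subsets
   of the same size drawn without replacement from the species observed in
   the matrix (not from any larger master list — the comparison is about
   *which* observed species are kept). A top-level seed deterministically
   derives one sub-seed per replicate, so any replicate is reproducible in
   isolation. Failed replicates are kept as NA, never dropped silently.
4. `subset_pvalue()` reports a parametric one-sided p — the upper tail of a
   normal fitted to the null kappas — as primary, with the empirical
   `(1 + #{null >= obs}) / (n + 1)` as companion. The parametric form is the
   only one that can produce p-values far below the `1/(n+1)` empirical
   floor, which is how sub-10^-4 p-values arise from a 100-replicate null.
   A zero-spread null sets a degeneracy flag (p 0, 0.5 or 1 by the sign of
   the difference).

## Reference-library auditing

`dedup_cluster()` collapses redundant per-species sequences the way cd-hit
is typically used at this scale: within each species, sort longest first and
greedily attach a sequence to the first cluster whose representative it
matches at >= 0.9 identity, else found a new cluster; the founder (longest)
is the representative. Identity is the best ungapped full-overlap offset
alignment, matches over the shorter length, with ambiguity codes requiring
literal equality. This deliberately reproduces the *contract* (group at a
similarity threshold, keep the longest) rather than cd-hit's word-filter
heuristics; exact concordance with cd-hit is a non-goal. The construction
makes dedup idempotent, keeps representatives maximal-length, and merging is
monotone in the threshold.

`coverage_report()` intersects a species list with per-marker libraries and
reports per-phylum sequenced proportions, the cross-marker overlap, and
library species absent from the list (reported, not an error).
`sequenced_species_filter()` turns a library into the species subset that
`subset_agreement()` consumes.

## In-silico primer evaluation

The external tool originally used for amplification prediction is replaced
by a transparent, configurable position-weighted score
(`primer_scoring_config()`): a primer base matches a template base iff their
IUPAC expansion sets intersect (liberal on ambiguous template bases, to
avoid false negatives); a mismatch costs 0.4 outside the 3' window, 1.0
inside the last 5 bases, and 3.0 at the 3'-terminal base (a terminal
mismatch blocks extension, hence it alone exceeds the default amplification
threshold of 1.0). These defaults are this package's own, stated here
because the original tool's "default parameters" are not printed anywhere
authoritative; every penalty and the threshold are arguments. Set-intersection
matching is provably equivalent to scoring against the full degenerate
expansion and taking the best, which the tests verify by brute force.

Because database sequences are often partial, a pair is only evaluated on
*testable* sequences: `locate_primer_region()` finds the minimal-score
annealing windows of the forward primer and reverse-complemented reverse
primer on a full-length reference (coordinates 0-based half-open), and
`testable_sequences()` keeps the records whose best local alignment to the
reference covers that whole span. The aligner is a native ungapped
seed-and-extend: exact 11-mer seeds define candidate diagonals and on each
diagonal the maximal-scoring segment (match +1 / mismatch -1) is found
exactly — an exact segment search rather than an x-drop heuristic, which at
barcode scale is just as fast and strictly no less sensitive.
`predict_amplification()` then calls a template positive iff a priming
forward site lies upstream of a priming reverse site (leftmost forward,
rightmost reverse), and `species_amplification_summary()` applies the
"positive if at least one sequence amplifies" rule per species, reporting
per-phylum percentages alongside the number tested (phyla with nothing
testable are NA, not 0%).

Thermodynamic melting-temperature modelling and multiplex cocktail design
are out of scope. The shipped `example_primer_pairs()` carry IUPAC-only
published COI pairs; inosine-containing primers cannot be represented in the
IUPAC alphabet and must be approximated (e.g. I -> N) by the user if needed.

## The simulator: what it emulates, what it does not

`generate_eg_map()` builds a species list with ~90% of species in five
dominant phyla (Annelida 36%, Mollusca 25%, Arthropoda 24%, Echinodermata
3%, Cnidaria 2%, rest 10% — the typical breakdown of curated soft-bottom
lists), uneven group proportions (default 0.20/0.25/0.30/0.15/0.10, GIII
largest, as in real lists), 5% unassigned, and a nested synthetic taxonomy.

`generate_gradient_communities()` factorizes occupancy and abundance:
species `s` occurs at a station with probability
`base_freq_s * p_g(s)(pressure)`, where `base_freq_s` is log-normal
(median 0.10, sdlog 1.5 — a long tail of rare species and a few ubiquitous
ones) and `p_g` are logistic group response curves (defaults: GI intercept
1.5 slope -4; GII 0.5/-1.5; GIII 0/0; GIV -1.5/2.5; GV -4/6), so sensitive
species fade and opportunists surge along the gradient and group ordering
holds at both ends. Present species draw shifted-geometric abundances (mean
20). Stations can come out azoic only by drawing no species — no forcing.
These parameter values are the package's stated world: they were chosen once
for realism (index values spanning all five classes along the ramp,
pressure–index Spearman correlation above 0.7 at 200 stations) and are not
tuned against test outcomes. The analysis itself never assumes this
particular abundance law — any long-tailed frequency structure suffices.

`generate_barcode_library()` covers a fraction of species (default 0.15,
the typical fraction of benthic index species with any barcode today)
uniformly, biased toward frequent species, or skewed toward GIII; sequences
derive from a common reference with planted primer sites by per-site
substitution (default 2%), optionally truncated to emulate partial entries,
with the ground-truth coverage mask returned for testing.

Not modelled: repeated station/year structure (stations are exchangeable),
spatial autocorrelation, biomass, within-species sequence phylogeny, and
calibration to any real data series. A green simulation test therefore
establishes that the *procedures* behave as designed on data with the right
qualitative structure — not that any particular real-world kappa value is
reproduced; the headline kappas of the motivating monitoring series depend
on an undeposited dataset and are deliberately not acceptance targets.

## Numerical and design notes

- Group percentages sum to 100 within 1e-9 whenever defined; the index is
  invariant under positive scaling of abundances (abundance mode) and under
  any count >= 1 (presence mode).
- Frequency ranking ties break alphabetically; random draws use R's default
  RNG under explicit seeds; per-replicate sub-seeds come from one
  `sample.int` call under the top-level seed.
- All sequence coordinates are 0-based half-open; the reverse primer is
  reverse-complemented once at load and everything is matched on the
  template's plus strand.
- CSV is the default table dialect, tab-separation auto-detected from the
  file extension; machine outputs carry full precision, one-decimal rounding
  is display-only.
- The CLI returns 0 on success, 2 on usage errors, 1 on runtime failure, and
  writes a provenance block (package version, seed, config hash) beside
  every output.

## Known limitations

- The primer score is a mismatch-count surrogate, not a hybridization
  thermodynamics model; its defaults rank primers sensibly but absolute
  amplification probabilities are not calibrated.
- `dedup_cluster()` is quadratic per species — ample for per-species
  redundancy removal, not a general-purpose clusterer.
- With very small assigned-species counts the index is reported with a
  warning rather than corrected; degenerate one-class classifications give
  kappa via the constant-rater convention, which can be brittle.
- The 20-dataset resampling-recovery check passes its >= 80% bound with no
  margin under the fixed default world; small generator changes can flip it,
  which is by design — the bound is a property of the stated world, not a
  tuned constant.
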