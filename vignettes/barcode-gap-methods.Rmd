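---
title: "Quantifying the DNA barcode gap: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the DNA barcode gap: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

A DNA barcode is useful for telling species apart when sequences from the
same species are much more similar to each other than sequences from
different species. The *barcode gap* is the separation between the
distribution of intra-specific pairwise distances and the distribution of
inter-specific pairwise distances for a marker. For fungi the standard
barcode is the nuclear ribosomal internal transcribed spacer (nrITS =
ITS1 + 5.8S + ITS2); short-read studies often use only the ITS1 or ITS2
sub-region, and the two behave differently: ITS1 evolves faster and is more
variable than ITS2, while 5.8S is strongly conserved.

In real curated datasets the raw gap — the difference between the smallest
inter-specific and largest intra-specific distance — is almost always
destroyed by a handful of outlying pairs (identical sequences assigned to
different species, or divergent conspecific sequences). This package
therefore assesses the gap with a quantile *stress test* rather than with
extremes.

## Distances

For an aligned pair of sequences, sites where either member carries a gap
or an ambiguity code are excluded for that pair only (*pairwise deletion*).
Among the comparable sites, with transition proportion $P$ (A–G, C–T) and
transversion proportion $Q$:

* raw (p-)distance: $d = P + Q$;
* Kimura two-parameter distance:
  $d = -\tfrac12 \ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big]$.

The K80 distance is undefined when no site is comparable or when the
logarithm's argument leaves its domain ($1-2P-Q \le 0$ or $1-2Q \le 0$,
i.e. saturation). Undefined pairs are carried as `NA`, excluded from the
pools and counted (`n_undefined`), never silently dropped: a cluster of
undefined pairs is a data problem worth seeing. Whenever both are defined,
the K80 value is at least the raw value (the correction is inflationary).

Two deliberate conventions:

* **Strict ambiguity exclusion.** Any character outside `A/C/G/T` (after
  normalising `U`→`T`, `?`→`N`, `.`→`-`) makes a site non-comparable for
  that pair. Distance routines that weight partial ambiguities
  fractionally will differ at rare sites; strict exclusion keeps $P$ and
  $Q$ exactly defined as counts.
* **Minimum overlap.** `min_comparable_sites` (default 1) turns pairs with
  tiny overlap into undefined entries. The companion sequence-level filter
  (`filter_by_coverage`, on by default) removes sequences covering less
  than 50% of a region before any pair is formed, mirroring standard
  curation practice for partial barcode reads.

The phylogenetic variant takes *patristic* distances — branch-length path
sums between tips of a maximum-likelihood tree — via
`ape::cophenetic.phylo()`; trees must carry branch lengths (a
unit-length fallback exists for topology-only exploration, off by
default).

## Pools and the stress test

Given a species partition, every unordered pair contributes once to the
intra-specific pool (same label) or the inter-specific pool (different
labels); pool sizes plus undefined pairs always sum to $\binom{N}{2}$.
Pools are summarised by count, mean, median, sample variance
($n-1$ denominator; a singleton pool has variance 0 with a warning,
because bona fide species represented by one sequence are deliberately
kept for inter-specific information) and type-7 quantiles
($h = (n-1)p + 1$ with linear interpolation — the default convention of
the R `quantile()` function this field's analyses rely on).

At stress-test level $p$ (default 0.85, 0.90, 0.95):

$$\text{gap}(p) = Q_{\text{inter}}(1-p) - Q_{\text{intra}}(p).$$

A positive value is the size of the gap once the outlying $1-p$ tails are
trimmed; a negative value means the trimmed distributions still overlap.
As $p$ grows the test gets stricter, so gap size is non-increasing in $p$
and presence is monotone (once lost, lost). The *midpoint*
$(Q_{\text{intra}}(p) + Q_{\text{inter}}(1-p))/2$ is reported in percent
and is the natural candidate for a clustering cutoff — computed whether or
not the gap exists, since an absent gap still has a centre.

**One-sided vs two-sided.** "Trimming the tails at 85%" can be read two
ways: one-sided (intra at $p$, inter at $1-p$; the default here) or
central two-sided intervals (intra at $(1+p)/2$, inter at $(1-p)/2$;
available as `two_sided = TRUE`). Both shrink the gap as $p$ grows; the
one-sided form is the default because it touches exactly the two tails
that face each other across the gap, which is what the stress test is
about. The flag exists so results under either reading can be produced
without code changes.

**Lumping and splitting.** `relabel()` re-partitions the same sequences
under a coarser or finer taxonomy. Lumping moves pairs from the inter to
the intra pool (exactly $n_1 n_2$ pairs when two species of sizes
$n_1, n_2$ merge), so the intra pool and its variance can only grow —
which is precisely the mechanism by which over-lumped taxonomies destroy
their own barcode gap.

## The synthetic-data generator

`simulate_dataset()` exists so that every stage of the pipeline can be
validated against known truth without any external download. It emulates
a curated single-genus barcode matrix:

* a species tree (star by default, so expectations stay analytic; a
  coalescent shape is available) with stem branches of length
  `inter_divergence` and individual terminal branches of length
  `intra_divergence`, both in expected substitutions/site — so two
  conspecific sequences diverge by $2 \times$ `intra_divergence` and two
  heterospecific ones by $2 \times$ (`inter_divergence` +
  `intra_divergence`) on the star tree;
* an exact continuous-time K80 mutation process along each branch
  (closed-form transition probabilities, not a Bernoulli approximation),
  with transition/transversion ratio `kappa` (default 2) — so the K80
  estimator applied downstream is the matched inverse of the generating
  process;
* three concatenated regions with relative rate multipliers
  (defaults ITS1 = 1.5, 5.8S = 0.1, ITS2 = 1.0 over 220/160/220 columns,
  width 600), reproducing the fast-ITS1 / frozen-5.8S / intermediate-ITS2
  structure of real fungal barcodes;
* per-sequence gap masking (default 2% of columns), either scattered or
  as contiguous terminal runs (`terminal_gaps`) to stress the coverage
  filter;
* a single seeded RNG: one integer seed makes the whole bundle —
  alignments, species map, tree — byte-reproducible.

Default sizes are 10 species × 5 sequences (singletons allowed via a
per-species vector), divergences 0.005 within and 0.04 between — values a
mycologist would recognise as a clean, well-sampled genus: roughly 1%
conspecific and 9% heterospecific divergence. `expected_pool_means()`
returns the analytic pool means implied by path-length additivity, which
the validation suite requires the full pipeline to recover within three
standard errors over 20 seeds.

What the generator does *not* emulate: indel evolution (gaps are masks,
not evolutionary events), alignment error, length heterogeneity between
taxa, intragenomic ITS variation, and rate variation *within* a region.
Passing tests therefore demonstrate correctness of the computations, not
that any particular real genus has a gap.

One numerical note: for the concatenated nrITS the analytic expectation
uses the length-weighted mean rate, while the pooled K80 estimate over
rate-heterogeneous concatenated sites is very slightly smaller (a Jensen
effect of pooling $P$, $Q$ across regions before the log — about 2% at
the defaults). This sits well inside the 3-SE recovery band and vanishes
for the rate-homogeneous single regions, on which recovery is also
checked.

## Numerical and degenerate-input choices

* Distances are computed and carried in double precision; rounding to 4
  decimals (sizes) or 1 decimal of a percent (midpoints) happens only at
  CSV export. A gap can therefore display as `TRUE 0.0000`: present but
  smaller than the table resolution.
* Gap presence is strictly `gap_size > 0`.
* Empty pools are errors that name the dataset and region (an all-singleton
  partition has no intra pairs and cannot be stress-tested); `NA`
  distances never reach the pools.
* Alignment validation is eager: unequal row lengths name the offending
  sequence, duplicate ids and unlabeled sequences fail before any
  computation.
* Region coordinates are 0-based half-open everywhere.

## Problem sizes used by the validation suite

The test suite validates the distance engine against a literal per-site
oracle on dozens of random alignments (≤ 10 sequences × ≤ 60 columns),
patristic matrices against an independent graph shortest-path oracle
(≤ 12 tips), quantiles against the naive type-7 formula, and the
stochastic properties (parameter recovery, ITS1 > ITS2 > nrITS variance
ordering, lumping inflating intra-specific variance, gap detection in
well-separated data) over 20–40 simulation seeds at the default dataset
size. The full suite and the acceptance script each run in well under a
minute on a single core.

## Limitations

* The stress test describes the gap; it is not a hypothesis test, and no
  significance statement is attached to `TRUE`/`FALSE`.
* Species partitions are inputs. The package deliberately does not infer
  them (no ASAP/GMYC/bPTP), so conclusions inherit whatever taxonomy the
  species map encodes — the lumping/splitting machinery exists to make
  that dependence visible.
* Cross-dataset "overall" statistics are pair-weighted by default, so a
  densely sampled genus dominates in proportion to its pair count;
  per-dataset averaging is available (`per_dataset_means = TRUE`) when
  equal weighting per genus is wanted.
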