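# barcodegap

Quantifying the DNA barcode gap in aligned barcode matrices — built for
the fungal nrITS region and its ITS1/ITS2 sub-regions, but applicable to
any aligned single-marker dataset with species assignments.

## The problem

A barcode marker discriminates species when within-species (intra-specific)
pairwise distances stay well below between-species (inter-specific)
distances; the separation between the two distributions is the *barcode
gap*. In curated datasets the naive gap — minimum inter minus maximum
intra — is almost always erased by a few outlying pairs. `barcodegap`
instead assesses the gap with a quantile **stress test**: at level
*p* ∈ {0.85, 0.90, 0.95},

    gap(p) = Q_inter(1 − p) − Q_intra(p)

where `Q` is the type-7 sample quantile of each pool. A positive value is
the size of the gap after trimming the facing tails; a negative value
means the trimmed distributions still overlap. The midpoint
`(Q_intra(p) + Q_inter(1 − p)) / 2` is the natural candidate clustering
cutoff for the dataset.

Distances are computed under pairwise deletion as either the raw
p-distance or the Kimura two-parameter distance

    d = −½ · ln[(1 − 2P − Q) · √(1 − 2Q)]

with transition proportion `P` (A–G, C–T) and transversion proportion `Q`,
or taken as patristic (branch-length path sum) distances from a
phylogenetic tree. Alternative species partitions of the same sequences
("lumping" vs "splitting" taxonomies) can be compared directly, and a
seeded synthetic ITS-matrix generator makes the whole pipeline verifiable
without external data.

## Worked example

```r
library(barcodegap)

# a synthetic genus: 6 species x 4 sequences, ITS1/5.8S/ITS2 structure
sim <- simulate_dataset(sim_config(n_species = 6, seqs_per_species = 4,
                                   seed = 2024))
fit <- barcode_gap(sim$alignments$ITS2, sim$partition, model = "k80")
fit
#> Barcode-gap analysis: synthetic [ITS2, k80, partition 'true']
#>   6 species, 24 sequences; 36 intra / 240 inter pairs
#>   intra mean 0.01352, inter mean 0.1202
#>   85% level: gap present (size 0.0681, midpoint 0.0533)
#>   90% level: gap present (size 0.0647, midpoint 0.0516)
#>   95% level: gap present (size 0.0507, midpoint 0.0491)
```

The 24 sequences form 36 same-species and 240 different-species pairs;
mean K80 divergence is ≈1.4% within and ≈12% between species, and a gap
of size 0.0507 (in substitutions/site) survives even the strictest 95%
trim, with a midpoint near 4.9% — the distance cutoff this marker would
support for these taxa. Lumping two species into one erases the gap, the
intra pool now containing heterospecific pairs:

```r
lumped <- relabel(sim$partition, c(sp01 = "merged", sp02 = "merged"),
                  "lumping")
barcode_gap(sim$alignments$ITS2, lumped, model = "k80")$assessment
#>   level intra_upper inter_lower     gap_size present   midpoint
#> 1  0.85  0.09517739  0.08807137 -0.007106021   FALSE 0.09162438
#> 2  0.90  0.09601954  0.08341235 -0.012607190   FALSE 0.08971594
#> 3  0.95  0.10336175  0.07436260 -0.028999152   FALSE 0.08886218
```

Real data enter through `read_alignment()` (aligned FASTA),
`read_partition()` (two-column species map, or
`partition_from_headers()`), and `read_tree()` (newick with branch
lengths, for the patristic variant via `barcode_gap(tree = ...)`).
`run_study()` loops datasets × regions × partitions and writes the
report tables (`stress_test.csv` with its Count/AVE footer,
`cutoffs.csv` with midpoints in percent, `summaries.csv`); the same
workflow is scriptable through the `inst/scripts/barcodegap` command-line
wrapper (`simulate`, `dist`, `cophenetic`, `stress` subcommands).

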