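test_that("simulation is deterministic for a fixed seed", {
  cfg <- sim_config(n_species = 4, seqs_per_species = 3, seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$alignments$nrITS$seqs, s2$alignments$nrITS$seqs)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in c("nrITS.fasta", "ITS1.fasta", "ITS2.fasta", "species_map.tsv",
              "true_tree.nwk"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  s3 <- simulate_dataset(sim_config(n_species = 4, seqs_per_species = 3,
                                    seed = 100))
  expect_false(identical(s1$alignments$nrITS$seqs, s3$alignments$nrITS$seqs))
})

test_that("dataset dimensions and pool sizes follow the config", {
  sim <- simulate_dataset(sim_config(n_species = 5, seqs_per_species = 4,
                                     seed = 61))
  expect_length(sim$alignments$nrITS$ids, 20)
  expect_identical(sim$alignments$nrITS$width,
                   sum(sim$config$region_lengths))
  expect_identical(sim$alignments$ITS1$width,
                   sim$config$region_lengths[["its1"]])
  dm <- pairwise_matrix(sim$alignments$nrITS, "raw")
  pools <- split_pools(dm, sim$partition)
  expect_identical(length(pools$intra), 5L * as.integer(choose(4, 2)))   # 30
  expect_identical(length(pools$inter), as.integer(choose(20, 2) - 30)) # 160
  expect_identical(length(pools$intra) + length(pools$inter) +
                     pools$n_undefined_excluded, as.integer(choose(20, 2)))
})

test_that("per-species sequence counts and singletons are honoured", {
  sim <- simulate_dataset(sim_config(n_species = 3,
                                     seqs_per_species = c(3, 1, 2),
                                     seed = 62))
  expect_length(sim$alignments$nrITS$ids, 6)
  counts <- table(sim$partition$assignments)
  expect_identical(as.integer(counts[c("sp01", "sp02", "sp03")]),
                   c(3L, 1L, 2L))
})

test_that("zero intra divergence gives identical conspecific sequences", {
  sim <- simulate_dataset(sim_config(n_species = 4, seqs_per_species = 3,
                                     intra_divergence = 0, gap_fraction = 0,
                                     seed = 63))
  pools <- split_pools(pairwise_matrix(sim$alignments$nrITS, "raw"),
                       sim$partition)
  expect_true(all(pools$intra == 0))
})

test_that("the true tree reproduces the configured path lengths", {
  cfg <- sim_config(n_species = 3, seqs_per_species = 2, seed = 64)
  sim <- simulate_dataset(cfg)
  d <- cophenetic_matrix(sim$tree)$values
  expect_equal(d["sp01_1", "sp01_2"], 2 * cfg$intra_divergence)
  expect_equal(d["sp01_1", "sp02_1"],
               2 * (cfg$inter_divergence + cfg$intra_divergence))
})

test_that("coalescent-shaped species trees keep tip labels and depth", {
  cfg <- sim_config(n_species = 5, seqs_per_species = c(2, 1, 3, 2, 2),
                    tree_shape = "coalescent", seed = 65)
  sim <- simulate_dataset(cfg)
  expect_setequal(sim$tree$tip.label, sim$alignments$nrITS$ids)
  d <- cophenetic_matrix(sim$tree)$values
  # conspecific tips still sit 2 * intra apart
  expect_equal(d["sp01_1", "sp01_2"], 2 * cfg$intra_divergence)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_species = 1), "2 species")
  expect_error(sim_config(gap_fraction = 0.9), "gap_fraction")
  expect_error(sim_config(kappa = -1), "kappa")
  expect_error(sim_config(region_lengths = c(its1 = 0, r58s = 10,
                                             its2 = 10)), "positive")
  expect_warning(sim_config(intra_divergence = 0.1,
                            inter_divergence = 0.05), "separate")
})

test_that("expected pool means follow path-length additivity", {
  cfg <- sim_config(inter_divergence = 0.04, intra_divergence = 0.005,
                    region_rates = c(its1 = 1.5, r58s = 0, its2 = 1.0))
  em <- expected_pool_means(cfg)
  expect_equal(unname(em$intra[["ITS2"]]), 0.01)
  expect_equal(unname(em$inter[["ITS2"]]), 0.09)    # 2 * (0.04 + 0.005)
  expect_equal(unname(em$inter[["ITS1"]]), 0.09 * 1.5)
  expect_identical(unname(em$inter[["r58s"]]), 0)   # rate 0 region
})

test_that("terminal gap masking produces contiguous ragged ends", {
  sim <- simulate_dataset(sim_config(n_species = 3, seqs_per_species = 3,
                                     gap_fraction = 0.2,
                                     terminal_gaps = TRUE, seed = 66))
  for (s in sim$alignments$nrITS$seqs)
    expect_match(s, "^-*[ACGT]+-*$")
})

test_that("written bundles read back through the ingestion functions", {
  sim <- simulate_dataset(sim_config(n_species = 3, seqs_per_species = 3,
                                     seed = 67))
  dir <- file.path(tempdir(), "bundle")
  paths <- write_dataset(sim, dir)
  aln <- read_alignment(paths[["nrITS"]], region = "nrITS")
  expect_identical(aln$seqs, sim$alignments$nrITS$seqs)
  part <- read_partition(paths[["species_map"]], aln)
  expect_identical(part$assignments, sim$partition$assignments)
  tr <- read_tree(paths[["tree"]])
  expect_setequal(tr$tip.label, aln$ids)
  meta <- yaml::read_yaml(paths[["metadata"]])
  expect_identical(meta$seed, sim$config$seed)
})
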