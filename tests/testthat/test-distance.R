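test_that("site classification follows pairwise-deletion semantics", {
  expect_identical(classify_pair_sites("ACGT", "ACGT"),
                   c(n_comparable = 4L, n_transition = 0L,
                     n_transversion = 0L))
  expect_identical(classify_pair_sites("ACGT", "GCGT"),
                   c(n_comparable = 4L, n_transition = 1L,
                     n_transversion = 0L))
  expect_identical(classify_pair_sites("AC-TN", "ACGTA"),
                   c(n_comparable = 3L, n_transition = 0L,
                     n_transversion = 0L))
  expect_identical(classify_pair_sites("ACGT", "TGCA"),
                   c(n_comparable = 4L, n_transition = 0L,
                     n_transversion = 4L))
  expect_error(classify_pair_sites("ACG", "ACGT"), "unequal")
})

test_that("p-distance and K80 match their closed forms", {
  cnt <- function(n, ts, tv) c(n_comparable = n, n_transition = ts,
                               n_transversion = tv)
  expect_identical(p_distance(cnt(4, 0, 0)), 0)
  expect_identical(p_distance(cnt(4, 1, 0)), 0.25)
  expect_true(is.na(p_distance(cnt(0, 0, 0))))
  expect_identical(k80_distance(cnt(10, 0, 0)), 0)
  expect_equal(k80_distance(cnt(10, 1, 0)), -0.5 * log(0.8))
  expect_equal(k80_distance(cnt(10, 1, 0)), 0.111572, tolerance = 1e-5)
  expect_equal(k80_distance(cnt(10, 0, 1)), -0.5 * log(0.9 * sqrt(0.8)))
  expect_equal(k80_distance(cnt(10, 0, 1)), 0.108466, tolerance = 1e-5)
  expect_true(is.na(k80_distance(cnt(10, 5, 0))))   # 1 - 2P - Q = 0
  expect_true(is.na(k80_distance(cnt(10, 0, 5))))   # 1 - 2Q = 0
  expect_true(is.na(k80_distance(cnt(0, 0, 0))))
})

test_that("defined K80 distances never fall below the p-distance", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    ts <- sample(0:n, 1)
    tv <- sample(0:(n - ts), 1)
    cnt <- c(n_comparable = n, n_transition = ts, n_transversion = tv)
    d <- k80_distance(cnt)
    if (!is.na(d)) expect_gte(d, p_distance(cnt) - 1e-12)
  }
})

test_that("pairwise_matrix equals the literal per-site oracle", {
  set.seed(22)
  for (rep in 1:10) {
    aln <- random_alignment(sample(3:8, 1), sample(20:60, 1))
    for (model in c("raw", "k80")) {
      dm <- suppressMessages(
        pairwise_matrix(aln, model, coverage_filter = FALSE))
      expect_identical(dm$values, oracle_matrix(aln, model))
    }
  }
})

test_that("distance matrices are symmetric, zero-diagonal, non-negative", {
  set.seed(23)
  aln <- random_alignment(8, 50)
  dm <- suppressMessages(pairwise_matrix(aln, "k80",
                                         coverage_filter = FALSE))
  expect_identical(dm$values, t(dm$values))
  expect_identical(unname(diag(dm$values)), rep(0, 8))
  expect_true(all(dm$values >= 0, na.rm = TRUE))
  expect_true(all(dm$comparable_sites <= aln$width))
  expect_identical(dm$ids, aln$ids)
})

test_that("pairwise deletion is local: masking touches only the masked pair's rows", {
  # unlike complete (column-wise) deletion, masking a column in two
  # sequences leaves every pair not involving them untouched
  set.seed(24)
  aln <- random_alignment(6, 40, gap_prob = 0, amb_prob = 0)
  before <- pairwise_matrix(aln, "raw", coverage_filter = FALSE)
  rows <- aln$seqs
  substr(rows[1], 5, 5) <- "-"
  substr(rows[2], 5, 5) <- "-"
  after <- pairwise_matrix(aligned_seqs(aln$ids, rows), "raw",
                           coverage_filter = FALSE)
  changed <- which(before$values != after$values, arr.ind = TRUE)
  expect_true(all(changed[, "row"] %in% 1:2 | changed[, "col"] %in% 1:2))
  expect_identical(before$values[3:6, 3:6], after$values[3:6, 3:6])
  # the masked pair itself loses exactly one comparable site
  expect_identical(before$comparable_sites[1, 2] -
                     after$comparable_sites[1, 2], 1L)
})

test_that("three identical sequences give an all-zero matrix", {
  aln <- aligned_seqs(c("a", "b", "c"), rep("ACGTACGT", 3))
  dm <- pairwise_matrix(aln, "k80")
  expect_true(all(dm$values == 0))
  expect_error(pairwise_matrix(aligned_seqs("a", "ACGT"), "raw"),
               "at least 2")
})

test_that("pairs below the comparable-site threshold become undefined", {
  aln <- aligned_seqs(c("a", "b"), c("AC--", "ACGT"))
  dm <- pairwise_matrix(aln, "raw", coverage_filter = FALSE)
  expect_identical(dm$values["a", "b"], 0)
  dm2 <- suppressMessages(
    pairwise_matrix(aln, "raw", min_comparable_sites = 3,
                    coverage_filter = FALSE))
  expect_true(is.na(dm2$values["a", "b"]))
  expect_identical(dm2$n_undefined, 1L)
})

test_that("the 50% coverage pre-filter drops gappy sequences", {
  aln <- aligned_seqs(c("a", "b", "c"),
                      c("ACGTACGT", "ACGTAC--", "A-------"))
  expect_message(dm <- pairwise_matrix(aln, "raw"), "removed")
  expect_identical(dm$ids, c("a", "b"))
  expect_identical(dm$n_filtered, 1L)
})

test_that("results agree with ape::dist.dna under pairwise deletion", {
  # realistic divergences: all distances defined in both implementations
  sim <- simulate_dataset(sim_config(n_species = 4, seqs_per_species = 3,
                                     gap_fraction = 0.08, seed = 25))
  aln <- sim$alignments$nrITS
  bin <- as.matrix(ape::as.DNAbin(strsplit(tolower(aln$seqs), "")))
  rownames(bin) <- aln$ids
  for (model in c("raw", "K80")) {
    ref <- as.matrix(ape::dist.dna(bin, model = model,
                                   pairwise.deletion = TRUE))
    dm <- pairwise_matrix(aln, tolower(model), coverage_filter = FALSE)
    expect_equal(dm$values[aln$ids, aln$ids], ref[aln$ids, aln$ids],
                 tolerance = 1e-12)
  }
  # saturated pairs: ape yields NaN/Inf, here they are NA-undefined
  sat <- aligned_seqs(c("a", "b"), c("ACACACAC", "CACACACA"))
  satbin <- as.matrix(ape::as.DNAbin(strsplit(tolower(sat$seqs), "")))
  rownames(satbin) <- sat$ids
  refd <- as.matrix(ape::dist.dna(satbin, "K80",
                                  pairwise.deletion = TRUE))["a", "b"]
  expect_false(is.finite(refd))
  dm <- suppressMessages(pairwise_matrix(sat, "k80",
                                         coverage_filter = FALSE))
  expect_true(is.na(dm$values["a", "b"]))
})

test_that("long-format export has one row per unordered pair", {
  set.seed(26)
  aln <- random_alignment(6, 30)
  dm <- suppressMessages(pairwise_matrix(aln, "k80",
                                         coverage_filter = FALSE))
  f <- tempfile(fileext = ".csv")
  write_distance_long(dm, f)
  long <- read.csv(f)
  expect_identical(nrow(long), as.integer(choose(6, 2)))
  expect_identical(unique(long$model), "k80")
  i <- match(long$id1[1], dm$ids); j <- match(long$id2[1], dm$ids)
  expect_equal(long$distance[1], dm$values[i, j])
})
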