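# Independent oracles and fixture builders shared across the tests.
# Everything here deliberately uses the slowest, most literal formulation
# so it cannot share a bug with the package internals.

# random aligned matrix over ACGT with gaps/ambiguities mixed in
random_alignment <- function(n_seq, width, gap_prob = 0.1, amb_prob = 0.05,
                             dataset = "rand", region = "custom") {
  alphabet <- c("A", "C", "G", "T")
  extras <- c("-", "N", "R", "Y")
  rows <- vapply(seq_len(n_seq), function(i) {
    ch <- sample(alphabet, width, replace = TRUE)
    k <- runif(width)
    ch[k < gap_prob] <- "-"
    ch[k >= gap_prob & k < gap_prob + amb_prob] <-
      sample(extras, sum(k >= gap_prob & k < gap_prob + amb_prob),
             replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  aligned_seqs(sprintf("s%02d", seq_len(n_seq)), rows,
               dataset_name = dataset, region = region)
}

# literal per-site loop: comparable iff both in ACGT; A<->G / C<->T are
# transitions, every other mismatch a transversion
oracle_pair_counts <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  nc <- ts <- tv <- 0L
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      nc <- nc + 1L
      if (x != y) {
        if ((x == "A" && y == "G") || (x == "G" && y == "A") ||
            (x == "C" && y == "T") || (x == "T" && y == "C"))
          ts <- ts + 1L
        else tv <- tv + 1L
      }
    }
  }
  c(n_comparable = nc, n_transition = ts, n_transversion = tv)
}

oracle_distance <- function(a, b, model) {
  cnt <- oracle_pair_counts(a, b)
  n <- cnt[["n_comparable"]]
  if (n == 0L) return(NA_real_)
  if (model == "raw")
    return((cnt[["n_transition"]] + cnt[["n_transversion"]]) / n)
  P <- cnt[["n_transition"]] / n
  Q <- cnt[["n_transversion"]] / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

oracle_matrix <- function(alignment, model) {
  n <- length(alignment$ids)
  m <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- oracle_distance(alignment$seqs[i],
                                          alignment$seqs[j], model)
  m
}

# type-7 quantile from first principles (1-based h = (n-1)p + 1)
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# tip-to-tip path length via igraph shortest paths on the tree graph
oracle_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length[
    match(paste(igraph::as_edgelist(g)[, 1], igraph::as_edgelist(g)[, 2]),
          paste(tree$edge[, 1], tree$edge[, 2]))])
  n <- length(tree$tip.label)
  tipv <- as.character(seq_len(n))
  out <- d[tipv, tipv]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# write a FASTA string to a temp file
tmp_fasta <- function(text) {
  f <- tempfile(fileext = ".fasta")
  writeLines(text, f)
  f
}

tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
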