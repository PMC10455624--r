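#' Pairwise distance matrix
#'
#' Symmetric matrix of pairwise distances tagged with the model that
#' produced it (`raw` p-distance, `k80` Kimura two-parameter, or
#' `cophenetic` tree path length). Undefined distances (no comparable
#' sites, or K80 saturation) are stored as `NA`. Sequence models also carry
#' the per-pair count of comparable sites.
#'
#' @param values symmetric numeric matrix with zero diagonal; dimnames give
#'   the sequence ids.
#' @param model one of `"raw"`, `"k80"`, `"cophenetic"`.
#' @param comparable_sites optional symmetric integer matrix of per-pair
#'   comparable-site counts (sequence models only).
#' @param n_filtered number of sequences removed by the coverage pre-filter.
#' @return An object of class `distance_matrix`: list with `model`, `ids`,
#'   `values`, `comparable_sites`, `n_undefined` (count of undefined
#'   unordered pairs) and `n_filtered`.
#' @export
distance_matrix <- function(values, model = c("raw", "k80", "cophenetic"),
                            comparable_sites = NULL, n_filtered = 0L) {
  model <- match.arg(model)
  values <- as.matrix(values)
  ids <- rownames(values)
  if (is.null(ids) || is.null(colnames(values)))
    stop("'values' must have row and column names (sequence ids)")
  if (!identical(ids, colnames(values)))
    stop("row and column names differ")
  if (any(diag(values) != 0, na.rm = TRUE) || anyNA(diag(values)))
    stop("diagonal must be exactly 0")
  if (!isTRUE(all.equal(values, t(values))) &&
      !identical(is.na(values), is.na(t(values))))
    stop("matrix must be symmetric")
  if (any(values < 0, na.rm = TRUE)) stop("negative distances")
  ut <- upper.tri(values)
  structure(
    list(model = model, ids = ids, values = values,
         comparable_sites = comparable_sites,
         n_undefined = sum(is.na(values[ut])),
         n_filtered = as.integer(n_filtered)),
    class = "distance_matrix"
  )
}

#' @export
print.distance_matrix <- function(x, ...) {
  n <- length(x$ids)
  cat("Pairwise distance matrix (", x$model, "): ", n, " sequences, ",
      choose(n, 2), " pairs", sep = "")
  if (x$n_undefined > 0) cat(", ", x$n_undefined, " undefined", sep = "")
  if (x$n_filtered > 0) cat(" (", x$n_filtered, " sequences filtered)", sep = "")
  cat("\n")
  invisible(x)
}

# Integer coding of aligned rows: A=1 C=2 G=3 T=4, everything else 0
# (non-comparable under pairwise deletion).
encode_alignment <- function(alignment) {
  chars <- strsplit(alignment$seqs, "", fixed = TRUE)
  m <- t(vapply(chars, function(ch) {
    i <- match(ch, c("A", "C", "G", "T"))
    i[is.na(i)] <- 0L
    i
  }, integer(alignment$width)))
  rownames(m) <- alignment$ids
  m
}

#' Classify the sites of one aligned pair
#'
#' Under pairwise deletion a site is comparable for a pair iff both
#' sequences carry an unambiguous base (`A`, `C`, `G` or `T`) at that
#' column; gaps, `N` and IUPAC ambiguity codes exclude the site for that
#' pair only. Among comparable mismatches, transitions are the purine and
#' pyrimidine exchanges A<->G and C<->T; all other mismatches are
#' transversions.
#'
#' @param rowA,rowB aligned sequence strings of equal length.
#' @return Named integer vector with `n_comparable`, `n_transition`,
#'   `n_transversion`.
#' @examples
#' classify_pair_sites("ACGT", "GCGT")   # one transition
#' classify_pair_sites("AC-TN", "ACGTA") # gap and N columns dropped
#' @export
classify_pair_sites <- function(rowA, rowB) {
  rowA <- normalize_sequences(rowA); rowB <- normalize_sequences(rowB)
  if (nchar(rowA) != nchar(rowB))
    stop("sequences have unequal lengths (", nchar(rowA), " vs ", nchar(rowB), ")")
  a <- utf8ToInt(rowA); b <- utf8ToInt(rowB)
  bases <- utf8ToInt("ACGT")
  ia <- match(a, bases); ib <- match(b, bases)
  comp <- !is.na(ia) & !is.na(ib)
  diff <- comp & (ia != ib)
  # purines code to odd positions (A=1, G=3); pyrimidines to even (C=2, T=4)
  ts <- diff & ((ia %% 2L) == (ib %% 2L))
  c(n_comparable = sum(comp), n_transition = sum(ts),
    n_transversion = sum(diff) - sum(ts))
}

#' Raw p-distance from pair site counts
#'
#' Proportion of differing sites among comparable sites:
#' `(n_transition + n_transversion) / n_comparable`.
#'
#' @param counts output of [classify_pair_sites()].
#' @return The p-distance, or `NA` when no site is comparable.
#' @export
p_distance <- function(counts) {
  n <- counts[["n_comparable"]]
  if (n == 0) return(NA_real_)
  (counts[["n_transition"]] + counts[["n_transversion"]]) / n
}

#' Kimura two-parameter (K80) distance from pair site counts
#'
#' With transition proportion `P` and transversion proportion `Q` among
#' comparable sites, the K80 distance is
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#' The distance is undefined (`NA`) when no site is comparable or when the
#' log argument leaves its domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`,
#' i.e. saturation).
#'
#' @param counts output of [classify_pair_sites()].
#' @return The K80 distance, or `NA`.
#' @export
k80_distance <- function(counts) {
  n <- counts[["n_comparable"]]
  if (n == 0) return(NA_real_)
  P <- counts[["n_transition"]] / n
  Q <- counts[["n_transversion"]] / n
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0) return(NA_real_)
  -0.5 * log(a * sqrt(b))
}

#' Drop low-coverage sequences from an alignment
#'
#' Removes sequences whose fraction of non-gap characters in the region is
#' below `min_coverage`, mirroring the usual curation rule that a sequence
#' must span at least half of a barcode region to enter the distance
#' analysis.
#'
#' @param alignment an [aligned_seqs()] object.
#' @param min_coverage minimum non-gap fraction (default 0.5).
#' @return The filtered [aligned_seqs()]; dropped ids are reported in a
#'   message.
#' @export
filter_by_coverage <- function(alignment, min_coverage = 0.5) {
  stopifnot(inherits(alignment, "aligned_seqs"))
  gaps <- vapply(strsplit(alignment$seqs, "", fixed = TRUE),
                 function(ch) sum(ch == "-"), integer(1))
  keep <- (1 - gaps / alignment$width) >= min_coverage
  if (all(keep)) return(alignment)
  if (!any(keep)) stop("coverage filter would remove every sequence")
  message(sum(!keep), " sequence(s) below ", min_coverage * 100,
          "% coverage removed: ", paste(alignment$ids[!keep], collapse = ", "))
  aligned_seqs(alignment$ids[keep], alignment$seqs[keep],
               dataset_name = alignment$dataset, region = alignment$region)
}

#' Pairwise distance matrix of an alignment
#'
#' Computes all unordered pairwise distances under pairwise deletion with
#' the raw (p-distance) or K80 model. Pairs with fewer than
#' `min_comparable_sites` comparable sites, and K80 pairs outside the log
#' domain, yield `NA` and are counted in the result's `n_undefined`.
#'
#' @param alignment an [aligned_seqs()] object with at least two sequences
#'   (after filtering).
#' @param model `"raw"` or `"k80"`.
#' @param min_comparable_sites pairs with fewer comparable sites are
#'   undefined (default 1).
#' @param coverage_filter apply [filter_by_coverage()] at 50% first
#'   (default `TRUE`).
#' @return A [distance_matrix()] with per-pair `comparable_sites`.
#' @export
pairwise_matrix <- function(alignment, model = c("raw", "k80"),
                            min_comparable_sites = 1L,
                            coverage_filter = TRUE) {
  stopifnot(inherits(alignment, "aligned_seqs"))
  model <- match.arg(model)
  n_before <- length(alignment$ids)
  if (coverage_filter) alignment <- filter_by_coverage(alignment)
  n <- length(alignment$ids)
  if (n < 2L) stop("need at least 2 sequences, got ", n)
  enc <- encode_alignment(alignment)
  vals <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  comp <- matrix(0L, n, n, dimnames = list(alignment$ids, alignment$ids))
  diag(comp) <- as.integer(rowSums(enc > 0L))
  for (i in seq_len(n - 1L)) {
    ai <- enc[i, ]
    for (j in (i + 1L):n) {
      bj <- enc[j, ]
      ok <- ai > 0L & bj > 0L
      nc <- sum(ok)
      df <- ok & (ai != bj)
      ts <- sum(df & ((ai %% 2L) == (bj %% 2L)))
      tv <- sum(df) - ts
      cnt <- c(n_comparable = nc, n_transition = ts, n_transversion = tv)
      d <- if (nc < min_comparable_sites) NA_real_
           else if (model == "raw") p_distance(cnt) else k80_distance(cnt)
      vals[i, j] <- vals[j, i] <- d
      comp[i, j] <- comp[j, i] <- nc
    }
  }
  dm <- distance_matrix(vals, model = model, comparable_sites = comp,
                        n_filtered = n_before - n)
  if (dm$n_undefined > 0)
    message(dm$n_undefined, " of ", choose(n, 2),
            " pairwise distances undefined (", model, ")")
  dm
}

#' Export a distance matrix to CSV
#'
#' `write_distance_csv()` writes the square matrix with an id header row and
#' column; `write_distance_long()` writes one row per unordered pair
#' (`id1,id2,model,distance,comparable_sites`), the format consumed by
#' downstream pooling.
#'
#' @param dm a [distance_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  utils::write.csv(dm$values, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
write_distance_long <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  utils::write.csv(distance_long(dm), path, row.names = FALSE)
  invisible(path)
}

distance_long <- function(dm) {
  n <- length(dm$ids)
  pr <- which(upper.tri(dm$values), arr.ind = TRUE)
  pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
  data.frame(
    id1 = dm$ids[pr[, 1L]], id2 = dm$ids[pr[, 2L]], model = dm$model,
    distance = dm$values[pr],
    comparable_sites = if (is.null(dm$comparable_sites)) NA_integer_
                       else dm$comparable_sites[pr],
    stringsAsFactors = FALSE
  )
}
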