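#' Barcode-gap analysis of one dataset
#'
#' The main entry point: computes pairwise distances for one aligned
#' dataset (or takes patristic distances from a tree), splits them into
#' intra- and inter-specific pools under a species partition, summarises
#' both pools and runs the quantile stress test.
#'
#' Exactly one of `alignment` or `tree` must be supplied. With an
#' alignment, distances are computed by [pairwise_matrix()] under `model`
#' (`"k80"` or `"raw"`, pairwise deletion); with a tree, patristic
#' distances come from [cophenetic_matrix()].
#'
#' @param alignment an [aligned_seqs()] object.
#' @param partition a [species_partition()] labelling every sequence.
#' @param model distance model for sequence input: `"k80"` (default) or
#'   `"raw"`.
#' @param tree a `phylo` tree (patristic variant); overrides `model`.
#' @param levels stress-test quantile levels (default 0.85, 0.90, 0.95).
#' @param two_sided see [stress_test()].
#' @param min_comparable_sites,coverage_filter passed to
#'   [pairwise_matrix()].
#' @param keep_matrix keep the full distance matrix in the returned object
#'   (default `TRUE`; set `FALSE` to save memory on large datasets).
#' @return An object of class `barcode_gap`: list with `pools`
#'   ([split_pools()] result), `intra_summary` and `inter_summary`
#'   ([summarize_pool()]), `assessment` ([stress_test()] data frame),
#'   `model`, `levels`, and optionally `matrix`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_species = 4, seqs_per_species = 3,
#'                                    seed = 1))
#' fit <- barcode_gap(sim$alignments$nrITS, sim$partition)
#' fit
#' summary(fit)
#' @export
barcode_gap <- function(alignment = NULL, partition, model = c("k80", "raw"),
                        tree = NULL, levels = c(0.85, 0.90, 0.95),
                        two_sided = FALSE, min_comparable_sites = 1L,
                        coverage_filter = TRUE, keep_matrix = TRUE) {
  stopifnot(inherits(partition, "species_partition"))
  if (is.null(alignment) == is.null(tree))
    stop("supply exactly one of 'alignment' or 'tree'")
  if (!is.null(tree)) {
    dm <- cophenetic_matrix(tree)
    dataset <- "tree"; region <- "custom"
  } else {
    stopifnot(inherits(alignment, "aligned_seqs"))
    model <- match.arg(model)
    dm <- pairwise_matrix(alignment, model = model,
                          min_comparable_sites = min_comparable_sites,
                          coverage_filter = coverage_filter)
    dataset <- alignment$dataset; region <- alignment$region
  }
  pools <- split_pools(dm, partition, dataset_name = dataset, region = region)
  fit <- structure(
    list(pools = pools,
         intra_summary = summarize_pool(pools$intra),
         inter_summary = summarize_pool(pools$inter),
         assessment = stress_test(pools, levels = levels,
                                  two_sided = two_sided),
         model = dm$model, levels = levels, two_sided = two_sided),
    class = "barcode_gap"
  )
  if (keep_matrix) fit$matrix <- dm
  fit
}

#' @export
print.barcode_gap <- function(x, digits = 4, ...) {
  p <- x$pools
  cat("Barcode-gap analysis: ", p$dataset, " [", p$region, ", ", x$model,
      ", partition '", p$partition_name, "']\n", sep = "")
  cat("  ", p$n_taxa, " species, ", p$n_seq, " sequences; ",
      length(p$intra), " intra / ", length(p$inter), " inter pairs",
      if (p$n_undefined_excluded > 0)
        paste0(" (", p$n_undefined_excluded, " undefined excluded)"),
      "\n", sep = "")
  cat("  intra mean ", signif(x$intra_summary$mean, digits),
      ", inter mean ", signif(x$inter_summary$mean, digits), "\n", sep = "")
  a <- x$assessment
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %2.0f%% level: gap %s (size %.4f, midpoint %.4f)\n",
                a$level[i] * 100, if (a$present[i]) "present" else "absent",
                a$gap_size[i], a$midpoint[i]))
  invisible(x)
}

#' @export
summary.barcode_gap <- function(object, ...) {
  structure(
    list(dataset = object$pools$dataset, region = object$pools$region,
         model = object$model, partition = object$pools$partition_name,
         n_taxa = object$pools$n_taxa, n_seq = object$pools$n_seq,
         intra = object$intra_summary, inter = object$inter_summary,
         assessment = object$assessment),
    class = "summary.barcode_gap"
  )
}

#' @export
print.summary.barcode_gap <- function(x, digits = 4, ...) {
  cat("Barcode-gap analysis of ", x$dataset, " [", x$region, ", ", x$model,
      ", partition '", x$partition, "']\n", sep = "")
  cat(x$n_taxa, " species, ", x$n_seq, " sequences\n\n", sep = "")
  cat("Intra-specific pool:\n"); print(x$intra, digits = digits)
  cat("\nInter-specific pool:\n"); print(x$inter, digits = digits)
  cat("\nStress test:\n")
  print(format(as.data.frame(x$assessment), digits = digits),
        row.names = FALSE)
  invisible(x)
}

#' Boxplot of the intra- and inter-specific pools
#'
#' Quick visual of the two distance distributions with the stress-test
#' quantile bounds at the first level overlaid as dashed lines.
#'
#' @param x a [barcode_gap()] object.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.barcode_gap <- function(x, ...) {
  p <- x$pools
  graphics::boxplot(list(intra = p$intra, inter = p$inter),
                    ylab = paste0("pairwise distance (", x$model, ")"),
                    main = paste0(p$dataset, " [", p$region, "]"), ...)
  a <- x$assessment[1L, ]
  graphics::abline(h = c(a$intra_upper, a$inter_lower), lty = 2,
                   col = c("red", "blue"))
  invisible(x)
}
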