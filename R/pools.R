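#' Intra- and inter-specific distance pools
#'
#' Flattened vectors of pairwise distances split by whether the two
#' sequences of each unordered pair belong to the same species (intra) or
#' to different species (inter). Every distinct pair contributes exactly
#' once; undefined distances are excluded and counted.
#'
#' @param matrix a [distance_matrix()].
#' @param partition a [species_partition()] labelling every matrix id.
#' @param dataset_name,region optional labels carried into reports; default
#'   to `"dataset"` / `"custom"`.
#' @return An object of class `distance_pools`: list with `dataset`,
#'   `region`, `model`, `partition_name`, numeric vectors `intra` and
#'   `inter`, `n_undefined_excluded` and `n_seq`, `n_taxa`. Pool sizes obey
#'   `length(intra) + length(inter) + n_undefined_excluded == choose(N, 2)`.
#' @export
split_pools <- function(matrix, partition, dataset_name = "dataset",
                        region = "custom") {
  stopifnot(inherits(matrix, "distance_matrix"),
            inherits(partition, "species_partition"))
  unlabeled <- setdiff(matrix$ids, names(partition$assignments))
  if (length(unlabeled))
    stop("no species label for id(s): ", paste(unlabeled, collapse = ", "))
  lab <- partition$assignments[matrix$ids]
  same <- outer(lab, lab, "==")
  ut <- upper.tri(matrix$values)
  v <- matrix$values[ut]
  s <- same[ut]
  structure(
    list(dataset = dataset_name, region = region, model = matrix$model,
         partition_name = partition$name,
         intra = v[s & !is.na(v)], inter = v[!s & !is.na(v)],
         n_undefined_excluded = sum(is.na(v)),
         n_seq = length(matrix$ids), n_taxa = length(unique(lab))),
    class = "distance_pools"
  )
}

#' Construct distance pools from raw vectors
#'
#' Low-level constructor for callers that already hold intra- and
#' inter-specific distance vectors (e.g. imported from a long-format CSV).
#' [split_pools()] is the usual way to build pools from a matrix.
#'
#' @param intra,inter numeric vectors of pairwise distances (no `NA`).
#' @param dataset_name,region,model,partition_name,n_undefined_excluded,n_seq,n_taxa
#'   metadata fields; see [split_pools()].
#' @return A `distance_pools` object.
#' @export
distance_pools <- function(intra, inter, dataset_name = "dataset",
                           region = "custom", model = "raw",
                           partition_name = "default",
                           n_undefined_excluded = 0L, n_seq = NA_integer_,
                           n_taxa = NA_integer_) {
  if (anyNA(intra) || anyNA(inter)) stop("pools must not contain NA")
  if (any(c(intra, inter) < 0)) stop("negative distances")
  structure(
    list(dataset = dataset_name, region = region, model = model,
         partition_name = partition_name,
         intra = as.numeric(intra), inter = as.numeric(inter),
         n_undefined_excluded = as.integer(n_undefined_excluded),
         n_seq = n_seq, n_taxa = n_taxa),
    class = "distance_pools"
  )
}

#' @export
print.distance_pools <- function(x, ...) {
  cat("Distance pools: ", x$dataset, " [", x$region, ", ", x$model,
      ", partition '", x$partition_name, "']\n", sep = "")
  cat("  ", x$n_taxa, " species, ", x$n_seq, " sequences: ",
      length(x$intra), " intra pairs, ", length(x$inter), " inter pairs",
      sep = "")
  if (x$n_undefined_excluded > 0)
    cat(", ", x$n_undefined_excluded, " undefined pairs excluded", sep = "")
  cat("\n")
  invisible(x)
}

#' Pool distances across datasets
#'
#' Concatenates the intra and inter pools of several datasets into one
#' overall pool. The default is pair-weighted (every pair counts once, so a
#' large genus dominates in proportion to its number of pairs);
#' `per_dataset_means = TRUE` instead averages the per-dataset pool means,
#' giving every dataset equal weight.
#'
#' @param pools_list list of [split_pools()] results (same model).
#' @param per_dataset_means average per-dataset means instead of
#'   concatenating pairs (default `FALSE`).
#' @return With pair weighting, a `distance_pools` object labelled
#'   `"overall"`; with `per_dataset_means = TRUE`, a list with `intra_mean`
#'   and `inter_mean`.
#' @export
combine_pools <- function(pools_list, per_dataset_means = FALSE) {
  stopifnot(length(pools_list) >= 1L,
            all(vapply(pools_list, inherits, logical(1), "distance_pools")))
  models <- unique(vapply(pools_list, `[[`, character(1), "model"))
  if (length(models) > 1L)
    stop("cannot pool across models: ", paste(models, collapse = ", "))
  if (per_dataset_means) {
    return(list(
      intra_mean = mean(vapply(pools_list,
                               function(p) mean(p$intra), numeric(1)),
                        na.rm = TRUE),
      inter_mean = mean(vapply(pools_list,
                               function(p) mean(p$inter), numeric(1)),
                        na.rm = TRUE)))
  }
  structure(
    list(dataset = "overall",
         region = paste(unique(vapply(pools_list, `[[`, character(1),
                                      "region")), collapse = "+"),
         model = models, partition_name = "overall",
         intra = unlist(lapply(pools_list, `[[`, "intra"), use.names = FALSE),
         inter = unlist(lapply(pools_list, `[[`, "inter"), use.names = FALSE),
         n_undefined_excluded = sum(vapply(pools_list, `[[`, integer(1),
                                           "n_undefined_excluded")),
         n_seq = sum(vapply(pools_list, `[[`, integer(1), "n_seq")),
         n_taxa = sum(vapply(pools_list, `[[`, integer(1), "n_taxa"))),
    class = "distance_pools"
  )
}

#' Export pools in long format
#'
#' One CSV row per pairwise distance:
#' `dataset,region,model,partition,type,distance` with `type` in
#' `{intra, inter}`.
#'
#' @param pools a [split_pools()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pools_long <- function(pools, path) {
  stopifnot(inherits(pools, "distance_pools"))
  df <- data.frame(
    dataset = pools$dataset, region = pools$region, model = pools$model,
    partition = pools$partition_name,
    type = rep(c("intra", "inter"),
               c(length(pools$intra), length(pools$inter))),
    distance = c(pools$intra, pools$inter), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
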