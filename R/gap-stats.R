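#' Sample quantile of a distance pool
#'
#' Type-7 quantile (linear interpolation of order statistics,
#' `h = (n - 1) p + 1`), the convention used throughout the gap analysis.
#' Thin wrapper over [stats::quantile()].
#'
#' @param values non-empty numeric vector.
#' @param p probability in `[0, 1]` (vectorised).
#' @return Numeric vector of quantiles, unnamed.
#' @export
pool_quantile <- function(values, p) {
  if (length(values) == 0L) stop("cannot take quantiles of an empty pool")
  if (anyNA(values)) stop("pool contains NA")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Summary statistics of a distance pool
#'
#' Count, mean, median, sample variance (n - 1 denominator; defined as 0
#' for a single value, with a warning) and a grid of type-7 quantiles.
#'
#' @param values non-empty numeric vector of pairwise distances.
#' @param probs quantile grid; the default brackets the stress-test levels.
#' @return A list of class `pool_summary` with `n`, `mean`, `median`,
#'   `variance` and named `quantiles`.
#' @export
summarize_pool <- function(values,
                           probs = c(0.05, 0.075, 0.10, 0.15,
                                     0.85, 0.90, 0.925, 0.95)) {
  if (length(values) == 0L)
    stop("cannot summarise an empty pool")
  if (anyNA(values)) stop("pool contains NA")
  v <- if (length(values) == 1L) {
    warning("pool of size 1: variance reported as 0")
    0
  } else stats::var(values)
  structure(
    list(n = length(values), mean = mean(values),
         median = stats::median(values), variance = v,
         quantiles = stats::setNames(pool_quantile(values, probs),
                                     format(probs, trim = TRUE))),
    class = "pool_summary"
  )
}

#' @export
print.pool_summary <- function(x, digits = 4, ...) {
  cat("n = ", x$n, ", mean = ", signif(x$mean, digits),
      ", median = ", signif(x$median, digits),
      ", variance = ", signif(x$variance, digits), "\n", sep = "")
  print(signif(x$quantiles, digits))
  invisible(x)
}

#' Barcode-gap stress test
#'
#' Assesses the barcode gap at progressively tighter quantile levels. At
#' level `p` the upper `p`-quantile of the intra-specific pool is
#' subtracted from the lower `(1 - p)`-quantile of the inter-specific pool:
#' a positive difference is the size of the gap between the two
#' distributions once their outlying tails are dropped, a negative one
#' means the distributions overlap at that level. With
#' `two_sided = TRUE` the tails are taken symmetrically around each
#' distribution instead (intra at `(1 + p) / 2`, inter at `(1 - p) / 2`).
#'
#' @param pools a [split_pools()] result with non-empty intra and inter
#'   pools.
#' @param levels quantile levels in `(0.5, 1)`; default `0.85, 0.90, 0.95`.
#' @param two_sided use central two-sided intervals (default `FALSE`).
#' @return A data frame of class `gap_assessment` with one row per level:
#'   `level`, `intra_upper`, `inter_lower`, `gap_size`
#'   (`inter_lower - intra_upper`), `present` (`gap_size > 0`) and
#'   `midpoint` (`(intra_upper + inter_lower) / 2`).
#' @export
stress_test <- function(pools, levels = c(0.85, 0.90, 0.95),
                        two_sided = FALSE) {
  stopifnot(inherits(pools, "distance_pools"))
  if (length(pools$intra) == 0L)
    stop("empty intra-specific pool (", pools$dataset, "/", pools$region,
         "): no conspecific pairs with defined distances")
  if (length(pools$inter) == 0L)
    stop("empty inter-specific pool (", pools$dataset, "/", pools$region, ")")
  if (any(levels <= 0.5 | levels >= 1))
    stop("stress-test levels must lie in (0.5, 1)")
  p_intra <- if (two_sided) (1 + levels) / 2 else levels
  p_inter <- if (two_sided) (1 - levels) / 2 else 1 - levels
  iu <- pool_quantile(pools$intra, p_intra)
  il <- pool_quantile(pools$inter, p_inter)
  out <- data.frame(
    level = levels, intra_upper = iu, inter_lower = il,
    gap_size = il - iu, present = (il - iu) > 0,
    midpoint = (iu + il) / 2
  )
  attr(out, "dataset") <- pools$dataset
  attr(out, "region") <- pools$region
  attr(out, "model") <- pools$model
  attr(out, "partition") <- pools$partition_name
  class(out) <- c("gap_assessment", "data.frame")
  out
}

#' Midpoint of the barcode gap
#'
#' The centre of the proposed gap, `(intra_upper + inter_lower) / 2`,
#' computed whether or not the gap is present; at the 95% level on raw
#' distances this is the candidate clustering cutoff for the dataset.
#'
#' @param assessment a [stress_test()] result (any subset of its rows).
#' @return Numeric vector of midpoints, one per row.
#' @export
gap_midpoint <- function(assessment) {
  stopifnot(is.data.frame(assessment),
            all(c("intra_upper", "inter_lower") %in% names(assessment)))
  (assessment$intra_upper + assessment$inter_lower) / 2
}
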