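#' Stress-test report across datasets and regions
#'
#' Assembles the per-dataset stress-test results of several
#' [barcode_gap()] fits into one wide table: one row per dataset x
#' partition, with `Gap?`/`Size` column pairs for every region x level,
#' plus a footer giving, per region x level, the count of detected gaps and
#' the average gap size among the detected ones only.
#'
#' @param fits list of [barcode_gap()] objects (one per dataset x region,
#'   same levels and model throughout).
#' @return An object of class `stress_report`: list with data frames
#'   `body` (columns `name`, `ntaxa`, `nseq`, then
#'   `gap_<region>_<level>` / `size_<region>_<level>`) and `footer`
#'   (`region`, `level`, `count`, `ave_size`).
#' @export
stress_report <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "barcode_gap")))
  levels <- fits[[1L]]$levels
  for (f in fits)
    if (!identical(f$levels, levels))
      stop("all fits must use the same stress-test levels")
  keys <- vapply(fits, function(f)
    paste0(f$pools$dataset, "\r", f$pools$partition_name), character(1))
  regions <- unique(vapply(fits, function(f) f$pools$region, character(1)))
  rows <- unique(keys)
  body <- data.frame(
    name = vapply(strsplit(rows, "\r", fixed = TRUE), function(k)
      if (k[2L] == "default") k[1L] else paste0(k[1L], " (", k[2L], ")"),
      character(1)),
    ntaxa = NA_integer_, nseq = NA_integer_,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (rg in regions) for (lv in levels) {
    body[[gap_col(rg, lv)]] <- NA
    body[[size_col(rg, lv)]] <- NA_real_
  }
  for (f in fits) {
    i <- match(paste0(f$pools$dataset, "\r", f$pools$partition_name), rows)
    body$ntaxa[i] <- f$pools$n_taxa
    body$nseq[i] <- f$pools$n_seq
    a <- f$assessment
    for (j in seq_len(nrow(a))) {
      body[[gap_col(f$pools$region, a$level[j])]][i] <- a$present[j]
      body[[size_col(f$pools$region, a$level[j])]][i] <- a$gap_size[j]
    }
  }
  footer <- do.call(rbind, lapply(regions, function(rg)
    do.call(rbind, lapply(levels, function(lv) {
      g <- body[[gap_col(rg, lv)]]; s <- body[[size_col(rg, lv)]]
      hit <- !is.na(g) & g
      data.frame(region = rg, level = lv, count = sum(hit),
                 ave_size = if (any(hit)) mean(s[hit]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))))
  structure(list(body = body, footer = footer, levels = levels,
                 regions = regions),
            class = "stress_report")
}

gap_col <- function(region, level) paste0("gap_", region, "_", level * 100)
size_col <- function(region, level) paste0("size_", region, "_", level * 100)

#' @export
print.stress_report <- function(x, ...) {
  cat("Barcode-gap stress test:", nrow(x$body), "dataset row(s),",
      length(x$regions), "region(s), levels",
      paste(x$levels, collapse = "/"), "\n")
  b <- x$body
  num <- vapply(b, is.numeric, logical(1)) & names(b) != "ntaxa" &
    names(b) != "nseq"
  b[num] <- lapply(b[num], round, 4)
  print(b, row.names = FALSE)
  cat("\nGaps detected (count / average size among detected):\n")
  f <- x$footer
  f$ave_size <- round(f$ave_size, 4)
  print(f, row.names = FALSE)
  invisible(x)
}

#' Gap-midpoint cutoff report
#'
#' Per dataset and region, gap presence and the gap midpoint (candidate
#' clustering cutoff) at a single quantile level, expressed in percent.
#' Typically run on raw-distance fits at the 95% level. The footer counts
#' the datasets with a gap and gives the range of midpoints among them.
#'
#' @param fits list of [barcode_gap()] objects whose levels include
#'   `level`.
#' @param level the quantile level to report (default 0.95).
#' @return An object of class `cutoff_report`: list with `body` (columns
#'   `name`, then `gap_<region>` / `midpoint_pct_<region>`) and `footer`
#'   (`region`, `count`, `max_pct`, `min_pct`, ranges over gap-present
#'   rows).
#' @export
cutoff_report <- function(fits, level = 0.95) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "barcode_gap")))
  keys <- vapply(fits, function(f)
    paste0(f$pools$dataset, "\r", f$pools$partition_name), character(1))
  regions <- unique(vapply(fits, function(f) f$pools$region, character(1)))
  rows <- unique(keys)
  body <- data.frame(
    name = vapply(strsplit(rows, "\r", fixed = TRUE), function(k)
      if (k[2L] == "default") k[1L] else paste0(k[1L], " (", k[2L], ")"),
      character(1)),
    stringsAsFactors = FALSE
  )
  for (rg in regions) {
    body[[paste0("gap_", rg)]] <- NA
    body[[paste0("midpoint_pct_", rg)]] <- NA_real_
  }
  for (f in fits) {
    i <- match(paste0(f$pools$dataset, "\r", f$pools$partition_name), rows)
    a <- f$assessment
    j <- which(abs(a$level - level) < 1e-9)
    if (length(j) != 1L)
      stop("fit for ", f$pools$dataset, "/", f$pools$region,
           " has no assessment at level ", level)
    body[[paste0("gap_", f$pools$region)]][i] <- a$present[j]
    body[[paste0("midpoint_pct_", f$pools$region)]][i] <- a$midpoint[j] * 100
  }
  footer <- do.call(rbind, lapply(regions, function(rg) {
    g <- body[[paste0("gap_", rg)]]
    m <- body[[paste0("midpoint_pct_", rg)]]
    hit <- !is.na(g) & g
    data.frame(region = rg, count = sum(hit),
               max_pct = if (any(hit)) max(m[hit]) else NA_real_,
               min_pct = if (any(hit)) min(m[hit]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(body = body, footer = footer, level = level),
            class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat("Gap midpoints at the ", x$level * 100, "% level (percent):\n", sep = "")
  b <- x$body
  num <- vapply(b, is.numeric, logical(1))
  b[num] <- lapply(b[num], round, 1)
  print(b, row.names = FALSE)
  print(x$footer, row.names = FALSE)
  invisible(x)
}

#' Per-pool summary table
#'
#' One row per fitted pool (intra and inter of every fit): counts, mean,
#' median, variance and the quantile grid of [summarize_pool()].
#'
#' @param fits list of [barcode_gap()] objects.
#' @return A data frame.
#' @export
pool_summary_table <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1), "barcode_gap")))
  do.call(rbind, lapply(fits, function(f) {
    do.call(rbind, lapply(c("intra", "inter"), function(type) {
      s <- f[[paste0(type, "_summary")]]
      cbind(
        data.frame(dataset = f$pools$dataset, region = f$pools$region,
                   model = f$model, partition = f$pools$partition_name,
                   type = type, n = s$n, mean = s$mean, median = s$median,
                   variance = s$variance, stringsAsFactors = FALSE),
        as.data.frame(as.list(stats::setNames(
          s$quantiles, paste0("q", names(s$quantiles))))))
    }))
  }))
}

#' Write report tables to CSV
#'
#' `write_stress_csv()` writes the stress-test body with the footer
#' appended as `Count` / `AVE` rows; `write_cutoff_csv()` likewise for the
#' midpoint table. Sizes and midpoints are rounded to 4 decimals, so a tiny
#' positive gap may display as 0.0000 while still counting as present.
#'
#' @param report a [stress_report()] or [cutoff_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stress_csv <- function(report, path) {
  stopifnot(inherits(report, "stress_report"))
  b <- report$body
  sz <- grep("^size_", names(b))
  b[sz] <- lapply(b[sz], function(v) ifelse(is.na(v), "", sprintf("%.4f", v)))
  count <- b[1L, ]; count[] <- ""
  ave <- count
  count$name <- "Count"; ave$name <- "AVE"
  for (i in seq_len(nrow(report$footer))) {
    fr <- report$footer[i, ]
    count[[gap_col(fr$region, fr$level)]] <- as.character(fr$count)
    ave[[gap_col(fr$region, fr$level)]] <-
      if (is.na(fr$ave_size)) "" else sprintf("%.4f", fr$ave_size)
  }
  out <- rbind(data.frame(lapply(b, as.character), stringsAsFactors = FALSE),
               data.frame(lapply(count, as.character), stringsAsFactors = FALSE),
               data.frame(lapply(ave, as.character), stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stress_csv
#' @export
write_cutoff_csv <- function(report, path) {
  stopifnot(inherits(report, "cutoff_report"))
  b <- report$body
  mp <- grep("^midpoint_", names(b))
  b[mp] <- lapply(b[mp], function(v) ifelse(is.na(v), "", sprintf("%.1f", v)))
  extra <- b[rep(1L, 3L), ]; extra[] <- ""
  extra$name <- c("Count", "Max", "Min")
  for (i in seq_len(nrow(report$footer))) {
    fr <- report$footer[i, ]
    extra[1L, paste0("gap_", fr$region)] <- as.character(fr$count)
    if (!is.na(fr$max_pct)) {
      extra[2L, paste0("midpoint_pct_", fr$region)] <- sprintf("%.1f", fr$max_pct)
      extra[3L, paste0("midpoint_pct_", fr$region)] <- sprintf("%.1f", fr$min_pct)
    }
  }
  out <- rbind(data.frame(lapply(b, as.character), stringsAsFactors = FALSE),
               data.frame(lapply(extra, as.character), stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
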