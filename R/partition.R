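#' Species partition
#'
#' Maps every sequence id of an alignment to a species label. Alternative
#' partitions of the same sequences (e.g. "lumping" vs "splitting"
#' taxonomies) are represented as separate named partitions.
#'
#' @param ids character vector of sequence ids.
#' @param labels character vector of species labels, same length as `ids`.
#' @param name partition name (e.g. `"default"`, `"lumping"`, `"splitting"`).
#' @return An object of class `species_partition`: list with `name` and
#'   `assignments` (named character vector, id -> label).
#' @export
species_partition <- function(ids, labels, name = "default") {
  ids <- as.character(ids); labels <- as.character(labels)
  if (length(ids) != length(labels))
    stop("'ids' and 'labels' must have the same length")
  if (length(ids) < 1L) stop("a partition needs at least one id")
  if (anyDuplicated(ids))
    stop("duplicate ids in partition: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(is.na(labels) | labels == ""))
    stop("empty or missing species labels")
  structure(list(name = name, assignments = stats::setNames(labels, ids)),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat("Species partition '", x$name, "': ", length(x$assignments),
      " sequences, ", length(unique(x$assignments)), " species\n", sep = "")
  invisible(x)
}

#' Read a species map from a two-column delimited file
#'
#' The file holds one `id<delim>species` pair per line; lines starting with
#' `#` and blank lines are ignored. Every id of `alignment` must be labelled;
#' map entries for ids absent from the alignment are dropped with a warning.
#'
#' @param path path to the species map file.
#' @param alignment the companion [aligned_seqs()] object.
#' @param delim field delimiter (default tab).
#' @param name partition name.
#' @return A [species_partition()] covering exactly the alignment ids, in
#'   alignment order.
#' @export
read_partition <- function(path, alignment, delim = "\t", name = "default") {
  stopifnot(inherits(alignment, "aligned_seqs"))
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = delim, header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("id", "species"),
                           colClasses = "character", quote = "")
  if (anyDuplicated(tab$id))
    stop("duplicate ids in species map: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  map <- stats::setNames(tab$species, tab$id)
  missing <- setdiff(alignment$ids, names(map))
  if (length(missing))
    stop("no species label for id(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(map), alignment$ids)
  if (length(extra))
    warning(length(extra), " species-map entr",
            if (length(extra) == 1L) "y" else "ies",
            " not present in the alignment ignored")
  species_partition(alignment$ids, unname(map[alignment$ids]), name = name)
}

#' Derive a species partition from FASTA header tokens
#'
#' Fallback for alignments whose headers encode the species, e.g.
#' `Russula_magnarosea|XYZ123` split on `"|"` with `field = 1`.
#'
#' @param alignment an [aligned_seqs()] object.
#' @param sep separator to split each id on (fixed string).
#' @param field 1-based index of the token holding the species label.
#' @param name partition name.
#' @return A [species_partition()].
#' @export
partition_from_headers <- function(alignment, sep = "|", field = 1L,
                                   name = "default") {
  stopifnot(inherits(alignment, "aligned_seqs"))
  parts <- strsplit(alignment$ids, sep, fixed = TRUE)
  labels <- vapply(parts, function(p) {
    if (length(p) < field) stop("id has fewer than ", field, " '", sep,
                                "'-separated fields")
    p[[field]]
  }, character(1))
  species_partition(alignment$ids, labels, name = name)
}

#' Merge or rename species labels ("lumping"/"splitting")
#'
#' Applies a label map to produce an alternative partition of the same
#' sequences. A many-to-one map lumps species; an identity-augmented map can
#' rename a subset.
#'
#' @param partition a [species_partition()].
#' @param merge_map named character vector, old label -> new label.
#' @param name name of the resulting partition.
#' @param allow_identity if `TRUE` (default) labels absent from `merge_map`
#'   are kept unchanged; if `FALSE` every observed label must be mapped.
#' @return A new [species_partition()].
#' @export
relabel <- function(partition, merge_map, name, allow_identity = TRUE) {
  stopifnot(inherits(partition, "species_partition"))
  old <- partition$assignments
  unmapped <- setdiff(unique(old), names(merge_map))
  if (length(unmapped) && !allow_identity)
    stop("labels without a mapping: ", paste(unmapped, collapse = ", "))
  full <- c(merge_map, stats::setNames(unmapped, unmapped))
  species_partition(names(old), unname(full[old]), name = name)
}
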