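#' Aligned sequence set
#'
#' Container for one aligned nucleotide matrix (one dataset, one barcode
#' region). Rows are stored as upper-case character strings of identical
#' length over the alphabet `A C G T N -` plus IUPAC ambiguity codes;
#' during construction `U` is normalised to `T`, `?` to `N` and `.` to `-`.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned rows, same length as `ids`.
#' @param dataset_name name of the dataset (typically a genus).
#' @param region one of `"nrITS"`, `"ITS1"`, `"ITS2"`, `"custom"`.
#' @return An object of class `aligned_seqs`: a list with elements `ids`,
#'   `seqs`, `dataset`, `region` and `width` (number of alignment columns).
#' @examples
#' aln <- aligned_seqs(c("a", "b"), c("ACGT", "AC-T"), "toy", "custom")
#' aln$width
#' @export
aligned_seqs <- function(ids, seqs, dataset_name = "dataset",
                         region = c("nrITS", "ITS1", "ITS2", "custom")) {
  region <- match.arg(region)
  ids <- as.character(ids)
  seqs <- normalize_sequences(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("'ids' and 'seqs' must have the same length")
  if (length(ids) < 1L)
    stop("an alignment needs at least one sequence")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- nchar(seqs)
  if (any(w != w[1L])) {
    bad <- ids[which(w != w[1L])[1L]]
    stop("unequal aligned lengths: sequence '", bad, "' has ", w[w != w[1L]][1L],
         " columns, expected ", w[1L])
  }
  if (w[1L] < 1L)
    stop("alignment must have at least one column")
  structure(
    list(ids = ids, seqs = seqs, dataset = dataset_name,
         region = region, width = w[1L]),
    class = "aligned_seqs"
  )
}

# Upper-case, U->T, ?->N, .->- : one normalisation used everywhere.
normalize_sequences <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  x <- gsub("?", "N", x, fixed = TRUE)
  gsub(".", "-", x, fixed = TRUE)
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("Aligned sequence set '", x$dataset, "' [", x$region, "]\n", sep = "")
  cat("  ", length(x$ids), " sequences x ", x$width, " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA file as an aligned matrix and validates it:
#' all rows must have identical length and ids must be unique. Sequences are
#' normalised (upper case, `U`->`T`, `?`->`N`, `.`->`-`).
#'
#' @param path path to a FASTA file with at least one record.
#' @param dataset_name dataset label attached to the result.
#' @param region region tag, see [aligned_seqs()].
#' @return An [aligned_seqs()] object.
#' @export
read_alignment <- function(path, dataset_name = basename(path),
                           region = c("nrITS", "ITS1", "ITS2", "custom")) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  aligned_seqs(names(recs), vapply(recs, as.character, character(1)),
               dataset_name = dataset_name, region = region)
}

#' Write an aligned sequence set to FASTA
#'
#' @param x an [aligned_seqs()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "aligned_seqs"))
  seqinr::write.fasta(as.list(x$seqs), names = x$ids, file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Region column coordinates
#'
#' Column intervals of the ITS1, 5.8S and ITS2 sub-regions within a full
#' nrITS alignment. Coordinates are 0-based and half-open (`[start, end)`),
#' must be in order, non-overlapping and within the alignment width when
#' applied.
#'
#' @param its1,r58s,its2 integer vectors `c(start, end)`.
#' @return An object of class `region_coords`.
#' @export
region_coords <- function(its1, r58s, its2) {
  iv <- list(its1 = as.integer(its1), r58s = as.integer(r58s),
             its2 = as.integer(its2))
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2L || v[1L] < 0L || v[2L] < v[1L])
      stop("invalid interval for ", nm, ": need 0-based half-open c(start, end)")
  }
  if (iv$its1[2L] > iv$r58s[1L] || iv$r58s[2L] > iv$its2[1L])
    stop("region intervals must be ordered ITS1 < 5.8S < ITS2 and non-overlapping")
  structure(iv, class = "region_coords")
}

#' Extract a sub-region from an alignment
#'
#' Slices the columns of a full nrITS alignment belonging to one sub-region.
#'
#' @param alignment an [aligned_seqs()] object.
#' @param coords a [region_coords()] object.
#' @param which one of `"its1"`, `"r58s"`, `"its2"`.
#' @return An [aligned_seqs()] object covering the requested columns, tagged
#'   with the matching region (`5.8S` slices are tagged `"custom"`).
#' @export
slice_region <- function(alignment, coords, which = c("its1", "r58s", "its2")) {
  stopifnot(inherits(alignment, "aligned_seqs"), inherits(coords, "region_coords"))
  which <- match.arg(which)
  iv <- coords[[which]]
  if (iv[2L] > alignment$width)
    stop("interval [", iv[1L], ",", iv[2L], ") out of bounds for width ",
         alignment$width)
  if (iv[2L] == iv[1L]) stop("empty interval for ", which)
  rows <- substr(alignment$seqs, iv[1L] + 1L, iv[2L])
  tag <- switch(which, its1 = "ITS1", its2 = "ITS2", r58s = "custom")
  aligned_seqs(alignment$ids, rows, dataset_name = alignment$dataset,
               region = tag)
}
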