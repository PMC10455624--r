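#' Configuration for the synthetic ITS-alignment generator
#'
#' Describes a multi-species barcode dataset with controlled divergences.
#' Individuals sit on a species tree (star by default) whose stem branches
#' have length `inter_divergence` and whose terminal individual branches
#' have length `intra_divergence`, both in expected substitutions/site at
#' region rate 1. Two conspecific sequences therefore diverge by
#' `2 * intra_divergence` in expectation, and two sequences from different
#' species by `2 * (inter_divergence + intra_divergence)` (star tree),
#' scaled by the per-region rate multiplier.
#'
#' The three regions emulate the structure of the fungal nrITS barcode:
#' a fast ITS1, a nearly frozen 5.8S and an intermediate ITS2.
#'
#' @param n_species number of species (>= 2).
#' @param seqs_per_species integer or per-species integer vector (allows
#'   singletons).
#' @param region_lengths named integer vector `c(its1=, r58s=, its2=)` of
#'   region widths in columns.
#' @param region_rates named numeric vector of relative rate multipliers,
#'   default `its1 = 1.5, r58s = 0.1, its2 = 1.0`.
#' @param inter_divergence species stem branch length
#'   (substitutions/site).
#' @param intra_divergence individual terminal branch length.
#' @param kappa transition/transversion rate ratio of the K80 mutation
#'   process (>= 0; `kappa = 2` gives the classic transition bias).
#' @param gap_fraction probability that a column of a sequence is masked to
#'   `-` (in `[0, 0.5)`).
#' @param terminal_gaps mask a contiguous prefix/suffix instead of random
#'   columns, emulating ragged sequence ends (default `FALSE`).
#' @param tree_shape `"star"` (i.i.d. species ancestors; analytic expected
#'   pool means) or `"coalescent"` (random ultrametric species tree rescaled
#'   to depth `inter_divergence`).
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_species = 10L, seqs_per_species = 5L,
                       region_lengths = c(its1 = 220L, r58s = 160L,
                                          its2 = 220L),
                       region_rates = c(its1 = 1.5, r58s = 0.1, its2 = 1.0),
                       inter_divergence = 0.04, intra_divergence = 0.005,
                       kappa = 2, gap_fraction = 0.02,
                       terminal_gaps = FALSE,
                       tree_shape = c("star", "coalescent"), seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  n_species <- as.integer(n_species)
  if (n_species < 2L) stop("need at least 2 species")
  nseq <- as.integer(rep_len(seqs_per_species, n_species))
  if (any(nseq < 1L)) stop("each species needs at least one sequence")
  rl <- region_lengths[c("its1", "r58s", "its2")]
  rr <- region_rates[c("its1", "r58s", "its2")]
  if (anyNA(rl) || any(rl <= 0L)) stop("region lengths must be positive")
  if (anyNA(rr) || any(rr < 0)) stop("region rates must be non-negative")
  if (kappa < 0) stop("kappa must be >= 0")
  if (gap_fraction < 0 || gap_fraction >= 0.5)
    stop("gap_fraction must lie in [0, 0.5)")
  if (inter_divergence < 0 || intra_divergence < 0)
    stop("divergences must be non-negative")
  if (intra_divergence >= inter_divergence && inter_divergence > 0)
    warning("intra_divergence >= inter_divergence: species will not separate")
  structure(
    list(n_species = n_species, seqs_per_species = nseq,
         region_lengths = stats::setNames(as.integer(rl),
                                          c("its1", "r58s", "its2")),
         region_rates = stats::setNames(as.numeric(rr),
                                        c("its1", "r58s", "its2")),
         inter_divergence = inter_divergence,
         intra_divergence = intra_divergence, kappa = kappa,
         gap_fraction = gap_fraction, terminal_gaps = terminal_gaps,
         tree_shape = tree_shape, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", x$n_species, " species, ",
      sum(x$seqs_per_species), " sequences, ",
      sum(x$region_lengths), " columns (",
      paste(names(x$region_lengths), x$region_lengths, sep = "=",
            collapse = ", "), ")\n", sep = "")
  cat("  stem ", x$inter_divergence, ", tip ", x$intra_divergence,
      ", kappa ", x$kappa, ", gaps ", x$gap_fraction,
      ", ", x$tree_shape, " tree, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# K80 transition probabilities after time t (total rate 1 sub/site):
# returns c(stay, transition, each-transversion).
k80_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(stay = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)
}

# Evolve an integer-coded sequence (A=1 C=2 G=3 T=4) for time t under K80.
mutate_k80 <- function(seq_int, t, kappa) {
  if (t <= 0) return(seq_int)
  p <- k80_probs(t, kappa)
  u <- stats::runif(length(seq_int))
  out <- seq_int
  ts_partner <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)                 # first transversion target
  tv2 <- c(4L, 3L, 4L, 3L)                 # second transversion target
  hit_ts <- u >= p[1L] & u < p[1L] + p[2L]
  hit_tv1 <- u >= p[1L] + p[2L] & u < p[1L] + p[2L] + p[3L]
  hit_tv2 <- u >= p[1L] + p[2L] + p[3L]
  out[hit_ts] <- ts_partner[seq_int[hit_ts]]
  out[hit_tv1] <- tv1[seq_int[hit_tv1]]
  out[hit_tv2] <- tv2[seq_int[hit_tv2]]
  out
}

# Full individual-level tree implied by the config (tips spXX_Y).
build_true_tree <- function(config) {
  sp <- sprintf("sp%02d", seq_len(config$n_species))
  tip_sets <- lapply(seq_len(config$n_species), function(i)
    sprintf("%s_%d", sp[i], seq_len(config$seqs_per_species[i])))
  ti <- config$intra_divergence
  stem <- config$inter_divergence
  if (config$tree_shape == "star") {
    clades <- vapply(seq_len(config$n_species), function(i) {
      tips <- tip_sets[[i]]
      if (length(tips) == 1L)
        sprintf("%s:%.10f", tips, stem + ti)
      else
        sprintf("(%s):%.10f",
                paste(sprintf("%s:%.10f", tips, ti), collapse = ","), stem)
    }, character(1))
    tree <- ape::read.tree(text = paste0("(", paste(clades, collapse = ","),
                                         ");"))
  } else {
    sp_tree <- ape::rcoal(config$n_species, tip.label = sp)
    depth <- max(ape::node.depth.edgelength(sp_tree))
    sp_tree$edge.length <- sp_tree$edge.length * (stem / depth)
    txt <- ape::write.tree(sp_tree)
    for (i in seq_len(config$n_species)) {
      tips <- tip_sets[[i]]
      if (length(tips) == 1L) {
        txt <- gsub(paste0("([(,])", sp[i], ":"),
                    paste0("\\1", tips, ":"), txt)
      } else {
        inner <- paste(sprintf("%s:%.10f", tips, ti), collapse = ",")
        txt <- gsub(paste0("([(,])", sp[i], ":"),
                    paste0("\\1(", inner, "):"), txt)
      }
    }
    tree <- ape::read.tree(text = txt)
    # singletons grafted without the individual branch: extend their edge
    for (i in which(config$seqs_per_species == 1L)) {
      k <- match(tip_sets[[i]], tree$tip.label)
      tree$edge.length[tree$edge[, 2L] == k] <-
        tree$edge.length[tree$edge[, 2L] == k] + ti
    }
  }
  tree
}

#' Simulate a synthetic multi-species barcode dataset
#'
#' Draws a uniform root sequence, evolves it along the individual-level
#' tree under a K80 substitution process (exact transition-probability
#' sampling per branch) with per-region rate scaling, masks gap columns,
#' and returns the per-region alignments, their nrITS concatenation, the
#' true species partition and the true tree. Deterministic for a fixed
#' seed.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_dataset`: list with `alignments`
#'   (named list `nrITS`, `ITS1`, `r58s`, `ITS2` of [aligned_seqs()]),
#'   `partition` ([species_partition()]), `tree` (`phylo`), `coords`
#'   ([region_coords()]) and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_species = 3, seqs_per_species = 2,
#'                                    seed = 7))
#' sim$alignments$nrITS
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- build_true_tree(config)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode + n_tip
  edges <- ape::reorder.phylo(tree, "cladewise")   # parent precedes child
  widths <- config$region_lengths
  tip_mat <- matrix(0L, n_tip, sum(widths))
  offset <- 0L
  for (r in c("its1", "r58s", "its2")) {
    L <- widths[[r]]
    rate <- config$region_rates[[r]]
    states <- vector("list", n_node)
    root <- n_tip + 1L
    states[[root]] <- sample.int(4L, L, replace = TRUE)
    for (e in seq_len(nrow(edges$edge))) {
      par <- edges$edge[e, 1L]; chl <- edges$edge[e, 2L]
      states[[chl]] <- mutate_k80(states[[par]],
                                  edges$edge.length[e] * rate, config$kappa)
    }
    for (k in seq_len(n_tip))
      tip_mat[k, offset + seq_len(L)] <- states[[k]]
    offset <- offset + L
  }
  # gap masking on the concatenated matrix, per sequence
  W <- sum(widths)
  chars <- matrix(c("A", "C", "G", "T")[tip_mat], n_tip, W)
  if (config$gap_fraction > 0) {
    for (k in seq_len(n_tip)) {
      if (config$terminal_gaps) {
        total <- stats::rbinom(1L, W, config$gap_fraction)
        pre <- if (total > 0L) sample.int(total + 1L, 1L) - 1L else 0L
        idx <- c(seq_len(pre), if (total - pre > 0L) (W - (total - pre) + 1L):W)
      } else {
        idx <- which(stats::runif(W) < config$gap_fraction)
      }
      if (length(idx)) chars[k, idx] <- "-"
    }
  }
  rows <- apply(chars, 1L, paste, collapse = "")
  ids <- tree$tip.label
  coords <- region_coords(
    its1 = c(0L, widths[["its1"]]),
    r58s = c(widths[["its1"]], widths[["its1"]] + widths[["r58s"]]),
    its2 = c(widths[["its1"]] + widths[["r58s"]], W))
  nrits <- aligned_seqs(ids, rows, dataset_name = "synthetic",
                        region = "nrITS")
  partition <- species_partition(ids, sub("_[0-9]+$", "", ids),
                                 name = "true")
  structure(
    list(alignments = list(
           nrITS = nrits,
           ITS1 = slice_region(nrits, coords, "its1"),
           r58s = slice_region(nrits, coords, "r58s"),
           ITS2 = slice_region(nrits, coords, "its2")),
         partition = partition, tree = tree, coords = coords,
         config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic barcode dataset (seed ", x$config$seed, "):\n", sep = "")
  print(x$alignments$nrITS)
  print(x$partition)
  invisible(x)
}

#' Analytic expected pool means of a simulation config
#'
#' Expected K80 distances implied by path lengths on the (star) true tree:
#' two conspecific individuals are separated by twice the individual branch
#' and two heterospecific individuals additionally by both species stems,
#' scaled by the per-region rate (nrITS uses the length-weighted mean
#' rate). Used as the oracle in parameter-recovery checks.
#'
#' @param config a [sim_config()].
#' @return List with named numeric vectors `intra` and `inter` (elements
#'   `nrITS`, `ITS1`, `r58s`, `ITS2`).
#' @export
expected_pool_means <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rates <- c(
    nrITS = sum(config$region_rates * config$region_lengths) /
      sum(config$region_lengths),
    ITS1 = config$region_rates[["its1"]],
    r58s = config$region_rates[["r58s"]],
    ITS2 = config$region_rates[["its2"]])
  list(intra = 2 * config$intra_divergence * rates,
       inter = 2 * (config$inter_divergence + config$intra_divergence) * rates)
}

#' Write a simulated dataset bundle to disk
#'
#' Emits the four aligned FASTA files, the species map TSV, the true tree
#' in newick format and a YAML metadata file echoing the configuration
#' (including the seed).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    nrITS = file.path(dir, "nrITS.fasta"),
    ITS1 = file.path(dir, "ITS1.fasta"),
    r58s = file.path(dir, "r58s.fasta"),
    ITS2 = file.path(dir, "ITS2.fasta"),
    species_map = file.path(dir, "species_map.tsv"),
    tree = file.path(dir, "true_tree.nwk"),
    metadata = file.path(dir, "metadata.yml"))
  for (r in c("nrITS", "ITS1", "r58s", "ITS2"))
    write_alignment(sim$alignments[[r]], paths[[r]])
  utils::write.table(
    data.frame(id = names(sim$partition$assignments),
               species = unname(sim$partition$assignments)),
    paths[["species_map"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ape::write.tree(sim$tree, paths[["tree"]])
  yaml::write_yaml(unclass(sim$config), paths[["metadata"]])
  invisible(paths)
}
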