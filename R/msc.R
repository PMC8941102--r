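## Multispecies-coalescent simulation.

## Flatten a rooted species tree (coalescent units) into the arrays the
## C++ simulator consumes. Ages are heights above the deepest tip plane,
## so age(parent) - age(child) equals the branch length on every edge.
msc_prepare <- function(species_tree, n_alleles = NULL) {
  assert_phylo(species_tree, "species_tree")
  if (!ape::is.rooted(species_tree)) {
    stop_pc("species tree must be rooted", class = "pc_validation_error")
  }
  if (!identical(branch_units(species_tree), "coalescent")) {
    stop_pc("species tree branch lengths must be in coalescent units; ",
            "declare them with set_branch_units(tree, \"coalescent\")",
            class = "pc_units_error")
  }
  if (is.null(species_tree$edge.length)) {
    stop_pc("species tree has no branch lengths", class = "pc_missing_lengths")
  }
  ntip <- length(species_tree$tip.label)
  M <- ntip + species_tree$Nnode
  edge <- species_tree$edge
  len <- species_tree$edge.length
  parent <- rep(-1L, M)
  elen <- rep(NA_real_, M)
  parent[edge[, 2L]] <- edge[, 1L] - 1L
  elen[edge[, 2L]] <- len
  internal <- seq.int(ntip + 1L, M)
  bad <- internal[internal != ntip + 1L & (is.na(elen[internal]) | elen[internal] < 0)]
  if (length(bad) > 0L) {
    stop_pc("internal branches must have non-negative coalescent-unit lengths",
            class = "pc_missing_lengths")
  }
  alleles <- rep(1L, ntip)
  if (!is.null(n_alleles)) {
    idx <- match(names(n_alleles), species_tree$tip.label)
    if (anyNA(idx)) {
      stop_pc("n_alleles names must be tip labels", class = "pc_validation_error")
    }
    alleles[idx] <- as.integer(n_alleles)
    if (any(alleles < 1L)) {
      stop_pc("n_alleles must be >= 1", class = "pc_validation_error")
    }
    if (any(alleles > 1L & is.na(elen[seq_len(ntip)]))) {
      stop_pc("multi-allele sampling requires terminal branch lengths",
              class = "pc_missing_lengths")
    }
  }
  elen[is.na(elen)] <- 0
  ## depth from root, then flip to ages
  depth <- numeric(M)
  tr <- ape::reorder.phylo(species_tree, "postorder")
  for (e in rev(seq_len(nrow(tr$edge)))) {
    ch <- tr$edge[e, 2L]
    depth[ch] <- depth[tr$edge[e, 1L]] + elen[ch]
  }
  age <- max(depth) - depth
  ## node postorder: tips first (any order), then internal nodes in edge
  ## postorder, root last
  internal_post <- unique(tr$edge[tr$edge[, 2L] > ntip, 2L])
  porder <- c(seq_len(ntip), internal_post, ntip + 1L)
  sorted_taxa <- sort(species_tree$tip.label)
  tip_bit <- match(species_tree$tip.label, sorted_taxa) - 1L
  list(parent = parent, age = age, porder = porder - 1L,
       tip_bit = c(tip_bit, rep(-1L, species_tree$Nnode)),
       alleles = alleles, ntip = ntip, taxa = sorted_taxa,
       tip_age = age[seq_len(ntip)])
}

#' Probability that a gene tree is concordant at a species-tree branch
#'
#' For an internal species-tree branch of length `t` coalescent units, the
#' probability that the gene-tree quartet around it matches the species
#' tree is `1 - (2/3) exp(-t)`; each of the two discordant arrangements
#' has probability `(1/3) exp(-t)`.
#'
#' @param t branch length(s) in coalescent units, `>= 0`.
#' @return numeric vector of concordance probabilities in `[1/3, 1]`.
#' @export
concordance_prob <- function(t) {
  if (!is.numeric(t) || any(is.na(t)) || any(t < 0)) {
    stop_pc("t must be non-negative", class = "pc_validation_error")
  }
  1 - (2 / 3) * exp(-t)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Draws `n` gene trees from a rooted species tree whose internal branch
#' lengths are in coalescent units (one unit = 2N generations; k lineages
#' coalesce with total rate k(k-1)/2 per unit). One lineage is sampled per
#' species unless `n_alleles` says otherwise. Deterministic given `seed`.
#'
#' @param species_tree rooted `phylo` with `branch_units() == "coalescent"`.
#' @param n number of gene trees to simulate.
#' @param seed integer seed.
#' @param n_alleles optional named integer vector (tip label -> number of
#'   sampled lineages); multi-allele tips require terminal branch lengths.
#' @return a `gene_tree_sample`: list with `trees` (a `multiPhylo`, branch
#'   lengths in coalescent time), `coalescence_heights` (n x (L-1) matrix
#'   of node ages, last column the root age), `seed`, `source`, `taxa`.
#' @export
simulate_gene_trees <- function(species_tree, n, seed = NULL, n_alleles = NULL) {
  if (!is_count(n) || n < 1) {
    stop_pc("n must be a positive integer", class = "pc_validation_error")
  }
  prep <- msc_prepare(species_tree, n_alleles)
  res <- with_seed(seed, msc_simulate_cpp(
    prep$parent, prep$age, prep$porder, prep$tip_bit, prep$alleles,
    prep$ntip, as.integer(n), FALSE))
  L <- sum(prep$alleles)
  tip_labels <- character(L)
  tip_height <- numeric(L)
  pos <- 1L
  for (i in seq_len(prep$ntip)) {
    k <- prep$alleles[i]
    labs <- if (k == 1L) species_tree$tip.label[i] else
      paste0(species_tree$tip.label[i], "_", seq_len(k))
    tip_labels[pos:(pos + k - 1L)] <- labs
    tip_height[pos:(pos + k - 1L)] <- prep$tip_age[i]
    pos <- pos + k
  }
  trees <- vector("list", n)
  for (r in seq_len(n)) {
    trees[[r]] <- build_gene_phylo(res$joins[[r]], res$heights[r, ],
                                   tip_labels, tip_height)
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees,
                 coalescence_heights = res$heights,
                 seed = seed, source = "simulated", taxa = prep$taxa),
            class = "gene_tree_sample")
}

## Assemble a phylo from the simulator's join table. Internal join j
## (1-based, root created last) becomes ape node 2L - j, so the root lands
## on ntip + 1 as phylo requires.
build_gene_phylo <- function(joins, heights, tip_labels, tip_height) {
  L <- length(tip_labels)
  ni <- L - 1L
  gid2phylo <- function(id) ifelse(id <= L, id, 2L * L - (id - L))
  parent_col <- rep(2L * L - seq_len(ni), each = 2L)
  child_ids <- as.integer(t(joins))
  child_col <- gid2phylo(child_ids)
  child_height <- ifelse(child_ids <= L, tip_height[pmin(child_ids, L)],
                         heights[pmax(child_ids - L, 1L)])
  parent_height <- rep(heights, each = 2L)
  tr <- list(edge = cbind(parent_col, child_col, deparse.level = 0),
             edge.length = parent_height - child_height,
             tip.label = tip_labels,
             Nnode = ni)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "units") <- "coalescent"
  tr
}

#' Simulate gene trees and tabulate their unrooted topologies
#'
#' A fast path for large simulations: gene trees are drawn exactly as in
#' [simulate_gene_trees()] but only the canonical unrooted topology key of
#' each tree is retained and tabulated. Limited to 31 or fewer taxa with
#' one sampled lineage per species.
#'
#' @inheritParams simulate_gene_trees
#' @return a `topology_spectrum` (see [spectrum_of()]).
#' @export
simulate_topology_counts <- function(species_tree, n, seed = NULL) {
  if (!is_count(n) || n < 1) {
    stop_pc("n must be a positive integer", class = "pc_validation_error")
  }
  prep <- msc_prepare(species_tree)
  if (prep$ntip > 31L) {
    stop_pc("topology tabulation supports at most 31 taxa",
            class = "pc_validation_error")
  }
  res <- with_seed(seed, msc_simulate_cpp(
    prep$parent, prep$age, prep$porder, prep$tip_bit, prep$alleles,
    prep$ntip, as.integer(n), TRUE))
  tab <- table(res$keys)
  counts <- as.integer(tab)
  names(counts) <- mask_keys_to_label_keys(names(tab), prep$taxa)
  new_topology_spectrum(counts, prep$taxa)
}

## Convert the simulator's numeric-mask keys ("m1-m2-...") into the
## label-based canonical keys produced by topology_key().
mask_keys_to_label_keys <- function(mask_keys, sorted_taxa) {
  vapply(mask_keys, function(k) {
    if (!nzchar(k)) return("")
    masks <- as.numeric(strsplit(k, "-", fixed = TRUE)[[1]])
    sides <- vapply(masks, function(m) {
      bits <- which(bitwAnd(as.integer(m), bitwShiftL(1L, seq_along(sorted_taxa) - 1L)) != 0L)
      paste(sorted_taxa[bits], collapse = ",")
    }, character(1))
    paste(sort(sides), collapse = "|")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.gene_tree_sample <- function(x, ...) {
  cat("Gene-tree sample:", length(x$trees), "trees on",
      length(x$taxa), "taxa (", x$source, ")\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}
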