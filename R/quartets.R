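## Per-branch normalized quartet supports (q1, q2, q3).
##
## For an internal species-tree branch the four surrounding taxon clusters
## A, B | C, D define, for every quartet (a in A, b in B, c in C, d in D),
## three possible unrooted arrangements: ab|cd (the species-tree one, q1),
## ac|bd (q2) and ad|bc (q3). Every resolved quartet observation in every
## gene tree counts once (pooled counting); quartets left unresolved by a
## polytomy are skipped, and gene trees missing taxa contribute only the
## quartets they contain.

.pc_env <- new.env(parent = emptyenv())

popcount32 <- function(x) {
  if (is.null(.pc_env$lut)) {
    b <- 0:65535
    cnt <- integer(65536)
    for (s in 0:15) cnt <- cnt + bitwAnd(bitwShiftR(b, s), 1L)
    .pc_env$lut <- cnt
  }
  lut <- .pc_env$lut
  lut[bitwAnd(x, 65535L) + 1L] + lut[bitwShiftR(x, 16L) + 1L]
}

## Nontrivial split masks of a tree in the bit space of `sorted_taxa`
## (bit i-1 = sorted_taxa[i]); canonical side excludes bit 0. Also returns
## the presence mask of the tree's taxa.
tree_split_masks <- function(tree, sorted_taxa) {
  n_all <- length(sorted_taxa)
  if (n_all > 31L) {
    stop_pc("bitmask split operations support at most 31 taxa",
            class = "pc_validation_error")
  }
  bit <- match(tree$tip.label, sorted_taxa) - 1L
  keep_tip <- !is.na(bit)
  present <- 0L
  for (b in bit[keep_tip]) present <- bitwOr(present, bitwShiftL(1L, b))
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  masks <- integer(ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    masks[i] <- if (keep_tip[i]) bitwShiftL(1L, bit[i]) else 0L
  }
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]
    masks[p] <- bitwOr(masks[p], masks[tr$edge[e, 2L]])
  }
  root <- ntip + 1L
  internal <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  m <- masks[internal]
  np <- popcount32(present)
  ## canonicalize within the present-taxon space: flip sides containing
  ## the lowest present bit
  ref <- bitwAnd(present, -present)
  flip <- bitwAnd(m, ref) != 0L
  m[flip] <- bitwAnd(present, bitwNot(m[flip]))
  pc <- popcount32(m)
  list(masks = unique(m[pc >= 2L & pc <= np - 2L]), present = present)
}

## The four clusters around an internal branch of a rooted binary species
## tree, as tip-label vectors.
branch_quadripartition <- function(species_tree, branch) {
  taxa <- species_tree$tip.label
  ntip <- length(taxa)
  root <- ntip + 1L
  clades <- tree_clades(species_tree)
  match_node <- NA_integer_
  for (v in seq.int(ntip + 1L, ntip + species_tree$Nnode)) {
    if (v == root) next
    side <- clades[[v]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (canonical_split(side, taxa) == branch) { match_node <- v; break }
  }
  if (is.na(match_node)) {
    stop_pc("branch '", branch, "' is not an internal branch of the species tree",
            class = "pc_validation_error")
  }
  v <- match_node
  kids_v <- species_tree$edge[species_tree$edge[, 1L] == v, 2L]
  if (length(kids_v) != 2L) {
    stop_pc("quadripartitions require a binary species tree at the focal branch",
            class = "pc_validation_error")
  }
  u <- species_tree$edge[species_tree$edge[, 2L] == v, 1L]
  sibs <- setdiff(species_tree$edge[species_tree$edge[, 1L] == u, 2L], v)
  if (u == root) {
    if (length(sibs) != 1L) {
      stop_pc("quadripartitions require a binary species tree at the root",
              class = "pc_validation_error")
    }
    kids_s <- species_tree$edge[species_tree$edge[, 1L] == sibs, 2L]
    if (length(kids_s) != 2L) {
      stop_pc("quadripartitions require a binary species tree at the focal branch",
              class = "pc_validation_error")
    }
    A <- clades[[kids_s[1L]]]
    B <- clades[[kids_s[2L]]]
  } else {
    if (length(sibs) != 1L) {
      stop_pc("quadripartitions require a binary species tree at the focal branch",
              class = "pc_validation_error")
    }
    A <- clades[[sibs]]
    B <- setdiff(taxa, clades[[u]])
  }
  list(A = A, B = B, C = clades[[kids_v[1L]]], D = clades[[kids_v[2L]]])
}

quartet_counts_for_masks <- function(masks_list, bitsA, bitsB, bitsC, bitsD) {
  counts <- c(0, 0, 0)
  for (g in seq_along(masks_list)) {
    masks <- masks_list[[g]]$masks
    present <- masks_list[[g]]$present
    for (a in bitsA) {
      if (bitwAnd(present, a) == 0L) next
      for (b in bitsB) {
        if (bitwAnd(present, b) == 0L) next
        ab <- bitwOr(a, b)
        for (cc in bitsC) {
          if (bitwAnd(present, cc) == 0L) next
          for (d in bitsD) {
            if (bitwAnd(present, d) == 0L) next
            q <- bitwOr(ab, bitwOr(cc, d))
            x <- bitwAnd(masks, q)
            two <- x[popcount32(x) == 2L]
            if (length(two) == 0L) next
            s <- two[1L]
            comp <- bitwXor(q, s)
            if (s == ab || comp == ab) {
              counts[1L] <- counts[1L] + 1
            } else if (s == bitwOr(a, cc) || comp == bitwOr(a, cc)) {
              counts[2L] <- counts[2L] + 1
            } else {
              counts[3L] <- counts[3L] + 1
            }
          }
        }
      }
    }
  }
  counts
}

#' Normalized quartet support (q1, q2, q3) for one species-tree branch
#'
#' Classifies, over all gene trees, every resolved quartet drawn from the
#' four taxon clusters around the branch, and returns the pooled
#' proportions. `q1` corresponds to the species-tree arrangement.
#'
#' @param species_tree rooted binary `phylo`.
#' @param gene_trees `multiPhylo`/list of gene trees (may miss taxa or
#'   contain polytomies), or a `gene_tree_sample`.
#' @param branch canonical split string (an element of
#'   [bipartitions()] of the species tree).
#' @return list with `branch`, `q1`, `q2`, `q3`, `n_quartets_resolved`.
#' @export
quartet_support <- function(species_tree, gene_trees, branch) {
  assert_phylo(species_tree, "species_tree")
  if (inherits(gene_trees, "gene_tree_sample")) gene_trees <- gene_trees$trees
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  sorted_taxa <- sort(species_tree$tip.label)
  masks_list <- lapply(gene_trees, tree_split_masks, sorted_taxa = sorted_taxa)
  quartet_support_impl(species_tree, masks_list, branch, sorted_taxa)
}

quartet_support_impl <- function(species_tree, masks_list, branch, sorted_taxa) {
  quad <- branch_quadripartition(species_tree, branch)
  to_bits <- function(labels) {
    bitwShiftL(1L, match(labels, sorted_taxa) - 1L)
  }
  counts <- quartet_counts_for_masks(masks_list, to_bits(quad$A),
                                     to_bits(quad$B), to_bits(quad$C),
                                     to_bits(quad$D))
  total <- sum(counts)
  if (total == 0) {
    stop_pc("no resolved quartets for branch '", branch, "'",
            class = "pc_validation_error")
  }
  list(branch = branch,
       q1 = counts[1L] / total, q2 = counts[2L] / total,
       q3 = counts[3L] / total,
       n_quartets_resolved = as.integer(total))
}

#' Quartet supports for every internal branch of a species tree
#'
#' @inheritParams quartet_support
#' @return a data frame with one row per internal branch: `branch`, `q1`,
#'   `q2`, `q3`, `n_quartets_resolved`.
#' @export
all_branch_supports <- function(species_tree, gene_trees) {
  assert_phylo(species_tree, "species_tree")
  if (inherits(gene_trees, "gene_tree_sample")) gene_trees <- gene_trees$trees
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  sorted_taxa <- sort(species_tree$tip.label)
  masks_list <- lapply(gene_trees, tree_split_masks, sorted_taxa = sorted_taxa)
  branches <- bipartitions(species_tree)
  rows <- lapply(branches, function(b) {
    as.data.frame(quartet_support_impl(species_tree, masks_list, b, sorted_taxa))
  })
  do.call(rbind, rows)
}
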