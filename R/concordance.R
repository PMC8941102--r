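## Gene-tree concordance/conflict classification at species-tree nodes.
##
## Each gene tree is compared with each species-tree bipartition after
## restriction to shared taxa. A gene tree is concordant at a node if it
## contains the identical restricted split with support at or above the
## threshold; it conflicts if it contains an incompatible split (all four
## pairwise side-intersections nonempty) at or above the threshold; it is
## uninformative otherwise (low support, missing taxa, or polytomy).

## Gene-tree splits restricted to `shared` taxa; returns canonical
## restricted split strings with supports, trivial restrictions removed.
restricted_gene_splits <- function(gene_tree, shared) {
  sp <- tree_splits(gene_tree)
  thr_na_pass <- !is.finite(sp$support)
  out_side <- list()
  out_sup <- numeric(0)
  for (i in seq_along(sp$node)) {
    side <- intersect(sp$side[[i]], shared)
    other <- length(shared) - length(side)
    if (length(side) < 2L || other < 2L) next
    out_side[[length(out_side) + 1L]] <- side
    out_sup <- c(out_sup, if (thr_na_pass[i]) Inf else sp$support[i])
  }
  if (length(out_side) == 0L) {
    return(list(key = character(0), side = list(), support = numeric(0)))
  }
  key <- vapply(out_side, canonical_split, character(1), taxa = shared)
  ## duplicated restricted splits (e.g. the two root-child edges of a
  ## rooted gene tree): one branch, one support -- use the largest labeled
  ## support; only a branch with no label anywhere passes unconditionally
  ukeys <- unique(key)
  sup <- vapply(ukeys, function(k) {
    s <- out_sup[key == k]
    if (any(is.finite(s))) max(s[is.finite(s)]) else Inf
  }, numeric(1))
  list(key = ukeys,
       side = out_side[match(ukeys, key)],
       support = unname(sup))
}

splits_conflict <- function(sideA, sideB, taxa) {
  a1 <- sideA; a2 <- setdiff(taxa, sideA)
  b1 <- sideB; b2 <- setdiff(taxa, sideB)
  length(intersect(a1, b1)) > 0L && length(intersect(a1, b2)) > 0L &&
    length(intersect(a2, b1)) > 0L && length(intersect(a2, b2)) > 0L
}

#' Classify one gene tree at one species-tree node
#'
#' @param node character vector: the taxa on one side of the species-tree
#'   bipartition.
#' @param gene_tree a `phylo` (supports in node labels; branches without a
#'   support value always count as informative).
#' @param taxa the full species-tree taxon set.
#' @param support_threshold minimum gene-tree branch support for a branch
#'   to inform the classification (auto-scaled; default 50%).
#' @return list with `status` (`"concordant"`, `"conflict"` or
#'   `"uninformative"`) and, for conflicts, `split`: the canonical
#'   conflicting split (restricted to shared taxa) with the highest
#'   support (ties broken lexicographically).
#' @export
classify_gene_tree <- function(node, gene_tree, taxa,
                               support_threshold = 50) {
  assert_phylo(gene_tree, "gene_tree")
  shared <- intersect(taxa, gene_tree$tip.label)
  A <- intersect(node, shared)
  B <- setdiff(shared, A)
  if (length(A) < 2L || length(B) < 2L) {
    return(list(status = "uninformative", split = NA_character_))
  }
  gs <- restricted_gene_splits(gene_tree, shared)
  if (length(gs$key) == 0L) {
    return(list(status = "uninformative", split = NA_character_))
  }
  thr <- match_support_scale(gs$support[is.finite(gs$support)],
                             support_threshold)
  ok <- gs$support >= thr
  target <- canonical_split(A, shared)
  if (any(ok & gs$key == target)) {
    return(list(status = "concordant", split = NA_character_))
  }
  conflicts <- which(ok & vapply(gs$side, splits_conflict, logical(1),
                                 sideB = A, taxa = shared))
  if (length(conflicts) > 0L) {
    sup <- gs$support[conflicts]
    best <- conflicts[order(-sup, gs$key[conflicts])][1L]
    return(list(status = "conflict", split = gs$key[best]))
  }
  list(status = "uninformative", split = NA_character_)
}

#' Gene-tree concordance summary at every species-tree node
#'
#' For each nontrivial species-tree bipartition, counts gene trees that
#' are concordant, that support the most common conflicting split
#' (`top_alt`), that support any other conflicting split, or that are
#' uninformative at the threshold (the four pie-chart categories used in
#' bipartition-mapping concordance analyses).
#'
#' @param species_tree a `phylo`.
#' @param gene_trees `multiPhylo`/list of gene trees or `gene_tree_sample`.
#' @param support_threshold minimum gene-tree branch support (default 50).
#' @return data frame with one row per node: `split`, `n_concordant`,
#'   `n_top_alt`, `n_other_conflict`, `n_uninformative`, the matching
#'   proportions, and `top_alt` (the modal conflicting split).
#' @export
concordance_summary <- function(species_tree, gene_trees,
                                support_threshold = 50) {
  assert_phylo(species_tree, "species_tree")
  if (inherits(gene_trees, "gene_tree_sample")) gene_trees <- gene_trees$trees
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (length(gene_trees) == 0L) {
    stop_pc("need at least one gene tree", class = "pc_validation_error")
  }
  taxa <- species_tree$tip.label
  clades <- tree_clades(species_tree)
  ntip <- length(taxa)
  nodes <- bipartitions(species_tree)
  sides <- lapply(nodes, function(b) {
    for (v in seq.int(ntip + 1L, ntip + species_tree$Nnode)) {
      side <- clades[[v]]
      if (length(side) >= 2L && length(side) <= ntip - 2L &&
          canonical_split(side, taxa) == b) {
        return(side)
      }
    }
    NULL
  })
  n_g <- length(gene_trees)
  rows <- vector("list", length(nodes))
  for (j in seq_along(nodes)) {
    status <- character(n_g)
    conf_split <- character(n_g)
    for (g in seq_len(n_g)) {
      cl <- classify_gene_tree(sides[[j]], gene_trees[[g]], taxa,
                               support_threshold)
      status[g] <- cl$status
      conf_split[g] <- cl$split
    }
    n_conc <- sum(status == "concordant")
    n_unin <- sum(status == "uninformative")
    confl <- conf_split[status == "conflict"]
    if (length(confl) > 0L) {
      tab <- sort(table(confl), decreasing = TRUE)
      top_alt <- names(tab)[1L]
      n_top <- as.integer(tab[1L])
      n_other <- length(confl) - n_top
    } else {
      top_alt <- NA_character_
      n_top <- 0L
      n_other <- 0L
    }
    rows[[j]] <- data.frame(
      split = nodes[j],
      n_concordant = n_conc, n_top_alt = n_top,
      n_other_conflict = n_other, n_uninformative = n_unin,
      p_concordant = n_conc / n_g, p_top_alt = n_top / n_g,
      p_other_conflict = n_other / n_g, p_uninformative = n_unin / n_g,
      top_alt = top_alt,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
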