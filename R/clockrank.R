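## Clock-likeness statistics and gene ranking for molecular dating.
##
## Genes are ranked by three criteria applied lexicographically: species
## tree concordance (descending), root-to-tip variance (ascending), and
## tree length (descending; longer trees carry more discernible signal).
## The top k genes feed the relaxed-clock analysis.

#' Clock-likeness statistics for one gene tree
#'
#' * `concordance`: fraction of the gene tree's nontrivial splits
#'   (restricted to taxa shared with the species tree) that are present in
#'   the species tree. A gene tree with no nontrivial splits after
#'   restriction is vacuously concordant (1, with a warning) so the later
#'   criteria decide its rank.
#' * `r2t_variance`: variance of root-to-tip path lengths after rooting.
#' * `tree_length`: sum of branch lengths.
#'
#' @param gene_tree a `phylo` with branch lengths.
#' @param species_tree reference `phylo`.
#' @param rooting list: `method` one of `"outgroup"`, `"midpoint"`,
#'   `"asis"`; for `"outgroup"`, `outgroup` (tip labels) and optionally
#'   `fallback_midpoint = TRUE` to midpoint-root genes whose outgroup is
#'   absent or non-monophyletic.
#' @return list with `concordance`, `r2t_variance`, `tree_length`.
#' @export
gene_stats <- function(gene_tree, species_tree,
                       rooting = list(method = "midpoint")) {
  assert_phylo(gene_tree, "gene_tree")
  assert_phylo(species_tree, "species_tree")
  if (is.null(gene_tree$edge.length)) {
    stop_pc("gene tree has no branch lengths", class = "pc_missing_lengths")
  }
  shared <- intersect(gene_tree$tip.label, species_tree$tip.label)
  if (length(shared) < 3L) {
    stop_pc("gene and species tree share fewer than 3 taxa",
            class = "pc_validation_error")
  }
  g <- if (length(gene_tree$tip.label) > length(shared)) {
    prune_to(gene_tree, shared)
  } else {
    gene_tree
  }
  s <- if (length(species_tree$tip.label) > length(shared)) {
    prune_to(species_tree, shared)
  } else {
    species_tree
  }
  gsplits <- bipartitions(g)
  ssplits <- bipartitions(s)
  concordance <- if (length(gsplits) == 0L) {
    warning("gene tree has no nontrivial splits; concordance is vacuously 1")
    1
  } else {
    length(intersect(gsplits, ssplits)) / length(gsplits)
  }
  rooted <- root_gene_tree(gene_tree, rooting)
  r2t <- var(root_to_tip_lengths(rooted))
  list(concordance = concordance,
       r2t_variance = r2t,
       tree_length = sum(gene_tree$edge.length))
}

root_gene_tree <- function(gene_tree, rooting) {
  method <- rooting$method %||% "midpoint"
  if (method == "asis") {
    if (!ape::is.rooted(gene_tree)) {
      stop_pc("gene tree is unrooted; choose an outgroup or midpoint rooting",
              class = "pc_rooting_error")
    }
    return(gene_tree)
  }
  if (method == "midpoint") {
    return(phangorn::midpoint(gene_tree))
  }
  if (method == "outgroup") {
    og <- intersect(rooting$outgroup, gene_tree$tip.label)
    ok <- length(og) > 0L && length(og) < length(gene_tree$tip.label) &&
      is_separated(gene_tree, og)
    if (ok) return(root_with_outgroup(gene_tree, og))
    if (isTRUE(rooting$fallback_midpoint %||% TRUE)) {
      return(phangorn::midpoint(gene_tree))
    }
    stop_pc("outgroup absent or non-monophyletic and midpoint fallback disabled",
            class = "pc_rooting_error")
  }
  stop_pc("unknown rooting method '", method, "'", class = "pc_validation_error")
}

#' Clock-likeness statistics for a set of gene trees
#'
#' @param gene_trees named list/`multiPhylo` of gene trees (names are the
#'   gene ids; unnamed lists get `gene_1`, `gene_2`, ...).
#' @inheritParams gene_stats
#' @return data frame: `gene`, `concordance`, `r2t_variance`,
#'   `tree_length`. Genes that cannot be rooted are excluded with a
#'   warning.
#' @export
gene_stats_table <- function(gene_trees, species_tree,
                             rooting = list(method = "midpoint")) {
  ids <- names(gene_trees) %||% paste0("gene_", seq_along(gene_trees))
  if (is.null(names(gene_trees))) names(gene_trees) <- ids
  rows <- list()
  failed <- character(0)
  for (id in ids) {
    st <- tryCatch(gene_stats(gene_trees[[id]], species_tree, rooting),
                   phyloconflict_error = function(e) NULL)
    if (is.null(st)) {
      failed <- c(failed, id)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(gene = id,
                                            concordance = st$concordance,
                                            r2t_variance = st$r2t_variance,
                                            tree_length = st$tree_length,
                                            stringsAsFactors = FALSE)
  }
  if (length(failed) > 0L) {
    warning("excluded unrootable/degenerate genes: ",
            paste(failed, collapse = ", "))
  }
  do.call(rbind, rows)
}

#' Rank genes by clock-likeness and select the top k
#'
#' Strict lexicographic ordering: concordance descending, then root-to-tip
#' variance ascending, then tree length descending, with gene id as the
#' deterministic tie-break.
#'
#' @param stats data frame as returned by [gene_stats_table()].
#' @param k number of genes to select (default 200).
#' @return character vector of the k selected gene ids, best first; the
#'   full ranking is attached as attribute `"ranking"`.
#' @export
rank_and_select <- function(stats, k = 200) {
  if (!is_count(k) || k <= 0) {
    stop_pc("k must be a positive integer", class = "pc_validation_error")
  }
  if (k > nrow(stats)) {
    stop_pc("k (", k, ") exceeds the number of genes (", nrow(stats), ")",
            class = "pc_validation_error")
  }
  ord <- order(-stats$concordance, stats$r2t_variance, -stats$tree_length,
               stats$gene)
  ranking <- stats$gene[ord]
  structure(ranking[seq_len(k)], ranking = ranking)
}
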