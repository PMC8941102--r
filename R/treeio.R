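## Tree input/output and bipartition algebra.
##
## Trees are ape `phylo` objects throughout. Two package conventions sit on
## top of ape: branch-length units are tracked with `set_branch_units()`,
## and internal node labels are interpreted as branch supports when numeric
## (the convention of bootstrap-annotated Newick gene trees).

#' Parse a Newick string into a tree
#'
#' A validating wrapper around [ape::read.tree()]. Internal node labels are
#' interpreted as support values when they are numeric, unless
#' `support = "label"` (in which case downstream support-aware operations
#' treat every branch as unannotated).
#'
#' @param text a Newick string terminated by `";"`.
#' @param support `"auto"` (numeric internal labels are supports) or
#'   `"label"` (labels are plain names, never supports).
#' @return a `phylo` object. Branch lengths absent from the string stay
#'   absent (no `edge.length` component), they are never silently zero.
#' @export
parse_newick <- function(text, support = c("auto", "label")) {
  support <- match.arg(support)
  if (!is.character(text) || length(text) != 1L) {
    stop_pc("`text` must be a single character string", class = "pc_parse_error")
  }
  trimmed <- trimws(text)
  if (!nzchar(trimmed) || substring(trimmed, nchar(trimmed)) != ";") {
    stop_pc("Newick string must end in ';'", class = "pc_parse_error")
  }
  chars <- strsplit(trimmed, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_pc("unbalanced ')' at character offset ", i,
                class = "pc_parse_error")
      }
    }
  }
  if (depth != 0L) {
    stop_pc("unbalanced '(': ", depth, " unclosed at end of string",
            class = "pc_parse_error")
  }
  tree <- tryCatch(
    ape::read.tree(text = trimmed),
    error = function(e) {
      stop_pc("malformed Newick string: ", conditionMessage(e),
              class = "pc_parse_error")
    }
  )
  if (is.null(tree)) {
    stop_pc("malformed Newick string (ape could not parse it)",
            class = "pc_parse_error")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    stop_pc("duplicate leaf labels: ", paste(dup, collapse = ", "),
            class = "pc_validation_error")
  }
  if (any(!nzchar(tree$tip.label))) {
    stop_pc("empty leaf labels are not allowed", class = "pc_validation_error")
  }
  attr(tree, "node_labels_are") <-
    if (support == "label") "label" else "support"
  attr(tree, "units") <- attr(tree, "units") %||% "none"
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  assert_phylo(tree)
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a gene-tree set (one Newick per line)
#'
#' @param file path to a file with one Newick string per line.
#' @inheritParams parse_newick
#' @return a `multiPhylo` list.
#' @export
read_gene_trees <- function(file, support = c("auto", "label")) {
  support <- match.arg(support)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parse_newick, support = support)
  class(trees) <- "multiPhylo"
  trees
}

## ---- clades and splits -----------------------------------------------

## Tip-label sets below every node (tips and internals), indexed by ape
## node id. The workhorse for all bipartition algebra.
tree_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  clades <- vector("list", nnode)
  for (i in seq_len(ntip)) clades[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]
    ch <- tr$edge[e, 2L]
    clades[[p]] <- c(clades[[p]], clades[[ch]])
  }
  clades
}

## Canonical one-side representation of a split: the side NOT containing
## the lexicographically smallest taxon, sorted and comma-joined.
canonical_split <- function(side, taxa) {
  ref <- min(taxa)
  if (ref %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = ",")
}

## All internal edges of `tree` with their split side (tips below the
## edge), the support of the edge, and whether the split is nontrivial.
## Root-child edges both appear (they induce the same unrooted split).
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  clades <- tree_clades(tree)
  sup <- if (identical(attr(tree, "node_labels_are"), "label")) {
    rep(NA_real_, tree$Nnode)
  } else {
    tree_support_values(tree)
  }
  root <- ntip + 1L
  nodes <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  sides <- clades[nodes]
  nontrivial <- vapply(sides, function(s) {
    length(s) >= 2L && length(s) <= ntip - 2L
  }, logical(1))
  list(node = nodes,
       side = sides,
       support = sup[nodes - ntip],
       nontrivial = nontrivial)
}

#' Nontrivial bipartitions of a tree
#'
#' Returns the set of nontrivial splits induced by the internal branches,
#' in a canonical string form: each split is represented by the side not
#' containing the lexicographically smallest taxon, sorted and
#' comma-joined. For an unrooted binary tree on n leaves there are exactly
#' n - 3 of them; a star tree has none.
#'
#' @param tree a `phylo` object.
#' @return sorted character vector of canonical split strings.
#' @export
bipartitions <- function(tree) {
  assert_phylo(tree)
  taxa <- tree$tip.label
  sp <- tree_splits(tree)
  sides <- sp$side[sp$nontrivial]
  sort(unique(vapply(sides, canonical_split, character(1), taxa = taxa)))
}

#' Collapse weakly supported branches
#'
#' Contracts every internal branch whose support is strictly below
#' `threshold`; the children of a contracted node are re-attached to its
#' parent and the contracted branch length is added to theirs (so
#' tip-to-tip path lengths are preserved). The result may be multifurcating.
#'
#' The support scale is auto-detected: values all <= 1 are treated as
#' proportions, otherwise as percentages, and the threshold is compared on
#' the detected scale.
#'
#' @param tree a `phylo` object with supports in its node labels.
#' @param threshold branches with support strictly below this collapse.
#' @return the collapsed `phylo` object.
#' @export
collapse_low_support <- function(tree, threshold) {
  assert_phylo(tree)
  sup <- tree_support_values(tree)
  thr <- match_support_scale(sup, threshold)
  hi <- if (all(sup[is.finite(sup)] <= 1) && length(sup[is.finite(sup)]) > 0) 1 else 100
  if (thr < 0 || thr > hi) {
    stop_pc("threshold ", threshold, " is outside the detected support scale [0, ",
            hi, "]", class = "pc_validation_error")
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  drop_nodes <- which(is.finite(sup) & sup < thr) + ntip
  drop_nodes <- setdiff(drop_nodes, root)
  if (length(drop_nodes) == 0L) return(tree)
  contract_nodes(tree, drop_nodes)
}

## Contract a set of internal (non-root) nodes: reattach children to the
## parent, adding the removed edge length to the children's edges.
contract_nodes <- function(tree, nodes) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edge <- tree$edge
  len <- tree$edge.length
  has_len <- !is.null(len)
  keep_row <- rep(TRUE, nrow(edge))
  for (v in nodes) {
    up <- which(edge[, 2L] == v & keep_row)
    if (length(up) != 1L) next
    parent <- edge[up, 1L]
    kids <- which(edge[, 1L] == v & keep_row)
    edge[kids, 1L] <- parent
    if (has_len) len[kids] <- len[kids] + len[up]
    keep_row[up] <- FALSE
  }
  edge <- edge[keep_row, , drop = FALSE]
  if (has_len) len <- len[keep_row]
  ## renumber surviving internal nodes compactly (root keeps ntip+1: it is
  ## never contracted and has the smallest internal id)
  kept_internal <- sort(unique(c(root, edge[, 1L], edge[, 2L][edge[, 2L] > ntip])))
  kept_internal <- kept_internal[kept_internal > ntip]
  newid <- integer(ntip + tree$Nnode)
  newid[seq_len(ntip)] <- seq_len(ntip)
  newid[kept_internal] <- ntip + seq_along(kept_internal)
  edge[] <- newid[edge]
  out <- list(edge = edge,
              tip.label = tree$tip.label,
              Nnode = length(kept_internal))
  if (has_len) out$edge.length <- len
  if (!is.null(tree$node.label)) {
    out$node.label <- tree$node.label[kept_internal - ntip]
  }
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  attr(out, "units") <- branch_units(tree)
  attr(out, "node_labels_are") <- attr(tree, "node_labels_are")
  out
}

#' Restrict a tree to a subset of taxa
#'
#' Induced subtree on `taxa`: remaining degree-2 internal nodes are
#' suppressed with their branch lengths summed.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip labels to keep (>= 2).
#' @return the pruned `phylo`.
#' @export
prune_to <- function(tree, taxa) {
  assert_phylo(tree)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L) {
    stop_pc("taxa not in tree: ", paste(sort(missing), collapse = ", "),
            class = "pc_validation_error")
  }
  if (length(taxa) < 2L) {
    stop_pc("need at least 2 taxa to prune to", class = "pc_validation_error")
  }
  out <- ape::keep.tip(tree, taxa)
  attr(out, "units") <- branch_units(tree)
  attr(out, "node_labels_are") <- attr(tree, "node_labels_are")
  out
}

## Is `group` separated from the rest by some branch (monophyletic in the
## unrooted sense)?
is_separated <- function(tree, group) {
  taxa <- tree$tip.label
  n <- length(taxa)
  k <- length(group)
  if (k == 1L || k == n - 1L) return(TRUE)
  clades <- tree_clades(tree)
  gs <- paste(sort(group), collapse = "\r")
  cs <- paste(sort(setdiff(taxa, group)), collapse = "\r")
  for (cl in clades) {
    key <- paste(sort(cl), collapse = "\r")
    if (key == gs || key == cs) return(TRUE)
  }
  FALSE
}

#' Root a tree on the branch separating an outgroup
#'
#' @param tree a `phylo` object.
#' @param outgroup character vector of tip labels; must be a proper
#'   nonempty subset of the leaves and monophyletic in the unrooted tree.
#' @return a rooted `phylo`; tip-to-tip path lengths are preserved.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  assert_phylo(tree)
  taxa <- tree$tip.label
  missing <- setdiff(outgroup, taxa)
  if (length(missing) > 0L) {
    stop_pc("outgroup taxa not in tree: ", paste(sort(missing), collapse = ", "),
            class = "pc_validation_error")
  }
  if (length(outgroup) == 0L || length(outgroup) >= length(taxa)) {
    stop_pc("outgroup must be a proper nonempty subset of the leaves",
            class = "pc_validation_error")
  }
  if (!is_separated(tree, outgroup)) {
    stop_pc("outgroup is not monophyletic in the unrooted tree",
            class = "pc_rooting_error")
  }
  out <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ## balance the root position on the outgroup branch: split its length so
  ## the deepest tips on either side are equidistant from the root when
  ## possible (recovers the original rooting of an ultrametric tree); the
  ## two root edges always keep their total, so path lengths are preserved
  if (!is.null(out$edge.length)) {
    ntip <- length(out$tip.label)
    root <- ntip + 1L
    rows <- which(out$edge[, 1L] == root)
    if (length(rows) == 2L) {
      tot <- sum(out$edge.length[rows])
      h <- vapply(rows, function(rw) {
        sub_tips <- tree_clades(out)[[out$edge[rw, 2L]]]
        tmp <- out
        tmp$edge.length[rw] <- 0
        max(node_depths(tmp)[match(sub_tips, out$tip.label)])
      }, numeric(1))
      e1 <- min(max((tot + h[2L] - h[1L]) / 2, 0), tot)
      out$edge.length[rows] <- c(e1, tot - e1)
    }
  }
  attr(out, "units") <- branch_units(tree)
  attr(out, "node_labels_are") <- attr(tree, "node_labels_are")
  out
}

## Root-to-tip path lengths of a rooted tree with branch lengths.
root_to_tip_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop_pc("tree has no branch lengths", class = "pc_missing_lengths")
  }
  depths <- node_depths(tree)
  setNames(depths[seq_along(tree$tip.label)], tree$tip.label)
}

## Distance from the root for every node (preorder accumulation). Missing
## edge lengths are an error, never assumed zero.
node_depths <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop_pc("tree has no branch lengths", class = "pc_missing_lengths")
  }
  if (anyNA(tree$edge.length)) {
    stop_pc("tree has NA branch lengths", class = "pc_missing_lengths")
  }
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  depths <- numeric(ntip + tree$Nnode)
  for (e in rev(seq_len(nrow(tr$edge)))) {
    depths[tr$edge[e, 2L]] <- depths[tr$edge[e, 1L]] + tr$edge.length[e]
  }
  depths
}
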