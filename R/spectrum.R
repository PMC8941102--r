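## Canonical unrooted topology keys and topology-frequency spectra.

#' Canonical key of an unrooted leaf-labeled topology
#'
#' Two trees receive the same key if and only if their nontrivial split
#' sets are equal; the key ignores branch lengths, supports, rotation and
#' root placement. Each split is written as its canonical side (the side
#' not containing the lexicographically smallest taxon), sides are sorted
#' and joined with `"|"`. A star tree keys to the empty string.
#'
#' @param tree a `phylo` with at least 3 leaves.
#' @return a single character key.
#' @export
topology_key <- function(tree) {
  assert_phylo(tree)
  if (length(tree$tip.label) < 3L) {
    stop_pc("topology keys need at least 3 taxa", class = "pc_validation_error")
  }
  paste(bipartitions(tree), collapse = "|")
}

new_topology_spectrum <- function(counts, taxa) {
  counts <- counts[order(-counts, names(counts))]
  structure(list(taxa = taxa,
                 counts = counts,
                 n_total = sum(counts)),
            class = "topology_spectrum")
}

#' Topology-frequency spectrum of a gene-tree sample
#'
#' Counts canonical unrooted topologies over a collection of gene trees.
#' Trees missing any of the requested taxa are dropped (and reported);
#' trees with extra taxa are pruned down when `restrict = TRUE`, otherwise
#' dropped.
#'
#' @param trees a `multiPhylo`, list of `phylo`, or [simulate_gene_trees()]
#'   result.
#' @param taxa taxon set to count on; default, the tips of the first tree.
#' @param restrict prune trees carrying a superset of `taxa`.
#' @return a `topology_spectrum`: list with `taxa`, `counts` (named,
#'   sorted by decreasing count then key) and `n_total`.
#' @export
spectrum_of <- function(trees, taxa = NULL, restrict = FALSE) {
  if (inherits(trees, "gene_tree_sample")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) {
    stop_pc("no trees supplied", class = "pc_validation_error")
  }
  taxa <- sort(taxa %||% trees[[1L]]$tip.label)
  keys <- character(length(trees))
  usable <- logical(length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    tips <- tr$tip.label
    if (!all(taxa %in% tips)) next
    if (length(tips) > length(taxa)) {
      if (!restrict) next
      tr <- prune_to(tr, taxa)
    }
    keys[i] <- topology_key(tr)
    usable[i] <- TRUE
  }
  if (!any(usable)) {
    stop_pc("no usable trees (all missing requested taxa)",
            class = "pc_validation_error")
  }
  dropped <- sum(!usable)
  if (dropped > 0L) {
    message(dropped, " tree(s) dropped (taxa missing or unprunable)")
  }
  tab <- table(keys[usable])
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  new_topology_spectrum(counts, taxa)
}

#' Relative topology frequencies of a spectrum
#'
#' @param x a `topology_spectrum`.
#' @return named numeric vector summing to 1.
#' @export
spectrum_frequencies <- function(x) {
  stopifnot(inherits(x, "topology_spectrum"))
  x$counts / x$n_total
}

#' @export
print.topology_spectrum <- function(x, ...) {
  cat("Topology spectrum on", length(x$taxa), "taxa;",
      length(x$counts), "distinct topologies over", x$n_total, "trees\n")
  top <- utils::head(x$counts, 5L)
  for (i in seq_along(top)) {
    cat(sprintf("  %6d  %.4f  %s\n", top[i], top[i] / x$n_total,
                substr(names(top)[i], 1, 60)))
  }
  if (length(x$counts) > 5L) cat("  ...\n")
  invisible(x)
}

#' Enumerate all unrooted binary topologies on a taxon set
#'
#' Generates the (2n-5)!! unrooted binary leaf-labeled topologies by
#' recursive leaf insertion and returns their canonical keys (same format
#' as [topology_key()]).
#'
#' @param taxa character vector of taxon labels (3 or more).
#' @param max_n guard against combinatorial explosion; default 8.
#' @return character vector of distinct keys, length (2n-5)!!.
#' @export
enumerate_topologies <- function(taxa, max_n = 8) {
  taxa <- sort(taxa)
  n <- length(taxa)
  if (n < 3L) {
    stop_pc("need at least 3 taxa", class = "pc_validation_error")
  }
  if (n > max_n) {
    stop_pc("refusing to enumerate ", n, " taxa (max_n = ", max_n, ")",
            class = "pc_validation_error")
  }
  ## edge lists on node ids: leaves 1..n, internal nodes negative
  trees <- list(matrix(c(-1L, 1L, -1L, 2L, -1L, 3L), ncol = 2, byrow = TRUE))
  if (n > 3L) {
    for (leaf in 4L:n) {
      nxt <- list()
      for (ed in trees) {
        new_int <- min(c(ed[ed < 0], 0L)) - 1L
        for (e in seq_len(nrow(ed))) {
          ed2 <- ed
          u <- ed[e, 1L]; v <- ed[e, 2L]
          ed2[e, ] <- c(u, new_int)
          ed2 <- rbind(ed2, c(new_int, v), c(new_int, leaf))
          nxt[[length(nxt) + 1L]] <- ed2
        }
      }
      trees <- nxt
    }
  }
  vapply(trees, edge_list_key, character(1), taxa = taxa)
}

## Canonical key straight from an (internal-negative) edge list.
edge_list_key <- function(ed, taxa) {
  n <- length(taxa)
  adj <- split(c(ed[, 2L], ed[, 1L]), c(ed[, 1L], ed[, 2L]))
  below <- function(node, parent) {
    kids <- setdiff(adj[[as.character(node)]], parent)
    if (length(kids) == 0L) return(node)
    unlist(lapply(kids, below, parent = node))
  }
  sides <- list()
  for (e in seq_len(nrow(ed))) {
    u <- ed[e, 1L]; v <- ed[e, 2L]
    tips <- below(v, u)
    if (length(tips) >= 2L && length(tips) <= n - 2L) {
      sides[[length(sides) + 1L]] <- taxa[sort(tips)]
    }
  }
  keys <- vapply(sides, canonical_split, character(1), taxa = taxa)
  paste(sort(unique(keys)), collapse = "|")
}
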