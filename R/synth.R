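## Synthetic-data generators.
##
## These emulate the study conditions the package's diagnostics are meant
## for: a species tree with one short focal internal branch among long
## ones (the deep-radiation setting), coalescent gene-tree samples of a
## few hundred to a few thousand genes, gene-tree estimation error modeled
## as random NNI perturbation with degraded support values, per-gene rate
## heterogeneity for clock-likeness ranking, and Mk1-evolved discrete
## characters. Every generator is deterministic given its seed.

#' Random species tree with one short focal internal branch
#'
#' Builds a rooted binary tree on `n_taxa` tips (labels `s1..sn`) whose
#' internal branches all have length `background` coalescent units except
#' one focal branch set to `focal_length`. Terminal branch lengths are
#' aligned so the tree is ultrametric in coalescent time. The focal
#' branch's canonical split is recorded in the `"focal_split"` attribute.
#'
#' @param n_taxa number of tips (>= 4).
#' @param focal_length focal internal branch length in coalescent units
#'   (default 0.06, deep-radiation regime).
#' @param background all other internal branch lengths (default 4).
#' @param seed integer seed controlling the random topology.
#' @return a rooted ultrametric `phylo` with coalescent units declared.
#' @export
make_species_tree <- function(n_taxa = 7, focal_length = 0.06,
                              background = 4, seed = NULL) {
  if (!is_count(n_taxa) || n_taxa < 4) {
    stop_pc("n_taxa must be an integer >= 4", class = "pc_validation_error")
  }
  tree <- with_seed(seed, ape::rtree(n_taxa, tip.label = paste0("s", seq_len(n_taxa))))
  tree$node.label <- NULL
  ntip <- n_taxa
  root <- ntip + 1L
  internal_rows <- which(tree$edge[, 2L] > ntip)
  tree$edge.length[internal_rows] <- background
  ## focal branch: prefer an internal edge whose parent is also a non-root
  ## internal node (a fully internal quadripartition); fall back to a
  ## root-child edge, whose two root edges then share the focal length
  parents <- tree$edge[internal_rows, 1L]
  deep <- internal_rows[parents != root]
  if (length(deep) > 0L) {
    focal_row <- deep[1L]
    tree$edge.length[focal_row] <- focal_length
  } else {
    ## both internal edges hang off the root (e.g. n = 4 balanced): the
    ## unrooted focal branch is the sum of the two root-child edges
    tree$edge.length[internal_rows] <- focal_length / 2
    focal_row <- internal_rows[1L]
  }
  ## align terminal branches: make the tree ultrametric
  tmp <- tree
  tip_rows <- which(tmp$edge[, 2L] <= ntip)
  tmp$edge.length[tip_rows] <- 0
  depth0 <- numeric(ntip + tmp$Nnode)
  tr <- ape::reorder.phylo(tmp, "postorder")
  for (e in rev(seq_len(nrow(tr$edge)))) {
    depth0[tr$edge[e, 2L]] <- depth0[tr$edge[e, 1L]] + tr$edge.length[e]
  }
  H <- max(depth0[seq_len(ntip)]) + 1
  for (row in tip_rows) {
    tip <- tree$edge[row, 2L]
    tree$edge.length[row] <- H - depth0[tip]
  }
  tree <- set_branch_units(tree, "coalescent")
  clades <- tree_clades(tree)
  attr(tree, "focal_split") <- canonical_split(clades[[tree$edge[focal_row, 2L]]],
                                               tree$tip.label)
  attr(tree, "focal_length") <- focal_length
  tree
}

## One random nearest-neighbor interchange across the edge above internal
## node v: swap a random child subtree of v with v's sibling subtree.
nni_at_node <- function(tree, v) {
  edge <- tree$edge
  up <- which(edge[, 2L] == v)
  u <- edge[up, 1L]
  sibs <- setdiff(edge[edge[, 1L] == u, 2L], v)
  if (length(sibs) == 0L) return(tree)
  b <- sibs[[sample.int(length(sibs), 1L)]]
  kids <- edge[edge[, 1L] == v, 2L]
  a <- kids[[sample.int(length(kids), 1L)]]
  row_a <- which(edge[, 2L] == a)
  row_b <- which(edge[, 2L] == b)
  tree$edge[row_a, 1L] <- u
  tree$edge[row_b, 1L] <- v
  tree
}

#' Simulated "observed" gene-tree sample with estimation error
#'
#' Draws `n_obs` coalescent gene trees from the species tree and emulates
#' gene-tree estimation error: each internal branch is independently hit
#' by a random NNI with probability `error_prob`, and support values are
#' drawn from a two-component model (perturbed branches from the low
#' component, untouched branches from the high component).
#'
#' @param species_tree rooted `phylo` in coalescent units.
#' @param n_obs number of gene trees.
#' @param error_prob per-internal-branch NNI probability in `[0, 1]`.
#' @param support_model list with `high` and `low` ranges (percent);
#'   default high Uniform(70, 100), low Uniform(0, 50).
#' @param seed integer seed.
#' @return a `gene_tree_sample` with `source = "observed"`; trees carry
#'   percent supports in their node labels.
#' @export
make_observed_sample <- function(species_tree, n_obs,
                                 error_prob = 0,
                                 support_model = list(high = c(70, 100),
                                                      low = c(0, 50)),
                                 seed = NULL) {
  if (!is.numeric(error_prob) || error_prob < 0 || error_prob > 1) {
    stop_pc("error_prob must lie in [0, 1]", class = "pc_validation_error")
  }
  with_seed(seed, {
    sample <- simulate_gene_trees(species_tree, n_obs)
    trees <- sample$trees
    for (i in seq_along(trees)) {
      tr <- trees[[i]]
      ntip <- length(tr$tip.label)
      root <- ntip + 1L
      internal <- setdiff(seq.int(ntip + 1L, ntip + tr$Nnode), root)
      hit <- internal[runif(length(internal)) < error_prob]
      for (v in hit) tr <- nni_at_node(tr, v)
      sup <- numeric(tr$Nnode)
      for (j in seq_len(tr$Nnode)) {
        rng <- if ((ntip + j) %in% hit) support_model$low else support_model$high
        sup[j] <- runif(1, rng[1], rng[2])
      }
      sup[1L] <- NA  # root carries no support
      tr$node.label <- ifelse(is.na(sup), "", sprintf("%.0f", sup))
      attr(tr, "node_labels_are") <- "support"
      trees[[i]] <- tr
    }
    class(trees) <- "multiPhylo"
    structure(list(trees = trees,
                   coalescence_heights = sample$coalescence_heights,
                   n_perturbed_branches = NA_integer_,
                   error_prob = error_prob,
                   seed = seed, source = "observed",
                   taxa = sample$taxa),
              class = "gene_tree_sample")
  })
}

#' Rate-heterogeneous gene trees for clock-likeness ranking
#'
#' Takes an ultrametric species tree as the time tree and builds one gene
#' tree per entry of `rate_var_grid`: branch lengths are time multiplied
#' by a per-branch lognormal rate with mean `base_rate` and log-scale
#' variance taken from the grid. A gene with rate variance 0 is exactly
#' ultrametric (clock-like).
#'
#' @param species_tree ultrametric `phylo` (the time tree).
#' @param rate_var_grid non-negative per-gene lognormal rate variances
#'   (one gene per entry).
#' @param base_rate expected substitution rate (default 1).
#' @param seed integer seed.
#' @return list with `trees` (named list `gene_1`, ...) and `truth` (data
#'   frame `gene`, `rate_var`).
#' @export
make_clock_fixture <- function(species_tree, rate_var_grid,
                               base_rate = 1, seed = NULL) {
  if (any(rate_var_grid < 0)) {
    stop_pc("rate variances must be non-negative", class = "pc_validation_error")
  }
  n_genes <- length(rate_var_grid)
  ids <- paste0("gene_", seq_len(n_genes))
  trees <- with_seed(seed, {
    lapply(seq_len(n_genes), function(g) {
      s2 <- rate_var_grid[g]
      tr <- species_tree
      ne <- length(tr$edge.length)
      rates <- if (s2 == 0) rep(base_rate, ne) else {
        rlnorm(ne, meanlog = log(base_rate) - s2 / 2, sdlog = sqrt(s2))
      }
      tr$edge.length <- tr$edge.length * rates
      tr <- set_branch_units(tr, "subst")
      tr
    })
  })
  names(trees) <- ids
  list(trees = trees,
       truth = data.frame(gene = ids, rate_var = rate_var_grid,
                          stringsAsFactors = FALSE))
}

#' Simulate discrete characters under the Mk1 model
#'
#' The root state is uniform on 0..k-1 and states evolve down each branch
#' with the Mk1 transition probabilities.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param rate Mk1 exchange rate r (> 0).
#' @param n_chars number of independent characters.
#' @param k number of states (default 5).
#' @param seed integer seed.
#' @return taxa x characters integer matrix of states in 0..k-1.
#' @export
make_mk1_characters <- function(tree, rate, n_chars, k = 5, seed = NULL) {
  if (!is.numeric(rate) || rate <= 0) {
    stop_pc("rate must be positive", class = "pc_validation_error")
  }
  if (!is_count(n_chars) || n_chars < 1) {
    stop_pc("n_chars must be a positive integer", class = "pc_validation_error")
  }
  model <- mk_model(k, rate)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  tr <- ape::reorder.phylo(tree, "postorder")
  with_seed(seed, {
    states <- matrix(NA_integer_, ntip + tree$Nnode, n_chars)
    states[root, ] <- sample.int(k, n_chars, replace = TRUE) - 1L
    for (e in rev(seq_len(nrow(tr$edge)))) {
      p <- tr$edge[e, 1L]
      ch <- tr$edge[e, 2L]
      P <- mk_transition_matrix(model, tr$edge.length[e])
      cum <- t(apply(P, 1L, cumsum))
      u <- runif(n_chars)
      idx <- states[p, ] + 1L
      drawn <- integer(n_chars)
      for (j in seq_len(n_chars)) {
        drawn[j] <- findInterval(u[j], cum[idx[j], ], left.open = TRUE) + 1L
      }
      states[ch, ] <- drawn - 1L
    }
    out <- states[seq_len(ntip), , drop = FALSE]
    rownames(out) <- tree$tip.label
    out
  })
}
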