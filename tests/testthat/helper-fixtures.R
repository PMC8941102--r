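# Fixtures and independent oracles used across the suite. All fixtures
# are built in code; random cases use fixed seeds.

# random rooted binary tree with branch lengths and percent supports
random_support_tree <- function(n, seed) {
  tr <- phyloconflict:::with_seed(seed, {
    t0 <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    t0$node.label <- sprintf("%.0f", runif(t0$Nnode, 0, 100))
    t0
  })
  attr(tr, "node_labels_are") <- "support"
  tr
}

cu_tree <- function(newick) {
  set_branch_units(parse_newick(newick), "coalescent")
}

# independent quartet-topology oracle: prune the gene tree to the four
# tips with ape and compare canonical keys of the three arrangements
oracle_quartet_counts <- function(gene_trees, A, B, C, D) {
  counts <- c(0, 0, 0)
  for (tr in gene_trees) {
    for (a in A) for (b in B) for (cc in C) for (d in D) {
      tips <- c(a, b, cc, d)
      if (!all(tips %in% tr$tip.label)) next
      sub <- ape::keep.tip(tr, tips)
      key <- topology_key(sub)
      k1 <- topology_key(parse_newick(sprintf("((%s,%s),(%s,%s));", a, b, cc, d)))
      k2 <- topology_key(parse_newick(sprintf("((%s,%s),(%s,%s));", a, cc, b, d)))
      k3 <- topology_key(parse_newick(sprintf("((%s,%s),(%s,%s));", a, d, b, cc)))
      if (key == k1) counts[1] <- counts[1] + 1
      else if (key == k2) counts[2] <- counts[2] + 1
      else if (key == k3) counts[3] <- counts[3] + 1
      # otherwise unresolved: skipped
    }
  }
  counts
}

# independent Mk transition probabilities via the matrix exponential of
# the rate matrix (ape::matexpo), not the closed form under test
oracle_mk_P <- function(k, r, t) {
  Q <- matrix(r, k, k)
  diag(Q) <- -(k - 1) * r
  ape::matexpo(Q * t)
}

# brute-force Mk likelihood: enumerate every internal-state assignment
oracle_mk_loglik <- function(tree, states, k, r) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  sts <- states[tree$tip.label]
  assignments <- as.matrix(expand.grid(rep(list(0:(k - 1)), nint)))
  total <- 0
  for (row in seq_len(nrow(assignments))) {
    s <- c(sts, assignments[row, ])
    prob <- 1 / k  # uniform root; root is node ntip+1 -> assignment col 1
    for (e in seq_len(nrow(tree$edge))) {
      sc <- s[tree$edge[e, 2L]]
      if (is.na(sc)) next  # missing tip: row sums are 1, factor drops out
      P <- oracle_mk_P(k, r, tree$edge.length[e])
      prob <- prob * P[s[tree$edge[e, 1L]] + 1L, sc + 1L]
    }
    total <- total + prob
  }
  log(total)
}

# brute-force marginal ancestral posteriors by enumeration
oracle_mk_marginals <- function(tree, states, k, r) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  sts <- states[tree$tip.label]
  assignments <- as.matrix(expand.grid(rep(list(0:(k - 1)), nint)))
  w <- numeric(nrow(assignments))
  for (row in seq_len(nrow(assignments))) {
    s <- c(sts, assignments[row, ])
    prob <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      P <- oracle_mk_P(k, r, tree$edge.length[e])
      sc <- s[tree$edge[e, 2L]]
      if (is.na(sc)) next
      prob <- prob * P[s[tree$edge[e, 1L]] + 1L, sc + 1L]
    }
    w[row] <- prob
  }
  marg <- matrix(0, nint, k)
  for (j in seq_len(nint)) {
    for (st in 0:(k - 1)) {
      marg[j, st + 1L] <- sum(w[assignments[, j] == st])
    }
  }
  marg / rowSums(marg)
}

# oracle for gene-tree splits using ape::prop.part (independent of the
# package's clade accumulation)
oracle_splits <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  sides <- lapply(pp, function(ix) labs[ix])
  sides <- Filter(function(s) length(s) >= 2 && length(s) <= n - 2, sides)
  sort(unique(vapply(sides, phyloconflict:::canonical_split, character(1),
                     taxa = labs)))
}
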