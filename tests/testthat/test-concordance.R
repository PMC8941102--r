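test_that("identical fully supported gene trees are concordant everywhere", {
  sp <- parse_newick("(((A,B),C),((D,E),F));")
  gene <- parse_newick("(((A,B)100,C)100,((D,E)100,F)100);")
  out <- concordance_summary(sp, rep(list(gene), 100), support_threshold = 50)
  expect_equal(out$n_concordant, rep(100L, nrow(out)))
  expect_equal(out$p_concordant, rep(1, nrow(out)))
  expect_equal(out$n_uninformative, rep(0L, nrow(out)))
})

test_that("a weakly supported branch is uninformative at the threshold", {
  sp <- parse_newick("((A,B),(C,D));")
  gene <- parse_newick("((A,B)30,(C,D));")
  cl <- classify_gene_tree(c("A", "B"), gene, sp$tip.label,
                           support_threshold = 50)
  expect_equal(cl$status, "uninformative")
  cl2 <- classify_gene_tree(c("A", "B"), gene, sp$tip.label,
                            support_threshold = 20)
  expect_equal(cl2$status, "concordant")
})

test_that("a taxon swap across the node is a conflict with the right split", {
  sp <- parse_newick("(((A,B),C),((D,E),F));")
  # gene tree swaps C and E across the ABC|DEF bipartition
  gene <- parse_newick("(((A,B)90,E)95,((D,C)90,F)90);")
  cl <- classify_gene_tree(c("A", "B", "C"), gene, sp$tip.label,
                           support_threshold = 50)
  expect_equal(cl$status, "conflict")
  # the highest-support conflicting split restricted to shared taxa:
  # {A,B,E} vs {C,D,F} (support 95), canonically the side without A
  expect_equal(cl$split, "C,D,F")
  # with all supports tied, the deterministic tie-break picks the
  # lexicographically smallest conflicting split
  gene_tied <- parse_newick("(((A,B)90,E)90,((D,C)90,F)90);")
  expect_equal(classify_gene_tree(c("A", "B", "C"), gene_tied,
                                  sp$tip.label)$split, "C,D")
})

test_that("missing taxa restrict the node before comparison", {
  sp <- parse_newick("(((A,B),C),((D,E),F));")
  gene <- parse_newick("((A,B),(D,F));")  # C, E absent
  # ABC restricted to shared taxa {A,B,D,F} is {A,B}: still testable
  cl <- classify_gene_tree(c("A", "B", "C"), gene, sp$tip.label)
  expect_equal(cl$status, "concordant")
  # AB restricted loses one side entirely -> uninformative
  cl2 <- classify_gene_tree(c("D", "E"), gene, sp$tip.label)
  expect_equal(cl2$status, "uninformative")
})

test_that("a 50/50 mixture splits between concordant and one alternative", {
  sp <- parse_newick("(((A,B),C),((D,E),F));")
  main <- parse_newick("(((A,B),C),((D,E),F));")
  alt <- parse_newick("(((A,C),B),((D,E),F));")  # NNI at the AB node
  out <- concordance_summary(sp, c(rep(list(main), 50), rep(list(alt), 50)))
  row <- out[out$split == "C,D,E,F", ]  # the {A,B} split, canonical side
  expect_equal(row$n_concordant, 50L)
  expect_equal(row$n_top_alt, 50L)
  expect_equal(row$n_other_conflict, 0L)
})

test_that("concordant fraction at a short focal branch matches theory", {
  t <- 0.05
  sp <- make_species_tree(7, focal_length = t, background = 8, seed = 71)
  g <- simulate_gene_trees(sp, 2000, seed = 72)  # no supports: all pass
  out <- concordance_summary(sp, g)
  row <- out[out$split == attr(sp, "focal_split"), ]
  p <- concordance_prob(t)
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(row$p_concordant - p), 3 * se + 0.01)
  # fully resolved, fully informative trees: nothing uninformative
  expect_equal(row$n_uninformative, 0L)
  expect_equal(row$n_concordant + row$n_top_alt + row$n_other_conflict, 2000L)
})

test_that("raising the support threshold only moves trees to uninformative", {
  sp <- make_species_tree(6, focal_length = 0.3, background = 2, seed = 81)
  obs <- make_observed_sample(sp, 150, error_prob = 0.3, seed = 82)
  prev_unin <- rep(-1L, 3)
  prev_inf <- rep(.Machine$integer.max, 3)
  for (thr in c(0, 40, 80)) {
    out <- concordance_summary(sp, obs, support_threshold = thr)
    expect_true(all(out$n_uninformative >= prev_unin))
    inf <- out$n_concordant + out$n_top_alt + out$n_other_conflict
    expect_true(all(inf <= prev_inf))
    prev_unin <- out$n_uninformative
    prev_inf <- inf
  }
})

test_that("concordance counts ignore gene-tree order", {
  sp <- make_species_tree(6, focal_length = 0.5, background = 2, seed = 91)
  obs <- make_observed_sample(sp, 60, error_prob = 0.2, seed = 92)
  a <- concordance_summary(sp, obs)
  b <- concordance_summary(sp, phyloconflict:::with_seed(3, sample(obs$trees)))
  expect_equal(a[order(a$split), ], b[order(b$split), ], ignore_attr = TRUE)
})

test_that("classification agrees with an independent split comparison", {
  sp <- make_species_tree(7, focal_length = 0.2, background = 1, seed = 95)
  g <- simulate_gene_trees(sp, 40, seed = 96)
  taxa <- sp$tip.label
  clades <- phyloconflict:::tree_clades(sp)
  for (b in bipartitions(sp)) {
    side <- NULL
    for (v in seq_along(clades)) {
      s <- clades[[v]]
      if (length(s) >= 2 && length(s) <= length(taxa) - 2 &&
          phyloconflict:::canonical_split(s, taxa) == b) side <- s
    }
    for (tr in g$trees[1:15]) {
      cl <- classify_gene_tree(side, tr, taxa, support_threshold = 0)
      # oracle: concordant iff the canonical split string occurs among
      # prop.part-derived splits; conflict otherwise (full overlap data)
      status <- if (b %in% oracle_splits(tr)) "concordant" else "conflict"
      expect_equal(cl$status, status)
    }
  }
})
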