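test_that("parse_newick reads leaves, lengths and supports", {
  tr <- parse_newick("(A,B);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_null(tr$edge.length)

  tr2 <- parse_newick("((A:1,B:1)90:0.5,C:1.5);")
  expect_equal(sort(tr2$tip.label), c("A", "B", "C"))
  sup <- suppressWarnings(as.numeric(tr2$node.label))
  expect_true(90 %in% sup)
  internal_edge <- which(tr2$edge[, 2] > length(tr2$tip.label))
  expect_equal(tr2$edge.length[internal_edge], 0.5)
})

test_that("parse_newick rejects malformed input with informative errors", {
  expect_error(parse_newick("(A,B)"), "must end in ';'")
  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick("(A,B));"), "offset")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
})

test_that("write/parse round trip preserves topology, lengths and supports", {
  for (seed in 1:50) {
    tr <- random_support_tree(sample(4:12, 1), seed = seed)
    rt <- parse_newick(write_newick(tr))
    expect_identical(bipartitions(rt), bipartitions(tr))
    m <- match(paste(rt$edge[, 1], rt$edge[, 2]),
               paste(tr$edge[, 1], tr$edge[, 2]))
    expect_true(all(abs(sort(rt$edge.length) - sort(tr$edge.length)) < 1e-9))
    expect_identical(sort(rt$node.label), sort(tr$node.label))
  }
})

test_that("collapse_low_support contracts exactly the weak branches", {
  tr <- parse_newick("((((A:1,B:1)10:1,C:1)90:1,(D:1,E:1)15:1)80:1,F:1);")
  expect_identical(collapse_low_support(tr, 5), tr)  # nothing below 5

  out <- collapse_low_support(tr, 20)
  expect_equal(length(bipartitions(out)), length(bipartitions(tr)) - 2L)
  expect_true("D,E,F" %in% bipartitions(out))    # the ABC split survives
  expect_false("D,E" %in% bipartitions(out))     # the weak DE split is gone
  # contracted lengths are pushed onto the children: root-to-tip paths stay
  expect_equal(phyloconflict:::root_to_tip_lengths(out)[tr$tip.label],
               phyloconflict:::root_to_tip_lengths(tr)[tr$tip.label],
               tolerance = 1e-12)
})

test_that("collapsing a fully unsupported tree yields a star", {
  tr <- parse_newick("(((A:1,B:1)0:1,(C:1,D:1)0:1)0:1,E:1);")
  star <- collapse_low_support(tr, 20)
  expect_length(bipartitions(star), 0)
  expect_equal(star$Nnode, 1L)
})

test_that("collapse threshold must sit on the detected support scale", {
  tr <- parse_newick("(((A:1,B:1)0.9:1,C:1)0.5:1,D:1);")  # proportions
  expect_error(collapse_low_support(tr, 150), "outside")
  out <- collapse_low_support(tr, 60)  # read as 0.6 on proportion scale
  expect_equal(length(bipartitions(out)), 1L)
})

test_that("bipartitions counts splits correctly", {
  expect_identical(bipartitions(parse_newick("((A,B),(C,D));")), "C,D")
  expect_length(bipartitions(parse_newick("(A,B,C,D,E);")), 0)
  tr7 <- random_support_tree(7, seed = 3)
  expect_length(bipartitions(tr7), 4L)  # n - 3
  # agreement with an independent split extraction
  for (seed in 4:8) {
    tr <- random_support_tree(sample(5:9, 1), seed = seed)
    expect_identical(bipartitions(tr), oracle_splits(tr))
  }
})

test_that("prune_to takes induced subtrees and sums suppressed edges", {
  tr <- parse_newick("(((A:1,B:2):3,C:4):5,D:6);")
  same <- prune_to(tr, c("A", "B", "C", "D"))
  expect_identical(bipartitions(same), bipartitions(tr))

  sub <- prune_to(tr, c("A", "C", "D"))
  expect_setequal(sub$tip.label, c("A", "C", "D"))
  # A-side edge absorbs the suppressed cherry edge: 1 + 3 = 4
  a_edge <- sub$edge.length[sub$edge[, 2] == which(sub$tip.label == "A")]
  expect_equal(a_edge, 4)

  two <- prune_to(tr, c("A", "D"))
  expect_equal(sum(two$edge.length), 1 + 3 + 5 + 6)

  expect_error(prune_to(tr, c("A", "Z", "Q")), "Z")
})

test_that("outgroup rooting preserves splits and path lengths", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  for (og in list("A", c("A", "B"), c("D", "E"))) {
    rooted <- root_with_outgroup(tr, og)
    expect_identical(bipartitions(rooted), bipartitions(tr))
    expect_equal(ape::cophenetic.phylo(rooted)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12)
  }
  expect_error(root_with_outgroup(tr, c("A", "C")), "monophyletic")
  expect_error(root_with_outgroup(tr, tr$tip.label), "proper")
})

test_that("rooting an ultrametric tree by its outgroup equalizes root-to-tip", {
  tr <- make_species_tree(6, seed = 5)
  root_child <- tr$edge[which(tr$edge[, 1] == 7L)[1], 2]
  og_side <- phyloconflict:::tree_clades(tr)[[root_child]]
  rooted <- root_with_outgroup(ape::unroot(tr), og_side)
  r2t <- phyloconflict:::root_to_tip_lengths(rooted)
  expect_lt(diff(range(r2t)), 1e-9)
})

test_that("pruning commutes with collapsing away from the pruned taxa", {
  for (seed in 11:15) {
    tr <- random_support_tree(8, seed = seed)
    keep <- tr$tip.label[1:6]
    a <- prune_to(collapse_low_support(tr, 20), keep)
    b <- collapse_low_support(prune_to(tr, keep), 20)
    # identical unless a collapsed branch bordered the pruned taxa; both
    # orders must at least agree on the surviving well-supported splits
    expect_true(all(bipartitions(a) %in% bipartitions(prune_to(tr, keep))))
    expect_true(all(bipartitions(b) %in% bipartitions(prune_to(tr, keep))))
  }
})
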