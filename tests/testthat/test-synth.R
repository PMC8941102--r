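test_that("make_species_tree places one focal branch among background ones", {
  sp <- make_species_tree(7, focal_length = 0.06, background = 4, seed = 1)
  ntip <- 7
  internal_lens <- sp$edge.length[sp$edge[, 2] > ntip]
  expect_length(internal_lens, 5)
  expect_equal(sum(abs(internal_lens - 0.06) < 1e-12), 1)
  expect_equal(sum(abs(internal_lens - 4) < 1e-12), 4)
  # ultrametric in coalescent time
  r2t <- phyloconflict:::root_to_tip_lengths(sp)
  expect_lt(diff(range(r2t)), 1e-9)
  expect_equal(branch_units(sp), "coalescent")
  expect_true(attr(sp, "focal_split") %in% bipartitions(sp))
})

test_that("a 4-taxon species tree has a single focal internal branch", {
  for (seed in 2:4) {
    sp <- make_species_tree(4, focal_length = 0.5, seed = seed)
    expect_length(bipartitions(sp), 1)
    # the single unrooted internal branch carries the focal length
    un <- ape::unroot(sp)
    internal_len <- un$edge.length[un$edge[, 2] > 4]
    expect_equal(internal_len, 0.5)
  }
})

test_that("seeds change the arrangement but not the length multiset", {
  a <- make_species_tree(7, seed = 10)
  b <- make_species_tree(7, seed = 20)
  la <- sort(a$edge.length[a$edge[, 2] > 7])
  lb <- sort(b$edge.length[b$edge[, 2] > 7])
  expect_equal(la, lb)
  expect_identical(make_species_tree(7, seed = 10)$edge, a$edge)
})

test_that("an error-free observed sample is indistinguishable from the MSC", {
  sp <- make_species_tree(5, focal_length = 0.4, background = 2, seed = 31)
  obs <- make_observed_sample(sp, 1500, error_prob = 0, seed = 32)
  ref <- simulate_gene_trees(sp, 1500, seed = 33)
  so <- spectrum_of(obs)
  sr <- spectrum_of(ref)
  cats <- union(names(so$counts), names(sr$counts))
  co <- ifelse(is.na(so$counts[cats]), 0L, so$counts[cats])
  cr <- ifelse(is.na(sr$counts[cats]), 0L, sr$counts[cats])
  keep <- co + cr >= 10  # chi-square over the well-filled categories
  suppressWarnings(p <- chisq.test(rbind(co[keep], cr[keep]))$p.value)
  expect_gt(p, 0.01)
  # and the coalescent-time invariant still holds
  expect_true(all(obs$coalescence_heights[, ncol(obs$coalescence_heights)] > 0))
})

test_that("full NNI noise destroys the concordance signal", {
  sp <- make_species_tree(4, focal_length = 1.5, seed = 41)
  clean <- make_observed_sample(sp, 800, error_prob = 0, seed = 42)
  noisy <- make_observed_sample(sp, 800, error_prob = 1, seed = 42)
  key <- topology_key(sp)
  f_clean <- spectrum_of(clean)$counts[key] / 800
  f_noisy <- spectrum_of(noisy)$counts[key] / 800
  expect_gt(f_clean, concordance_prob(1.5) - 0.06)
  expect_lt(f_noisy, f_clean - 0.1)
})

test_that("perturbed branches get low supports, clean branches high ones", {
  sp <- make_species_tree(7, focal_length = 0.5, background = 3, seed = 51)
  obs <- make_observed_sample(sp, 120, error_prob = 0.4, seed = 52)
  sup <- unlist(lapply(obs$trees, function(tr) {
    s <- suppressWarnings(as.numeric(tr$node.label))
    s[is.finite(s)]
  }))
  expect_true(all(sup >= 0 & sup <= 100))
  expect_gt(mean(sup >= 70), 0.3)  # high component present
  expect_gt(mean(sup <= 50), 0.1)  # low component present
  # collapsing at 20% removes some but not all branches
  collapsed <- collapse_low_support(obs$trees[[1]], 20)
  expect_lte(length(bipartitions(collapsed)),
             length(bipartitions(obs$trees[[1]])))
})

test_that("clock fixtures honor their rate-variance grid", {
  sp <- make_species_tree(6, seed = 61)
  fix <- make_clock_fixture(sp, rate_var_grid = c(0, 0, 0.4), seed = 62)
  for (g in 1:2) {
    r2t <- phyloconflict:::root_to_tip_lengths(fix$trees[[g]])
    expect_lt(diff(range(r2t)), 1e-9)  # zero variance -> ultrametric
  }
  r2t3 <- phyloconflict:::root_to_tip_lengths(fix$trees[[3]])
  expect_gt(diff(range(r2t3)), 1e-3)
  expect_equal(fix$truth$rate_var, c(0, 0, 0.4))
  again <- make_clock_fixture(sp, rate_var_grid = c(0, 0, 0.4), seed = 62)
  expect_equal(sapply(again$trees, write_newick),
               sapply(fix$trees, write_newick))
})

test_that("Mk1 character simulation matches its transition probabilities", {
  # near-zero rate: everything inherits the root state
  sp <- make_species_tree(5, seed = 71)
  frozen <- make_mk1_characters(sp, rate = 1e-9, n_chars = 50, seed = 72)
  expect_true(all(apply(frozen, 2, function(col) length(unique(col)) == 1)))

  # two-tip tree: P(tip differs from the other) from the closed form
  two <- set_branch_units(parse_newick("(A:1,B:0.0001);"), "none")
  n <- 10000
  k <- 5
  r <- 0.3
  chars <- make_mk1_characters(two, rate = r, n_chars = n, k = k, seed = 73)
  p_same <- 1 / k + (k - 1) / k * exp(-k * r * 1.0001)
  obs_same <- mean(chars["A", ] == chars["B", ])
  expect_lt(abs(obs_same - p_same), 3 * sqrt(p_same * (1 - p_same) / n))

  expect_identical(chars, make_mk1_characters(two, rate = r, n_chars = n,
                                              k = k, seed = 73))
})
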