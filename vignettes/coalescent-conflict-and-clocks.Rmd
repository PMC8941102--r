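---
title: "Diagnosing gene-tree conflict and preparing relaxed-clock dating with phyloconflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing gene-tree conflict and preparing relaxed-clock dating with phyloconflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconflict)
```

## The problem this package addresses

Deep, rapid radiations leave a characteristic signature in phylogenomic
data: a species tree with one or more very short internal branches, and
hundreds of gene trees that disagree with each other and with the species
tree around exactly those branches. Ancient green algal radiations are a
canonical example — coalescent species trees of green seaweeds place some
of the deepest divergences on branches of a few hundredths of a
coalescent unit, with the three possible resolutions of each short branch
supported by roughly equal thirds of the gene trees.

Two very different processes can produce such conflict: genuine
biological gene-tree heterogeneity through incomplete lineage sorting
(ILS), or analytical artifacts (model misspecification, estimation
error). `phyloconflict` implements the simulation-based diagnostic for
the first explanation, the descriptive statistics used to localize
conflict, and the bespoke numerical components needed to set up a
downstream Bayesian relaxed-clock dating analysis on the genes least
affected by rate variation.

## The multispecies coalescent engine

Everything rests on the multispecies coalescent (MSC). Gene lineages are
traced backwards through a rooted species tree whose internal branch
lengths are measured in coalescent units (one unit = 2N generations).
Within a branch currently holding $k$ lineages, the waiting time to the
next coalescence is exponential with rate $k(k-1)/2$; a uniformly chosen
pair merges if the event falls inside the branch, and the survivors are
passed to the parent branch. Above the root, coalescence continues
without bound. One lineage enters per species by default (the setting of
interest here); a per-species allele map is accepted, in which case
terminal branch lengths are required.

The well-known closed form anchors everything: for an internal branch of
length $t$, a gene tree resolves the surrounding quartet concordantly
with probability

$$P(\text{concordant}) = 1 - \tfrac{2}{3} e^{-t},$$

and each discordant resolution has probability $(1/3)e^{-t}$.
`concordance_prob()` exposes this and the test suite holds the simulator
to it at $n = 50{,}000$ within three binomial standard errors for
$t \in \{0, 0.06, 0.5, 1, 3\}$. The simulator core is written in C++
(via Rcpp) because the ILS test consumes millions of simulated trees; it
draws from R's RNG stream, so every result is reproducible from a single
integer seed.

```{r msc-example}
sp <- set_branch_units(parse_newick("((A:1,B:1):0.5,(C:1,D:1):0);"),
                       "coalescent")
simulate_topology_counts(sp, 20000, seed = 1)
concordance_prob(0.5)
```

## The ILS test: topology-frequency correlation

`run_ils_test()` asks whether observed gene-tree conflict looks like what
the MSC alone would produce. It simulates a large sample (default
100,000) of gene trees from the species tree, tabulates canonical
unrooted topologies of both the observed and the simulated samples on
the union of their categories (zero-filled where absent), and computes
the Pearson correlation of the two frequency vectors, with a two-sided
p-value from the Student-t transform on (number of categories − 2)
degrees of freedom. A correlation near 1 says ILS can account for the
conflict; observed mass on topologies the MSC considers near-impossible
drives the correlation down.

Design choices worth knowing:

* **Topologies are compared unrooted** after restriction to the species
  taxon set. Observed gene trees are typically maximum-likelihood trees
  with no meaningful root; comparing rooted shapes would inject an
  arbitrary root. (`topology_key()` is the canonicalization: two trees
  key equally iff their nontrivial split sets are equal.)
* **The category space is the union of observed keys**, not the full
  $(2n-5)!!$ enumeration (945 topologies at $n = 7$). Frequency tables
  naturally yield the union; `full_space = TRUE` switches to the
  enumeration (available through `enumerate_topologies()`, guarded to
  $n \le 8$) for sensitivity analysis.
* **Frequencies, not counts, are correlated**, so the observed and
  simulated sample sizes need not match.

Under self-consistency — observed data truly drawn from the MSC on the
same species tree — the correlation should approach 1 as the observed
sample grows. The acceptance suite runs exactly this experiment at the
study scale: a 7-taxon species tree with one focal branch of 0.06
coalescent units among 4-unit branches, observed samples of 891 and 1280
trees against 100,000 simulated, 20 replicate seed pairs. Median
correlations land around 0.999, comfortably above the 0.994/0.997
reference values for real data of those sizes.

## Localizing conflict: quartet supports and concordance classes

`quartet_support()` computes, for an internal species-tree branch, the
normalized frequencies $(q_1, q_2, q_3)$ of the three unrooted
arrangements of the four taxon clusters surrounding the branch, pooled
over every resolved quartet observation in every gene tree ($q_1$ is the
species-tree arrangement). Pooling follows quartet-count semantics:
each resolved quartet in each gene tree counts once; quartets left
unresolved by polytomies are skipped, not fractionally allocated, and
gene trees missing taxa contribute only the quartets they contain.
Per-branch sweeps come from `all_branch_supports()`. The implementation
uses bitmask split algebra and is limited to 31 taxa; the brute-force
oracle in the test suite (prune to each quartet, classify) checks it
exactly on every fixture.

`concordance_summary()` reproduces the pie-chart decomposition of
bipartition-mapping tools: at each species-tree node, each gene tree is
**concordant** (contains the identical restricted split at or above the
support threshold, default 50%), a **conflict** (contains an
incompatible split — all four pairwise side-intersections nonempty — at
or above the threshold), or **uninformative** (low support, missing
taxa, or polytomy). Conflicts are further divided into the modal
conflicting split (the "top alternative") and the rest. When one gene
tree contains several conflicting splits, the one with the highest
support represents it, with a lexicographic tie-break; this
split-level operationalization is what a bipartition mapping sees, and
it is deterministic. Support scales are auto-detected (values ≤ 1 are
proportions), and a branch with no support label anywhere always counts
as informative.

## Gene-tree cleaning

Gene-tree estimation error is handled the way species-tree pipelines
handle it: `collapse_low_support()` contracts every internal branch with
support strictly below a threshold (e.g. 20%), producing polytomies that
downstream statistics treat as unresolved rather than wrong. The
contracted branch length is added to the children's branches, so
root-to-tip path lengths are unchanged. All downstream code accepts
multifurcating trees.

## Selecting clock-like genes for dating

Relaxed-clock dating on hundreds of genes is expensive and sensitive to
among-lineage rate variation, so a standard step is to rank genes by
clock-likeness and date only the best. `gene_stats()` computes the three
criteria, and `rank_and_select()` applies them as a strict lexicographic
sort, in this order:

1. **concordance** with the species tree (descending): the fraction of
   the gene tree's nontrivial splits, restricted to shared taxa, present
   in the species tree. A gene tree with no nontrivial splits after
   restriction is vacuously concordant (flagged with a warning) so the
   later criteria decide its fate.
2. **root-to-tip variance** (ascending), in (substitutions/site)²,
   computed after rooting. Rooting is a configuration choice —
   outgroup (with optional midpoint fallback), midpoint, or as-is —
   because gene trees from ML programs are unrooted and no single
   convention is canonical.
3. **tree length** (descending): longer trees carry more discernible
   signal, so among equally clock-like genes the more informative one
   ranks higher.

Ties beyond all three criteria break deterministically by gene id. The
alternative reading of "sequential" criteria — proportion-based
sequential filtering rather than a hierarchical sort — is deliberately
not the default; the hierarchical sort is the simplest faithful
composition of the three orderings and is what the tests pin down.

The synthetic clock fixture (`make_clock_fixture()`) draws per-branch
rates from a lognormal with gene-specific log-scale variance and
multiplies them onto an ultrametric time tree, so a gene's true
clock-likeness is known. On a 69-taxon tree (the size of a realistic
dating phylogeny) with 100 genes spanning rate variances 0–1, the
selection order correlates with the true variance at Spearman ≈ 0.85.
With very few taxa the root-to-tip variance estimator itself is too
noisy for any ranking method to do much better than chance ordering
among similar genes — a real limitation of the statistic, not of the
implementation, and the reason the fixture uses a realistically sized
tree.

## Fossil-calibration densities and dating hyperpriors

The dating setup (the MCMC itself is out of scope) needs three bespoke
numerical pieces, all in time units of 100 My:

* **Soft-bounded uniform calibrations** (`uniform_soft_density()`):
  constant density on $[t_L, t_U]$, a power-decay left tail on
  $(0, t_L)$ carrying mass $p_L$, and an exponential right tail carrying
  mass $p_U$, each matched continuously to the plateau — the convention
  of established dating software. A tail mass of $10^{-300}$ encodes a
  hard bound; numerically, any mass below $10^{-10}$ is treated as hard
  (the power exponent would overflow long before that). Closed-form CDF
  and quantile functions drive inverse-CDF sampling
  (`sample_calibration()`), and quadrature in the tests confirms unit
  mass and exact tail masses to $10^{-6}$.
* **Minimum-truncated Cauchy calibrations** (`cauchy_min_density()`):
  location $t_L(1+p)$, scale $c\,t_L$, truncated to $(t_L, \infty)$ and
  renormalized, with a hard minimum. Defaults $p = 0.1$, $c = 1$ follow
  the cited tool's conventions; the source analyses do not print the
  values they used, so these are documented defaults, not assertions.
* **The gamma rate hyperprior** (`derive_rate_prior()`): the mean branch
  rate is a pairwise distance divided by a calibrating age; the gamma
  prior keeps the requested shape and sets its rate so the mean comes
  out right. The canonical worked example: distance 0.3581
  substitutions/site over 10 time units with shape 2 gives
  $G(2, 55.85)$ with mean 0.03581 substitutions/site per 100 My.
  The rate-variance hyperprior $G(1, 10)$ (mean 0.1) and the sampling
  fraction $\rho = 65/6478 \approx 0.01$ are one-liners
  (`gamma_prior()`, `sampling_fraction()`), kept as named, tested
  functions because they are exactly the quantities a dating
  configuration must reproduce.

A bundled plain-text table
(`system.file("extdata", "calibrations.tsv", package = "phyloconflict")`)
encodes eight calibration nodes and three calibration strategies that
differ only in where — or whether — a 1000-My fossil minimum is
attached (stem of a terminal order, stem of the larger clade, or
excluded). `load_calibration_table(strategy = )` returns the active
specifications: 8, 8, and 7 records respectively.

## Mk1 ancestral-state reconstruction

Cytomorphological evolution (unicellular, colonial, siphonous,
multicellular, siphonocladous — states 0–4) is modeled with the
symmetric k-state, one-parameter Markov model. Transition probabilities
are closed-form, $P_{ii}(t) = 1/k + \frac{k-1}{k}e^{-krt}$ and
$P_{ij}(t) = 1/k - \frac{1}{k}e^{-krt}$; the root distribution is the
model's uniform stationary distribution. `mk1_loglik()` is Felsenstein
pruning (missing tips contribute all-ones partials), `fit_mk1()`
maximizes the single rate, and `marginal_states()` computes marginal
posterior state probabilities at every internal node by an
inside–outside two-pass.

Numerical notes:

* The rate search runs on the **log scale** across the bounds
  $[10^{-8}, 10^3]$ (tolerance $10^{-8}$): the likelihood profile's peak
  is narrow relative to six decades of rate, and a linear golden-section
  search demonstrably walks past it onto the saturated plateau.
* With all observed tips in one state the rate is unidentifiable (the
  profile decreases monotonically); the lower bound is returned with a
  warning.
* The branch lengths used for reconstruction are a user decision — the
  guide phylogeny for such analyses is typically a coalescent tree whose
  lengths are not substitution lengths — so the functions require
  explicit lengths and the fixtures document their own choices.

Both the pruning likelihood and the marginals are tested against full
enumeration over ancestral-state assignments on every tree up to six
tips, and the transition matrix against the matrix exponential of the
generator. Parameter recovery from 500 simulated characters lands within
a few percent of the true rate in an informative regime (tree depth ≲ 1
expected change per state); the 20% acceptance tolerance is generous.

## The synthetic-data generators, and what they do not emulate

`make_species_tree()` builds the deep-radiation study condition: a
random rooted topology with all internal branches at a background length
(default 4 coalescent units — essentially conflict-free) except one
focal branch (default 0.06 — heavy ILS), terminal branches aligned so
the tree is ultrametric in coalescent time. `make_observed_sample()`
adds gene-tree estimation error: each internal branch of each simulated
gene tree is hit by a random nearest-neighbor interchange with
probability ε, perturbed branches draw supports from a low component
(Uniform(0, 50)), untouched branches from a high one (Uniform(70, 100)).
This exercises the 20% collapse and 50% concordance thresholds with a
controllable error rate.

What the generators deliberately do **not** emulate: sequence-level
estimation error (no alignment simulation and re-inference), correlated
error across branches, support values with realistic bootstrap
distributions, missing-taxon patterns of real transcriptome matrices,
and any non-ILS source of discordance (hybridization, paralogy).
Passing tests therefore show that the statistics do what they claim on
MSC-plus-NNI data; they do not show that ILS is the only explanation a
real dataset could admit.

## Problem sizes and determinism

The default test and acceptance runs use the study-scale sizes where
they matter (100,000 simulated trees per ILS replicate, 50,000-tree
closed-form checks, 891/1280 observed trees, 500 characters, 100 genes
on a 69-taxon tree) and small fixtures everywhere correctness is the
question. Every stochastic function takes an integer seed, routes it
through a single RNG stream, and restores the caller's RNG state, so
identical seeds give bit-identical results and the seed of every
reported quantity is recorded alongside it.

## Known limitations

* Quartet supports and topology tabulation use 32-bit split masks:
  at most 31 taxa. Concordance classification and clock ranking have no
  such limit.
* The ILS test's p-value treats topology categories as independent
  observations, as the underlying correlation test does; with few
  categories it is a rough guide, and the effect size (r) is the
  quantity to interpret.
* Polytomous observed topologies form their own categories in the
  spectrum rather than being distributed over their resolutions.
* The dating MCMC, approximate-likelihood machinery, and birth–death
  hyperparameter estimation are out of scope by design; this package
  produces their inputs.
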