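## Topology-frequency correlation test for incomplete lineage sorting.
##
## A large gene-tree sample is simulated under the multispecies coalescent
## from the species tree; the topology-frequency spectrum of the observed
## gene trees is compared with the simulated spectrum by Pearson
## correlation over the union of topology categories. A correlation close
## to 1 indicates that ILS alone can account for the observed gene-tree
## conflicts.

#' Pearson correlation with a Student-t p-value
#'
#' The sample Pearson correlation of `x` and `y` with the two-sided
#' p-value from the transform `t = r * sqrt((m - 2) / (1 - r^2))` on
#' `m - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return list with `estimate` (r), `statistic` (t), `df`, `p.value`.
#' @export
pearson_cor_test <- function(x, y) {
  if (length(x) != length(y)) {
    stop_pc("x and y must have equal length", class = "pc_validation_error")
  }
  m <- length(x)
  if (m < 3L) {
    stop_pc("need at least 3 paired observations", class = "pc_validation_error")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_pc("missing values are not allowed", class = "pc_validation_error")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop_pc("correlation is undefined for a constant vector",
            class = "pc_degenerate_error")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  df <- m - 2L
  if (abs(r) == 1) {
    tstat <- Inf * sign(r)
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
  }
  list(estimate = r, statistic = tstat, df = df, p.value = p)
}

## Topology keys of observed gene trees on the species taxon set.
observed_keys <- function(observed, taxa, prune = TRUE) {
  if (inherits(observed, "gene_tree_sample")) observed <- observed$trees
  if (inherits(observed, "phylo")) observed <- list(observed)
  keys <- character(0)
  dropped <- 0L
  for (tr in observed) {
    tips <- tr$tip.label
    if (!all(taxa %in% tips)) { dropped <- dropped + 1L; next }
    if (length(tips) > length(taxa)) {
      if (!prune) { dropped <- dropped + 1L; next }
      tr <- prune_to(tr, taxa)
    }
    keys <- c(keys, topology_key(tr))
  }
  if (dropped > 0L) {
    message(dropped, " observed tree(s) dropped (missing taxa)")
  }
  keys
}

#' Test whether observed gene-tree discordance is consistent with ILS
#'
#' Simulates `n_sim` gene trees under the multispecies coalescent from
#' `species_tree`, tabulates unrooted topology frequencies of the
#' simulated and the observed samples on the union of their topology
#' categories (zero-filled where absent), and correlates the two
#' frequency vectors with [pearson_cor_test()].
#'
#' @param species_tree rooted `phylo` with coalescent-unit branch lengths.
#' @param observed observed gene trees (`multiPhylo`, list, or
#'   `gene_tree_sample`); trees with extra taxa are pruned, trees missing
#'   taxa dropped.
#' @param n_sim number of simulated gene trees (default 100000).
#' @param seed integer seed for the simulation.
#' @param full_space if `TRUE`, use all enumerated unrooted binary
#'   topologies as the category space (taxa <= 8) instead of the union of
#'   observed categories.
#' @return an `ils_test` object: list with `pearson_r`, `p_value`,
#'   `statistic`, `df`, `n_obs`, `n_sim`, `seed`, `categories`, and the
#'   paired frequency table `freq` (columns `key`, `observed`,
#'   `simulated`).
#' @export
run_ils_test <- function(species_tree, observed, n_sim = 100000,
                         seed = NULL, full_space = FALSE) {
  if (!is_count(n_sim) || n_sim < 1000) {
    stop_pc("n_sim must be an integer >= 1000", class = "pc_validation_error")
  }
  taxa <- sort(species_tree$tip.label)
  obs_keys <- observed_keys(observed, taxa)
  n_obs <- length(obs_keys)
  if (n_obs == 0L) {
    stop_pc("no usable observed trees", class = "pc_validation_error")
  }
  sim_spec <- simulate_topology_counts(species_tree, n_sim, seed = seed)
  obs_tab <- table(obs_keys)
  cats <- sort(union(names(sim_spec$counts), names(obs_tab)))
  if (full_space) {
    cats <- sort(union(cats, enumerate_topologies(taxa)))
  }
  if (length(cats) < 3L) {
    stop_pc("fewer than 3 topology categories; correlation is degenerate",
            class = "pc_degenerate_error")
  }
  obs_f <- as.numeric(obs_tab[cats]) / n_obs
  obs_f[is.na(obs_f)] <- 0
  sim_f <- as.numeric(sim_spec$counts[cats]) / sim_spec$n_total
  sim_f[is.na(sim_f)] <- 0
  ct <- pearson_cor_test(obs_f, sim_f)
  structure(list(pearson_r = ct$estimate,
                 p_value = ct$p.value,
                 statistic = ct$statistic,
                 df = ct$df,
                 n_obs = n_obs,
                 n_sim = n_sim,
                 seed = seed,
                 categories = cats,
                 freq = data.frame(key = cats, observed = obs_f,
                                   simulated = sim_f,
                                   stringsAsFactors = FALSE)),
            class = "ils_test")
}

#' @export
print.ils_test <- function(x, ...) {
  cat("ILS topology-frequency correlation test\n")
  cat(sprintf("  observed trees: %d; simulated trees: %d; categories: %d\n",
              x$n_obs, x$n_sim, length(x$categories)))
  cat(sprintf("  Pearson r = %.4f (t = %.2f, df = %d, p = %.3g)\n",
              x$pearson_r, x$statistic, x$df, x$p_value))
  cat("  r near 1 => ILS alone can account for the gene-tree conflicts\n")
  invisible(x)
}
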