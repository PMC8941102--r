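## Maximum-likelihood Mk1 (k-state, single-rate) ancestral-state
## reconstruction on a fixed tree.
##
## Under the symmetric k-state Markov model with a single exchange rate r,
## the transition probabilities along a branch of length t are
##   P_ii(t) = 1/k + (k-1)/k * exp(-k r t)
##   P_ij(t) = 1/k - 1/k * exp(-k r t),  i != j,
## and the stationary (and root) distribution is uniform. The default
## state coding follows the five cytomorphological types used for green
## algae: unicellular (0), colonial (1), siphonous (2), multicellular (3),
## siphonocladous (4).

#' Cytomorphology state labels
#' @export
MK_STATE_LABELS <- c("unicellular", "colonial", "siphonous",
                     "multicellular", "siphonocladous")

#' Mk1 model object
#'
#' @param k number of states (>= 2).
#' @param rate single exchange rate r (> 0).
#' @return an `mk_model`.
#' @export
mk_model <- function(k, rate) {
  if (!is_count(k) || k < 2) {
    stop_pc("k must be an integer >= 2", class = "pc_validation_error")
  }
  if (!is.numeric(rate) || rate <= 0) {
    stop_pc("rate must be positive", class = "pc_validation_error")
  }
  structure(list(k = as.integer(k), rate = rate), class = "mk_model")
}

#' Mk1 transition probability matrix
#'
#' @param model an `mk_model` (or `k`/`rate` given directly).
#' @param t branch length (>= 0).
#' @return k x k stochastic matrix.
#' @export
mk_transition_matrix <- function(model, t) {
  k <- model$k
  e <- exp(-k * model$rate * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

## Tip partial-likelihood matrix (k x n_char) for one taxon: a one-hot
## column per observed state, all-ones for missing data.
tip_partials <- function(states, k) {
  n_char <- length(states)
  L <- matrix(0, k, n_char)
  for (j in seq_len(n_char)) {
    if (is.na(states[j])) {
      L[, j] <- 1
    } else {
      L[states[j] + 1L, j] <- 1
    }
  }
  L
}

## Validate and align character data with the tree tips. `data` is a
## named integer vector (one character) or a taxa x characters matrix of
## state indices in 0..k-1, NA = missing.
align_states <- function(tree, data, k) {
  if (is.vector(data)) data <- matrix(data, ncol = 1,
                                      dimnames = list(names(data), NULL))
  if (is.null(rownames(data))) {
    stop_pc("character data must be named by taxon", class = "pc_validation_error")
  }
  extra <- setdiff(rownames(data), tree$tip.label)
  if (length(extra) > 0L) {
    stop_pc("character data for taxa not in tree: ",
            paste(extra, collapse = ", "), class = "pc_validation_error")
  }
  obs <- data[!is.na(data)]
  if (length(obs) > 0L && (any(obs < 0) || any(obs >= k))) {
    stop_pc("states must be integers in 0..k-1", class = "pc_validation_error")
  }
  full <- matrix(NA_integer_, length(tree$tip.label), ncol(data),
                 dimnames = list(tree$tip.label, colnames(data)))
  full[rownames(data), ] <- data
  full
}

## Post-order conditional likelihoods for all nodes; returns the list of
## k x n_char partial matrices plus the postorder edge table.
mk_down_pass <- function(tree, states, model) {
  if (is.null(tree$edge.length)) {
    stop_pc("tree has no branch lengths", class = "pc_missing_lengths")
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop_pc("all branch lengths must be present and non-negative",
            class = "pc_missing_lengths")
  }
  k <- model$k
  ntip <- length(tree$tip.label)
  n_char <- ncol(states)
  tr <- ape::reorder.phylo(tree, "postorder")
  partial <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) partial[[i]] <- tip_partials(states[i, ], k)
  ones <- matrix(1, k, n_char)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]
    ch <- tr$edge[e, 2L]
    P <- mk_transition_matrix(model, tr$edge.length[e])
    msg <- P %*% partial[[ch]]
    if (is.null(partial[[p]])) partial[[p]] <- ones
    partial[[p]] <- partial[[p]] * msg
  }
  list(partial = partial, tr = tr)
}

#' Mk1 log-likelihood of discrete character data on a tree
#'
#' Felsenstein pruning with uniform root frequencies 1/k; missing tips
#' contribute an all-ones partial vector. Multiple characters (columns)
#' are summed.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param data named vector (taxon -> state in 0..k-1) or taxa x
#'   characters matrix; NA = missing.
#' @param model an `mk_model`.
#' @return total log-likelihood.
#' @export
mk1_loglik <- function(tree, data, model) {
  assert_phylo(tree)
  states <- align_states(tree, data, model$k)
  dp <- mk_down_pass(tree, states, model)
  root <- length(tree$tip.label) + 1L
  site_lik <- colSums(dp$partial[[root]]) / model$k
  sum(log(site_lik))
}

#' Maximum-likelihood fit of the Mk1 rate
#'
#' Bounded scalar maximization of [mk1_loglik()] over r in
#' `[1e-8, 1e3]` (tolerance 1e-8). With all observed tips in a single
#' state the rate is unidentifiable (the profile is monotone decreasing)
#' and the lower bound is returned with a warning.
#'
#' @inheritParams mk1_loglik
#' @param k number of states; default 5 (the cytomorphology coding), or
#'   the smallest k covering the observed states if larger.
#' @return an `mk_model` with the fitted rate; the maximized
#'   log-likelihood is attached as attribute `"loglik"`.
#' @export
fit_mk1 <- function(tree, data, k = 5) {
  if (is.vector(data)) data <- matrix(data, ncol = 1,
                                      dimnames = list(names(data), NULL))
  obs <- data[!is.na(data)]
  k <- max(k, max(obs) + 1L)
  if (length(unique(obs)) < 2L) {
    warning("all observed states identical; rate is unidentifiable, ",
            "returning the lower bound")
    model <- mk_model(k, 1e-8)
    attr(model, "loglik") <- mk1_loglik(tree, data, model)
    return(model)
  }
  ## search on the log scale: the profile peak is narrow relative to the
  ## six-decade bound range and a linear golden-section would overlook it
  f <- function(lr) mk1_loglik(tree, data, mk_model(k, exp(lr)))
  opt <- optimize(f, interval = log(c(1e-8, 1e3)), maximum = TRUE, tol = 1e-8)
  model <- mk_model(k, exp(opt$maximum))
  attr(model, "loglik") <- opt$objective
  model
}

#' Marginal ancestral-state probabilities at internal nodes
#'
#' Two-pass (inside/outside) computation of the marginal posterior state
#' distribution at every internal node, conditioning on all tip data,
#' with uniform root frequencies.
#'
#' @inheritParams mk1_loglik
#' @param data a single character: named vector taxon -> state.
#' @return matrix (internal nodes x k) of probabilities, rows summing to
#'   1; row names are ape node ids.
#' @export
marginal_states <- function(tree, data, model) {
  assert_phylo(tree)
  states <- align_states(tree, data, model$k)
  if (ncol(states) != 1L) {
    stop_pc("marginal reconstruction takes a single character",
            class = "pc_validation_error")
  }
  k <- model$k
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  dp <- mk_down_pass(tree, states, model)
  partial <- lapply(dp$partial, function(m) m[, 1L])
  tr <- dp$tr
  nnode_total <- ntip + tree$Nnode
  ## outside pass, preorder: above[v] = prob of data outside v's subtree
  ## given the state at v
  above <- vector("list", nnode_total)
  above[[root]] <- rep(1 / k, k)
  edges_pre <- rev(seq_len(nrow(tr$edge)))
  children <- split(tr$edge[, 2L], tr$edge[, 1L])
  Pmat <- lapply(seq_len(nrow(tr$edge)), function(e) {
    mk_transition_matrix(model, tr$edge.length[e])
  })
  msg_up <- lapply(seq_len(nrow(tr$edge)), function(e) {
    as.numeric(Pmat[[e]] %*% partial[[tr$edge[e, 2L]]])
  })
  edge_of_child <- integer(nnode_total)
  edge_of_child[tr$edge[, 2L]] <- seq_len(nrow(tr$edge))
  for (e in edges_pre) {
    u <- tr$edge[e, 1L]
    v <- tr$edge[e, 2L]
    sib_msgs <- rep(1, k)
    for (w in children[[as.character(u)]]) {
      if (w == v) next
      sib_msgs <- sib_msgs * msg_up[[edge_of_child[w]]]
    }
    at_u <- above[[u]] * sib_msgs
    above[[v]] <- as.numeric(t(Pmat[[e]]) %*% at_u)
  }
  internal <- seq.int(root, nnode_total)
  out <- matrix(NA_real_, length(internal), k,
                dimnames = list(internal,
                                if (k == 5L) MK_STATE_LABELS else
                                  paste0("state", seq_len(k) - 1L)))
  for (i in seq_along(internal)) {
    v <- internal[i]
    m <- partial[[v]] * above[[v]]
    out[i, ] <- m / sum(m)
  }
  out
}

#' Annotate a tree with most-probable ancestral states
#'
#' @inheritParams marginal_states
#' @return the tree with node labels set to the most probable state label
#'   at each internal node.
#' @export
annotate_ancestral_states <- function(tree, data, model) {
  marg <- marginal_states(tree, data, model)
  lab <- colnames(marg)[max.col(marg, ties.method = "first")]
  tree$node.label <- lab
  attr(tree, "node_labels_are") <- "label"
  tree
}
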