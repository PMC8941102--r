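#' @useDynLib phyloconflict, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize pt runif var rlnorm dcauchy pcauchy qcauchy
#'   integrate setNames
#' @importFrom utils read.delim
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All exported stochastic functions route through this so that
## a `seed` argument is both reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_pc <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "phyloconflict_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

assert_phylo <- function(tree, arg = "tree") {
  if (!inherits(tree, "phylo")) {
    stop_pc(sprintf("`%s` must be a 'phylo' object", arg),
            class = "pc_type_error")
  }
  invisible(tree)
}

## Branch-length unit bookkeeping ("coalescent", "subst", "t100My", "none").
#' Get or set the branch-length units recorded on a tree
#'
#' Units are carried as an attribute on the `phylo` object and checked by
#' operations that are only meaningful on one scale (e.g. coalescent
#' simulation requires `"coalescent"`).
#'
#' @param tree a `phylo` object.
#' @param units one of `"coalescent"`, `"subst"`, `"t100My"`, `"none"`.
#' @return `set_branch_units()` returns the tree with the attribute set;
#'   `branch_units()` returns the current unit string (default `"none"`).
#' @export
set_branch_units <- function(tree, units = c("coalescent", "subst",
                                             "t100My", "none")) {
  assert_phylo(tree)
  units <- match.arg(units)
  attr(tree, "units") <- units
  tree
}

#' @rdname set_branch_units
#' @export
branch_units <- function(tree) {
  attr(tree, "units") %||% "none"
}

## Support values live in node labels (the Newick convention for
## bootstrap/posterior annotations). Numeric labels parse as supports,
## non-numeric labels give NA.
tree_support_values <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(lab))
}

## Detect whether supports are proportions (all <= 1) or percentages, and
## put `threshold` on the same scale as `values`.
match_support_scale <- function(values, threshold) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) return(threshold)
  scale <- if (all(v <= 1)) "probability" else "percent"
  if (scale == "probability" && threshold > 1) threshold <- threshold / 100
  if (scale == "percent" && threshold <= 1) threshold <- threshold * 100
  threshold
}
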