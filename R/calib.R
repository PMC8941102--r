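## Fossil-calibration densities and dating hyperpriors.
##
## Two calibration families are supported, following the conventions of
## Bayesian relaxed-clock dating software:
##
## * soft-bounded uniform on [tL, tU]: constant density between the
##   bounds; a power-decay left tail on (0, tL) carrying mass pL and an
##   exponential right tail on (tU, Inf) carrying mass pU, each matched
##   continuously to the plateau. A tail mass <= 1e-10 is treated as a
##   hard bound (zero density beyond it).
## * minimum-truncated Cauchy: location tL(1+p), scale c*tL, truncated to
##   (tL, Inf) and renormalized; the minimum is hard.
##
## Ages are expressed in units of 100 My throughout.

HARD_EPS <- 1e-10

#' Construct a node-calibration specification
#'
#' @param node node label.
#' @param family `"uniform"` (soft-bounded uniform), `"cauchy_min"`
#'   (minimum-truncated Cauchy) or `"none"`.
#' @param tL minimum age (100-My units; required).
#' @param tU maximum age (uniform only).
#' @param pL,pU lower/upper tail masses in `[0, 0.5)`; a mass of 1e-300
#'   encodes a hard bound.
#' @param p,c Cauchy location offset and scale multipliers (defaults 0.1
#'   and 1).
#' @return a `calibration_spec`.
#' @export
calibration_spec <- function(node, family = c("uniform", "cauchy_min", "none"),
                             tL = NA, tU = NA, pL = 0.025, pU = 0.025,
                             p = 0.1, c = 1) {
  family <- match.arg(family)
  if (family != "none") {
    if (!is.finite(tL) || tL <= 0) {
      stop_pc("tL must be a positive age", class = "pc_validation_error")
    }
  }
  if (family == "uniform") {
    if (!is.finite(tU)) {
      stop_pc("uniform calibrations need a maximum age tU",
              class = "pc_validation_error")
    }
    if (tU <= tL) {
      stop_pc("tU must exceed tL", class = "pc_validation_error")
    }
    for (pm in c(pL, pU)) {
      if (!is.finite(pm) || pm < 0 || pm >= 0.5) {
        stop_pc("tail masses must lie in [0, 0.5)", class = "pc_validation_error")
      }
    }
  }
  structure(list(node = node, family = family, tL = tL, tU = tU,
                 pL = pL, pU = pU, p = p, c = c),
            class = "calibration_spec")
}

#' Soft-bounded uniform calibration density
#'
#' @param t age(s) in 100-My units, `> 0`.
#' @param spec a `calibration_spec` with `family == "uniform"`.
#' @return density values; the function integrates to 1 over (0, Inf).
#' @export
uniform_soft_density <- function(t, spec) {
  stopifnot(inherits(spec, "calibration_spec"), spec$family == "uniform")
  if (any(t <= 0)) {
    stop_pc("ages must be positive", class = "pc_validation_error")
  }
  hard_L <- spec$pL <= HARD_EPS
  hard_U <- spec$pU <= HARD_EPS
  pL <- if (hard_L) 0 else spec$pL
  pU <- if (hard_U) 0 else spec$pU
  h <- (1 - pL - pU) / (spec$tU - spec$tL)
  d <- numeric(length(t))
  mid <- t >= spec$tL & t <= spec$tU
  d[mid] <- h
  lo <- t < spec$tL
  if (any(lo) && !hard_L) {
    theta <- h * spec$tL / pL
    d[lo] <- h * exp((theta - 1) * (log(t[lo]) - log(spec$tL)))
  }
  hi <- t > spec$tU
  if (any(hi) && !hard_U) {
    lambda <- h / pU
    d[hi] <- h * exp(-lambda * (t[hi] - spec$tU))
  }
  d
}

#' Minimum-truncated Cauchy calibration density
#'
#' @param t age(s) in 100-My units.
#' @param spec a `calibration_spec` with `family == "cauchy_min"` and
#'   `tL > 0`.
#' @return density values; zero at and below the hard minimum, mode at
#'   `tL * (1 + p)`, integrating to 1 over `(tL, Inf)`.
#' @export
cauchy_min_density <- function(t, spec) {
  stopifnot(inherits(spec, "calibration_spec"), spec$family == "cauchy_min")
  A <- spec$tL * (1 + spec$p)
  s <- spec$c * spec$tL
  Z <- 1 - pcauchy(spec$tL, location = A, scale = s)
  d <- numeric(length(t))
  above <- t > spec$tL
  d[above] <- dcauchy(t[above], location = A, scale = s) / Z
  d
}

#' Calibration density, CDF and quantile function
#'
#' Dispatch on the spec's family. The quantile function inverts the CDF
#' in closed form and drives [sample_calibration()].
#'
#' @param t age(s).
#' @param q probabilities in `[0, 1]`.
#' @param spec a `calibration_spec`.
#' @return numeric vector.
#' @export
calibration_density <- function(t, spec) {
  switch(spec$family,
         uniform = uniform_soft_density(t, spec),
         cauchy_min = cauchy_min_density(t, spec),
         stop_pc("spec has no density (family 'none')",
                 class = "pc_validation_error"))
}

#' @rdname calibration_density
#' @export
calibration_cdf <- function(t, spec) {
  if (spec$family == "cauchy_min") {
    A <- spec$tL * (1 + spec$p)
    s <- spec$c * spec$tL
    F0 <- pcauchy(spec$tL, location = A, scale = s)
    out <- (pcauchy(t, location = A, scale = s) - F0) / (1 - F0)
    out[t <= spec$tL] <- 0
    return(pmin(pmax(out, 0), 1))
  }
  stopifnot(spec$family == "uniform")
  hard_L <- spec$pL <= HARD_EPS
  hard_U <- spec$pU <= HARD_EPS
  pL <- if (hard_L) 0 else spec$pL
  pU <- if (hard_U) 0 else spec$pU
  h <- (1 - pL - pU) / (spec$tU - spec$tL)
  out <- numeric(length(t))
  lo <- t < spec$tL
  if (any(lo)) {
    out[lo] <- if (hard_L) 0 else {
      theta <- h * spec$tL / pL
      pL * exp(theta * (log(pmax(t[lo], 0)) - log(spec$tL)))
    }
  }
  mid <- t >= spec$tL & t <= spec$tU
  out[mid] <- pL + h * (t[mid] - spec$tL)
  hi <- t > spec$tU
  if (any(hi)) {
    out[hi] <- if (hard_U) 1 else {
      lambda <- h / pU
      1 - pU * exp(-lambda * (t[hi] - spec$tU))
    }
  }
  pmin(pmax(out, 0), 1)
}

#' @rdname calibration_density
#' @export
calibration_quantile <- function(q, spec) {
  if (any(q < 0 | q > 1)) {
    stop_pc("quantile probabilities must lie in [0, 1]",
            class = "pc_validation_error")
  }
  if (spec$family == "cauchy_min") {
    A <- spec$tL * (1 + spec$p)
    s <- spec$c * spec$tL
    F0 <- pcauchy(spec$tL, location = A, scale = s)
    return(qcauchy(F0 + q * (1 - F0), location = A, scale = s))
  }
  stopifnot(spec$family == "uniform")
  hard_L <- spec$pL <= HARD_EPS
  hard_U <- spec$pU <= HARD_EPS
  pL <- if (hard_L) 0 else spec$pL
  pU <- if (hard_U) 0 else spec$pU
  h <- (1 - pL - pU) / (spec$tU - spec$tL)
  out <- numeric(length(q))
  lo <- q < pL
  if (any(lo)) {
    theta <- h * spec$tL / pL
    out[lo] <- spec$tL * exp(log(q[lo] / pL) / theta)
  }
  mid <- q >= pL & q <= 1 - pU
  out[mid] <- spec$tL + (q[mid] - pL) / h
  hi <- q > 1 - pU
  if (any(hi)) {
    lambda <- h / pU
    out[hi] <- spec$tU - log((1 - q[hi]) / pU) / lambda
  }
  out
}

#' Sample ages from a calibration density
#'
#' Inverse-CDF sampling; deterministic given `seed`.
#'
#' @param spec a `calibration_spec`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of ages (100-My units).
#' @export
sample_calibration <- function(spec, n, seed = NULL) {
  if (!is_count(n) || n < 1) {
    stop_pc("n must be a positive integer", class = "pc_validation_error")
  }
  u <- with_seed(seed, runif(n))
  calibration_quantile(u, spec)
}

#' Gamma prior container
#'
#' @param shape,rate positive gamma parameters.
#' @return a `gamma_prior` with `shape`, `rate` and `mean = shape / rate`.
#' @export
gamma_prior <- function(shape, rate) {
  if (!is.numeric(shape) || shape <= 0 || !is.numeric(rate) || rate <= 0) {
    stop_pc("shape and rate must be positive", class = "pc_validation_error")
  }
  structure(list(shape = shape, rate = rate, mean = shape / rate),
            class = "gamma_prior")
}

#' Gamma hyperprior on the mean branch rate from a calibrating distance
#'
#' The mean substitution rate is the pairwise distance divided by the
#' calibrated divergence age; the gamma hyperprior keeps the requested
#' shape and sets `rate = shape / mean` so its mean equals that rate.
#'
#' @param pairwise_distance substitutions per site (> 0).
#' @param age calibrated divergence age in 100-My units (> 0).
#' @param shape gamma shape parameter (default 2).
#' @return a `gamma_prior`: list with `shape`, `rate`, `mean`
#'   (substitutions per site per 100 My).
#' @export
derive_rate_prior <- function(pairwise_distance, age, shape = 2) {
  if (!is.numeric(pairwise_distance) || pairwise_distance <= 0 ||
      !is.numeric(age) || age <= 0 || !is.numeric(shape) || shape <= 0) {
    stop_pc("pairwise_distance, age and shape must be positive",
            class = "pc_validation_error")
  }
  mu <- pairwise_distance / age
  structure(list(shape = shape, rate = shape / mu, mean = mu),
            class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("Gamma prior G(%g, %g), mean %g\n", x$shape, x$rate, x$mean))
  invisible(x)
}

#' Birth-death sampling fraction
#'
#' The proportion of extant species represented in the ingroup sample.
#'
#' @param n_ingroup sampled ingroup taxa (> 0).
#' @param n_extant extant species in the clade (`>= n_ingroup`).
#' @return the sampling fraction rho in (0, 1].
#' @export
sampling_fraction <- function(n_ingroup, n_extant) {
  if (!is_count(n_ingroup) || !is_count(n_extant) ||
      n_ingroup <= 0 || n_ingroup > n_extant) {
    stop_pc("need 0 < n_ingroup <= n_extant", class = "pc_validation_error")
  }
  n_ingroup / n_extant
}

#' Dating configuration container
#'
#' Stores pass-through settings for a relaxed-clock dating run (the MCMC
#' itself is outside this package's scope): birth/death rates, sampling
#' fraction, time unit and clock model tag.
#'
#' @param lambda birth rate.
#' @param mu death rate.
#' @param rho sampling fraction in (0, 1].
#' @param time_unit size of the time unit in My (default 100).
#' @param clock clock model tag (default `"IR"`, independent rates).
#' @return a `dating_config`.
#' @export
dating_config <- function(lambda, mu, rho, time_unit = 100, clock = "IR") {
  if (!is.numeric(rho) || rho <= 0 || rho > 1) {
    stop_pc("rho must lie in (0, 1]", class = "pc_validation_error")
  }
  structure(list(lambda = lambda, mu = mu, rho = rho,
                 time_unit = time_unit, clock = clock),
            class = "dating_config")
}

#' Load a calibration table for one calibration strategy
#'
#' Reads a TSV with columns `node`, `clade`, `family`, `tL`, `tU`, `pL`,
#' `pU`, `p`, `c`, `strategies` (comma-separated strategy tags) and
#' returns the calibrations active under the requested strategy. The
#' bundled table (`system.file("extdata", "calibrations.tsv", package =
#' "phyloconflict")`) encodes eight calibration nodes in 100-My units; the
#' three strategies differ only in where (or whether) the 1000-My
#' filamentous-fossil minimum is attached.
#'
#' @param file path to the TSV; default, the bundled table.
#' @param strategy 1, 2 or 3.
#' @return list of `calibration_spec` objects.
#' @export
load_calibration_table <- function(file = NULL, strategy = 1) {
  if (!strategy %in% c(1, 2, 3)) {
    stop_pc("strategy must be 1, 2 or 3", class = "pc_validation_error")
  }
  file <- file %||% system.file("extdata", "calibrations.tsv",
                                package = "phyloconflict", mustWork = TRUE)
  tab <- read.delim(file, stringsAsFactors = FALSE)
  needed <- c("node", "family", "tL", "tU", "pL", "pU", "strategies")
  miss <- setdiff(needed, names(tab))
  if (length(miss) > 0L) {
    stop_pc("calibration table lacks columns: ", paste(miss, collapse = ", "),
            class = "pc_validation_error")
  }
  active <- vapply(strsplit(tab$strategies, ","), function(s) {
    as.character(strategy) %in% trimws(s)
  }, logical(1))
  tab <- tab[active & tab$family != "none", , drop = FALSE]
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (row$family == "uniform" && !is.finite(row$tU)) {
      stop_pc("uniform calibration '", row$node, "' is missing tU",
              class = "pc_validation_error")
    }
    calibration_spec(node = row$node, family = row$family,
                     tL = row$tL, tU = row$tU,
                     pL = row$pL, pU = if (is.finite(row$pU)) row$pU else 0.025,
                     p = if ("p" %in% names(tab) && is.finite(row$p)) row$p else 0.1,
                     c = if ("c" %in% names(tab) && is.finite(row$c)) row$c else 1)
  })
}
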