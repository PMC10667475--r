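#' Adjacent-repeat frequency of a sampling sequence
#'
#' The fraction of adjacent pairs in the sequence that share a species,
#' `v = (# adjacent equal pairs) / (m - 1)`. A quick estimator of the
#' non-independence parameter, but it systematically overestimates it:
#' `E(v) = (1 - pi) * sum(p^2) + pi`, so the upward bias equals the
#' community's Simpson concentration scaled by `1 - pi`.
#'
#' @param seq Character vector of species labels in sampling order (m >= 2).
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' solow_v(c("a", "a", "b"))  # 0.5
solow_v <- function(seq) {
  m <- length(seq)
  if (m < 2L) abort("need at least two individuals to form adjacent pairs")
  mean(seq[-1] == seq[-m])
}

#' Method-of-moments estimate of the non-independence parameter
#'
#' Solves for `pi` from two moment equations: the expectation of the
#' adjacent-repeat frequency `v` and the Markov-adjusted expression of the
#' Gini-Simpson index, with expectations replaced by their sample values
#' (the maximum-likelihood plug-in `D_ml = 1 - sum((n_i/m)^2)` estimates the
#' Gini-Simpson term). Eliminating `sum(p^2)` reduces the system to a
#' quadratic in `pi`,
#'
#'   `m D_ml pi^2 + [(1 - v)(m + 1) - 2 m D_ml] pi + [m D_ml - (1 - v)(m - 1)] = 0`,
#'
#' whose smaller root is the estimator (the larger root drifts towards 1).
#' When the discriminant is negative, the root is negative, or the root
#' exceeds its upper bound `v`, the estimate falls back to `v` itself;
#' roots negative only by numerical noise (above `-1e-9`) are clipped to 0.
#' A sample containing a single species (`D_ml = 0`) degenerates the
#' quadratic and likewise falls back.
#'
#' @param v Adjacent-repeat frequency (see [solow_v()]).
#' @param gini_ml Maximum-likelihood Gini-Simpson plug-in of the same sample.
#' @param m Sample size.
#' @return List with `pi_hat`, `delta_hat = (1 + pi_hat)/(1 - pi_hat)`,
#'   `used_fallback`, and `discriminant`.
#' @export
pi_from_moments <- function(v, gini_ml, m) {
  if (m < 2) abort("need m >= 2")
  if (v < 0 || v > 1) abort("v must lie in [0, 1]")
  fallback <- function(disc) {
    pi_hat <- min(max(v, 0), 1)
    list(pi_hat = pi_hat,
         delta_hat = if (pi_hat < 1) (1 + pi_hat) / (1 - pi_hat) else Inf,
         used_fallback = TRUE, discriminant = disc)
  }
  if (gini_ml <= 0) return(fallback(NA_real_))
  a <- m * gini_ml
  b <- (1 - v) * (m + 1) - 2 * m * gini_ml
  disc <- (1 - v)^2 * (m + 1)^2 - 8 * m * gini_ml * (1 - v)  # = b^2 - 4ac
  if (disc < 0) return(fallback(disc))
  root <- (-b - sqrt(disc)) / (2 * a)
  if (root < 0 && root > -1e-9) root <- 0
  if (root < 0 || root > v) return(fallback(disc))
  list(pi_hat = root,
       delta_hat = (1 + root) / (1 - root),
       used_fallback = FALSE, discriminant = disc)
}

#' Estimate the non-independence parameter from a sampling sequence
#'
#' Computes the adjacent-repeat frequency `v` and the nearly unbiased
#' method-of-moments estimate of the non-independence parameter `pi` (see
#' [pi_from_moments()] for the estimator and its fallback rules), together
#' with the sampling-inflation factor `delta = (1 + pi)/(1 - pi)` used by the
#' Markov-adjusted diversity estimators.
#'
#' @param seq Character vector of species labels in sampling order (m >= 2).
#' @return An object of class `pi_fit` with fields `v`, `pi_hat`,
#'   `delta_hat`, `used_fallback`, `discriminant`, `m`, `s_obs`.
#' @seealso [tidy.pi_fit()], [gini_markov()], [rao_markov()]
#' @export
#' @examples
#' mod <- markov_model(make_abundances(10, "geometric", 0.8), pi = 0.3)
#' fit <- estimate_pi(sample_markov_sequence(mod, 200, seed = 7))
#' tidy(fit)
estimate_pi <- function(seq) {
  m <- length(seq)
  if (m < 2L) abort("need at least two individuals")
  v <- solow_v(seq)
  counts <- counts_from_sequence(seq)
  dml <- gini_ml(counts)
  sol <- pi_from_moments(v, dml, m)
  structure(c(list(v = v), sol, list(m = m, s_obs = sum(counts$n > 0))),
            class = "pi_fit")
}

#' @export
print.pi_fit <- function(x, ...) {
  cat(sprintf(
    "Non-independence estimate: pi_hat = %.4f (v = %.4f, delta_hat = %.3f)%s\n",
    x$pi_hat, x$v, x$delta_hat,
    if (x$used_fallback) " [fallback to v]" else ""))
  cat(sprintf("  m = %d individuals, %d species observed\n", x$m, x$s_obs))
  invisible(x)
}

#' Tidy a non-independence fit
#'
#' @param x A `pi_fit` from [estimate_pi()].
#' @param ... Unused.
#' @return A one-row tibble with columns `v`, `pi_hat`, `delta_hat`,
#'   `used_fallback`, `discriminant`.
#' @exportS3Method generics::tidy
#' @export
tidy.pi_fit <- function(x, ...) {
  tibble(v = x$v, pi_hat = x$pi_hat, delta_hat = x$delta_hat,
         used_fallback = x$used_fallback, discriminant = x$discriminant)
}

#' @rdname tidy.pi_fit
#' @return `glance()`: a one-row tibble with `m`, `s_obs`, `used_fallback`.
#' @exportS3Method generics::glance
#' @export
glance.pi_fit <- function(x, ...) {
  tibble(m = x$m, s_obs = x$s_obs, used_fallback = x$used_fallback)
}

check_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (!all(c("species", "n") %in% names(counts))) {
    abort("counts need columns `species` and `n`")
  }
  if (any(counts$n < 0)) abort("counts must be non-negative")
  list(species = as.character(counts$species), n = as.numeric(counts$n),
       m = sum(counts$n))
}

#' Gini-Simpson index estimators
#'
#' Three estimators of the Gini-Simpson index `1 - sum(p^2)` from observed
#' species counts:
#' * `gini_ml()` — the maximum-likelihood plug-in `1 - sum((n_i/m)^2)`;
#' * `gini_unbiased()` — the classical finite-sample correction
#'   `1 - sum(n_i (n_i - 1)) / (m (m - 1))`, unbiased under independent
#'   sampling;
#' * `gini_markov()` — the adjustment for non-independent sequential
#'   sampling, `(m^2 - sum(n_i^2)) / (m (m - delta_hat))`, which equals the
#'   unbiased estimator at `delta_hat = 1` (independent sampling) and
#'   inflates the estimate as the sampling dependence grows.
#'
#' @param counts A counts table (columns `species`, `n`), e.g. from
#'   [counts_from_sequence()].
#' @param delta_hat Estimated inflation factor `(1 + pi)/(1 - pi)`; must be
#'   smaller than `m` for the adjusted denominator to stay positive.
#' @return A single numeric index value.
#' @name gini_estimators
#' @examples
#' cts <- counts_from_sequence(c("a", "a", "b", "b"))
#' gini_ml(cts)        # 0.5
#' gini_unbiased(cts)  # 2/3
NULL

#' @rdname gini_estimators
#' @export
gini_ml <- function(counts) {
  x <- check_counts(counts)
  if (x$m < 1) abort("need at least one individual")
  1 - sum((x$n / x$m)^2)
}

#' @rdname gini_estimators
#' @export
gini_unbiased <- function(counts) {
  x <- check_counts(counts)
  if (x$m < 2) abort("need at least two individuals")
  1 - sum(x$n * (x$n - 1)) / (x$m * (x$m - 1))
}

#' @rdname gini_estimators
#' @export
gini_markov <- function(counts, delta_hat) {
  x <- check_counts(counts)
  if (!is.numeric(delta_hat) || delta_hat < 1) abort("delta_hat must be >= 1")
  if (x$m <= delta_hat) {
    abort(sprintf("m (%g) must exceed delta_hat (%g)", x$m, delta_hat))
  }
  (x$m^2 - sum(x$n^2)) / (x$m * (x$m - delta_hat))
}

rao_quad_form <- function(counts, d) {
  x <- check_counts(counts)
  d <- align_distances(d, x$species)
  list(q = as.numeric(x$n %*% d %*% x$n), m = x$m)  # zero diagonal: off-diag sum
}

#' Rao's quadratic diversity estimators
#'
#' Estimators of Rao's quadratic diversity
#' `Q(p) = sum_{i != j} d_ij p_i p_j` — the expected pairwise distance
#' between two randomly drawn individuals — from observed counts and a
#' species distance matrix:
#' * `rao_ml()` — plug-in with `p_hat_i = n_i / m`;
#' * `rao_unbiased()` — `sum_{i != j} d_ij n_i n_j / (m (m - 1))`, unbiased
#'   under independent sampling;
#' * `rao_markov()` — `sum_{i != j} d_ij n_i n_j / (m (m - delta_hat))`, the
#'   nearly unbiased version under non-independent sequential sampling,
#'   reducing exactly to `rao_unbiased()` at `delta_hat = 1`.
#'
#' With the 0/1 distance matrix ([identity_distances()]) each variant reduces
#' exactly to its Gini-Simpson counterpart.
#'
#' @param counts A counts table (columns `species`, `n`).
#' @param d Distance matrix whose dimnames cover the counts' species.
#' @param delta_hat Estimated inflation factor, `1 <= delta_hat < m`.
#' @return A single numeric index value (units of `d`).
#' @name rao_estimators
#' @examples
#' cts <- counts_from_sequence(c("a", "b"))
#' d <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' rao_ml(cts, d)        # 2
#' rao_unbiased(cts, d)  # 4
NULL

#' @rdname rao_estimators
#' @export
rao_ml <- function(counts, d) {
  x <- rao_quad_form(counts, d)
  if (x$m < 1) abort("need at least one individual")
  x$q / x$m^2
}

#' @rdname rao_estimators
#' @export
rao_unbiased <- function(counts, d) {
  x <- rao_quad_form(counts, d)
  if (x$m < 2) abort("need at least two individuals")
  x$q / (x$m * (x$m - 1))
}

#' @rdname rao_estimators
#' @export
rao_markov <- function(counts, d, delta_hat) {
  x <- rao_quad_form(counts, d)
  if (!is.numeric(delta_hat) || delta_hat < 1) abort("delta_hat must be >= 1")
  if (x$m <= delta_hat) {
    abort(sprintf("m (%g) must exceed delta_hat (%g)", x$m, delta_hat))
  }
  x$q / (x$m * (x$m - delta_hat))
}

#' Population diversity of a community
#'
#' `true_rao()` evaluates Rao's quadratic diversity
#' `sum_{i != j} d_ij p_i p_j` at the true relative abundances;
#' `true_gini()` evaluates the Gini-Simpson index `1 - sum(p^2)`. These are
#' the target values simulations compare estimators against.
#'
#' @param abundances Abundance table (columns `species`, `p`).
#' @param d Distance matrix covering the community's species.
#' @return A single numeric value.
#' @export
true_rao <- function(abundances, d) {
  a <- as_abundances(abundances)
  d <- align_distances(d, a$species)
  as.numeric(a$p %*% d %*% a$p)
}

#' @rdname true_rao
#' @export
true_gini <- function(abundances) {
  a <- as_abundances(abundances)
  1 - sum(a$p^2)
}

#' All estimators applied to one sampling sequence
#'
#' Convenience wrapper for pipelines and the command-line tool: estimates the
#' non-independence parameter and all six diversity estimators (three
#' Gini-Simpson, three Rao) from a single ordered sequence. When no distance
#' matrix is supplied the 0/1 identity distances are used, so the Rao columns
#' duplicate the Gini-Simpson columns. The Markov-adjusted estimators are set
#' to `NA` (with a warning) when the estimated inflation factor reaches the
#' sample size, which can only happen in tiny or single-species samples.
#'
#' @param seq Character vector of species labels in sampling order.
#' @param d Optional distance matrix; identity distances when `NULL`.
#' @param universe Species universe for the counts; defaults to the distinct
#'   labels in `seq` plus the distance matrix's species, if given.
#' @return One-row tibble with columns `m`, `v`, `pi_hat`, `delta_hat`,
#'   `used_fallback`, `gini_ml`, `gini_unbiased`, `gini_markov`, `rao_ml`,
#'   `rao_unbiased`, `rao_markov`.
#' @export
estimate_all <- function(seq, d = NULL, universe = NULL) {
  if (is.null(universe)) {
    universe <- if (is.null(d)) unique(seq) else union(rownames(d), unique(seq))
  }
  counts <- counts_from_sequence(seq, universe)
  if (is.null(d)) d <- identity_distances(universe)
  fit <- estimate_pi(seq)
  markov_ok <- is.finite(fit$delta_hat) && fit$delta_hat < fit$m
  if (!markov_ok) {
    warn("delta_hat >= m: Markov-adjusted estimates set to NA")
  }
  tibble(
    m = fit$m, v = fit$v, pi_hat = fit$pi_hat, delta_hat = fit$delta_hat,
    used_fallback = fit$used_fallback,
    gini_ml = gini_ml(counts),
    gini_unbiased = gini_unbiased(counts),
    gini_markov = if (markov_ok) gini_markov(counts, fit$delta_hat) else NA_real_,
    rao_ml = rao_ml(counts, d),
    rao_unbiased = rao_unbiased(counts, d),
    rao_markov = if (markov_ok) rao_markov(counts, d, fit$delta_hat) else NA_real_
  )
}
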