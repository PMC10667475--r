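#' Replicate-summary metrics
#'
#' Average, bias and root mean squared error of a set of replicate estimates
#' against a known truth: `avg = mean`, `bias = avg - truth`,
#' `rmse = sqrt(mean((estimate - truth)^2))`. The replicate variance is
#' `rmse^2 - bias^2`, so `rmse >= |bias|` always. Missing estimates are
#' dropped (with their count reported).
#'
#' @param estimates Numeric vector of replicate estimates.
#' @param truth The true value.
#' @return One-row tibble with `avg`, `bias`, `rmse`, `n_used`.
#' @export
#' @examples
#' metrics(c(0, 2), truth = 1)  # avg 1, bias 0, rmse 1
metrics <- function(estimates, truth) {
  keep <- estimates[is.finite(estimates)]
  if (length(keep) == 0L) abort("no usable estimates")
  avg <- mean(keep)
  tibble(avg = avg, bias = avg - truth,
         rmse = sqrt(mean((keep - truth)^2)), n_used = length(keep))
}

# deterministic child seeds (< 2^31) from a master seed
child_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

summarise_replicates <- function(est, truths, m, condition) {
  purrr::map_dfr(names(truths), function(name) {
    dplyr::bind_cols(
      tibble(m = m, condition = condition, estimator = name,
             truth = truths[[name]]),
      metrics(est[[name]], truths[[name]]))
  })
}

#' Semi-numerical evaluation of the estimators
#'
#' Reproduces the semi-numerical simulation design: a real (or synthetic)
#' community's relative abundances and distance matrix serve as the
#' generating truth; for each combination of non-independence level `pi` and
#' sample size `m`, many Markov sequential samples are simulated and every
#' estimator is applied, then summarised as average, bias and RMSE against
#' the known truths (the true `pi`, the population Gini-Simpson index, and
#' the population Rao diversity).
#'
#' @param abundances Abundance table (columns `species`, `p`).
#' @param d Optional distance matrix; identity distances when `NULL` (Rao
#'   rows then equal the Gini-Simpson rows).
#' @param pi_values Non-independence levels to simulate.
#' @param m_values Sample sizes to simulate.
#' @param replicates Replicates per condition.
#' @param seed Master seed; per-replicate child seeds are derived
#'   deterministically so tables reproduce bit-identically.
#' @return A tibble of class `diversity_summary` with columns `m`,
#'   `condition` (the true pi, as `pi=<value>`), `estimator`, `truth`, `avg`,
#'   `bias`, `rmse`, `n_used`.
#' @export
#' @examples
#' comm <- make_abundances(10, "geometric", 0.8)
#' run_semi_numerical(comm, pi_values = 0.25, m_values = 50,
#'                    replicates = 200, seed = 1)
run_semi_numerical <- function(abundances, d = NULL,
                               pi_values = c(0.1, 0.25, 0.4, 0.55, 0.7),
                               m_values = c(50, 75, 100, 125),
                               replicates = 5000, seed = 1) {
  a <- as_abundances(abundances)
  if (is.null(d)) d <- identity_distances(a$species)
  d <- align_distances(d, a$species)
  if (replicates < 1) abort("need at least one replicate")
  if (any(m_values < 2)) abort("all sample sizes must be at least 2")
  grid <- tidyr::expand_grid(pi = pi_values, m = m_values)
  seeds <- matrix(child_seeds(seed, nrow(grid) * replicates), nrow = replicates)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    pi <- grid$pi[g]; m <- grid$m[g]
    model <- markov_model(a, pi)
    est <- purrr::map_dfr(seq_len(replicates), function(r) {
      seq <- sample_markov_sequence(model, m, seed = seeds[r, g])
      counts <- counts_from_sequence(seq, universe = a$species)
      fit <- estimate_pi(seq)
      ok <- is.finite(fit$delta_hat) && fit$delta_hat < m
      tibble(
        v = fit$v, pi_hat = fit$pi_hat,
        gini_ml = gini_ml(counts),
        gini_unbiased = gini_unbiased(counts),
        gini_markov = if (ok) gini_markov(counts, fit$delta_hat) else NA_real_,
        rao_ml = rao_ml(counts, d),
        rao_unbiased = rao_unbiased(counts, d),
        rao_markov = if (ok) rao_markov(counts, d, fit$delta_hat) else NA_real_)
    })
    truths <- list(v = pi, pi_hat = pi,
                   gini_ml = true_gini(a), gini_unbiased = true_gini(a),
                   gini_markov = true_gini(a),
                   rao_ml = true_rao(a, d), rao_unbiased = true_rao(a, d),
                   rao_markov = true_rao(a, d))
    summarise_replicates(est, truths, m, sprintf("pi=%g", pi))
  })
  structure(out, class = c("diversity_summary", class(out)))
}

#' Line-transect evaluation on a mapped community
#'
#' For each target sample size, draws replicated line-transect samples from
#' the mapped community, applies the non-independence and diversity
#' estimators, and summarises them against the community-wide truths
#' computed from the full census (all mapped individuals). Because the
#' spatial pattern — not a known Markov parameter — generates the
#' dependence here, `v` and `pi_hat` rows report raw averages with truth set
#' to `NA` and bias/rmse omitted.
#'
#' @param community A `point_community`.
#' @param d Optional distance matrix over the census species; identity when
#'   `NULL`.
#' @param m_values Sample sizes (all at most the census size).
#' @param width Transect band width.
#' @param replicates Replicates per sample size.
#' @param seed Master seed.
#' @return A tibble of class `diversity_summary` (condition = `"transect"`).
#' @export
run_transect_experiment <- function(community, d = NULL,
                                    m_values = c(50, 100, 500),
                                    width = 1, replicates = 500, seed = 1) {
  stopifnot(inherits(community, "point_community"))
  a <- census_abundances(community)
  if (is.null(d)) d <- identity_distances(a$species)
  d <- align_distances(d, a$species)
  if (any(m_values > nrow(community))) abort("some m exceed the census size")
  seeds <- matrix(child_seeds(seed, length(m_values) * replicates),
                  nrow = replicates)
  out <- purrr::map_dfr(seq_along(m_values), function(g) {
    m <- m_values[g]
    est <- purrr::map_dfr(seq_len(replicates), function(r) {
      seq <- transect_sample(community, m, width = width, seed = seeds[r, g])
      counts <- counts_from_sequence(seq, universe = a$species)
      fit <- estimate_pi(seq)
      ok <- is.finite(fit$delta_hat) && fit$delta_hat < m
      tibble(
        v = fit$v, pi_hat = fit$pi_hat,
        gini_ml = gini_ml(counts),
        gini_unbiased = gini_unbiased(counts),
        gini_markov = if (ok) gini_markov(counts, fit$delta_hat) else NA_real_,
        rao_ml = rao_ml(counts, d),
        rao_unbiased = rao_unbiased(counts, d),
        rao_markov = if (ok) rao_markov(counts, d, fit$delta_hat) else NA_real_)
    })
    truths <- list(v = NA_real_, pi_hat = NA_real_,
                   gini_ml = true_gini(a), gini_unbiased = true_gini(a),
                   gini_markov = true_gini(a),
                   rao_ml = true_rao(a, d), rao_unbiased = true_rao(a, d),
                   rao_markov = true_rao(a, d))
    purrr::map_dfr(names(truths), function(name) {
      truth <- truths[[name]]
      keep <- est[[name]][is.finite(est[[name]])]
      tibble(m = m, condition = "transect", estimator = name, truth = truth,
             avg = mean(keep),
             bias = if (is.na(truth)) NA_real_ else mean(keep) - truth,
             rmse = if (is.na(truth)) NA_real_ else sqrt(mean((keep - truth)^2)),
             n_used = length(keep))
    })
  })
  structure(out, class = c("diversity_summary", class(out)))
}

#' Pivot a long summary into the classical wide table layout
#'
#' One row per (condition, m), with `avg`/`bias`/`rmse` columns for each
#' estimator — the layout evaluation tables are usually printed in.
#'
#' @param x A `diversity_summary`.
#' @param estimators Optional subset of estimator names to keep.
#' @return A wide tibble.
#' @export
pivot_summary <- function(x, estimators = NULL) {
  if (!is.null(estimators)) x <- dplyr::filter(x, .data$estimator %in% estimators)
  tidyr::pivot_wider(
    dplyr::select(x, "condition", "m", "estimator", "avg", "bias", "rmse"),
    names_from = "estimator", values_from = c("avg", "bias", "rmse"),
    names_vary = "slowest")
}

#' Plot bias and RMSE against sample size
#'
#' @param object A `diversity_summary`.
#' @param ... Unused.
#' @return A ggplot: bias and RMSE facets by condition, one line per
#'   estimator.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.diversity_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object, !is.na(.data$bias)),
    cols = c("bias", "rmse"), names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$value,
                                     colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(metric ~ condition, scales = "free_y") +
    ggplot2::labs(x = "sample size m", y = NULL, colour = "estimator") +
    ggplot2::theme_minimal()
}
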