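#' A first-order Markov model of sequential sampling
#'
#' In the model, the first sampled individual is drawn from the community's
#' relative abundances; every later individual repeats the previous species
#' with probability `pi` and is otherwise a fresh independent draw from the
#' abundances. `pi = 0` recovers independent (multinomial) sampling; `pi = 1`
#' locks the sequence onto a single species. The same process written as a
#' transition matrix has entries `(1 - pi) p_j + pi [j == i]`.
#'
#' @param abundances Abundance table (see [as_abundances()]).
#' @param pi Non-independence parameter in `[0, 1]`.
#' @return An object of class `markov_model`.
#' @export
#' @examples
#' mod <- markov_model(make_abundances(3, "uniform"), pi = 0.4)
#' transition_matrix(mod)
markov_model <- function(abundances, pi) {
  abundances <- as_abundances(abundances)
  if (!is.numeric(pi) || length(pi) != 1L || is.na(pi) || pi < 0 || pi > 1) {
    abort("`pi` must be a single value in [0, 1]")
  }
  structure(list(abundances = abundances, pi = pi), class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("First-order Markov sampling model: %d species, pi = %g\n",
              nrow(x$abundances), x$pi))
  invisible(x)
}

#' Transition matrix of the sequential-sampling Markov chain
#'
#' Row `i`, column `j` holds the probability that the next individual belongs
#' to species `j` given the previous one belonged to species `i`:
#' `(1 - pi) p_j` off the diagonal and `(1 - pi) p_i + pi` on it. Rows sum to
#' one and the abundance vector is the chain's stationary distribution.
#'
#' @param model A [markov_model()].
#' @return A row-stochastic S x S matrix with species labels.
#' @export
transition_matrix <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  p <- model$abundances$p
  s <- length(p)
  tm <- (1 - model$pi) * matrix(p, s, s, byrow = TRUE) + model$pi * diag(s)
  dimnames(tm) <- list(model$abundances$species, model$abundances$species)
  tm
}

#' Simulate a sequential sampling sequence
#'
#' Uses the mixture form of the chain directly: draw all candidate fresh
#' labels iid from the abundances, draw repeat indicators with probability
#' `pi`, and carry the last fresh label forward through each run of repeats.
#' This is distributionally identical to stepping through the transition
#' matrix but needs no S x S matrix, so it scales to communities with many
#' species.
#'
#' @param model A [markov_model()].
#' @param m Sample size (number of individuals), at least 1.
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of `m` species labels in sampling order.
#' @export
#' @examples
#' mod <- markov_model(make_abundances(3, "uniform"), pi = 0.5)
#' sample_markov_sequence(mod, 10, seed = 1)
sample_markov_sequence <- function(model, m, seed = NULL) {
  stopifnot(inherits(model, "markov_model"))
  if (!is.numeric(m) || length(m) != 1L || m < 1) abort("`m` must be at least 1")
  m <- as.integer(m)
  if (!is.null(seed)) set.seed(seed)
  p <- model$abundances$p
  fresh <- sample.int(length(p), m, replace = TRUE, prob = p)
  if (m > 1L && model$pi > 0) {
    keep <- c(TRUE, runif(m - 1L) >= model$pi)   # TRUE = take the fresh draw
    src <- cummax(seq_len(m) * keep)             # index of last fresh draw
    fresh <- fresh[src]
  }
  model$abundances$species[fresh]
}

#' Expected adjacent-repeat frequency of a model
#'
#' The expectation of the adjacent-repeat statistic `v` (see [solow_v()])
#' under the model: `(1 - pi) * sum(p^2) + pi`. The first term is the excess
#' by which `v` overestimates `pi`; it vanishes only for infinitely even
#' communities.
#'
#' @param model A [markov_model()].
#' @return A single number in `[0, 1]`.
#' @export
expected_v <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  (1 - model$pi) * sum(model$abundances$p^2) + model$pi
}

#' Large-sample covariance of two species' sample counts
#'
#' Under the Markov sampling model the counts of two distinct species `i` and
#' `j` in a sample of size `m` have covariance approximately
#' `-delta * m * p_i * p_j`, with inflation factor
#' `delta = (1 + pi) / (1 - pi)`. At `pi = 0` this is the multinomial
#' covariance; at `pi = 1` the factor diverges and the formula is undefined.
#'
#' @param model A [markov_model()].
#' @param m Sample size (the approximation is asymptotic in `m`).
#' @param i,j Species labels or indices; must differ.
#' @return The approximate covariance (individuals squared).
#' @export
abundance_covariance <- function(model, m, i, j) {
  stopifnot(inherits(model, "markov_model"))
  if (model$pi >= 1) abort("covariance is undefined at pi = 1 (delta diverges)")
  sp <- model$abundances$species
  idx <- function(k) if (is.character(k)) match(k, sp) else as.integer(k)
  i <- idx(i); j <- idx(j)
  if (is.na(i) || is.na(j) || i < 1 || j < 1 || i > length(sp) || j > length(sp)) {
    abort("unknown species")
  }
  if (i == j) abort("species must differ (this is the cross-covariance)")
  delta <- (1 + model$pi) / (1 - model$pi)
  -delta * m * model$abundances$p[i] * model$abundances$p[j]
}
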