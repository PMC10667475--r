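# Shared fixtures and independent oracles for the test suite.

# 34-species skewed community used throughout the semi-numerical checks
geom34 <- function() make_abundances(34, "geometric", shape = 0.9)

# Independent numerical solver for the non-independence parameter: solves the
# two moment equations directly by bracketed bisection over pi, without using
# the closed-form quadratic root. Equation A gives the Simpson concentration
# implied by the adjacent-repeat frequency, C = (v - pi)/(1 - pi); equation B
# says 1 - C = m * D / (m - delta(pi)) with delta = (1 + pi)/(1 - pi) and D
# the ML Gini-Simpson plug-in. The residual of B after substituting A is
# monotone enough that the first sign change on a fine grid brackets the
# smaller root.
bisect_pi <- function(v, d_ml, m, tol = 1e-12) {
  pi_max <- min(v, (m - 1) / (m + 1) - 1e-9)
  if (pi_max <= 0) return(NA_real_)
  f <- function(pi) {
    delta <- (1 + pi) / (1 - pi)
    (v - pi) / (1 - pi) + m * d_ml / (m - delta) - 1
  }
  grid <- seq(0, pi_max, length.out = 512)
  fg <- vapply(grid, f, numeric(1))
  sign_change <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (length(sign_change) == 0L) return(NA_real_)
  lo <- grid[sign_change[1]]; hi <- grid[sign_change[1] + 1]
  flo <- f(lo)
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Reference sampler stepping through the full transition matrix row by row
# (the definitional form of the chain), used to cross-check the O(1)-memory
# mixture sampler.
sample_by_transition_rows <- function(model, m) {
  tm <- transition_matrix(model)
  sp <- model$abundances$species
  z <- integer(m)
  z[1] <- sample.int(length(sp), 1, prob = model$abundances$p)
  for (k in seq_len(m - 1)) {
    z[k + 1] <- sample.int(length(sp), 1, prob = tm[z[k], ])
  }
  sp[z]
}

# Monte-Carlo standard error of a mean
mc_se <- function(x) stats::sd(x) / sqrt(length(x))

# deterministic per-replicate seeds for test experiments
child_seeds_for_test <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}
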