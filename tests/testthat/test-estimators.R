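test_that("adjacent-repeat frequency counts equal neighbours", {
  expect_equal(solow_v(c("A", "B", "C")), 0)
  expect_equal(solow_v(c("A", "A", "A", "A")), 1)
  expect_equal(solow_v(c("A", "A", "B")), 0.5)
  expect_error(solow_v("A"), "two individuals")
})

test_that("the moment quadratic root matches the bisection oracle", {
  set.seed(12)
  checked <- 0
  while (checked < 200) {
    v <- runif(1, 0.02, 0.9)
    d_ml <- runif(1, 0.05, 0.95)
    m <- sample(10:500, 1)
    sol <- pi_from_moments(v, d_ml, m)
    if (sol$used_fallback) next
    oracle <- bisect_pi(v, d_ml, m)
    if (is.na(oracle)) next
    expect_equal(sol$pi_hat, oracle, tolerance = 1e-8)
    checked <- checked + 1
  }
})

test_that("fallback rules return v when the root is unusable", {
  # single observed species: gini_ml = 0 degenerates the quadratic
  fit <- estimate_pi(rep("A", 10))
  expect_true(fit$used_fallback)
  expect_equal(fit$pi_hat, 1)
  # negative discriminant forces the fallback
  sol <- pi_from_moments(v = 0.9, gini_ml = 0.9, m = 50)
  expect_lt(sol$discriminant, 0)
  expect_true(sol$used_fallback)
  expect_equal(sol$pi_hat, 0.9)
  # pi_hat never exceeds its upper bound v
  set.seed(9)
  mod <- markov_model(make_abundances(10, "geometric", 0.8), 0.3)
  for (k in 1:200) {
    f <- estimate_pi(sample_markov_sequence(mod, 40))
    expect_gte(f$pi_hat, 0)
    expect_lte(f$pi_hat, f$v + 1e-12)
    expect_gte(f$delta_hat, 1)
  }
})

test_that("estimate_pi is nearly unbiased on iid sequences", {
  mod <- markov_model(make_abundances(100, "uniform"), 0)
  set.seed(31)
  ph <- replicate(2000, estimate_pi(sample_markov_sequence(mod, 200))$pi_hat)
  expect_lt(abs(mean(ph)), 0.02)
})

test_that("tidy and glance summarise a pi fit", {
  fit <- estimate_pi(c("a", "a", "b", "a", "c"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("v", "pi_hat", "delta_hat", "used_fallback", "discriminant"))
  expect_equal(td$v, 0.25)
  gl <- glance(fit)
  expect_equal(gl$m, 5L)
  expect_equal(gl$s_obs, 3L)
})

test_that("Gini-Simpson estimators reproduce hand-computed values", {
  n11 <- tibble::tibble(species = c("a", "b"), n = c(1, 1))
  expect_equal(gini_ml(n11), 0.5)
  expect_equal(gini_unbiased(n11), 1)
  expect_equal(gini_markov(n11, 1), 1)
  mono <- tibble::tibble(species = "a", n = 7)
  expect_equal(gini_ml(mono), 0)
  expect_equal(gini_unbiased(tibble::tibble(species = c("a", "b"), n = c(2, 0))), 0)
  n22 <- tibble::tibble(species = c("a", "b"), n = c(2, 2))
  expect_equal(gini_ml(n22), 0.5)
  expect_equal(gini_unbiased(n22), 2 / 3)
  n31 <- tibble::tibble(species = c("a", "b"), n = c(3, 1))
  expect_equal(gini_markov(n31, 2), 0.75)
  expect_error(gini_markov(n31, 4), "exceed")
})

test_that("Rao estimators reproduce hand-computed values", {
  sp <- c("a", "b")
  d4 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(sp, sp))
  n11 <- tibble::tibble(species = sp, n = c(1, 1))
  expect_equal(rao_ml(n11, d4), 2)
  expect_equal(rao_unbiased(n11, d4), 4)
  expect_equal(rao_markov(n11, d4, 1), 4)
  expect_equal(rao_ml(tibble::tibble(species = sp, n = c(5, 0)), d4), 0)
  p <- as_abundances(data.frame(species = sp, p = c(0.25, 0.75)))
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(sp, sp))
  expect_equal(true_rao(p, d2), 0.75)
  expect_error(rao_ml(n11, d4[1, 1, drop = FALSE]), "lacks species")
})

test_that("Rao reduces exactly to Gini-Simpson under identity distances", {
  set.seed(14)
  for (k in 1:20) {
    s <- sample(2:15, 1)
    n <- tibble::tibble(species = sprintf("s%02d", 1:s),
                        n = stats::rpois(s, 4) + (1:s == 1))
    if (sum(n$n) < 3) next
    d <- identity_distances(n$species)
    dh <- runif(1, 1, min(3, sum(n$n) - 1))
    expect_equal(rao_ml(n, d), gini_ml(n), tolerance = 1e-12)
    expect_equal(rao_unbiased(n, d), gini_unbiased(n), tolerance = 1e-12)
    expect_equal(rao_markov(n, d, dh), gini_markov(n, dh), tolerance = 1e-12)
    # delta = 1 recovers the classical unbiased estimators exactly
    expect_identical(rao_markov(n, d, 1), rao_unbiased(n, d))
    expect_identical(gini_markov(n, 1), gini_unbiased(n))
  }
})

test_that("the Markov adjustment is non-decreasing in delta", {
  n <- tibble::tibble(species = letters[1:4], n = c(10, 5, 3, 2))
  deltas <- seq(1, 18, by = 0.5)
  vals <- vapply(deltas, function(d) gini_markov(n, d), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("estimate_all assembles the full per-sequence row", {
  set.seed(6)
  mod <- markov_model(make_abundances(8, "geometric", 0.8), 0.3)
  seq <- sample_markov_sequence(mod, 120)
  row <- estimate_all(seq)
  expect_named(row, c("m", "v", "pi_hat", "delta_hat", "used_fallback",
                      "gini_ml", "gini_unbiased", "gini_markov",
                      "rao_ml", "rao_unbiased", "rao_markov"))
  # identity distances by default: Rao columns equal Gini columns
  expect_equal(row$rao_ml, row$gini_ml)
  expect_equal(row$rao_markov, row$gini_markov)
  # single-species degenerate sample: markov columns unavailable
  expect_warning(row2 <- estimate_all(rep("A", 5)), "NA")
  expect_true(is.na(row2$gini_markov))
})
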