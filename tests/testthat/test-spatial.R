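region_sq <- c(0, 100, 0, 100)

test_that("point communities validate their region", {
  df <- data.frame(x = c(1, 99), y = c(1, 50), species = c("a", "b"))
  com <- as_point_community(df, region_sq)
  expect_equal(community_region(com), region_sq)
  expect_error(as_point_community(df, c(0, 10, 0, 10)), "inside the region")
  expect_error(as_point_community(df[0, ], region_sq), "at least one")
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, f)
  expect_equal(nrow(load_point_community(f, region_sq)), 2L)
})

test_that("transect placement starts on the edge and points inward", {
  for (k in 1:50) {
    tr <- place_transect(region_sq, width = 1, seed = k)
    s <- tr$start
    on_edge <- any(abs(s - region_sq[c(1, 3)]) < 1e-12) ||
      any(abs(s - region_sq[c(2, 4)]) < 1e-12)
    expect_true(on_edge)
    expect_gt(tr$length, 0)
    step <- s + 1e-6 * c(cos(tr$angle), sin(tr$angle))
    expect_true(step[1] >= region_sq[1] && step[1] <= region_sq[2] &&
                  step[2] >= region_sq[3] && step[2] <= region_sq[4])
    end <- s + tr$length * c(cos(tr$angle), sin(tr$angle))
    expect_true(all(end >= region_sq[c(1, 3)] - 1e-9) &&
                  all(end <= region_sq[c(2, 4)] + 1e-9))
  }
  tr_in <- place_transect(region_sq, edge_start = FALSE, seed = 1)
  expect_true(tr_in$start[1] > 0 && tr_in$start[1] < 100)
})

test_that("band membership uses closed boundaries", {
  tr <- structure(list(start = c(0, 50), angle = 0, width = 2, length = 100),
                  class = "transect")
  com <- as_point_community(
    data.frame(x = c(50, 30, 30, 10, 99),
               y = c(50, 51, 51.0001, 49.5, 50),
               species = c("on_line", "on_edge", "outside", "in_band", "far")),
    region_sq)
  inb <- individuals_in_band(com, tr)
  expect_setequal(inb$species, c("on_line", "on_edge", "in_band", "far"))
})

test_that("distance ordering is correct and ties are random", {
  rec <- data.frame(x = c(3, 1, 2), y = 0, species = c("c", "a", "b"))
  expect_equal(order_by_distance(rec, c(0, 0))$species, c("a", "b", "c"))
  tie <- data.frame(x = c(1, -1), y = 0, species = c("p", "q"))
  first <- vapply(1:400, function(k)
    order_by_distance(tie, c(0, 0), seed = k)$species[1], character(1))
  expect_gt(mean(first == "p"), 0.4)
  expect_lt(mean(first == "p"), 0.6)
  expect_error(order_by_distance(rec[0, ], c(0, 0)), "no individuals")
})

test_that("synthetic communities conserve requested totals", {
  a <- make_abundances(7, "geometric", 0.7)
  com <- csr_community(a, 1000, region_sq, seed = 2)
  expect_equal(nrow(com), 1000L)
  tab <- table(factor(com$species, levels = a$species))
  expect_true(all(abs(tab - 1000 * a$p) < 3 * sqrt(1000 * a$p * (1 - a$p))))
  th <- thomas_community(a, 1000, region_sq, parents = 2, cluster_sd = 3, seed = 2)
  expect_equal(nrow(th), 1000L)
  # largest-remainder allocation is exact per species
  tab_th <- table(factor(th$species, levels = a$species))
  expect_true(all(abs(tab_th - 1000 * a$p) <= 1))
  expect_true(all(th$x >= 0 & th$x <= 100 & th$y >= 0 & th$y <= 100))
  # reproducibility
  expect_identical(th, thomas_community(a, 1000, region_sq, parents = 2,
                                        cluster_sd = 3, seed = 2))
})

test_that("transect sampling returns exactly m labels, deterministically", {
  a <- make_abundances(5, "uniform")
  com <- csr_community(a, 3000, region_sq, seed = 10)
  s1 <- transect_sample(com, 80, width = 2, seed = 3)
  expect_length(s1, 80L)
  expect_identical(s1, transect_sample(com, 80, width = 2, seed = 3))
  expect_error(transect_sample(com, 4000, width = 2, seed = 1), "census size")
})

test_that("no individual is surveyed twice", {
  # give every individual a unique label so identity survives in the sequence
  set.seed(44)
  n <- 600
  com <- as_point_community(
    data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100),
               species = sprintf("ind%04d", 1:n)),
    region_sq)
  seq <- transect_sample(com, 400, width = 10, seed = 5)
  expect_equal(anyDuplicated(seq), 0L)
})

test_that("aggregated communities induce sequential dependence, CSR does not", {
  a <- make_abundances(10, "geometric", 0.8)
  clus <- thomas_community(a, 8000, region_sq, parents = 2, cluster_sd = 3,
                           seed = 20)
  csr <- csr_community(a, 8000, region_sq, seed = 21)
  set.seed(22)
  v_clus <- replicate(150, solow_v(transect_sample(clus, 200, width = 2)))
  v_csr <- replicate(150, solow_v(transect_sample(csr, 200, width = 2)))
  expect_gt(mean(v_clus), mean(v_csr) + 0.05)
  # CSR sequences look independent: v close to the census Simpson concentration
  conc <- sum(census_abundances(csr)$p^2)
  expect_lt(abs(mean(v_csr) - conc), 3 * mc_se(v_csr) + 0.01)
})

test_that("dependence weakens as the cluster scale grows", {
  a <- make_abundances(10, "geometric", 0.8)
  set.seed(33)
  mean_v <- vapply(c(2, 8, 40), function(sd) {
    com <- thomas_community(a, 8000, region_sq, parents = 2, cluster_sd = sd)
    mean(replicate(120, solow_v(transect_sample(com, 200, width = 2))))
  }, numeric(1))
  expect_true(all(diff(mean_v) <= 0.02))  # non-increasing up to MC slack
  expect_gt(mean_v[1], mean_v[3])
})
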