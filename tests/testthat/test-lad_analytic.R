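test_that("extinction probability is the minimal quadratic root", {
  expect_equal(extinction_prob(0.5, 0), 0)
  expect_equal(extinction_prob(0.4, 0.1), 0.25)
  # critical limit
  expect_gt(extinction_prob(0.3001, 0.3), 0.999)
  expect_error(extinction_prob(0.2, 0.3), "supercritical")
  # Monte-Carlo cross-check: single-lineage eventual extinction frequency
  set.seed(11)
  b <- 0.4; d <- 0.1
  died <- replicate(1e4, {
    n <- 1
    for (g in 1:60) {
      if (n == 0) break
      x <- stats::runif(n)
      n <- 2 * sum(x < b) + sum(x >= b + d)
      if (n > 200) break              # escaped: counts as survival
    }
    n == 0
  })
  expect_lt(abs(mean(died) - 0.25), 0.02)
})

test_that("MRCA wait is geometric in s and matches the genealogy simulator", {
  expect_equal(mrca_wait_pmf(1, 5), c(1, 0, 0, 0, 0))
  expect_equal(mrca_wait_pmf(0.5, 3), c(0.5, 0.25, 0.125))
  # driver present from generation 1 in every lineage (r=0, eps=0): LAD is
  # exactly the wait of that clone, so the simulator is the oracle for the
  # geometric law. The law describes a single clone's MRCA wait, so tumors
  # where two independent clones competed are excluded.
  for (bd in list(c(0.5, 0), c(0.7, 0.2))) {
    sim <- simulate_tumors(division_params(b = bd[1], d = bd[2]),
                           repair_params(0, 0, 0), n_tumors = 1e4,
                           config = fast_sim_config, seed = 12)
    wait <- sim$tumors$lad[sim$tumors$n_clones == 1]
    s <- bd[1] - bd[2]
    expect_lt(abs(mean(wait) - 1 / s), 0.02 / s)
    p <- chisq_gof_p(lad_counts(wait, 10)[-1],
                     c(mrca_wait_pmf(s, 9), 1 - sum(mrca_wait_pmf(s, 9))))
    expect_gt(p, 0.01)
  }
})

test_that("analytic pmf reproduces the no-repair edge case and the u = 0 law", {
  pm <- lad_pmf(0.6, 0, 0, 0, n_max = 12, horizon = 15, tail = "lump")
  expect_equal(unname(pm$p["0"]), 0)
  expect_equal(unname(lad_pmf(0.5, 0.3, 0, 0.4, n_max = 10)$p["0"]), 0)
  # with no repair every generation-1 cell founds a driver clone; the
  # per-clone wait is geometric and the whole-tumor law (with clonal
  # competition) is checked against the simulator
  sim <- simulate_tumors(division_params(s = 0.6), repair_params(0, 0, 0),
                         n_tumors = 8000, config = fast_sim_config, seed = 14)
  expect_gt(chisq_gof_p(lad_counts(sim$tumors$lad, 12), pm$p), 0.01)
  one <- sim$tumors$lad[sim$tumors$n_clones == 1]
  geom <- 0.6 * 0.4^(0:9)
  expect_gt(chisq_gof_p(lad_counts(one, 10)[-1],
                        c(geom[1:9], 1 - sum(geom[1:9]))), 0.01)
})

test_that("analytic pmf is a proper distribution with dominance in s", {
  for (s in c(0.3, 0.6, 0.9)) for (r in c(0.1, 0.4)) for (eps in c(0.15, 0.75)) {
    pm <- lad_pmf(s, r, min(0.05, r), eps, n_max = 15)
    expect_true(all(pm$p >= 0))
    expect_lt(abs(sum(pm$p) - 1), 1e-9)
  }
  p_lo <- cumsum(lad_pmf(0.3, 0.2, 0.05, 0.15)$p)
  p_hi <- cumsum(lad_pmf(0.8, 0.2, 0.05, 0.15)$p)
  expect_true(all(p_hi >= p_lo - 1e-9))
})

test_that("probability of an immediate MRCA increases with mutagenic repair", {
  # r - u fixed while u rises (Fig-2C-style sweep)
  p0 <- vapply(seq(0.05, 0.55, by = 0.1), function(u)
    unname(lad_pmf(0.6, u + 0.15, u, 0.15, n_max = 10)$p["0"]), numeric(1))
  expect_true(all(diff(p0) > 0))
})

test_that("analytic pmf matches the simulator at a non-trivial parameter set", {
  pm <- lad_pmf(0.6, 0.2, 0.05, 0.15, n_max = 12, horizon = 15, tail = "lump")
  sim <- simulate_tumors(division_params(s = 0.6), repair_params(0.2, 0.05, 0.15),
                         n_tumors = 8000, config = fast_sim_config, seed = 13)
  expect_gt(chisq_gof_p(lad_counts(sim$tumors$lad, 12), pm$p), 0.01)
})
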