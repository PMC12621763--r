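test_that("parameter constructors validate their invariants", {
  expect_error(division_params(b = 0.4, d = 0.4), "supercritical")
  expect_error(division_params(b = 0.7, d = 0.5), "exceed 1")
  expect_error(division_params(s = -0.1), "0, 1|supercritical")
  expect_equal(division_params(s = 0.6)$b, 0.6)
  expect_equal(division_params(b = 0.8, d = 0.2)$s, 0.6)
  expect_error(repair_params(0.2, 0.3, 0.5), "cannot exceed")
  expect_error(repair_params(1.2, 0.1, 0.5), "0, 1")
})

test_that("certain repair and certain error-free replication are deterministic", {
  set.seed(1)
  for (i in 1:20) {
    full <- step_driver_locus("LESION_ONE_STRAND", repair_params(1, 0, 0.5))
    expect_equal(full$post_repair, "WILDTYPE")
    expect_equal(full$daughters, c("WILDTYPE", "WILDTYPE"))
    ef <- step_driver_locus("LESION_ONE_STRAND", repair_params(0, 0, 1))
    expect_setequal(ef$daughters, c("LESION_ONE_STRAND", "WILDTYPE"))
  }
})

test_that("lesion-strand outcome frequencies match the repair/translesion rates", {
  set.seed(42)
  r <- 0.3; u <- 0.1; eps <- 0.4
  rp <- repair_params(r, u, eps)
  n <- 1e5
  # outcome of one cycle from a single-strand lesion, classified by the
  # four exclusive routes of the repair/replication schema
  outs <- vapply(seq_len(n), function(i) {
    st <- step_driver_locus("LESION_ONE_STRAND", rp)
    if (st$post_repair == "WILDTYPE") "full_repair"
    else if (st$post_repair == "HETERODUPLEX") "mutagenic"
    else if ("LESION_ONE_STRAND" %in% st$daughters) "tls_error_free"
    else "tls_error"
  }, character(1))
  expected <- c(full_repair = r - u, mutagenic = u,
                tls_error_free = (1 - r) * eps, tls_error = (1 - r) * (1 - eps))
  for (k in names(expected)) {
    p <- expected[[k]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(outs == k) - p), 4 * se)
  }
})

test_that("division outcomes and lesion segregation follow the branching law", {
  kar <- karyotype_synthetic(n_chrom = 10, genome_mb = 100)
  cell <- new_cell(kar)
  set.seed(7)
  always <- divide(cell, division_params(b = 1, d = 0))
  expect_equal(always$n_stem, 2L)
  dead <- divide(cell, division_params(b = 0.5, d = 0),
                 b_override = 0, d_override = 1)
  expect_equal(dead$n_stem, 0L)
  # outcome frequencies and twofold lesion dilution
  b <- 0.4; d <- 0.25
  n <- 1e5
  res <- replicate(n, {
    o <- divide(cell, division_params(b = b, d = d))
    c(o$n_stem, if (o$n_stem > 0) sum(o$daughters[[1]]$lesion_strands) else NA)
  })
  for (pair in list(c(2, b), c(0, d), c(1, 1 - b - d))) {
    p <- pair[2]; se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(res[1, ] == pair[1]) - p), 4 * se)
  }
  lesions <- res[2, !is.na(res[2, ])]
  expect_lt(abs(mean(lesions) - sum(cell$lesion_strands) / 2),
            4 * sqrt(5 / length(lesions)))
})

test_that("exhaustive duplex-state cases pin LAD to 0 and 1", {
  # certain mutagenic repair before the first division: the exposed cell
  # itself is the MRCA
  s0 <- simulate_tumors(division_params(b = 1, d = 0), repair_params(1, 1, 0.5),
                        n_tumors = 30, seed = 3)
  expect_true(all(s0$tumors$lad == 0))
  # no repair, certain erroneous replication: every generation-1 cell is a
  # surviving heteroduplex founding two surviving lineages
  s1 <- simulate_tumors(division_params(b = 1, d = 0), repair_params(0, 0, 0),
                        n_tumors = 30, seed = 4)
  expect_true(all(s1$tumors$lad == 1))
})

test_that("no mutagenic repair makes LAD zero impossible", {
  sim <- simulate_tumors(division_params(s = 0.6), repair_params(0.3, 0, 0.3),
                         n_tumors = 2000, config = fast_sim_config, seed = 5)
  expect_true(all(sim$tumors$lad > 0))
})

test_that("simulated LAD point mass and stochastic dominance in s", {
  d1 <- simulate_lad_distribution(division_params(b = 1, d = 0),
                                  repair_params(0, 0, 0), n_tumors = 200,
                                  n_max = 10, seed = 6)
  expect_equal(unname(d1$counts["1"]), 200)
  # Fig-2A-style shift: larger s moves LAD mass toward 0 (CDF dominance)
  rp <- repair_params(0.2, 0.05, 0.15)
  lo <- simulate_tumors(division_params(s = 0.2), rp, n_tumors = 3000,
                        config = fast_sim_config, seed = 7)$tumors$lad
  hi <- simulate_tumors(division_params(s = 0.8), rp, n_tumors = 3000,
                        config = fast_sim_config, seed = 8)$tumors$lad
  cdf_lo <- cumsum(lad_counts(lo, 10)) / 3000
  cdf_hi <- cumsum(lad_counts(hi, 10)) / 3000
  expect_true(all(cdf_hi >= cdf_lo - 0.02))
  expect_gt(mean(lo), mean(hi))
})

test_that("multi-driver simulation produces distributions for 1-5 drivers", {
  # final joint selective advantage 0.6 under the multi-driver setting
  for (k in c(1, 3, 5)) {
    d <- simulate_lad_distribution(division_params(s = 0.6),
                                   repair_params(0.2, 0.05, 0.45),
                                   n_drivers = k, n_tumors = 50, n_max = 15,
                                   config = list(horizon = 15, cap = 1500,
                                                 max_attempts = 5000),
                                   seed = 100 + k)
    expect_equal(d$n, 50)
  }
})
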