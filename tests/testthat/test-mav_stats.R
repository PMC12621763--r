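test_that("independent co-occurrence expectation follows the birthday form", {
  e1 <- expected_independent_mavs(n_mut = 1, observed_mavs = 0,
                                  callable_sites = 1e6)
  expect_true(is.na(e1$enrichment))
  # uniform closed form: C(N,2)/G times the distinct-alternate probability
  e <- expected_independent_mavs(n_mut = 1000, observed_mavs = 0,
                                 callable_sites = 1e6)
  expect_equal(e$expected_uniform, choose(1000, 2) / 1e6 * (2 / 3),
               tolerance = 1e-12)
  expect_equal(choose(1000, 2) / 1e6, 0.4995)
  expect_equal(e$expected, e$expected_uniform, tolerance = 0.01)
  # Monte-Carlo oracle
  set.seed(61)
  N <- 2000; G <- 1e5
  obs <- replicate(60, {
    site <- sample.int(G, N, replace = TRUE)
    alt <- sample.int(3, N, replace = TRUE)
    sum(vapply(split(alt, site)[table(site) >= 2], function(a)
      length(unique(a)) >= 2, logical(1)))
  })
  e2 <- expected_independent_mavs(n_mut = N, observed_mavs = 0,
                                  callable_sites = G)
  expect_lt(abs(mean(obs) - e2$expected) / e2$expected, 0.05)
})

test_that("a lesion-segregation sample is flagged as MAV-enriched", {
  set.seed(62)
  s <- gen_metastatic_sample(n_mavs = 8, background_mutations = 5000, seed = 63)
  tab <- normalize_mutations(data.frame(chrom = s$mutations$chrom,
                                        pos0 = s$mutations$pos - 1L,
                                        ref = s$mutations$ref,
                                        alt = s$mutations$alt))
  res <- expected_independent_mavs(
    tab, callable_sites = sum(karyotype_human("female")$length_bp))
  expect_gt(res$enrichment, 10)
  expect_true(res$enriched)
})

test_that("enrichment is near one under the independence null", {
  set.seed(64)
  G <- 2e5; N <- 2000
  ratio <- replicate(200, {
    site <- sample.int(G, N, replace = TRUE)
    alt <- sample.int(3, N, replace = TRUE)
    obs <- sum(vapply(split(alt, site)[table(site) >= 2], function(a)
      length(unique(a)) >= 2, logical(1)))
    obs / expected_independent_mavs(n_mut = N, observed_mavs = 0,
                                    callable_sites = G)$expected
  })
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("pair-spectrum cosine behaves on identical, disjoint and rescaled profiles", {
  sig <- chemo_spectrum()
  pp <- signature_pair_profile(sig)
  expect_equal(cosine_similarity(pp, pp), 1)
  expect_equal(cosine_similarity(pp, 5000 * pp), 1)  # scale invariance
  q <- pp; q[pp > 0] <- 0; q[which(pp == 0)[1:10]] <- 0.1
  expect_equal(cosine_similarity(pp, q), 0)
  expect_error(cosine_similarity(pp, 0 * pp), "zero-norm")
})

test_that("planted-signature MAVs resemble the signature more than independence", {
  set.seed(65)
  sig <- chemo_spectrum()
  flat <- setNames(rep(1 / 96, 96), sbs_channels())
  wins <- replicate(100, {
    s <- gen_metastatic_sample(n_mavs = 10, background_mutations = 200,
                               seed = sample.int(1e6, 1))
    mv <- s$mutations[duplicated(s$mutations[c("chrom", "pos")]) |
                        duplicated(s$mutations[c("chrom", "pos")], fromLast = TRUE), ]
    key <- paste(mv$chrom, mv$pos)
    mav_tab <- do.call(rbind, lapply(unique(key), function(k) {
      ev <- mv[key == k, ]
      if (length(unique(ev$alt)) < 2) return(NULL)
      data.frame(context = ev$context[1], alt1 = ev$alt[1], alt2 = ev$alt[2])
    }))
    sim <- mav_spectrum_similarity(mav_tab, flat, sig)
    sim$cos_signature > sim$cos_independent
  })
  expect_gte(mean(wins), 0.95)
})

test_that("the phasing trend test detects perfect matching in the top category", {
  # frozen oracle value from stats::prop.trend.test on this table
  top <- phasing_trend_test(matching = c(15, 15, 16), totals = c(30, 30, 16))
  expect_equal(top$p.value, 0.003268131, tolerance = 1e-5)
  expect_lt(top$p.value, 0.01)
  flat <- suppressWarnings(
    phasing_trend_test(matching = c(20, 10, 5), totals = c(40, 20, 10)))
  expect_equal(unname(flat$statistic), 0)
  expect_error(phasing_trend_test(matching = 16, totals = 16), "two ordered")
  # null calibration: p roughly uniform under equal proportions
  set.seed(66)
  ps <- replicate(300, {
    m <- stats::rbinom(3, c(40, 40, 40), 0.5)
    phasing_trend_test(m, c(40, 40, 40))$p.value
  })
  expect_lt(abs(mean(ps) - 0.5), 0.08)
})

test_that("lesion MAVs phase to the same allele; detection bias disfavors matching", {
  set.seed(67)
  s <- gen_metastatic_sample(n_mavs = 12, background_mutations = 100, seed = 68)
  expect_true(all(s$phased_mavs$truth_phase == "matching"))
  expect_true(all(s$phased_mavs$phase %in% c("matching", "unphased")))
  # independent doubles phase 50/50 before bias; the same-allele detection
  # handicap can only push the observed matching proportion below half
  p_same_detect <- 2^(-(0:300) / 150)
  expect_true(all(p_same_detect <= 1))
  n <- 2000
  same <- stats::runif(n) < 0.5
  d <- sample(0:300, n, replace = TRUE)
  detected <- ifelse(same, stats::runif(n) < 2^(-d / 150), TRUE)
  matching_prop <- sum(same & detected) / sum(detected)
  expect_lte(matching_prop, 0.5)
})
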