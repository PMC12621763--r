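toy_karyotype <- data.frame(chrom = c("chr1", "chr2"),
                            length_bp = c(5e6, 3e6))

test_that("binning counts MAV sites once and respects the karyotype", {
  muts <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                     pos0 = c(100L, 100L, 2500000L, 10L, 10L),
                     ref = c("T", "T", "C", "T", "T"),
                     alt = c("A", "C", "T", "A", "A"))
  tr <- build_segments(muts, toy_karyotype, bin_size = 1e6)
  expect_equal(nrow(tr), 8)  # 5 + 3 bins
  # site with alts {A,C} is one MAV; duplicate alt {A,A} is none
  expect_equal(tr$n_mav[tr$chrom == "chr1" & tr$start == 0], 1)
  expect_equal(sum(tr$n_mav[tr$chrom == "chr2"]), 0)
  expect_error(build_segments(muts[0, ], toy_karyotype), "empty")
  expect_warning(
    build_segments(data.frame(chrom = c("chr1", "chrZ"), pos0 = c(1L, 1L),
                              ref = "T", alt = "A"), toy_karyotype),
    "off the karyotype")
})

test_that("saturated and empty tracks decode to the extreme states", {
  kar <- data.frame(chrom = "chr1", length_bp = 50e6)
  tr <- build_segments(data.frame(chrom = "chr1", pos0 = 1L, ref = "T", alt = "A"),
                       kar, bin_size = 1e6)
  tr$n_mav <- rpois(50, 8)  # MAV-rich at 2*lambda with lambda = 4
  dec <- decode_lesion_states(tr, config = list(lambda = 4))
  expect_true(all(dec$viterbi == 3))
  tr$n_mav <- rep(0L, 50); tr$n_mav[1] <- 1L  # near-empty, large lambda
  dec0 <- decode_lesion_states(tr, config = list(lambda = 50, min_mav_sites = 1))
  expect_true(all(dec0$viterbi[-1] == 1))
  tr$n_mav <- rep(0L, 50)
  expect_false(decode_lesion_states(tr)$estimable)
})

test_that("posteriors are proper and Viterbi beats exhaustive enumeration", {
  set.seed(21)
  kar <- data.frame(chrom = "chr1", length_bp = 8e6)
  tr <- build_segments(data.frame(chrom = "chr1", pos0 = 1L, ref = "T", alt = "A"),
                       kar, bin_size = 1e6)
  tr$n_mav <- c(5L, 6L, 0L, 0L, 3L, 2L, 7L, 6L)
  dec <- decode_lesion_states(tr, config = list(lambda = 3, rho = 2e-7))
  expect_true(all(abs(rowSums(dec$posteriors) - 1) < 1e-9))
  # brute force over all 3^8 paths
  Tm <- lesionlad:::.hmm_transition(2e-7, 1e6)
  logE <- lesionlad:::.hmm_log_emission(tr$n_mav, 3, 1e-3)
  paths <- as.matrix(expand.grid(rep(list(1:3), 8)))
  lp <- apply(paths, 1, function(st) {
    ll <- log(dec$prior[st[1]]) + logE[1, st[1]]
    for (t in 2:8) ll <- ll + log(Tm[st[t - 1], st[t]]) + logE[t, st[t]]
    ll
  })
  expect_equal(unname(paths[which.max(lp), ]), dec$viterbi)
})

test_that("LAD-2 occupancy approaches the binomial segregation law", {
  # one homolog pair per chromosome-like block, states from Binomial(2, 1/2),
  # 1e4 bins in total
  set.seed(22)
  n_blocks <- 500; bins_per <- 20; lambda <- 5
  kar <- data.frame(chrom = paste0("c", seq_len(n_blocks)),
                    length_bp = bins_per * 1e6)
  copies <- stats::rbinom(n_blocks, 2, 0.5)
  tr <- build_segments(data.frame(chrom = "c1", pos0 = 1L, ref = "T", alt = "A"),
                       kar, bin_size = 1e6)
  tr$n_mav <- stats::rpois(n_blocks * bins_per, lambda * rep(copies, each = bins_per))
  dec <- decode_lesion_states(tr)
  occ <- colMeans(dec$posteriors)
  expect_lt(max(abs(occ - c(0.25, 0.5, 0.25))), 0.05)
  est <- estimate_lad(tr, dec, n_boot = 0)
  expect_equal(est$n_hat, 2L)
})

test_that("occupancy algebra and LAD-0/1 disambiguation behave as specified", {
  set.seed(23)
  kar <- karyotype_synthetic()
  # a state-3 genome with strand asymmetry is one division old ...
  co1 <- gen_tumor_cohort(n_tumors = 1, lad_values = 1, seed = 31)
  e1 <- estimate_lad_for(co1$tumors[[1]], kar)
  expect_equal(e1$n_hat, 1L)
  expect_false(e1$lad0_flag)
  expect_gt(e1$mean_abs_asym, 0.5)
  expect_gt(e1$p3, 0.9)
  # ... while without asymmetry it is the exposed cell itself
  co0 <- gen_tumor_cohort(n_tumors = 1, lad_values = 0, seed = 32)
  e0 <- estimate_lad_for(co0$tumors[[1]], kar)
  expect_equal(e0$n_hat, 0L)
  expect_true(e0$lad0_flag)
  expect_lt(e0$mean_abs_asym, 0.25)
})

test_that("median estimate is unbiased per LAD and robust to MAV density", {
  set.seed(24)
  kar <- karyotype_synthetic()
  for (n in 0:5) {
    co <- gen_tumor_cohort(n_tumors = 15, lad_values = n, seed = 40 + n)
    est <- vapply(co$tumors, function(m) estimate_lad_for(m, kar)$n_hat,
                  integer(1))
    # at LAD 5 a tumor can lose every lesion strand and be inestimable
    expect_equal(unname(median(est, na.rm = TRUE)), n,
                 info = paste("true LAD", n))
  }
  # halving the MAV rate leaves the estimate unbiased (f depends on
  # occupancy, not on lambda)
  for (rate in c(3, 1.5)) {
    co <- gen_tumor_cohort(n_tumors = 7, lad_values = 2, mav_per_mb = rate,
                           seed = 50 + rate * 2)
    est <- vapply(co$tumors, function(m) estimate_lad_for(m, kar)$n_hat,
                  integer(1))
    expect_equal(unname(median(est)), 2)
  }
})

test_that("decoded segments export merged BED intervals", {
  kar <- data.frame(chrom = "chr1", length_bp = 6e6)
  tr <- build_segments(data.frame(chrom = "chr1", pos0 = 1L, ref = "T", alt = "A"),
                       kar, bin_size = 1e6)
  tr$n_mav <- c(8L, 9L, 8L, 4L, 0L, 0L)
  dec <- decode_lesion_states(tr, config = list(lambda = 4, rho = 1e-6))
  bed <- decoded_segments_bed(tr, dec)
  # copy number can only change by one homolog per breakpoint
  expect_equal(nrow(bed), 3)
  expect_equal(bed$start, c(0, 3e6, 4e6))
  expect_equal(bed$state, c(3, 2, 1))
})
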