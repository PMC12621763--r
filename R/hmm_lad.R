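#' Bin a mutation table into a genome segment track
#'
#' Deterministic fixed-width binning (0-based half-open) over the
#' karyotype. Each bin records the total mutation-record count and the
#' number of multiallelic sites (a site with >= 2 distinct alternate
#' alleles counts once, in the bin containing its position). Per-chromosome
#' Watson-Crick asymmetry of non-MAV mutations (pyrimidine- vs
#' purine-reference counts) is attached for LAD-0 diagnostics.
#'
#' @param mutations mutation table as from [read_mutation_table()].
#' @param karyotype data.frame `chrom`, `length_bp`.
#' @param bin_size bin width in bp (default 1 Mb).
#' @return object of class `segment_track`: data.frame `chrom`, `start`,
#'   `end`, `n_mut`, `n_mav` with attributes `bin_size`, `karyotype`,
#'   `wc_asym` (per-chromosome asymmetry data.frame).
#' @export
build_segments <- function(mutations, karyotype, bin_size = 1e6) {
  if (nrow(mutations) == 0) stop("empty mutation table")
  mutations <- normalize_mutations(mutations, karyotype)
  bins <- do.call(rbind, lapply(seq_len(nrow(karyotype)), function(i) {
    len <- karyotype$length_bp[i]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = karyotype$chrom[i], start = start,
               end = pmin(start + bin_size, len), stringsAsFactors = FALSE)
  }))
  key <- function(chrom, pos0) paste(chrom, pos0 %/% bin_size)
  bin_key <- key(bins$chrom, bins$start)
  bins$n_mut <- as.vector(table(factor(key(mutations$chrom, mutations$pos0),
                                       levels = bin_key)))
  mav_sites <- unique(mutations[mutations$is_mav, c("chrom", "pos0")])
  bins$n_mav <- as.vector(table(factor(key(mav_sites$chrom, mav_sites$pos0),
                                       levels = bin_key)))
  non_mav <- mutations[!mutations$is_mav, , drop = FALSE]
  asym <- NULL
  if (nrow(non_mav) > 0) {
    pyr <- non_mav$ref %in% c("C", "T")
    tb <- table(factor(non_mav$chrom, levels = karyotype$chrom), pyr)
    n_pur <- if ("FALSE" %in% colnames(tb)) tb[, "FALSE"] else rep(0, nrow(tb))
    n_pyr <- if ("TRUE" %in% colnames(tb)) tb[, "TRUE"] else rep(0, nrow(tb))
    tot <- n_pur + n_pyr
    asym <- data.frame(chrom = karyotype$chrom,
                       n_pyr = as.numeric(n_pyr), n_pur = as.numeric(n_pur),
                       asym = ifelse(tot > 0, (n_pyr - n_pur) / tot, NA),
                       stringsAsFactors = FALSE)
  }
  structure(bins, bin_size = bin_size, karyotype = karyotype, wc_asym = asym,
            class = c("segment_track", "data.frame"))
}

# log emission matrix: n_mav ~ Poisson(lambda * (copies + bg) * exposure),
# exposure = bin width / nominal bin size (partial chromosome-end bins)
.hmm_log_emission <- function(n_mav, lambda, bg = 1e-3, exposure = 1) {
  vapply(0:2, function(k)
    stats::dpois(n_mav, lambda * (k + bg) * exposure, log = TRUE),
    numeric(length(n_mav)))
}

.hmm_transition <- function(rho, bin_size) {
  tau <- 1 - exp(-max(rho, 1e-12) * bin_size)
  matrix(c(1 - tau, tau, 0,
           tau / 2, 1 - tau, tau / 2,
           0, tau, 1 - tau), 3, 3, byrow = TRUE)
}

# scaled forward-backward (+ optional Viterbi) on one chromosome
.hmm_chrom <- function(logE, Tm, prior, viterbi = TRUE) {
  n <- nrow(logE)
  logT <- log(pmax(Tm, 1e-300))
  la <- matrix(-Inf, n, 3); lb <- matrix(0, n, 3)
  la[1, ] <- log(prior) + logE[1, ]
  if (n > 1) for (t in seq_len(n - 1)) {
    m <- la[t, ]; mx <- max(m)
    la[t + 1, ] <- mx + log(exp(m - mx) %*% Tm) + logE[t + 1, ]
  }
  if (n > 1) for (t in rev(seq_len(n - 1))) {
    m <- logE[t + 1, ] + lb[t + 1, ]; mx <- max(m)
    lb[t, ] <- mx + log(Tm %*% exp(m - mx))
  }
  lg <- la + lb
  mx <- apply(lg, 1, max)
  post <- exp(lg - mx)
  post <- post / rowSums(post)
  ll <- { x <- la[n, ]; m0 <- max(x); m0 + log(sum(exp(x - m0))) }
  path <- NULL
  if (viterbi) {
    dv <- matrix(-Inf, n, 3); bp <- matrix(0L, n, 3)
    dv[1, ] <- log(prior) + logE[1, ]
    if (n > 1) for (t in 2:n) {
      cand <- dv[t - 1, ] + logT      # cand[i, j]: from i to j
      bp[t, ] <- max.col(t(cand), ties.method = "first")
      dv[t, ] <- cand[cbind(bp[t, ], 1:3)] + logE[t, ]
    }
    path <- integer(n); path[n] <- which.max(dv[n, ])
    if (n > 1) for (t in rev(seq_len(n - 1))) path[t] <- bp[t + 1, path[t + 1]]
  }
  # expected number of state changes between adjacent bins (for rho EM)
  n_switch <- 0
  if (n > 1) for (t in seq_len(n - 1)) {
    lj <- outer(la[t, ], logE[t + 1, ] + lb[t + 1, ], "+") + logT
    pj <- exp(lj - max(lj))
    n_switch <- n_switch + 1 - sum(diag(pj)) / sum(pj)
  }
  list(post = post, path = path, loglik = ll, n_switch = n_switch)
}

#' Decode lesion-homolog copy states along the genome
#'
#' Three-state HMM over genome bins: states 1/2/3 are 0/1/2 lesion-bearing
#' homologs; MAV counts are Poisson with mean proportional to the lesion
#' copy number; transitions between adjacent copy numbers model mitotic
#' recombination breakpoints (per-bin probability `1 - exp(-rho bin)`).
#' Emission rate `lambda`, breakpoint rate `rho` and the stationary prior
#' are estimated by EM, run from several `lambda` starts to bracket the
#' copy-number/rate ambiguity; chromosome boundaries reset the chain to
#' the prior. Posteriors are computed in log space.
#'
#' @param track a [build_segments()] track.
#' @param config list overriding `lambda` (fix instead of EM), `rho`,
#'   `em_rounds` (default 10), `bg` (background emission fraction, default
#'   1e-3), `prior`, and `min_mav_sites` (minimum genome-wide MAV count
#'   for the decoding to be attempted, default 5).
#' @return object of class `lesion_decoding`: list with `posteriors`
#'   (bins x 3), `viterbi`, `lambda`, `rho`, `prior`, `loglik`,
#'   `estimable`.
#' @export
decode_lesion_states <- function(track, config = list()) {
  stopifnot(inherits(track, "segment_track"))
  cfg <- list(lambda = NULL, rho = NULL, em_rounds = 10, bg = 1e-3,
              prior = c(1, 1, 1) / 3, min_mav_sites = 5)
  cfg[names(config)] <- config
  bin_size <- attr(track, "bin_size")
  if (sum(track$n_mav) < max(cfg$min_mav_sites, 1))
    return(structure(list(estimable = FALSE, posteriors = NULL,
                          viterbi = NULL, lambda = NA, rho = NA,
                          prior = cfg$prior, loglik = NA),
                     class = "lesion_decoding"))
  lam_all <- max(sum(track$n_mav) / nrow(track), 1e-6)
  lam_nz <- mean(track$n_mav[track$n_mav > 0])
  # bracket the copy-number/rate ambiguity: EM is run from each start and
  # the solution with the best likelihood kept
  inits <- if (!is.null(cfg$lambda)) cfg$lambda
           else unique(c(lam_nz, lam_nz / 2, lam_all))
  fits <- lapply(inits, function(l0)
    .decode_em(track, l0, cfg, bin_size))
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  # likelihood tie (near-homogeneous genomes; same parameter count):
  # independent homolog retention makes the occupancy binomial(2, q), so
  # among statistically indistinguishable solutions the one closest to
  # that family is the physical one
  binom_dist <- function(f) {
    p <- colMeans(f$posteriors)
    q <- (p[2] + 2 * p[3]) / 2
    sum(abs(p - stats::dbinom(0:2, 2, q)))
  }
  best <- which(ll > max(ll) - 2)
  pick <- best[which.min(vapply(fits[best], binom_dist, numeric(1)))]
  structure(fits[[pick]], class = "lesion_decoding")
}

.decode_em <- function(track, lambda, cfg, bin_size) {
  # init at the scale of a few recombination breakpoints per genome;
  # a loose start lets the chain absorb Poisson noise as state switches
  rho <- if (!is.null(cfg$rho)) cfg$rho else 0.01 / bin_size
  prior <- cfg$prior / sum(cfg$prior)
  chroms <- split(seq_len(nrow(track)), track$chrom)
  fit <- NULL
  exposure <- (track$end - track$start) / bin_size
  rounds <- cfg$em_rounds + 1  # final pass with converged parameters
  for (round in seq_len(rounds)) {
    Tm <- .hmm_transition(rho, bin_size)
    logE <- .hmm_log_emission(track$n_mav, lambda, cfg$bg, exposure)
    post <- matrix(NA_real_, nrow(track), 3)
    path <- integer(nrow(track))
    ll <- 0; n_switch <- 0; n_pairs <- 0
    for (idx in chroms) {
      hc <- .hmm_chrom(logE[idx, , drop = FALSE], Tm, prior,
                       viterbi = round == rounds)
      post[idx, ] <- hc$post
      if (round == rounds) path[idx] <- hc$path
      ll <- ll + hc$loglik
      n_switch <- n_switch + hc$n_switch
      n_pairs <- n_pairs + length(idx) - 1
    }
    fit <- list(posteriors = post, viterbi = path, lambda = lambda, rho = rho,
                prior = prior, loglik = ll, estimable = TRUE)
    if (round == rounds) break
    # EM updates
    e_copies <- (post %*% (0:2 + cfg$bg)) * exposure
    if (is.null(cfg$lambda))
      lambda <- max(sum(track$n_mav) / max(sum(e_copies), 1e-9), 1e-6)
    if (is.null(cfg$rho) && n_pairs > 0) {
      tau_hat <- min(max(n_switch / n_pairs, 1e-10), 0.5)
      rho <- max(-log(1 - tau_hat) / bin_size, 1e-12)
    }
    prior <- colMeans(post)
  }
  fit
}

#' Estimate per-tumor LAD from decoded lesion states
#'
#' The lesion-strand fraction is `f = (p2 + 2 p3) / 4`, the
#' genome-length-weighted expected number of retained lesion strands out of
#' the four strands of a homolog pair; under lesion segregation `f = 2^-n`
#' with `n` the LAD, so `n_hat = round(-log2 f)`. LAD 0 and 1 both give
#' state 3 genome-wide; they are disambiguated by the chromosome-scale
#' Watson-Crick asymmetry of non-MAV mutations (present for LAD >= 1 where
#' every homolog's mutations polarize to one inherited strand, absent for
#' LAD = 0) and by the per-copy MAV density (2 lambda vs lambda), both
#' logged in the result.
#'
#' @param track a [build_segments()] track.
#' @param decoding a [decode_lesion_states()] result.
#' @param n_max clamp for the point estimate.
#' @param asym_threshold mean |asymmetry| below which a state-3 genome is
#'   called LAD 0 (default 0.25).
#' @param n_boot chromosome-bootstrap replicates for the confidence
#'   interval.
#' @return object of class `lad_estimate`: list with `n_hat`, `f_hat`,
#'   `p1`, `p2`, `p3`, `lambda`, `rho`, `lad0_flag`, `mean_abs_asym`,
#'   `ci` (bootstrap interval for `n_hat`), `estimable`.
#' @export
estimate_lad <- function(track, decoding, n_max = 15, asym_threshold = 0.25,
                         n_boot = 50) {
  stopifnot(inherits(track, "segment_track"), inherits(decoding, "lesion_decoding"))
  if (!isTRUE(decoding$estimable))
    return(structure(list(estimable = FALSE, n_hat = NA_integer_,
                          f_hat = NA_real_, lad0_flag = FALSE),
                     class = "lad_estimate"))
  wt <- (track$end - track$start)
  occ <- function(post, w) {
    p <- colSums(post * w) / sum(w)
    p / sum(p)
  }
  p <- occ(decoding$posteriors, wt)
  f_from_p <- function(p) (p[2] + 2 * p[3]) / 4
  f <- f_from_p(p)
  if (f <= 0)
    return(structure(list(estimable = FALSE, n_hat = NA_integer_,
                          f_hat = 0, p1 = p[1], p2 = p[2], p3 = p[3],
                          lad0_flag = FALSE), class = "lad_estimate"))
  asym <- attr(track, "wc_asym")
  mean_abs_asym <- if (is.null(asym)) NA_real_ else {
    tot <- asym$n_pyr + asym$n_pur
    ok <- !is.na(asym$asym) & tot >= 10
    if (!any(ok)) NA_real_
    else sum(abs(asym$asym[ok]) * tot[ok]) / sum(tot[ok])
  }
  n_raw <- as.integer(max(0, min(n_max, round(-log2(f)))))
  lad0 <- p[3] > 0.9 && !is.na(mean_abs_asym) && mean_abs_asym < asym_threshold
  n_hat <- if (lad0) 0L else max(1L, n_raw)
  # chromosome bootstrap for the interval
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ch <- unique(track$chrom)
    boots <- vapply(seq_len(n_boot), function(i) {
      pick <- sample(ch, replace = TRUE)
      idx <- unlist(lapply(pick, function(cc) which(track$chrom == cc)))
      fb <- f_from_p(occ(decoding$posteriors[idx, , drop = FALSE], wt[idx]))
      if (fb <= 0) NA_real_ else -log2(fb)
    }, numeric(1))
    boots <- boots[is.finite(boots)]
    if (length(boots) >= 10)
      ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  structure(list(n_hat = n_hat, f_hat = f, p1 = p[1], p2 = p[2], p3 = p[3],
                 lambda = decoding$lambda, rho = decoding$rho,
                 lad0_flag = lad0, mean_abs_asym = mean_abs_asym,
                 ci = ci, estimable = TRUE),
            class = "lad_estimate")
}

#' @export
print.lad_estimate <- function(x, ...) {
  if (!isTRUE(x$estimable)) { cat("LAD not estimable\n"); return(invisible(x)) }
  cat(sprintf("LAD estimate: n = %d (f = %.4g; occupancies %.3f/%.3f/%.3f)\n",
              x$n_hat, x$f_hat, x$p1, x$p2, x$p3))
  cat(sprintf("  lambda = %.3g, rho = %.3g, LAD0 flag = %s, mean |WC asym| = %.3g\n",
              x$lambda, x$rho, x$lad0_flag, x$mean_abs_asym))
  invisible(x)
}

#' Decoded lesion-state segments as BED
#'
#' Merges runs of bins sharing a Viterbi state into BED intervals
#' (0-based half-open) with the state (1/2/3 = 0/1/2 lesion homologs) in
#' the name column.
#'
#' @param track a [build_segments()] track.
#' @param decoding a [decode_lesion_states()] result.
#' @return data.frame `chrom`, `start`, `end`, `state`.
#' @export
decoded_segments_bed <- function(track, decoding) {
  stopifnot(isTRUE(decoding$estimable))
  out <- list()
  for (cc in unique(track$chrom)) {
    idx <- which(track$chrom == cc)
    st <- decoding$viterbi[idx]
    runs <- rle(st)
    ends <- cumsum(runs$lengths)
    starts <- c(1, head(ends, -1) + 1)
    out[[cc]] <- data.frame(chrom = cc,
                            start = track$start[idx[starts]],
                            end = track$end[idx[ends]],
                            state = runs$values,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
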