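#' Exact (Garwood) Poisson confidence interval
#'
#' Chi-square-quantile inversion of the Poisson distribution: for an
#' observed count `c`, the lower bound is `qchisq(alpha/2, 2c)/2` (0 when
#' `c = 0`) and the upper bound `qchisq(1 - alpha/2, 2c + 2)/2`.
#'
#' @param count non-negative integer count (vectorised).
#' @param level confidence level, default 0.95.
#' @return matrix with columns `lower`, `upper`.
#' @export
poisson_ci <- function(count, level = 0.95) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("counts must be non-negative")
  if (any(count != round(count))) stop("counts must be integer")
  alpha <- 1 - level
  lower <- ifelse(count == 0, 0, stats::qchisq(alpha / 2, 2 * count) / 2)
  upper <- stats::qchisq(1 - alpha / 2, 2 * count + 2) / 2
  cbind(lower = lower, upper = upper)
}

#' Cohort LAD distribution with Poisson confidence intervals
#'
#' Tabulates per-tumor LAD values (or takes pre-tabulated counts) over
#' `0..n_max` and attaches 95% Garwood intervals per bin.
#'
#' @param lads integer vector of per-tumor LAD values (values above `n_max`
#'   are lumped into the top bin), or NULL if `counts` given.
#' @param counts named or positional numeric vector of counts over
#'   `0..n_max` (alternative input).
#' @param n_max largest LAD bin.
#' @param level confidence level for the per-bin Poisson intervals.
#' @param label optional cohort label (e.g. the driver gene).
#' @return object of class `lad_distribution`: list with `counts`, `n`,
#'   `ci` (matrix), `n_max`, `label`.
#' @export
lad_distribution <- function(lads = NULL, counts = NULL, n_max = 15,
                             level = 0.95, label = NULL) {
  if (is.null(counts)) {
    if (is.null(lads) || length(lads) == 0) stop("supply lads or counts")
    if (anyNA(lads)) {
      warning(sum(is.na(lads)), " inestimable LAD value(s) dropped")
      lads <- lads[!is.na(lads)]
      if (length(lads) == 0) stop("no estimable LAD values")
    }
    if (any(lads < 0)) stop("LAD values must be non-negative")
    counts <- as.numeric(table(factor(pmin(lads, n_max), levels = 0:n_max)))
  } else {
    if (length(counts) != n_max + 1)
      stop("counts must cover 0..n_max")
    counts <- as.numeric(counts)
  }
  structure(list(counts = setNames(counts, 0:n_max), n = sum(counts),
                 ci = poisson_ci(counts, level), level = level,
                 n_max = n_max, label = label),
            class = "lad_distribution")
}

#' @export
print.lad_distribution <- function(x, ...) {
  cat("LAD distribution", if (!is.null(x$label)) paste0("[", x$label, "]"),
      "- N =", x$n, "tumors\n")
  df <- data.frame(lad = 0:x$n_max, count = as.numeric(x$counts),
                   ci_lower = round(x$ci[, 1], 2), ci_upper = round(x$ci[, 2], 2))
  print(df[df$count > 0 | df$lad <= 5, ], row.names = FALSE)
  invisible(x)
}

#' Default parameter grids for LAD-distribution fitting
#'
#' `s` in 0.05..0.95 (step 0.05), `r` in 0..0.8 (step 0.1), `u` in
#' 0..min(r, 0.55) (step 0.05), `eps` in 0..0.9 (step 0.15).
#'
#' @return list of numeric vectors `s`, `r`, `u`, `eps`.
#' @export
default_grids <- function() {
  list(s = seq(0.05, 0.95, by = 0.05),
       r = seq(0, 0.8, by = 0.1),
       u = seq(0, 0.55, by = 0.05),
       eps = seq(0, 0.9, by = 0.15))
}

# Expand grids to the feasible combos (u <= r) as a data.frame.
.expand_grid_combos <- function(grids) {
  g <- expand.grid(s = grids$s, r = grids$r, u = grids$u, eps = grids$eps,
                   KEEP.OUT.ATTRS = FALSE)
  g[g$u <= g$r, , drop = FALSE]
}

#' Model LAD pmfs over a parameter grid
#'
#' Precomputes (and caches across fits) the model pmf for every feasible
#' parameter combination, analytically for a single driver or by simulation
#' for several drivers.
#'
#' @param grids list of vectors `s`, `r`, `u`, `eps` (see [default_grids()]).
#' @param n_max largest LAD bin.
#' @param model `"analytic"` (single driver) or `"simulation"`.
#' @param n_drivers number of drivers (simulation model only).
#' @param sim_reps formed tumors per combo for the simulation model.
#' @param seed seed for the simulation model.
#' @return list with `combos` (data.frame) and `pmf` (matrix, one row per
#'   combo, columns `0..n_max`, tail mass lumped into the top bin).
#' @export
grid_pmfs <- function(grids = default_grids(), n_max = 15,
                      model = c("analytic", "simulation"), n_drivers = 1,
                      sim_reps = 10000, seed = NULL) {
  model <- match.arg(model)
  combos <- .expand_grid_combos(grids)
  if (nrow(combos) == 0) stop("empty parameter grid")
  if (model == "simulation" && !is.null(seed)) set.seed(seed)
  pmf <- matrix(NA_real_, nrow(combos), n_max + 1)
  keep <- rep(TRUE, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    p <- tryCatch({
      if (model == "analytic")
        lad_pmf(co$s, co$r, co$u, co$eps, n_max = n_max, tail = "lump")$p
      else {
        d <- simulate_lad_distribution(division_params(s = co$s),
                                       repair_params(co$r, co$u, co$eps),
                                       n_drivers = n_drivers,
                                       n_tumors = sim_reps, n_max = n_max)
        d$counts / d$n
      }
    }, error = function(e) NULL)
    if (is.null(p)) keep[i] <- FALSE else pmf[i, ] <- p
  }
  list(combos = combos[keep, , drop = FALSE],
       pmf = pmf[keep, , drop = FALSE])
}

#' Fit the model grid to an observed LAD distribution
#'
#' A parameter combination is accepted iff for every LAD bin `n <= n_max`
#' the model-expected count `N * pmf(n)` lies inside the Poisson confidence
#' interval of the observed count. The headline statistic is `min_s`, the
#' smallest selection coefficient among accepted combinations: the minimum
#' initial growth advantage required to explain the observed distribution.
#'
#' @param obs a [lad_distribution()].
#' @param grids parameter grids (see [default_grids()]), ignored when
#'   `models` is supplied.
#' @param model `"analytic"` or `"simulation"` (passed to [grid_pmfs()]).
#' @param models optional precomputed [grid_pmfs()] result (recommended when
#'   fitting many cohorts against the same grid).
#' @param n_drivers,sim_reps,seed passed to [grid_pmfs()].
#' @param level family-wise confidence level of the acceptance band.
#' @param ci_adjust `"bonferroni"` (default) widens the per-bin Poisson
#'   intervals to `1 - (1 - level)/k` over the `k` LAD bins, giving a
#'   simultaneous band whose joint truth-coverage is at least `level`;
#'   `"none"` uses per-bin `level` intervals (anticonservative jointly).
#' @return object of class `grid_fit`: list with `combos` (data.frame with
#'   `accepted` flag), `min_s` (NA if nothing accepted), `accepted_count`,
#'   `n_obs`.
#' @export
fit_grid <- function(obs, grids = default_grids(),
                     model = c("analytic", "simulation"), models = NULL,
                     n_drivers = 1, sim_reps = 10000, seed = NULL,
                     level = 0.95, ci_adjust = c("bonferroni", "none")) {
  stopifnot(inherits(obs, "lad_distribution"))
  if (obs$n < 1) stop("observed distribution is empty")
  model <- match.arg(model)
  ci_adjust <- match.arg(ci_adjust)
  if (is.null(models))
    models <- grid_pmfs(grids, n_max = obs$n_max, model = model,
                        n_drivers = n_drivers, sim_reps = sim_reps, seed = seed)
  if (ncol(models$pmf) != obs$n_max + 1)
    stop("model pmfs and observed distribution use different n_max")
  k <- obs$n_max + 1
  lvl <- if (ci_adjust == "bonferroni") 1 - (1 - level) / k else level
  ci <- poisson_ci(as.numeric(obs$counts), level = lvl)
  expected <- models$pmf * obs$n
  lo <- ci[, 1]; hi <- ci[, 2]
  ok <- expected >= matrix(lo, nrow(expected), length(lo), byrow = TRUE) &
        expected <= matrix(hi, nrow(expected), length(hi), byrow = TRUE)
  accepted <- rowSums(ok) == ncol(ok)
  combos <- models$combos
  combos$accepted <- accepted
  min_s <- if (any(accepted)) min(combos$s[accepted]) else NA_real_
  structure(list(combos = combos, min_s = min_s,
                 accepted_count = sum(accepted), n_obs = obs$n,
                 label = obs$label),
            class = "grid_fit")
}

#' @export
print.grid_fit <- function(x, ...) {
  cat("Grid fit", if (!is.null(x$label)) paste0("[", x$label, "]"),
      "- N =", x$n_obs, "tumors\n")
  cat("  accepted combos:", x$accepted_count, "of", nrow(x$combos), "\n")
  cat("  minimum selection coefficient among accepted: ",
      if (is.na(x$min_s)) "none accepted" else x$min_s, "\n")
  invisible(x)
}

#' Two-sample chi-square comparison of LAD distributions
#'
#' Diagnostic comparison of two cohorts' LAD counts (bins pooled so that
#' every expected count is at least 5).
#'
#' @param a,b two [lad_distribution()] objects with the same `n_max`.
#' @return an `htest` result.
#' @export
compare_lad_distributions <- function(a, b) {
  stopifnot(inherits(a, "lad_distribution"), inherits(b, "lad_distribution"),
            a$n_max == b$n_max)
  m <- rbind(a$counts, b$counts)
  tot <- colSums(m)
  keep <- tot >= 5
  if (any(!keep)) m <- cbind(m[, keep, drop = FALSE], rowSums(m[, !keep, drop = FALSE]))
  suppressWarnings(stats::chisq.test(m))
}

#' Bootstrap the minimum selection coefficient over tumors
#'
#' Resamples tumors with replacement and refits the grid, giving a
#' diagnostic distribution of `min_s`.
#'
#' @param lads per-tumor LAD values.
#' @param models precomputed [grid_pmfs()] (strongly recommended).
#' @param n_boot bootstrap replicates.
#' @param n_max largest LAD bin.
#' @param seed optional seed.
#' @return numeric vector of `min_s` values (NA where nothing accepted).
#' @export
bootstrap_min_s <- function(lads, models, n_boot = 100, n_max = 15,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_boot), function(i) {
    d <- lad_distribution(lads = sample(lads, replace = TRUE), n_max = n_max)
    fit_grid(d, models = models)$min_s
  }, numeric(1))
}
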