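#' Eventual extinction probability of a post-driver lineage
#'
#' For a supercritical birth-death branching process with per-generation
#' probabilities `b` (two stem daughters) and `d` (none), the extinction
#' probability of a single lineage is the minimal root of
#' `b q^2 - (b + d) q + d = 0`, i.e. `q = d / b`.
#'
#' @param b,d per-generation birth and death probabilities, `b > d`.
#' @return the extinction probability `q`.
#' @export
extinction_prob <- function(b, d) {
  if (!is.finite(b) || !is.finite(d) || b < 0 || d < 0 || b + d > 1)
    stop("invalid division probabilities")
  if (b <= d) stop("process is not supercritical (requires b > d)")
  d / b
}

#' Distribution of divisions from a driver-competent cell to the MRCA split
#'
#' Conditional on the lineage surviving, each division of a driver-competent
#' cell is the both-daughters-survive split with probability
#' `b (1 - q)^2 / (1 - q) = b - d = s`, so the wait is geometric:
#' `P(k) = s (1 - s)^(k - 1)` for `k >= 1`. The derivation is verified
#' against the genealogy simulator in the test suite.
#'
#' @param s selection coefficient in (0, 1].
#' @param n_max truncation point of the returned pmf.
#' @return numeric vector `p[k] = P(wait = k)`, `k = 1..n_max`.
#' @export
mrca_wait_pmf <- function(s, n_max = 15) {
  if (!is.finite(s) || s <= 0 || s > 1) stop("s must lie in (0, 1]")
  k <- seq_len(n_max)
  s * (1 - s)^(k - 1)
}

# Enumerate one generation of the driver-duplex chain: repair outcomes
# followed by replication, as (prob, post-repair state, daughter pair).
# States indexed 1..5 = WW, LW, LL, LM, MM.
.locus_transitions <- function(r, u, eps) {
  full <- r - u
  repair <- list(
    `1` = c(`1` = 1),
    `2` = c(`1` = full, `4` = u, `2` = 1 - r),
    `3` = c(`1` = full^2, `4` = u * (2 - u), `2` = 2 * full * (1 - r),
            `3` = (1 - r)^2),
    `4` = c(`5` = full, `4` = 1 - full),
    `5` = c(`5` = 1))
  repl <- list(
    `1` = list(list(p = 1, a = 1L, b = 1L)),
    `2` = list(list(p = eps, a = 2L, b = 1L), list(p = 1 - eps, a = 4L, b = 1L)),
    `3` = list(list(p = eps^2, a = 2L, b = 2L),
               list(p = 2 * eps * (1 - eps), a = 2L, b = 4L),
               list(p = (1 - eps)^2, a = 4L, b = 4L)),
    `4` = list(list(p = eps, a = 2L, b = 5L), list(p = 1 - eps, a = 4L, b = 5L)),
    `5` = list(list(p = 1, a = 5L, b = 5L)))
  out <- vector("list", 5)
  for (sig in 1:5) {
    rows <- list()
    rp <- repair[[as.character(sig)]]
    for (nm in names(rp)) {
      if (rp[[nm]] <= 0) next
      s2 <- as.integer(nm)
      for (dd in repl[[nm]]) {
        if (dd$p <= 0) next
        rows[[length(rows) + 1]] <-
          list(p = rp[[nm]] * dd$p, post = s2, a = dd$a, b = dd$b)
      }
    }
    out[[sig]] <- rows
  }
  out
}

# Division-rate pair by driver status of the post-repair state.
.fit_bd <- function(post_state, division) {
  if (post_state >= 4) c(division$b, division$d)
  else c(division$b_pre, division$b_pre)
}

# Per-state eternal-extinction probabilities of the multitype process.
.duplex_extinction <- function(division, repair, tol = 1e-13, max_iter = 5000) {
  tr <- .locus_transitions(repair$r, repair$u, repair$eps)
  q <- division$d / division$b
  b0 <- division$b_pre
  v <- c(1, 1, 1, q, q)           # WW, LW, LL, LM, MM
  for (it in seq_len(max_iter)) {
    vn <- v
    for (sig in 2:4) {            # WW and MM have known fixpoints
      acc <- 0
      for (row in tr[[sig]]) {
        driver <- row$post >= 4
        bf <- if (driver) division$b else b0
        df <- if (driver) division$d else b0
        va <- v[row$a]; vb <- v[row$b]
        acc <- acc + row$p * (df + (1 - bf - df) * (va + vb) / 2 + bf * va * vb)
      }
      vn[sig] <- acc
    }
    vn[1] <- 1; vn[5] <- q
    if (max(abs(vn - v)) < tol) { v <- vn; break }
    v <- vn
  }
  v
}

# Homogeneous per-state CDFs of the first driver-split time, conditioned on
# eternal subtree survival; a both-surviving split at a non-driver cell is
# resolved by A_fun (competition rule).
.spine_cdf <- function(tr, v, w, division, N, A_fun) {
  G <- matrix(0, 5, N + 1)
  for (n in 0:N) for (sg in 2:5) {
    if (w[sg] <= 0) next
    acc <- 0
    for (row in tr[[sg]]) {
      bd <- .fit_bd(row$post, division); bf <- bd[1]; df <- bd[2]
      a <- row$a; b <- row$b
      wa <- w[a]; wb <- w[b]; va <- v[a]; vb <- v[b]
      Ga <- if (n > 0) G[a, n] else 0
      Gb <- if (n > 0) G[b, n] else 0
      if (row$post >= 4) acc <- acc + row$p * bf * wa * wb
      else if (wa * wb > 0) acc <- acc + row$p * bf * wa * wb * A_fun(a, b, Ga, Gb)
      acc <- acc + row$p * (bf * (wa * vb * Ga + va * wb * Gb) +
                              (1 - bf - df) * (wa * Ga + wb * Gb) / 2)
    }
    G[sg, n + 1] <- acc / w[sg]
  }
  G
}

# Winner-time pmfs for competing sibling clones. The earlier-established
# clone is larger at the horizon up to the almost-sure limit W of the
# normalised clone size; W is approximated Gamma with the exact branching
# variance, giving P(earlier wins | gap) in closed beta form.
.winner_tables <- function(G, division, N) {
  s <- division$s; m <- 1 + s
  var_w <- (4 * division$b + (1 - division$b - division$d) - m^2) / (m^2 - m)
  sig <- if (var_w <= 1e-8) {
    function(delta) ifelse(delta > 0, 1, ifelse(delta < 0, 0, 0.5))
  } else {
    k <- 1 / var_w
    function(delta) { cc <- m^delta; stats::pbeta(cc / (1 + cc), k, k) }
  }
  sd_ <- outer(0:N, 0:N, function(i, j) sig(j - i))
  g <- cbind(G[, 1], t(apply(G, 1, diff)))
  g <- g / pmax(rowSums(g), 1e-12)
  tabs <- list()
  for (pr in list(c(2, 2), c(2, 4), c(4, 4))) {
    ga <- g[pr[1], ]; gb <- g[pr[2], ]
    J <- outer(ga, gb)
    tabs[[paste(pr, collapse = "_")]] <- rowSums(J * sd_) + colSums(J * (1 - sd_))
  }
  tabs
}

# P(no driver-carrying descendant after m further generations | state),
# m = 0..H (finite-horizon complement of .duplex_extinction).
.finite_horizon_failure <- function(tr, division, H) {
  v <- matrix(0, H + 1, 5)
  v[1, ] <- c(1, 1, 1, 0, 0)
  for (m in seq_len(H)) for (sg in 1:5) {
    acc <- 0
    for (row in tr[[sg]]) {
      bd <- .fit_bd(row$post, division); bf <- bd[1]; df <- bd[2]
      va <- v[m, row$a]; vb <- v[m, row$b]
      acc <- acc + row$p * (df + (1 - bf - df) * (va + vb) / 2 + bf * va * vb)
    }
    v[m + 1, sg] <- acc
  }
  v
}

#' Analytic single-driver LAD distribution
#'
#' Dynamic program over the driver-locus duplex chain (lesion on both
#' strands, lesion opposite wildtype, heteroduplex, mutant) coupled to the
#' branching process. Conditional on tumor formation, the LAD is the
#' generation at which a driver-competent cell first divides such that both
#' daughter subtrees carry driver cells at the tracking horizon (the tumor
#' MRCA). A both-surviving split at a non-driver cell spawns two competing
#' clones; the winner is the larger clone at the horizon, modelled through
#' the almost-sure limit of the normalised clone size (Gamma approximation
#' with the exact branching-process variance). Mass beyond `n_max` is
#' reported as `truncation_mass`.
#'
#' @param s selection coefficient (post-driver `b - d`) in (0, 1].
#' @param r,u,eps repair/translesion parameters, see [repair_params()].
#' @param n_max largest LAD value tabulated (default 15).
#' @param division optional [division_params()] giving the full `(b, d,
#'   b_pre)` split; defaults to `(b, d) = (s, 0)`, `b_pre = 0.25`.
#' @param horizon tracking horizon in generations (as in the simulator);
#'   `Inf` gives the eternal-survival limit.
#' @param tail `"renormalize"` rescales the pmf over `0..n_max`;
#'   `"lump"` adds the tail mass to the `n_max` bin (matching empirical
#'   distributions whose LAD values are capped at `n_max`).
#' @return object of class `lad_pmf`: list with `p` (named vector over
#'   `0..n_max`), `params`, `truncation_mass`, `p_formed`.
#' @export
lad_pmf <- function(s, r, u, eps, n_max = 15, division = NULL, horizon = 25,
                    tail = c("renormalize", "lump")) {
  tail <- match.arg(tail)
  rep_par <- repair_params(r, u, eps)
  if (is.null(division)) division <- division_params(s = s)
  if (abs(division$s - s) > 1e-12) stop("division params inconsistent with s")
  tr <- .locus_transitions(r, u, eps)
  v <- .duplex_extinction(division, rep_par)
  w <- 1 - v
  if (w[3] <= 1e-12)
    stop("tumor formation has probability zero under these parameters")
  N <- n_max + 30L
  G_min <- .spine_cdf(tr, v, w, division, N,
                      function(a, b, Ga, Gb) 1 - (1 - Ga) * (1 - Gb))
  tabs <- .winner_tables(G_min, division, N)
  H <- if (is.finite(horizon)) as.integer(horizon) else NA_integer_
  v_fin <- if (is.finite(horizon)) .finite_horizon_failure(tr, division, H)
           else matrix(v, 2, 5, byrow = TRUE)
  emit <- numeric(N + 1)
  pi_n <- c(0, 0, 1, 0, 0)              # exposed cell: both strands lesioned
  for (n in 0:N) {
    wf <- if (is.finite(horizon)) 1 - v_fin[max(H - n - 1, 0) + 1, ] else w
    nxt <- numeric(5)
    for (sg in 1:5) {
      if (pi_n[sg] <= 0) next
      for (row in tr[[sg]]) {
        bd <- .fit_bd(row$post, division); bf <- bd[1]; df <- bd[2]
        a <- row$a; b <- row$b
        if (row$post >= 4) {
          emit[n + 1] <- emit[n + 1] + pi_n[sg] * row$p * bf * wf[a] * wf[b]
        } else if (wf[a] * wf[b] > 0) {
          tb <- tabs[[paste(sort(c(a, b)), collapse = "_")]]
          wt <- pi_n[sg] * row$p * bf * wf[a] * wf[b]
          len <- min(length(tb), N - n)
          if (len > 0) {
            idx <- (n + 2):(n + 1 + len)
            emit[idx] <- emit[idx] + wt * tb[seq_len(len)]
          }
        }
        nxt[a] <- nxt[a] + pi_n[sg] * row$p * (bf * (1 - wf[b]) + (1 - bf - df) / 2)
        nxt[b] <- nxt[b] + pi_n[sg] * row$p * (bf * (1 - wf[a]) + (1 - bf - df) / 2)
      }
    }
    pi_n <- nxt
    if (sum(pi_n) < 1e-14) break
  }
  total <- sum(emit)
  if (total <= 0) stop("no LAD mass computable under these parameters")
  p <- emit[seq_len(n_max + 1L)]
  trunc_mass <- 1 - sum(p) / total
  if (tail == "lump") {
    p[n_max + 1L] <- p[n_max + 1L] + total - sum(emit[seq_len(n_max + 1L)])
  }
  p <- p / sum(p)
  structure(list(p = setNames(p, 0:n_max),
                 params = list(s = s, r = r, u = u, eps = eps,
                               division = division, horizon = horizon,
                               tail = tail),
                 n_max = n_max, truncation_mass = trunc_mass,
                 p_formed = 1 - v_fin[nrow(v_fin), 3]),
            class = "lad_pmf")
}

#' @export
print.lad_pmf <- function(x, ...) {
  cat("Analytic LAD distribution (single driver)\n")
  cat(sprintf("  s = %.3g, r = %.3g, u = %.3g, eps = %.3g\n",
              x$params$s, x$params$r, x$params$u, x$params$eps))
  cat(sprintf("  P(formed) = %.4g, truncation mass beyond n_max = %.3g\n",
              x$p_formed, x$truncation_mass))
  print(round(x$p, 4))
  invisible(x)
}
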