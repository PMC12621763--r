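#' @useDynLib lesionlad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom setNames quantile median rmultinom rpois
NULL

DRIVER_STATES <- c("WILDTYPE", "LESION_ONE_STRAND", "LESION_BOTH_STRANDS",
                   "HETERODUPLEX", "MUTANT")
# integer codes used by the C++ core: 0=WW 1=LW 2=LL 3=LM 4=MM
.state_code <- c(WILDTYPE = 0L, LESION_ONE_STRAND = 1L,
                 LESION_BOTH_STRANDS = 2L, HETERODUPLEX = 3L, MUTANT = 4L)

#' Division-rate parameters of the branching process
#'
#' Per-generation probabilities of the three division outcomes: symmetric
#' self-renewal (two stem daughters, probability `b`), symmetric
#' differentiation (no stem daughter, probability `d`) and asymmetric
#' division (one stem daughter, probability `1 - b - d`). The selection
#' coefficient `s = b - d` is the expected per-generation growth rate of the
#' clone. Before driver acquisition the population is kept constant, so the
#' pre-driver process is critical with `b = d = b_pre`.
#'
#' @param s post-driver selection coefficient; if supplied, `b = s + d`.
#' @param b,d post-driver birth/death probabilities (used when `s` is NULL).
#' @param b_pre pre-driver birth (= death) probability.
#' @return an object of class `division_params`.
#' @export
division_params <- function(s = NULL, b = NULL, d = 0, b_pre = 0.25) {
  if (!is.null(s)) {
    if (is.null(d)) d <- 0
    b <- s + d
  }
  if (is.null(b)) stop("supply either `s` or `b`")
  for (p in c(b, d, b_pre)) {
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (b + d > 1) stop("b + d must not exceed 1")
  if (2 * b_pre > 1) stop("pre-driver b + d must not exceed 1")
  if (b <= d) stop("post-driver process must be supercritical (b > d)")
  structure(list(b = b, d = d, s = b - d, b_pre = b_pre),
            class = "division_params")
}

#' Lesion repair and translesion-replication parameters
#'
#' `r` is the total per-generation probability that a lesion is repaired;
#' of that, `u` is mutagenic repair (repair synthesis writes a mutant base
#' opposite the lesion, creating a lesion-mutation heteroduplex) and (r - u)
#' full, error-free repair. An unrepaired lesion is replicated across:
#' error-free with probability `eps` (wildtype base inserted opposite),
#' erroneously with probability `1 - eps` (mutation inserted opposite).
#'
#' @param r total repair probability per generation.
#' @param u mutagenic-repair probability (`u <= r`).
#' @param eps error-free translesion replication probability.
#' @return an object of class `repair_params`.
#' @export
repair_params <- function(r, u, eps) {
  for (p in c(r, u, eps)) {
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (u > r) stop("mutagenic repair u cannot exceed total repair r")
  structure(list(r = r, u = u, eps = eps), class = "repair_params")
}

.repair_state <- function(code, r, u) {
  full <- r - u
  if (code == 0L || code == 4L) return(code)
  if (code == 1L) {
    x <- runif(1)
    return(if (x < full) 0L else if (x < r) 3L else 1L)
  }
  if (code == 3L) {
    return(if (runif(1) < full) 4L else 3L)
  }
  # both strands lesioned; strands treated sequentially, mutagenic repair of
  # one lesion overwrites the partner strand with the mutant base
  x1 <- runif(1)
  if (x1 < full) {
    x2 <- runif(1)
    return(if (x2 < full) 0L else if (x2 < r) 3L else 1L)
  }
  if (x1 < r) return(3L)
  x2 <- runif(1)
  if (x2 < full) return(1L)
  if (x2 < r) return(3L)
  2L
}

.replicate_state <- function(code, eps) {
  les <- function() if (runif(1) < eps) 1L else 3L
  pair <- switch(as.character(code),
                 "0" = c(0L, 0L), "4" = c(4L, 4L),
                 "2" = c(les(), les()),
                 "1" = c(les(), 0L),
                 "3" = c(les(), 4L))
  if (runif(1) < 0.5) pair <- rev(pair)
  pair
}

#' One repair-replication cycle at a driver locus
#'
#' Applies one generation of lesion dynamics to the duplex state of a driver
#' site: repair (full with probability (r - u), mutagenic with probability
#' `u`, none with `1 - r`), then semiconservative replication in which each
#' unrepaired lesion is copied error-free (probability `eps`) or erroneously
#' (probability `1 - eps`). Each daughter inherits one of the two daughter
#' duplexes. `WILDTYPE` and `MUTANT` are absorbing.
#'
#' @param state one of `"WILDTYPE"`, `"LESION_ONE_STRAND"`,
#'   `"LESION_BOTH_STRANDS"`, `"HETERODUPLEX"`, `"MUTANT"`.
#' @param repair a [repair_params()] object.
#' @return list with `post_repair` (state after the repair phase) and
#'   `daughters` (character vector of the two daughter duplex states).
#' @export
step_driver_locus <- function(state, repair) {
  stopifnot(inherits(repair, "repair_params"))
  state <- match.arg(state, DRIVER_STATES)
  code <- .state_code[[state]]
  post <- .repair_state(code, repair$r, repair$u)
  kids <- .replicate_state(post, repair$eps)
  list(post_repair = names(.state_code)[match(post, .state_code)],
       daughters = names(.state_code)[match(kids, .state_code)])
}

#' Construct a stem cell for the lesion-segregation model
#'
#' @param karyotype data.frame with columns `chrom` and `length_bp`.
#' @param n_drivers number of driver loci, each initialised to
#'   `LESION_BOTH_STRANDS` when `mutagenized = TRUE`.
#' @param mutagenized if TRUE, all strands of all homologs carry lesions
#'   (the state of the exposed cell immediately after the pulse).
#' @return an object of class `lesion_cell`.
#' @export
new_cell <- function(karyotype, n_drivers = 1, mutagenized = TRUE) {
  stopifnot(is.data.frame(karyotype), all(c("chrom", "length_bp") %in% names(karyotype)))
  nc <- nrow(karyotype)
  structure(list(
    karyotype = karyotype,
    # lesion_strands[i, j]: homolog j of chromosome i carries a lesion strand
    lesion_strands = matrix(mutagenized, nc, 2,
                            dimnames = list(karyotype$chrom, c("hom1", "hom2"))),
    driver_states = rep(if (mutagenized) "LESION_BOTH_STRANDS" else "WILDTYPE",
                        n_drivers),
    generation = 0L), class = "lesion_cell")
}

#' Divide a stem cell with random segregation of lesion strands
#'
#' Division outcome has probabilities `(b, 1 - b - d, d)` for (2, 1, 0) stem
#' daughters. Each daughter inherits the lesion-bearing strand of each
#' homolog independently with probability 1/2 (lesion segregation). An
#' optional mitotic-recombination rate per chromosome swaps the
#' lesion-strand indicators of the two homologs of a pair before
#' segregation.
#'
#' @param cell a [new_cell()] object.
#' @param params a [division_params()] object; the post-driver `(b, d)` pair
#'   is used (pass `division_params(b = x, d = x, ...)`-like values through
#'   `b_override`/`d_override` for pre-driver cells).
#' @param mitotic_recomb_rate probability per chromosome per division of an
#'   exchange between homologs.
#' @param b_override,d_override optional explicit outcome probabilities.
#' @return list with `n_stem` (0, 1 or 2) and `daughters` (list of
#'   `lesion_cell`s of length `n_stem`).
#' @export
divide <- function(cell, params, mitotic_recomb_rate = 0,
                   b_override = NULL, d_override = NULL) {
  stopifnot(inherits(cell, "lesion_cell"), inherits(params, "division_params"))
  b <- if (is.null(b_override)) params$b else b_override
  d <- if (is.null(d_override)) params$d else d_override
  if (b < 0 || d < 0 || b + d > 1) stop("invalid division probabilities")
  x <- runif(1)
  n_stem <- if (x < b) 2L else if (x < b + d) 0L else 1L
  ls <- cell$lesion_strands
  if (mitotic_recomb_rate > 0) {
    swap <- runif(nrow(ls)) < mitotic_recomb_rate
    ls[swap, ] <- ls[swap, c(2, 1)]
  }
  make_daughter <- function() {
    keep <- matrix(runif(length(ls)) < 0.5, nrow(ls), 2) & ls
    kid <- cell
    kid$lesion_strands <- keep
    kid$generation <- cell$generation + 1L
    kid
  }
  daughters <- if (n_stem > 0) replicate(n_stem, make_daughter(), simplify = FALSE)
               else list()
  list(n_stem = n_stem, daughters = daughters)
}

.fitness_ladders <- function(division, n_drivers, partial_s = NULL) {
  # b/d by number of acquired drivers k = 0..n_drivers
  b_by_k <- rep(division$b_pre, n_drivers + 1)
  d_by_k <- rep(division$b_pre, n_drivers + 1)
  if (!is.null(partial_s)) {
    if (length(partial_s) != max(n_drivers - 1, 0))
      stop("partial_s must have length n_drivers - 1")
    for (k in seq_along(partial_s)) {
      b_by_k[k + 1] <- min(division$b_pre + partial_s[k], 1 - division$b_pre)
      d_by_k[k + 1] <- division$b_pre
    }
  }
  b_by_k[n_drivers + 1] <- division$b
  d_by_k[n_drivers + 1] <- division$d
  list(b = b_by_k, d = d_by_k)
}

.sim_config <- function(config = list()) {
  cfg <- list(horizon = 25L, cap = 4000L, max_attempts = 1000L,
              heteroduplex_fit = TRUE, partial_s = NULL)
  cfg[names(config)] <- config
  if (cfg$horizon < 5) stop("tracked-generation horizon must be at least 5")
  cfg
}

#' Simulate a single tumor-initiation attempt sequence
#'
#' Starts from one mutagenized cell (lesions on both strands of every driver
#' locus), applies mutagenic repair before the first division (enabling
#' LAD = 0), tracks the stem-cell genealogy to the horizon, and declares a
#' tumor formed when driver-carrying cells survive to the horizon. Clones
#' are grouped by their earliest driver-competent ancestor, the largest
#' clone wins (ties broken by the seeded RNG), and LAD is the generation of
#' the most recent common ancestor of the winning clone's horizon cells.
#'
#' @param division a [division_params()] object.
#' @param repair a [repair_params()] object.
#' @param n_drivers number of driver loci required jointly for full fitness.
#' @param config list overriding `horizon` (default 25), `cap` (4000),
#'   `max_attempts` (1000), `heteroduplex_fit` (TRUE; if FALSE only
#'   double-strand mutant loci confer fitness) and `partial_s`
#'   (per-intermediate-driver selection, default neutral).
#' @param seed optional integer seed.
#' @return an object of class `sim_result` with fields `formed`, `lad`,
#'   `mrca_generation`, `attempts`, `truncated`, `mrca_competent` and the
#'   parameters used.
#' @export
simulate_tumor <- function(division, repair, n_drivers = 1, config = list(),
                           seed = NULL) {
  res <- simulate_tumors(division, repair, n_drivers, n_tumors = 1L,
                         config = config, seed = seed)
  out <- lapply(res$tumors, `[[`, 1)
  structure(c(out, list(params = res$params, seed = seed,
                        formed = !is.na(res$tumors$lad[1]))),
            class = "sim_result")
}

#' Simulate many formed tumors
#'
#' Vectorised version of [simulate_tumor()]: repeats initiation attempts
#' until `n_tumors` tumors have formed (or `max_attempts` is exhausted per
#' tumor, in which case the LAD is `NA`).
#'
#' @inheritParams simulate_tumor
#' @param n_tumors number of formed tumors to collect.
#' @return list with `tumors` (data.frame: lad, attempts, truncated,
#'   mrca_competent, horizon_used) and `params`.
#' @export
simulate_tumors <- function(division, repair, n_drivers = 1, n_tumors = 1,
                            config = list(), seed = NULL) {
  stopifnot(inherits(division, "division_params"),
            inherits(repair, "repair_params"), n_tumors >= 1)
  cfg <- .sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  lad <- .fitness_ladders(division, n_drivers, cfg$partial_s)
  raw <- cpp_simulate_tumors(as.integer(n_tumors), lad$b, lad$d,
                             repair$r, repair$u, repair$eps,
                             as.integer(n_drivers), as.integer(cfg$horizon),
                             as.integer(cfg$cap), as.integer(cfg$max_attempts),
                             isTRUE(cfg$heteroduplex_fit))
  tumors <- data.frame(lad = raw$lad, mrca_generation = raw$lad,
                       attempts = raw$attempts, truncated = raw$truncated,
                       mrca_competent = raw$mrca_competent,
                       horizon_used = raw$horizon_used,
                       n_clones = raw$n_clones)
  if (any(tumors$truncated, na.rm = TRUE))
    message("population cap reached in ", sum(tumors$truncated, na.rm = TRUE),
            " tumor(s); genealogy truncated at the cap generation")
  list(tumors = tumors,
       params = list(division = division, repair = repair,
                     n_drivers = n_drivers, config = cfg, seed = seed))
}

#' Simulate an empirical LAD distribution
#'
#' Repeats [simulate_tumor()] conditioning on formed tumors and tabulates
#' the LAD values into a [lad_distribution()].
#'
#' @inheritParams simulate_tumors
#' @param n_max largest LAD bin reported (larger values are lumped there).
#' @param label cohort label.
#' @return a `lad_distribution` object (see [lad_distribution()]).
#' @export
simulate_lad_distribution <- function(division, repair, n_drivers = 1,
                                      n_tumors = 1000, n_max = 15,
                                      config = list(), seed = NULL,
                                      label = NULL) {
  res <- simulate_tumors(division, repair, n_drivers, n_tumors, config, seed)
  lads <- res$tumors$lad
  if (all(is.na(lads)))
    stop("no tumors formed within the configured attempt budget")
  lads <- lads[!is.na(lads)]
  lad_distribution(lads = pmin(lads, n_max), n_max = n_max, label = label)
}
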