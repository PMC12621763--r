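.BASES <- c("A", "C", "G", "T")
.PYR_CONTEXTS <- {
  ctx <- expand.grid(p5 = .BASES, ref = c("C", "T"), p3 = .BASES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(ctx$p5, "[", ctx$ref, "]", ctx$p3)
}

#' 96-channel substitution classes and MAV-pair classes
#'
#' `sbs_channels()` returns the standard 96 pyrimidine-centered
#' trinucleotide substitution channels (e.g. `"A[C>T]G"`).
#' `mav_pair_channels()` returns the 96 unordered alternate-allele pair
#' channels within a shared context (e.g. `"A[C>A/T]G"`), the natural
#' resolution for multiallelic variants: 32 contexts times 3 unordered
#' pairs of the 3 alternates.
#'
#' @return character vector of channel names.
#' @export
sbs_channels <- function() {
  out <- character(0)
  for (ref in c("C", "T")) for (p5 in .BASES) for (p3 in .BASES)
    for (alt in setdiff(.BASES, ref))
      out <- c(out, paste0(p5, "[", ref, ">", alt, "]", p3))
  out
}

#' @rdname sbs_channels
#' @export
mav_pair_channels <- function() {
  out <- character(0)
  for (ref in c("C", "T")) for (p5 in .BASES) for (p3 in .BASES) {
    alts <- setdiff(.BASES, ref)
    for (i in 1:2) for (j in (i + 1):3)
      out <- c(out, paste0(p5, "[", ref, ">", alts[i], "/", alts[j], "]", p3))
  }
  out
}

.rc <- function(x) chartr("ACGT", "TGCA", sapply(strsplit(x, ""), function(s)
  paste(rev(s), collapse = "")))

#' Collapse a mutation with trinucleotide context to its 96-channel class
#'
#' Purine-reference mutations are reverse-complemented to the
#' pyrimidine-centered convention.
#'
#' @param context trinucleotide reference context (character vector).
#' @param alt alternate allele.
#' @return channel names as in [sbs_channels()].
#' @export
classify_sbs <- function(context, alt) {
  stopifnot(all(nchar(context) == 3))
  ref <- substr(context, 2, 2)
  flip <- ref %in% c("A", "G")
  context[flip] <- .rc(context[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ref <- substr(context, 2, 2)
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3))
}

#' Expected multiallelic variants under independent co-occurrence
#'
#' Birthday-problem expectation for the number of sites hit by two or more
#' independent mutations with distinct alternate alleles. With per-context
#' opportunities, each context contributes
#' `G_c * P(Poisson(N_c/G_c) >= 2) * P(distinct alts)`; the uniform-rate
#' closed form `C(N,2)/G * P(distinct)` is returned as a cross-check. The
#' enrichment ratio flags lesion segregation when observed/expected > 10.
#'
#' @param mutation_table mutation table (normalized; see
#'   [normalize_mutations()]); `n_mut`/`observed_mavs` may be given
#'   directly instead.
#' @param callable_sites number of callable sites `G` (scalar, or named by
#'   context matching a `context` column).
#' @param spectrum optional 96-channel profile used for the
#'   distinct-alternate probability (default: alternates uniform, P = 2/3).
#' @param n_mut,observed_mavs scalar alternative input.
#' @param enrichment_threshold fold-excess defining the enriched flag.
#' @return list with `expected`, `expected_uniform`, `observed`,
#'   `enrichment` (NA when expected is 0 or fewer than 2 mutations),
#'   `enriched`.
#' @export
expected_independent_mavs <- function(mutation_table = NULL, callable_sites,
                                      spectrum = NULL, n_mut = NULL,
                                      observed_mavs = NULL,
                                      enrichment_threshold = 10) {
  if (any(callable_sites <= 0)) stop("callable_sites must be positive")
  if (is.null(n_mut)) {
    stopifnot(!is.null(mutation_table))
    n_mut <- nrow(mutation_table)
    sites <- unique(mutation_table[, c("chrom", "pos0")])
    observed_mavs <- sum(tapply(mutation_table$alt,
                                paste(mutation_table$chrom, mutation_table$pos0),
                                function(a) length(unique(a)) >= 2))
  }
  p_distinct <- .p_distinct_alts(spectrum)
  G <- sum(callable_sites)
  expected_uniform <- if (n_mut >= 2) choose(n_mut, 2) / G * p_distinct else 0
  # Poisson per-site with per-context opportunity
  expected <- if (n_mut >= 2) {
    if (length(callable_sites) > 1) {
      ctx_counts <- .context_counts(mutation_table, names(callable_sites))
      sum(vapply(seq_along(callable_sites), function(i) {
        mu <- ctx_counts[i] / callable_sites[i]
        callable_sites[i] * (1 - exp(-mu) * (1 + mu)) * p_distinct
      }, numeric(1)))
    } else {
      mu <- n_mut / G
      G * (1 - exp(-mu) * (1 + mu)) * p_distinct
    }
  } else 0
  enr <- if (n_mut < 2 || expected <= 0) NA_real_ else observed_mavs / expected
  list(expected = expected, expected_uniform = expected_uniform,
       observed = observed_mavs, enrichment = enr,
       enriched = isTRUE(enr > enrichment_threshold))
}

.p_distinct_alts <- function(spectrum) {
  if (is.null(spectrum)) return(2 / 3)
  ch <- names(spectrum)
  ctx <- sub(">.*\\]", "]", ch)        # context with alt removed
  p <- 0; tot <- 0
  for (cc in unique(ctx)) {
    w <- spectrum[ctx == cc]
    if (sum(w) <= 0) next
    a <- w / sum(w)
    p <- p + sum(w) * (1 - sum(a^2))
    tot <- tot + sum(w)
  }
  if (tot <= 0) 2 / 3 else p / tot
}

.context_counts <- function(tab, contexts) {
  if (is.null(tab$context)) stop("per-context opportunities need a 'context' column")
  key <- sub("\\[([CT])>.*\\]", "[\\1]", classify_sbs(tab$context, tab$alt))
  as.numeric(table(factor(key, levels = contexts)))
}

#' MAV-pair spectrum and cosine similarities
#'
#' Builds the observed MAV-pair profile over the 96 unordered alternate
#' pair channels and compares it (cosine similarity) with (a) the pair
#' profile implied by a mutagen signature and (b) the independent
#' co-occurrence expectation (product measure of the sample's own
#' single-mutation spectrum), both computed with
#' [signature_pair_profile()].
#'
#' @param mav_table data.frame with columns `context` (trinucleotide
#'   reference context) and `alt1`, `alt2` (the two alternate alleles).
#' @param sample_spectrum 96-channel spectrum of the sample's single
#'   mutations (named as [sbs_channels()]).
#' @param signature 96-channel mutagen signature.
#' @return list with `pair_profile`, `cos_signature`, `cos_independent`.
#' @export
mav_spectrum_similarity <- function(mav_table, sample_spectrum, signature) {
  if (nrow(mav_table) == 0) stop("need at least one MAV")
  obs <- mav_pair_profile(mav_table)
  sig_pairs <- signature_pair_profile(signature)
  ind_pairs <- signature_pair_profile(sample_spectrum)
  list(pair_profile = obs,
       cos_signature = cosine_similarity(obs, sig_pairs),
       cos_independent = cosine_similarity(obs, ind_pairs))
}

#' @rdname mav_spectrum_similarity
#' @export
mav_pair_profile <- function(mav_table) {
  ch <- mav_pair_channels()
  ctx <- mav_table$context
  a1 <- mav_table$alt1; a2 <- mav_table$alt2
  ref <- substr(ctx, 2, 2)
  flip <- ref %in% c("A", "G")
  ctx[flip] <- .rc(ctx[flip])
  a1[flip] <- chartr("ACGT", "TGCA", a1[flip])
  a2[flip] <- chartr("ACGT", "TGCA", a2[flip])
  ref <- substr(ctx, 2, 2)
  key <- vapply(seq_along(ctx), function(i) {
    alts <- setdiff(.BASES, ref[i])
    pr <- sort(match(c(a1[i], a2[i]), alts))
    paste0(substr(ctx[i], 1, 1), "[", ref[i], ">", alts[pr[1]], "/",
           alts[pr[2]], "]", substr(ctx[i], 3, 3))
  }, character(1))
  cnt <- table(factor(key, levels = ch))
  p <- as.numeric(cnt)
  names(p) <- ch
  if (sum(p) > 0) p / sum(p) else p
}

#' Pair profile implied by a single-mutation spectrum
#'
#' Product measure over unordered pairs of distinct alternates sharing a
#' reference context: `w(ctx, {a, b}) = 2 s(ctx, a) s(ctx, b)`,
#' normalized over the 96 pair channels. Used both for the signature
#' expectation (lesions repeatedly read by translesion polymerases draw
#' alternates from the signature's conditional alt distribution) and for
#' the independent co-occurrence expectation (two independent hits from
#' the sample spectrum).
#'
#' @param spectrum 96-channel spectrum named as [sbs_channels()].
#' @return normalized named vector over [mav_pair_channels()].
#' @export
signature_pair_profile <- function(spectrum) {
  if (is.null(names(spectrum))) stop("spectrum must be named by channel")
  ch <- mav_pair_channels()
  out <- setNames(numeric(length(ch)), ch)
  for (i in seq_along(ch)) {
    m <- regmatches(ch[i], regexec("^(.)\\[(.)>(.)/(.)\\](.)$", ch[i]))[[1]]
    c1 <- paste0(m[2], "[", m[3], ">", m[4], "]", m[6])
    c2 <- paste0(m[2], "[", m[3], ">", m[5], "]", m[6])
    s1 <- spectrum[c1]; s2 <- spectrum[c2]
    out[i] <- 2 * (if (is.na(s1)) 0 else s1) * (if (is.na(s2)) 0 else s2)
  }
  if (sum(out) > 0) out / sum(out) else out
}

#' Cosine similarity between non-negative profiles
#'
#' @param x,y numeric vectors of equal length.
#' @return cosine in `[0, 1]` for non-negative inputs.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm profile")
  sum(x * y) / (nx * ny)
}

#' Cochran-Armitage trend test on MAV phasing
#'
#' Tests for a monotone trend in the proportion of "matching" phased MAVs
#' (both alternates on the same parental allele) across ordered sample
#' enrichment categories, using equally spaced integer scores
#' (stats::prop.trend.test).
#'
#' @param matching number of matching phased MAVs per ordered category.
#' @param totals total phased MAVs per category.
#' @return an `htest` with the trend chi-square and p-value.
#' @export
phasing_trend_test <- function(matching, totals) {
  if (length(matching) < 2) stop("need at least two ordered categories")
  if (length(matching) != length(totals)) stop("length mismatch")
  if (any(totals < 1)) stop("each category needs at least one phased MAV")
  if (any(matching > totals)) stop("matching cannot exceed totals")
  stats::prop.trend.test(matching, totals, score = seq_along(matching))
}

#' Phase MAV alternates to a nearby germline heterozygous SNP
#'
#' A MAV is phaseable when a germline het SNP lies within `window` bp (the
#' read-length constraint); the phase relation is `"matching"` when both
#' alternates co-occur with the same germline allele, `"opposite"`
#' otherwise.
#'
#' @param mavs data.frame with `chrom`, `pos0` and phase columns `hap1`,
#'   `hap2` (haplotype index 1/2 carrying each alternate; NA = unknown).
#' @param het_snps data.frame with `chrom`, `pos0` of usable germline
#'   het SNPs.
#' @param window maximum phasing distance in bp (default 300).
#' @return the `mavs` table with `phase` in
#'   `c("matching", "opposite", "unphased")`.
#' @export
phase_mavs <- function(mavs, het_snps, window = 300) {
  phase <- rep("unphased", nrow(mavs))
  for (i in seq_len(nrow(mavs))) {
    near <- het_snps$chrom == mavs$chrom[i] &
      abs(het_snps$pos0 - mavs$pos0[i]) <= window
    if (any(near) && !is.na(mavs$hap1[i]) && !is.na(mavs$hap2[i]))
      phase[i] <- if (mavs$hap1[i] == mavs$hap2[i]) "matching" else "opposite"
  }
  mavs$phase <- phase
  mavs
}
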