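#' Stand-in mutational spectra for synthetic data
#'
#' `den_spectrum()` is a synthetic stand-in for a DEN-like profile:
#' 60% T>N (evenly split), 25% C>T, 15% other, flat across trinucleotide
#' contexts. `chemo_spectrum()` is a synthetic stand-in for a
#' procarbazine/platinum-like lesion signature concentrated on T>A.
#' Both are labelled synthetic: the published trinucleotide profiles are
#' not reproduced here, only their qualitative shape.
#'
#' @return named 96-channel probability vector (see [sbs_channels()]).
#' @export
den_spectrum <- function() {
  ch <- sbs_channels()
  w <- setNames(numeric(96), ch)
  type <- sub("^.\\[(.>.)\\].$", "\\1", ch)
  w[type %in% c("T>A", "T>C", "T>G")] <- 0.60 / sum(type %in% c("T>A", "T>C", "T>G"))
  w[type == "C>T"] <- 0.25 / sum(type == "C>T")
  w[type %in% c("C>A", "C>G")] <- 0.15 / sum(type %in% c("C>A", "C>G"))
  w / sum(w)
}

#' @rdname den_spectrum
#' @export
chemo_spectrum <- function() {
  ch <- sbs_channels()
  w <- setNames(numeric(96), ch)
  type <- sub("^.\\[(.>.)\\].$", "\\1", ch)
  w[type == "T>A"] <- 0.70 / sum(type == "T>A")
  w[type == "T>C"] <- 0.15 / sum(type == "T>C")
  w[type == "T>G"] <- 0.10 / sum(type == "T>G")
  w[type == "C>T"] <- 0.05 / sum(type == "C>T")
  w / sum(w)
}

.channel_parts <- function(ch) {
  m <- regmatches(ch, regexec("^(.)\\[(.)>(.)\\](.)$", ch))
  data.frame(p5 = vapply(m, `[`, "", 2), ref = vapply(m, `[`, "", 3),
             alt = vapply(m, `[`, "", 4), p3 = vapply(m, `[`, "", 5),
             stringsAsFactors = FALSE)
}

# draw n mutations from a spectrum; record on minus strand = complemented
.draw_mutations <- function(n, spectrum, strand_minus) {
  if (n == 0) return(data.frame(ref = character(0), alt = character(0),
                                context = character(0)))
  ch <- sample(names(spectrum), n, replace = TRUE, prob = spectrum)
  pp <- .channel_parts(ch)
  ctx <- paste0(pp$p5, pp$ref, pp$p3)
  ref <- pp$ref; alt <- pp$alt
  if (any(strand_minus)) {
    ctx[strand_minus] <- .rc(ctx[strand_minus])
    ref[strand_minus] <- chartr("ACGT", "TGCA", ref[strand_minus])
    alt[strand_minus] <- chartr("ACGT", "TGCA", alt[strand_minus])
  }
  data.frame(ref = ref, alt = alt, context = ctx, stringsAsFactors = FALSE)
}

# second, distinct alternate from the spectrum's conditional alt law
.draw_second_alt <- function(spectrum, context_pyr, alt1_pyr) {
  vapply(seq_along(context_pyr), function(i) {
    ref <- substr(context_pyr[i], 2, 2)
    alts <- setdiff(.BASES, c(ref, alt1_pyr[i]))
    chs <- paste0(substr(context_pyr[i], 1, 1), "[", ref, ">", alts, "]",
                  substr(context_pyr[i], 3, 3))
    w <- spectrum[chs]; w[is.na(w)] <- 0
    if (sum(w) <= 0) w <- rep(1, length(alts))
    sample(alts, 1, prob = w)
  }, character(1))
}

#' Generate a synthetic mutagen-pulsed tumor cohort
#'
#' For each tumor a true LAD is drawn from the branching-process simulator
#' (or taken from `lad_values`). Lesion strands are segregated per homolog
#' (segment-wise under mitotic recombination); genome-wide mutations are
#' placed with the mutagen spectrum, polarized per homolog to the strand
#' inherited at the first post-pulse division (no polarization for
#' LAD = 0, where both strands survive in the MRCA); multiallelic variants
#' arise only inside retained lesion segments, at twice the per-strand
#' rate for LAD = 0.
#'
#' @param params list with `s`, `r`, `u`, `eps`.
#' @param n_tumors cohort size.
#' @param mutation_load genome-wide mutations per tumor (desk-scale
#'   default 5000; the mouse-scale load is ~59,000).
#' @param mav_per_mb expected MAVs per megabase of retained lesion strand.
#' @param karyotype karyotype data.frame (default 20-chromosome 200 Mb
#'   desk genome).
#' @param recomb_rate mitotic-recombination probability per chromosome per
#'   division.
#' @param spectrum 96-channel mutagen spectrum.
#' @param lad_values optional integer vector of true LADs (bypasses the
#'   simulator; recycled to `n_tumors`).
#' @param sim_config simulator config (see [simulate_tumors()]).
#' @param seed optional seed.
#' @return list with `tumors` (list of mutation data.frames: `chrom`,
#'   `pos`, `ref`, `alt`, `context`) and `truth` (per-tumor LAD, realized
#'   lesion-strand fraction, MAV counts, parameters, seed).
#' @export
gen_tumor_cohort <- function(params = list(s = 0.6, r = 0.2, u = 0.05, eps = 0.15),
                             n_tumors = 10, mutation_load = 5000,
                             mav_per_mb = 3, karyotype = karyotype_synthetic(),
                             recomb_rate = 0.05, spectrum = den_spectrum(),
                             lad_values = NULL,
                             sim_config = list(horizon = 15, cap = 1500),
                             seed = NULL) {
  if (mutation_load < 100) stop("mutation_load must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lad_values)) {
    sim <- simulate_tumors(division_params(s = params$s),
                           repair_params(params$r, params$u, params$eps),
                           n_tumors = n_tumors, config = sim_config)
    lad_values <- sim$tumors$lad
    if (any(is.na(lad_values))) stop("simulator failed to form tumors")
  } else {
    lad_values <- rep_len(as.integer(lad_values), n_tumors)
  }
  nc <- nrow(karyotype)
  len <- karyotype$length_bp
  wts <- len / sum(len)
  tumors <- vector("list", n_tumors)
  truth_rows <- vector("list", n_tumors)
  for (t in seq_len(n_tumors)) {
    lad <- lad_values[t]
    polarity <- matrix(sample(c(TRUE, FALSE), nc * 2, replace = TRUE), nc, 2)
    # background (biallelic) mutations, genome-wide
    n_bg <- mutation_load
    chrom_i <- sample.int(nc, n_bg, replace = TRUE, prob = wts)
    hom_i <- sample.int(2, n_bg, replace = TRUE)
    minus <- if (lad == 0) sample(c(TRUE, FALSE), n_bg, replace = TRUE)
             else !polarity[cbind(chrom_i, hom_i)]
    bg <- .draw_mutations(n_bg, spectrum, minus)
    bg$chrom <- karyotype$chrom[chrom_i]
    bg$pos <- floor(stats::runif(n_bg) * len[chrom_i]) + 1
    # retained lesion segments in the MRCA
    if (lad == 0) {
      segs <- NULL
      frac <- matrix(1, nc, 2)
      retained_mb <- 4 * sum(len) / 1e6   # both strands of both homologs
    } else {
      segs <- .retained_segments(nc, lad, recomb_rate)
      frac <- .segment_fractions(segs, nc)
      retained_mb <- sum(frac * len / 1e6)
    }
    f_realized <- if (lad == 0) 1 else sum(frac * len) / (4 * sum(len))
    # MAVs inside retained lesion segments
    rate_mb <- if (lad == 0) 2 * mav_per_mb else mav_per_mb
    mav_list <- list()
    for (ci in seq_len(nc)) for (h in 1:2) {
      if (lad == 0) {
        ivs <- matrix(c(0, 1), 1)
      } else {
        ivs <- segs[[ci]][[h]]
        if (nrow(ivs) == 0) next
      }
      seg_mb <- sum(ivs[, 2] - ivs[, 1]) * len[ci] / 1e6
      nm <- stats::rpois(1, rate_mb * seg_mb)
      if (nm == 0) next
      # positions uniform within the retained intervals
      cum <- cumsum(ivs[, 2] - ivs[, 1])
      x <- stats::runif(nm) * cum[length(cum)]
      seg_idx <- findInterval(x, c(0, cum), rightmost.closed = TRUE)
      off <- x - c(0, cum)[seg_idx]
      posu <- ivs[seg_idx, 1] + off
      pos <- floor(posu * len[ci]) + 1
      minus_m <- if (lad == 0) sample(c(TRUE, FALSE), nm, replace = TRUE)
                 else rep(!polarity[ci, h], nm)
      m1 <- .draw_mutations(nm, spectrum, minus_m)
      ctx_pyr <- ifelse(minus_m, .rc(m1$context), m1$context)
      alt1_pyr <- ifelse(minus_m, chartr("ACGT", "TGCA", m1$alt), m1$alt)
      alt2_pyr <- .draw_second_alt(spectrum, ctx_pyr, alt1_pyr)
      alt2 <- ifelse(minus_m, chartr("ACGT", "TGCA", alt2_pyr), alt2_pyr)
      mav_list[[length(mav_list) + 1]] <- data.frame(
        chrom = karyotype$chrom[ci], pos = pos,
        ref = c(m1$ref, m1$ref), alt = c(m1$alt, alt2),
        context = c(m1$context, m1$context), stringsAsFactors = FALSE)
    }
    mav <- if (length(mav_list)) do.call(rbind, mav_list) else NULL
    tab <- rbind(bg[, c("chrom", "pos", "ref", "alt", "context")],
                 if (!is.null(mav)) mav[, c("chrom", "pos", "ref", "alt", "context")])
    tumors[[t]] <- tab[order(tab$chrom, tab$pos), ]
    truth_rows[[t]] <- data.frame(
      tumor = t, lad = lad, f_realized = f_realized,
      n_mav = if (is.null(mav)) 0L else nrow(mav) / 2L,
      retained_mb = retained_mb)
  }
  list(tumors = tumors,
       truth = list(per_tumor = do.call(rbind, truth_rows),
                    params = params, mutation_load = mutation_load,
                    mav_per_mb = mav_per_mb, recomb_rate = recomb_rate,
                    karyotype = karyotype, seed = seed))
}

# per-homolog retained lesion intervals (unit coordinates) after lad-1
# divisions; recombination swaps complementary tails within the pair
.retained_segments <- function(nc, lad, recomb_rate) {
  segs <- lapply(seq_len(nc), function(i)
    list(matrix(c(0, 1), 1), matrix(c(0, 1), 1)))
  if (lad == 1) return(segs)
  for (div in seq_len(lad - 1)) {
    for (i in seq_len(nc)) {
      pair <- segs[[i]]
      if (recomb_rate > 0 && stats::runif(1) < recomb_rate) {
        x <- stats::runif(1)
        clip_r <- function(m) { m <- m[m[, 2] > x, , drop = FALSE]
                                m[, 1] <- pmax(m[, 1], x); m }
        clip_l <- function(m) { m <- m[m[, 1] < x, , drop = FALSE]
                                m[, 2] <- pmin(m[, 2], x); m }
        pair <- list(rbind(clip_l(pair[[1]]), clip_r(pair[[2]])),
                     rbind(clip_l(pair[[2]]), clip_r(pair[[1]])))
      }
      for (h in 1:2) if (stats::runif(1) < 0.5)
        pair[[h]] <- pair[[h]][0, , drop = FALSE]
      segs[[i]] <- pair
    }
  }
  segs
}

.segment_fractions <- function(segs, nc) {
  frac <- matrix(0, nc, 2)
  for (i in seq_len(nc)) for (h in 1:2) {
    m <- segs[[i]][[h]]
    frac[i, h] <- if (nrow(m) == 0) 0 else sum(m[, 2] - m[, 1])
  }
  frac
}

#' Generate a sparse-MAV metastatic-like sample
#'
#' Emulates post-chemotherapy metastatic tumors: a genome-wide background
#' of mutations (mixed signatures, no strand polarization) plus a handful
#' of lesion-derived MAVs confined to the chromosomes whose lesion strand
#' the MRCA retained at the given LAD. Germline heterozygous SNPs are
#' planted and a distance-dependent detection bias applied to phasing:
#' same-allele pairs are harder to phase the farther the SNP.
#'
#' @param n_mavs number of lesion MAVs to plant (0..~15).
#' @param background_mutations genome-wide background count.
#' @param signature lesion signature (96-channel) for MAV alternates.
#' @param background_spectrum spectrum of background mutations.
#' @param lad true LAD of the sample.
#' @param karyotype karyotype (default human female).
#' @param phasing list: `het_spacing_bp` (mean germline het SNP spacing),
#'   `window` (phasing window), `bias_halflife` (bp; same-allele detection
#'   probability decays with SNP distance).
#' @param seed optional seed.
#' @return list with `mutations`, `het_snps`, `phased_mavs` (with truth
#'   phase and observed phase after detection bias), `truth`.
#' @export
gen_metastatic_sample <- function(n_mavs = 5, background_mutations = 5000,
                                  signature = chemo_spectrum(),
                                  background_spectrum = NULL, lad = 2,
                                  karyotype = karyotype_human("female"),
                                  phasing = list(het_spacing_bp = 1500,
                                                 window = 300,
                                                 bias_halflife = 150),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(background_spectrum)) {
    background_spectrum <- setNames(rep(1 / 96, 96), sbs_channels())
  }
  nc <- nrow(karyotype)
  len <- karyotype$length_bp
  wts <- len / sum(len)
  ci <- sample.int(nc, background_mutations, replace = TRUE, prob = wts)
  bg <- .draw_mutations(background_mutations, background_spectrum,
                        sample(c(TRUE, FALSE), background_mutations, TRUE))
  bg$chrom <- karyotype$chrom[ci]
  bg$pos <- floor(stats::runif(background_mutations) * len[ci]) + 1
  mav <- NULL
  if (n_mavs > 0) {
    repeat {
      retained <- matrix(stats::runif(nc * 2) < 2^-(lad - 1), nc, 2)
      if (lad == 1) retained[] <- TRUE
      if (any(retained)) break
    }
    w_eff <- rep(wts, each = 2) * as.vector(t(retained))
    hom <- sample.int(2 * nc, n_mavs, replace = TRUE, prob = w_eff)
    ci2 <- (hom - 1L) %/% 2L + 1L
    minus <- sample(c(TRUE, FALSE), n_mavs, replace = TRUE)
    m1 <- .draw_mutations(n_mavs, signature, minus)
    ctx_pyr <- ifelse(minus, .rc(m1$context), m1$context)
    alt1_pyr <- ifelse(minus, chartr("ACGT", "TGCA", m1$alt), m1$alt)
    alt2_pyr <- .draw_second_alt(signature, ctx_pyr, alt1_pyr)
    alt2 <- ifelse(minus, chartr("ACGT", "TGCA", alt2_pyr), alt2_pyr)
    pos <- floor(stats::runif(n_mavs) * len[ci2]) + 1
    mav <- data.frame(chrom = karyotype$chrom[ci2], pos = pos,
                      ref = c(m1$ref, m1$ref), alt = c(m1$alt, alt2),
                      context = c(m1$context, m1$context),
                      stringsAsFactors = FALSE)
  }
  mutations <- rbind(bg[, c("chrom", "pos", "ref", "alt", "context")],
                     if (!is.null(mav))
                       mav[, c("chrom", "pos", "ref", "alt", "context")])
  mutations <- mutations[order(mutations$chrom, mutations$pos), ]
  # germline het SNPs at roughly uniform spacing
  n_het <- round(sum(len) / phasing$het_spacing_bp)
  ch <- sample.int(nc, n_het, replace = TRUE, prob = wts)
  het <- data.frame(chrom = karyotype$chrom[ch],
                    pos0 = floor(stats::runif(n_het) * len[ch]))
  phased <- NULL
  if (n_mavs > 0) {
    phased <- data.frame(chrom = mav$chrom[seq_len(n_mavs)],
                         pos0 = mav$pos[seq_len(n_mavs)] - 1L,
                         truth_phase = "matching", stringsAsFactors = FALSE)
    obs <- character(n_mavs)
    for (i in seq_len(n_mavs)) {
      near <- which(het$chrom == phased$chrom[i] &
                      abs(het$pos0 - phased$pos0[i]) <= phasing$window)
      if (!length(near)) { obs[i] <- "unphased"; next }
      d <- min(abs(het$pos0[near] - phased$pos0[i]))
      p_det <- 2^(-d / phasing$bias_halflife)  # same-allele detection bias
      obs[i] <- if (stats::runif(1) < p_det) "matching" else "unphased"
    }
    phased$phase <- obs
  }
  list(mutations = mutations, het_snps = het, phased_mavs = phased,
       truth = list(lad = lad, n_mavs_planted = n_mavs,
                    mav_sites = if (is.null(mav)) NULL else
                      unique(mav[, c("chrom", "pos")]),
                    seed = seed))
}

.default_clone_plan <- function() {
  data.frame(
    node = c("R", "N1", "N2", "N3", "Tc1", "Tc2", "Tc3", "Tc4",
              "P0", "n418", "n419", "n421", "Ta1", "Ta2",
              "n420", "n432", "Tb1", "Tb2", "Tb3", "Tb4"),
    parent = c(NA, "R", "N1", "N1", "N2", "N2", "N3", "N3",
               "R", "P0", "n418", "n418", "n421", "n421",
               "n419", "n419", "n420", "n420", "n432", "n432"),
    divisions = c(0L, 4L, 2L, 2L, 5L, 5L, 5L, 5L,
                  3L, 2L, 1L, 4L, 3L, 3L,
                  5L, 5L, 4L, 4L, 4L, 4L),
    stringsAsFactors = FALSE)
}

#' Generate a chemotherapy-pulsed single-cell phylogeny
#'
#' Builds a colony phylogeny from a clone plan (nodes, parents, branch
#' lengths in divisions), applies mutagen pulses that deposit lesions on
#' both strands of every chromosome of the pulsed cell, and propagates
#' each lesion strand through the division-resolved genealogy: homolog
#' strands co-segregate (complementary strands to complementary
#' daughters, producing chromosome-scale Watson-Crick anticorrelation in
#' sister lineages), unrepaired lesions survive each division with
#' probability 1/2 per lineage, and error-prone translesion replication
#' (probability `1 - eps`) fixes a mutation one division later in the
#' sister lineage of the lesion path. Repeated error-prone replications of
#' one lesion yield MAVs (different alternates) and PVVs (same alternate
#' on phylogeny-inconsistent branches).
#'
#' @param clone_plan data.frame `node`, `parent`, `divisions` (root has
#'   NA parent, 0 divisions); default emulates a chemotherapy-treated
#'   blood phylogeny with two consecutive pulses two divisions apart.
#' @param pulse_schedule named integer vector: lesions deposited at the
#'   top cell of each named branch (default two pulses of 150).
#' @param lesion_persistence per-division probability that an unrepaired
#'   lesion escapes repair (default 0.9).
#' @param eps error-free translesion replication probability.
#' @param signature 96-channel lesion signature (alternate alleles drawn
#'   from its conditional alternate law, so repeated readings of one
#'   lesion often agree, producing PVVs).
#' @param background_per_division background mutations per branch
#'   division.
#' @param homologs_per_chrom 1 (default) represents each chromosome as a
#'   single lesion-bearing duplex, the resolution at which strand
#'   inheritance is drawn; 2 gives the diploid representation, where the
#'   two homologs' independent segregation dilutes the sister-branch
#'   Watson-Crick anticorrelation by about half.
#' @param karyotype karyotype (default human female).
#' @param seed optional seed.
#' @return list with `newick` (string), `branch_mutations` (data.frame
#'   `branch`, `chrom`, `pos`, `ref`, `alt`), and `truth` (lesion table,
#'   event log, expected MAV/PVV site lists, pulse nodes, sister pair).
#' @export
gen_pulsed_phylogeny <- function(clone_plan = NULL,
                                 pulse_schedule = c(n418 = 300, n419 = 300),
                                 lesion_persistence = 0.9, eps = 0.3,
                                 signature = chemo_spectrum(),
                                 background_per_division = 5,
                                 homologs_per_chrom = 1,
                                 karyotype = karyotype_human("female"),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(clone_plan)) clone_plan <- .default_clone_plan()
  stopifnot(all(c("node", "parent", "divisions") %in% names(clone_plan)))
  if (any(clone_plan$divisions[!is.na(clone_plan$parent)] < 1))
    stop("every non-root branch needs at least one division")
  if (!all(names(pulse_schedule) %in% clone_plan$node))
    stop("pulse_schedule names must be clone_plan nodes")
  kids <- split(clone_plan$node, clone_plan$parent)
  root <- clone_plan$node[is.na(clone_plan$parent)]
  tips <- setdiff(clone_plan$node, names(kids))
  ndiv <- setNames(clone_plan$divisions, clone_plan$node)
  nc <- nrow(karyotype)
  len <- karyotype$length_bp
  wts <- len / sum(len)
  # shared segregation coins: which daughter slot gets the Watson strand
  coins <- new.env(parent = emptyenv())
  coin <- function(branch, div, ci, hom) {
    k <- paste(branch, div, ci, hom, sep = "|")
    if (is.null(coins[[k]])) coins[[k]] <- sample(1:2, 1)
    coins[[k]]
  }
  events <- list()
  lesions <- list()
  walk_lesion <- function(id, branch, div, ci, hom, watson, pending_alt,
                          ref, pos, ctx_pyr) {
    # lesion sits in the cell at division `div` (1-based) of `branch`
    repeat {
      last_div <- div == ndiv[branch]
      children <- if (last_div) kids[[branch]] else NULL
      # a branching division has two tracked daughters; an intermediate
      # division (or a chain node with a single child) tracks only slot 1
      branching <- !is.null(children) && length(children) >= 2
      # side taken by the lesion strand at this division
      w_side <- coin(branch, div, ci, hom)
      l_side <- if (watson) w_side else 3 - w_side
      # pending mutation strand is complementary: goes to the other side
      if (!is.null(pending_alt)) {
        m_side <- 3 - l_side
        if (branching) {
          events[[length(events) + 1]] <<- data.frame(
            lesion = id, branch = children[m_side], chrom = karyotype$chrom[ci],
            pos = pos, ref = ref, alt = pending_alt, stringsAsFactors = FALSE)
        } else if (m_side == 1) {
          # the tracked daughter fixes the mutation: recorded on the branch
          # that contains (or follows) it
          fix_branch <- if (last_div && length(children) == 1) children[1]
                        else branch
          events[[length(events) + 1]] <<- data.frame(
            lesion = id, branch = fix_branch, chrom = karyotype$chrom[ci],
            pos = pos, ref = ref, alt = pending_alt, stringsAsFactors = FALSE)
        }
        pending_alt <- NULL
      }
      # repair before the next replication
      if (stats::runif(1) > lesion_persistence) return(invisible())
      # error-prone translesion replication creates a new pending mutation
      if (stats::runif(1) > eps) {
        ref_pyr <- substr(ctx_pyr, 2, 2)
        alts <- setdiff(.BASES, ref_pyr)
        chs <- paste0(substr(ctx_pyr, 1, 1), "[", ref_pyr, ">", alts, "]",
                      substr(ctx_pyr, 3, 3))
        w <- signature[chs]; w[is.na(w)] <- 0
        if (sum(w) <= 0) w <- rep(1, 3)
        alt_pyr <- sample(alts, 1, prob = w)
        # recorded on the reference strand: complement for Crick lesions
        pending_alt <- if (watson) alt_pyr else chartr("ACGT", "TGCA", alt_pyr)
      }
      # follow the lesion strand
      if (last_div) {
        if (is.null(children)) return(invisible())  # persists into the colony
        if (branching) {
          branch <- children[l_side]
        } else {
          if (l_side != 1) return(invisible())      # untracked sibling
          branch <- children[1]
        }
        div <- 1
        if (ndiv[branch] == 0) return(invisible())
      } else {
        if (l_side != 1) return(invisible())        # untracked sibling
        div <- div + 1
      }
    }
  }
  lesion_id <- 0
  for (pn in names(pulse_schedule)) {
    n_les <- pulse_schedule[[pn]]
    ci <- sample.int(nc, n_les, replace = TRUE, prob = wts)
    hom <- sample.int(homologs_per_chrom, n_les, replace = TRUE)
    watson <- sample(c(TRUE, FALSE), n_les, replace = TRUE)
    for (j in seq_len(n_les)) {
      lesion_id <- lesion_id + 1
      ch <- sample(names(signature), 1, prob = signature)
      pp <- .channel_parts(ch)
      ctx_pyr <- paste0(pp$p5, pp$ref, pp$p3)
      ref <- if (watson[j]) pp$ref else chartr("ACGT", "TGCA", pp$ref)
      pos <- floor(stats::runif(1) * len[ci[j]]) + 1
      lesions[[lesion_id]] <- data.frame(
        lesion = lesion_id, origin = pn, chrom = karyotype$chrom[ci[j]],
        pos = pos, hom = hom[j], watson = watson[j], ref = ref,
        stringsAsFactors = FALSE)
      walk_lesion(lesion_id, pn, 1L, ci[j], hom[j], watson[j], NULL,
                  ref, pos, ctx_pyr)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(lesion = integer(0), branch = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0))
  # deduplicate: one lesion can fix the same alt only once per branch
  ev <- unique(ev)
  # background mutations: globally unique positions, random strand
  bg <- list()
  for (b in setdiff(clone_plan$node, root)) {
    nb <- stats::rpois(1, background_per_division * ndiv[b])
    if (nb == 0) next
    ci <- sample.int(nc, nb, replace = TRUE, prob = wts)
    mm <- .draw_mutations(nb, setNames(rep(1 / 96, 96), sbs_channels()),
                          sample(c(TRUE, FALSE), nb, TRUE))
    bg[[b]] <- data.frame(branch = b, chrom = karyotype$chrom[ci],
                          pos = floor(stats::runif(nb) * len[ci]) + 1,
                          ref = mm$ref, alt = mm$alt, stringsAsFactors = FALSE)
  }
  bg <- if (length(bg)) do.call(rbind, bg) else NULL
  if (!is.null(bg)) {
    key <- paste(bg$chrom, bg$pos)
    bg <- bg[!duplicated(key), ]
  }
  branch_mutations <- rbind(ev[, c("branch", "chrom", "pos", "ref", "alt")],
                            if (!is.null(bg))
                              bg[, c("branch", "chrom", "pos", "ref", "alt")])
  rownames(branch_mutations) <- NULL
  # expected footprints from the event log
  exp_mav <- exp_pvv <- NULL
  if (nrow(ev) > 0) {
    by_lesion <- split(ev, ev$lesion)
    rows_m <- list(); rows_p <- list()
    for (e in by_lesion) {
      if (nrow(e) < 2 || length(unique(e$branch)) < 2) next
      if (length(unique(e$alt)) >= 2)
        rows_m[[length(rows_m) + 1]] <- e[1, c("lesion", "chrom", "pos")]
      dup <- names(which(table(e$alt) >= 2))
      for (aa in dup) {
        if (length(unique(e$branch[e$alt == aa])) >= 2)
          rows_p[[length(rows_p) + 1]] <-
            cbind(e[e$alt == aa, ][1, c("lesion", "chrom", "pos")], alt = aa)
      }
    }
    exp_mav <- if (length(rows_m)) do.call(rbind, rows_m) else NULL
    exp_pvv <- if (length(rows_p)) do.call(rbind, rows_p) else NULL
  }
  newick <- .plan_to_newick(clone_plan, root, kids)
  list(newick = newick, branch_mutations = branch_mutations,
       truth = list(lesions = do.call(rbind, lesions), events = ev,
                    expected_mavs = exp_mav, expected_pvvs = exp_pvv,
                    pulse_nodes = names(pulse_schedule),
                    sister_pair = c("n420", "n432"), seed = seed,
                    clone_plan = clone_plan))
}

.plan_to_newick <- function(plan, root, kids) {
  build <- function(node) {
    ch <- kids[[node]]
    lab <- paste0(node, ":", plan$divisions[plan$node == node])
    if (is.null(ch)) return(lab)
    paste0("(", paste(vapply(ch, build, character(1)), collapse = ","), ")", lab)
  }
  paste0(build(root), ";")
}
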