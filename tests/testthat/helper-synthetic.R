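# shared helpers for the test suite

# convert a generated tumor mutation data.frame (1-based pos) to the
# internal 0-based table
as_internal <- function(m) {
  data.frame(chrom = m$chrom, pos0 = m$pos - 1L, ref = m$ref, alt = m$alt,
             stringsAsFactors = FALSE)
}

# full per-tumor LAD estimation pipeline
estimate_lad_for <- function(m, karyotype, ...) {
  tr <- build_segments(normalize_mutations(as_internal(m), karyotype),
                       karyotype)
  estimate_lad(tr, decode_lesion_states(tr), n_boot = 0, ...)
}

# chi-square GOF with pooling of low-expectation bins
chisq_gof_p <- function(counts, probs, min_exp = 5) {
  keep <- which(probs * sum(counts) >= min_exp)
  if (length(keep) < length(probs)) {
    pc <- sum(counts[-keep]); pp <- sum(probs[-keep])
    counts <- counts[keep]; probs <- probs[keep]
    if (pp > 0) { counts <- c(counts, pc); probs <- c(probs, pp) }
  }
  suppressWarnings(stats::chisq.test(counts, p = probs / sum(probs))$p.value)
}

# LAD counts from a simulator run
lad_counts <- function(lads, n_max) {
  as.numeric(table(factor(pmin(lads, n_max), levels = 0:n_max)))
}

read_pulsed <- function(g) {
  read_tree(ape::read.tree(text = g$newick), g$branch_mutations)
}

node_of <- function(ptree, label) {
  match(label, c(ptree$tree$tip.label, ptree$tree$node.label))
}

fast_sim_config <- list(horizon = 15, cap = 1500)
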