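balanced4 <- function() {
  tree <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
  muts <- data.frame(branch = c("A", "B", "C", "D"),
                     chrom = "chr1", pos = c(10, 20, 30, 40),
                     ref = "T", alt = "A")
  read_tree(tree, muts)
}

test_that("trees load with resolved branch ids and validate inputs", {
  pt <- balanced4()
  expect_equal(nrow(pt$mutations), 4)
  expect_true(all(pt$mutations$node %in% 1:4))
  expect_warning(read_tree(ape::read.tree(text = "((A:1,B:1)ab:1,C:1)r;"),
                           data.frame()), "empty mutation table")
  expect_error(read_tree(ape::read.tree(text = "((A:1,B:1)ab:1,C:1)r;"),
                         data.frame(branch = "nope", chrom = "chr1", pos = 1,
                                    ref = "T", alt = "A")),
               "unresolvable")
})

test_that("MAV and PVV definitions are applied to sister and non-nested branches", {
  tree <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
  muts <- data.frame(branch = c("A", "B", "A", "C"),
                     chrom = c("chr1", "chr1", "chr2", "chr2"),
                     pos = c(100, 100, 500, 500),
                     ref = "T", alt = c("A", "C", "G", "G"))
  pt <- read_tree(tree, muts)
  fp <- detect_footprints(pt)
  expect_equal(nrow(fp$mavs), 1)
  labels <- c(pt$tree$tip.label, pt$tree$node.label)
  expect_equal(labels[fp$mavs$lesion_node], "ab")   # parent of the sisters
  expect_equal(nrow(fp$pvvs), 1)
  expect_equal(labels[fp$pvvs$lesion_node], "r")
  # identical alt on nested branches is ambiguous, not a PVV
  muts2 <- data.frame(branch = c("ab", "A"), chrom = "chr3", pos = c(9, 9),
                      ref = "T", alt = c("A", "A"))
  fp2 <- detect_footprints(read_tree(tree, muts2))
  expect_null(fp2$pvvs)
  expect_equal(nrow(fp2$ambiguous), 1)
})

test_that("detection is invariant to input row order", {
  g <- gen_pulsed_phylogeny(pulse_schedule = c(n418 = 80), seed = 71)
  pt1 <- read_pulsed(g)
  shuffled <- g$branch_mutations[sample(nrow(g$branch_mutations)), ]
  pt2 <- read_tree(ape::read.tree(text = g$newick), shuffled)
  f1 <- detect_footprints(pt1); f2 <- detect_footprints(pt2)
  expect_equal(f1$lesion_nodes, f2$lesion_nodes)
  expect_equal(nrow(f1$mavs), nrow(f2$mavs))
  expect_equal(nrow(f1$pvvs), nrow(f2$pvvs))
})

test_that("planted footprints are recovered and lesion-free trees are clean", {
  set.seed(72)
  recov <- replicate(3, {
    g <- gen_pulsed_phylogeny(seed = sample.int(1e6, 1))
    fp <- detect_footprints(read_pulsed(g))
    truth_sites <- unique(rbind(g$truth$expected_mavs[c("chrom", "pos")],
                                g$truth$expected_pvvs[c("chrom", "pos")]))
    found <- unique(rbind(
      if (!is.null(fp$mavs)) data.frame(chrom = fp$mavs$chrom,
                                        pos = fp$mavs$pos0 + 1) else NULL,
      if (!is.null(fp$pvvs)) data.frame(chrom = fp$pvvs$chrom,
                                        pos = fp$pvvs$pos0 + 1) else NULL))
    mean(paste(truth_sites$chrom, truth_sites$pos) %in%
           paste(found$chrom, found$pos))
  })
  expect_gte(mean(recov), 0.95)
  # no pulse, background only: zero false positives
  g0 <- gen_pulsed_phylogeny(pulse_schedule = c(n418 = 0), seed = 73)
  fp0 <- detect_footprints(read_pulsed(g0))
  expect_null(fp0$mavs)
  expect_null(fp0$pvvs)
})

test_that("perfectly mirrored strand asymmetries give rho minus one", {
  tree <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
  n <- 8
  mk <- function(branch, ta, at) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(data.frame(branch = branch, chrom = paste0("chr", i),
                       pos = seq_len(ta[i]) * 10 + ifelse(branch == "A", 0, 5),
                       ref = "T", alt = "A"),
            data.frame(branch = branch, chrom = paste0("chr", i),
                       pos = seq_len(at[i]) * 1000 + ifelse(branch == "A", 0, 5),
                       ref = "A", alt = "T"))
    }))
  }
  ta <- c(9, 8, 7, 6, 4, 3, 2, 1)
  pt <- read_tree(tree, rbind(mk("A", ta, 10 - ta), mk("B", 10 - ta, ta)))
  wc <- wc_anticorrelation(pt, node_of(pt, "A"), node_of(pt, "B"))
  expect_equal(wc$rho, -1)
  expect_lt(wc$p_value, 0.01)
})

test_that("the anticorrelation test is not applied to sparse chromosomes", {
  pt <- balanced4()
  wc <- wc_anticorrelation(pt, node_of(pt, "A"), node_of(pt, "B"))
  expect_false(wc$testable)
})

test_that("single-division sisters below a pulse show negative asymmetry correlation", {
  set.seed(74)
  ps <- replicate(5, {
    g <- gen_pulsed_phylogeny(pulse_schedule = c(n419 = 300),
                              seed = sample.int(1e6, 1))
    pt <- read_pulsed(g)
    wc_anticorrelation(pt, node_of(pt, "n420"), node_of(pt, "n432"))$p_value
  })
  expect_gte(mean(ps < 0.05), 0.8)
})

test_that("lesion persistence across many divisions decays at least geometrically", {
  set.seed(75)
  # a lesion planted above a k-division chain can only mark the two tips
  # below it if it persists through all k divisions
  yield <- vapply(c(1L, 5L), function(k) {
    plan <- data.frame(node = c("R", "P", "X", "T1", "T2"),
                       parent = c(NA, "R", "P", "X", "X"),
                       divisions = c(0L, 2L, k, 2L, 2L))
    g <- gen_pulsed_phylogeny(clone_plan = plan,
                              pulse_schedule = c(P = 3000), seed = 76 + k)
    ev <- g$truth$events
    ev <- ev[ev$branch %in% c("T1", "T2"), ]
    spanning <- tapply(ev$branch, ev$lesion, function(b) length(unique(b)) >= 2)
    sum(spanning, na.rm = TRUE) / 3000
  }, numeric(1))
  # four extra divisions cost far more than one halving in yield
  expect_lt(yield[2], yield[1] * 0.5)
})

test_that("lesion nodes sit above expanding subtrees relative to matched controls", {
  set.seed(77)
  g <- gen_pulsed_phylogeny(seed = 78)
  pt <- read_pulsed(g)
  fp <- detect_footprints(pt)
  strong <- fp$lesion_nodes$node[fp$lesion_nodes$n_total >= 5]
  st <- lesion_node_statistics(pt, strong, horizon = 100,
                               pvv_records = fp$pvvs, seed = 79)
  # the pulsed clade is the expanding one by construction
  expect_true(is.finite(st$mean_diff))
  expect_gte(st$mean_diff, 0)
  expect_true(!is.null(st$distances))
  # identity control: using the lesion nodes as their own controls
  depth <- lesionlad:::.root_mut_depth(pt)
  cnt <- lesionlad:::.branch_mut_counts(pt)
  own <- vapply(strong, function(nd)
    lesionlad:::.branching_points_below(pt, nd, 100, depth, cnt), numeric(1))
  expect_equal(mean(own - own), 0)
})
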