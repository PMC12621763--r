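#' Read a single-cell phylogeny with branch-assigned mutations
#'
#' Loads a rooted Newick tree (ape) and a branch-mutation table. Each
#' mutation is assigned to exactly one branch, identified by the branch's
#' child node: either a tip/node label or an ape node number in the
#' `branch` column. Unresolvable branch ids raise an error listing the
#' offenders.
#'
#' @param newick_path path to a Newick file (or an `ape::phylo` object).
#' @param branch_mutations path to a TSV (or a data.frame) with columns
#'   `branch`, `chrom`, `pos` or `pos0`, `ref`, `alt`.
#' @return object of class `phylo_lesion_tree`: list with `tree` (phylo),
#'   `mutations` (data.frame with resolved integer `node`), `parent`
#'   (parent lookup vector), `root`.
#' @export
read_tree <- function(newick_path, branch_mutations) {
  tree <- if (inherits(newick_path, "phylo")) newick_path
          else ape::read.tree(newick_path)
  if (is.null(tree)) stop("could not parse Newick input")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  muts <- if (is.data.frame(branch_mutations)) branch_mutations
          else utils::read.delim(branch_mutations, stringsAsFactors = FALSE)
  if (nrow(muts) > 0) {
    need <- c("branch", "chrom", "ref", "alt")
    if (!all(need %in% names(muts)))
      stop("branch mutation table must have columns: ",
           paste(need, collapse = ", "))
    if (!"pos0" %in% names(muts)) {
      if (!"pos" %in% names(muts)) stop("need a pos or pos0 column")
      muts$pos0 <- as.integer(muts$pos) - 1L
    }
    labels <- c(tree$tip.label,
                if (!is.null(tree$node.label)) tree$node.label else character(0))
    n_all <- ape::Ntip(tree) + tree$Nnode
    node <- suppressWarnings(as.integer(as.character(muts$branch)))
    by_label <- match(as.character(muts$branch), labels)
    lab_node <- ifelse(!is.na(by_label), by_label, NA_integer_)
    # numeric ids must be valid node numbers; otherwise fall back to labels
    node <- ifelse(!is.na(node) & node >= 1 & node <= n_all, node, lab_node)
    if (any(is.na(node))) {
      bad <- unique(as.character(muts$branch)[is.na(node)])
      stop("unresolvable branch id(s): ", paste(head(bad, 10), collapse = ", "))
    }
    muts$node <- node
  } else {
    muts <- data.frame(branch = character(0), chrom = character(0),
                       pos0 = integer(0), ref = character(0),
                       alt = character(0), node = integer(0))
    warning("empty mutation table: all branches have zero mutation length")
  }
  parent <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  structure(list(tree = tree, mutations = muts, parent = parent,
                 root = ape::Ntip(tree) + 1L),
            class = "phylo_lesion_tree")
}

# path of nodes from root to node (inclusive)
.root_path <- function(ptree, node) {
  path <- node
  while (!is.na(ptree$parent[node])) {
    node <- ptree$parent[node]
    path <- c(node, path)
  }
  path
}

.mrca_pair <- function(ptree, a, b) {
  pa <- .root_path(ptree, a)
  pb <- .root_path(ptree, b)
  k <- min(length(pa), length(pb))
  same <- which(pa[seq_len(k)] == pb[seq_len(k)])
  pa[max(same)]
}

.is_ancestor <- function(ptree, a, b) {
  # TRUE if a is an ancestor of b (strict)
  if (a == b) return(FALSE)
  b <- ptree$parent[b]
  while (!is.na(b)) {
    if (b == a) return(TRUE)
    b <- ptree$parent[b]
  }
  FALSE
}

# per-branch mutation counts indexed by child node
.branch_mut_counts <- function(ptree) {
  n_all <- length(ptree$parent)
  cnt <- tabulate(ptree$mutations$node, nbins = n_all)
  cnt
}

# mutation distance from root per node (sum of branch mutation counts)
.root_mut_depth <- function(ptree) {
  cnt <- .branch_mut_counts(ptree)
  n_all <- length(ptree$parent)
  depth <- rep(NA_real_, n_all)
  depth[ptree$root] <- 0
  # edges of a phylo are not guaranteed topologically ordered; iterate
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(ptree$tree$edge))) {
      p <- ptree$tree$edge[e, 1]; c <- ptree$tree$edge[e, 2]
      if (!is.na(depth[p]) && is.na(depth[c])) {
        depth[c] <- depth[p] + cnt[c]; done <- FALSE
      }
    }
    if (done) break
  }
  depth
}

#' Detect lesion footprints (MAVs and PVVs) on a phylogeny
#'
#' Scans all sites with two or more mutation events. A site whose events
#' carry distinct alternate alleles on distinct branches is a multiallelic
#' variant (MAV): the shared lesion must have been present in the common
#' ancestor, so the lesion node is the MRCA of the event branches' parent
#' nodes. A site with the identical alternate on branches inconsistent
#' with a single origin (neither branch ancestral to the other) is a
#' phylogeny violating variant (PVV); its repair node is the deeper event
#' node, where the error-prone outcome was last fixed. Ancestor-descendant
#' same-allele pairs are flagged ambiguous, not guessed.
#'
#' @param ptree a [read_tree()] object.
#' @return list with `mavs`, `pvvs`, `ambiguous` (data.frames) and
#'   `lesion_nodes` (per-node MAV+PVV counts and distinct lesion-bearing
#'   chromosome counts).
#' @export
detect_footprints <- function(ptree) {
  stopifnot(inherits(ptree, "phylo_lesion_tree"))
  muts <- ptree$mutations
  mavs <- pvvs <- amb <- list()
  if (nrow(muts) > 0) {
    muts <- muts[order(muts$chrom, muts$pos0, muts$node, muts$alt), ]
    key <- paste(muts$chrom, muts$pos0)
    for (site in unique(key[duplicated(key)])) {
      ev <- muts[key == site, , drop = FALSE]
      if (length(unique(ev$node)) < 2 && length(unique(ev$alt)) < 2) next
      # MAV: first pair of distinct alts on distinct branches
      alt_u <- unique(ev$alt)
      if (length(alt_u) >= 2) {
        e1 <- ev[ev$alt == alt_u[1], ][1, ]
        e2 <- ev[ev$alt == alt_u[2], ][1, ]
        if (e1$node != e2$node) {
          lesion <- .mrca_pair(ptree, ptree$parent[e1$node], ptree$parent[e2$node])
          mavs[[length(mavs) + 1]] <- data.frame(
            chrom = e1$chrom, pos0 = e1$pos0, ref = e1$ref,
            alt1 = e1$alt, alt2 = e2$alt, node1 = e1$node, node2 = e2$node,
            lesion_node = lesion, stringsAsFactors = FALSE)
        } else {
          amb[[length(amb) + 1]] <- data.frame(
            chrom = e1$chrom, pos0 = e1$pos0, reason = "distinct alts on one branch",
            stringsAsFactors = FALSE)
        }
      }
      # PVV: identical alt on >= 2 distinct, non-nested branches
      for (aa in alt_u) {
        nodes <- unique(ev$node[ev$alt == aa])
        if (length(nodes) < 2) next
        n1 <- nodes[1]; n2 <- nodes[2]
        if (.is_ancestor(ptree, n1, n2) || .is_ancestor(ptree, n2, n1)) {
          amb[[length(amb) + 1]] <- data.frame(
            chrom = ev$chrom[1], pos0 = ev$pos0[1],
            reason = "same alt on nested branches", stringsAsFactors = FALSE)
          next
        }
        lesion <- .mrca_pair(ptree, ptree$parent[n1], ptree$parent[n2])
        depth <- .root_mut_depth(ptree)
        repair <- if (depth[n1] >= depth[n2]) n1 else n2
        pvvs[[length(pvvs) + 1]] <- data.frame(
          chrom = ev$chrom[1], pos0 = ev$pos0[1], ref = ev$ref[1], alt = aa,
          node1 = n1, node2 = n2, lesion_node = lesion, repair_node = repair,
          stringsAsFactors = FALSE)
      }
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  mavs <- bind(mavs); pvvs <- bind(pvvs); amb <- bind(amb)
  nodes <- sort(unique(c(if (!is.null(mavs)) mavs$lesion_node,
                         if (!is.null(pvvs)) pvvs$lesion_node)))
  lesion_nodes <- NULL
  if (length(nodes)) {
    lesion_nodes <- do.call(rbind, lapply(nodes, function(nd) {
      cm <- if (!is.null(mavs)) mavs[mavs$lesion_node == nd, ] else NULL
      cp <- if (!is.null(pvvs)) pvvs[pvvs$lesion_node == nd, ] else NULL
      chroms <- unique(c(if (!is.null(cm)) cm$chrom, if (!is.null(cp)) cp$chrom))
      data.frame(node = nd,
                 n_mav = if (is.null(cm)) 0L else nrow(cm),
                 n_pvv = if (is.null(cp)) 0L else nrow(cp),
                 n_total = (if (is.null(cm)) 0L else nrow(cm)) +
                   (if (is.null(cp)) 0L else nrow(cp)),
                 n_chrom = length(chroms), stringsAsFactors = FALSE)
    }))
  }
  list(mavs = mavs, pvvs = pvvs, ambiguous = amb, lesion_nodes = lesion_nodes)
}

#' Watson-Crick asymmetry anticorrelation between sister branches
#'
#' For each chromosome, the strand asymmetry of a mutation class
#' (reference-strand polarized, e.g. `"T>A"` versus its complement
#' `"A>T"`) is `(n_class - n_complement) / (n_class + n_complement)`.
#' Sister cells one division below a mutagenized ancestor inherit
#' complementary lesion strands, so their per-chromosome asymmetries
#' anticorrelate. Spearman correlation across chromosomes, one-sided
#' toward negative.
#'
#' @param ptree a [read_tree()] object.
#' @param branch_a,branch_b the two branches (child node ids) to compare;
#'   mutations of each branch may optionally include descendants via
#'   `include_descendants`.
#' @param mut_class mutation class polarized on the reference strand
#'   (`"T>A"` form).
#' @param min_chroms minimum chromosomes informative in both branches.
#' @param include_descendants if TRUE, pools each branch's subtree
#'   mutations.
#' @return list with `rho`, `p_value`, `per_chrom` (data.frame of the two
#'   asymmetry vectors), `testable`.
#' @export
wc_anticorrelation <- function(ptree, branch_a, branch_b, mut_class = "T>A",
                               min_chroms = 5, include_descendants = FALSE) {
  stopifnot(inherits(ptree, "phylo_lesion_tree"))
  cls <- strsplit(mut_class, ">")[[1]]
  comp <- chartr("ACGT", "TGCA", cls)
  collect <- function(node) {
    nodes <- node
    if (include_descendants) {
      n_all <- length(ptree$parent)
      nodes <- c(node, which(vapply(seq_len(n_all), function(x)
        .is_ancestor(ptree, node, x), logical(1))))
    }
    ptree$mutations[ptree$mutations$node %in% nodes, , drop = FALSE]
  }
  asym <- function(mu) {
    n_c <- table(factor(mu$chrom[mu$ref == cls[1] & mu$alt == cls[2]],
                        levels = unique(ptree$mutations$chrom)))
    n_r <- table(factor(mu$chrom[mu$ref == comp[1] & mu$alt == comp[2]],
                        levels = unique(ptree$mutations$chrom)))
    tot <- as.numeric(n_c + n_r)
    data.frame(chrom = names(n_c), asym = ifelse(tot > 0,
               (as.numeric(n_c) - as.numeric(n_r)) / tot, NA),
               n = tot, stringsAsFactors = FALSE)
  }
  aa <- asym(collect(branch_a)); bb <- asym(collect(branch_b))
  ok <- !is.na(aa$asym) & !is.na(bb$asym)
  if (sum(ok) < min_chroms)
    return(list(rho = NA_real_, p_value = NA_real_, per_chrom = NULL,
                testable = FALSE))
  ct <- suppressWarnings(stats::cor.test(aa$asym[ok], bb$asym[ok],
                                         method = "spearman",
                                         alternative = "less"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       per_chrom = data.frame(chrom = aa$chrom[ok], asym_a = aa$asym[ok],
                              asym_b = bb$asym[ok]),
       testable = TRUE)
}

# internal nodes with >= 2 children within a mutation-distance window below `node`
.branching_points_below <- function(ptree, node, horizon, depth, cnt) {
  n_all <- length(ptree$parent)
  kids <- split(ptree$tree$edge[, 2], ptree$tree$edge[, 1])
  count <- 0
  stack <- kids[[as.character(node)]]
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    if (depth[x] - depth[node] > horizon) next
    ch <- kids[[as.character(x)]]
    if (!is.null(ch) && length(ch) >= 2) count <- count + 1
    stack <- c(stack, ch)
  }
  count
}

#' Lesion-node expansion statistics versus matched controls
#'
#' Two footprints of rapid expansion below lesion-marked nodes: (a) the
#' number of branching points within a fixed mutation-distance window
#' below each lesion node, compared with control nodes matched on root
#' distance (within a tolerance band) and excluding
#' ancestors/descendants of lesion nodes; (b) the lesion-node to
#' repair-node mutation distance of each PVV, compared with control node
#' pairs of the same topological span drawn among non-lesion nodes.
#'
#' @param ptree a [read_tree()] object.
#' @param lesion_nodes integer vector of lesion node ids (e.g. from
#'   [detect_footprints()]).
#' @param horizon mutation-distance window for branching-point counts.
#' @param match_tol relative root-distance tolerance for control matching
#'   (default 0.10).
#' @param pvv_records optional `pvvs` data.frame from [detect_footprints()]
#'   for the distance comparison.
#' @param n_boot bootstrap replicates for confidence intervals.
#' @param seed optional seed.
#' @return list with `branching` (per-node counts and matched-control
#'   means, plus `ratio_ge10`), `distances` (lesion vs control pair
#'   distances), bootstrap CIs.
#' @export
lesion_node_statistics <- function(ptree, lesion_nodes, horizon = 50,
                                   match_tol = 0.10, pvv_records = NULL,
                                   n_boot = 200, seed = NULL) {
  stopifnot(inherits(ptree, "phylo_lesion_tree"))
  if (length(lesion_nodes) < 1) stop("need at least one lesion node")
  if (!is.null(seed)) set.seed(seed)
  depth <- .root_mut_depth(ptree)
  cnt <- .branch_mut_counts(ptree)
  n_tip <- ape::Ntip(ptree$tree)
  internal <- (n_tip + 1):(n_tip + ptree$tree$Nnode)
  related <- unique(unlist(lapply(lesion_nodes, function(ln)
    c(ln, which(vapply(seq_along(ptree$parent), function(x)
      .is_ancestor(ptree, ln, x) || .is_ancestor(ptree, x, ln), logical(1)))))))
  pool <- setdiff(internal, related)
  branching <- do.call(rbind, lapply(lesion_nodes, function(ln) {
    ctrl <- pool[abs(depth[pool] - depth[ln]) <=
                   pmax(match_tol * depth[ln], 1)]
    obs <- .branching_points_below(ptree, ln, horizon, depth, cnt)
    cm <- if (length(ctrl)) mean(vapply(ctrl, function(x)
      .branching_points_below(ptree, x, horizon, depth, cnt), numeric(1)))
      else NA_real_
    data.frame(node = ln, branchings = obs, control_mean = cm,
               n_controls = length(ctrl))
  }))
  ctrl_counts <- unlist(lapply(lesion_nodes, function(ln) {
    ctrl <- pool[abs(depth[pool] - depth[ln]) <= pmax(match_tol * depth[ln], 1)]
    vapply(ctrl, function(x)
      .branching_points_below(ptree, x, horizon, depth, cnt), numeric(1))
  }))
  ratio_ge10 <- if (length(ctrl_counts) && mean(ctrl_counts >= 10) > 0)
    mean(branching$branchings >= 10) / mean(ctrl_counts >= 10) else NA_real_
  boot_diff <- if (all(is.finite(branching$control_mean))) {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample(nrow(branching), replace = TRUE)
      mean(branching$branchings[idx] - branching$control_mean[idx])
    }, numeric(1))
  } else NULL
  distances <- NULL
  if (!is.null(pvv_records) && nrow(pvv_records) > 0) {
    span_edges <- function(a, b) {
      # edges on path a..b (a ancestral)
      k <- 0L; x <- b
      while (!is.na(x) && x != a) { x <- ptree$parent[x]; k <- k + 1L }
      if (is.na(x)) NA_integer_ else k
    }
    les_d <- vapply(seq_len(nrow(pvv_records)), function(i)
      depth[pvv_records$repair_node[i]] - depth[pvv_records$lesion_node[i]],
      numeric(1))
    spans <- vapply(seq_len(nrow(pvv_records)), function(i)
      span_edges(pvv_records$lesion_node[i], pvv_records$repair_node[i]),
      integer(1))
    ctrl_d <- unlist(lapply(unique(spans[!is.na(spans)]), function(k) {
      cand <- pool
      out <- c()
      for (nd in cand) {
        x <- nd; ok <- TRUE
        for (j in seq_len(k)) {
          kidv <- ptree$tree$edge[ptree$tree$edge[, 1] == x, 2]
          if (!length(kidv)) { ok <- FALSE; break }
          x <- kidv[sample.int(length(kidv), 1)]
        }
        if (ok) out <- c(out, depth[x] - depth[nd])
      }
      out
    }))
    distances <- list(lesion = les_d, control = ctrl_d,
                      lesion_mean = mean(les_d, na.rm = TRUE),
                      control_mean = if (length(ctrl_d)) mean(ctrl_d) else NA_real_)
  }
  list(branching = branching,
       mean_diff = mean(branching$branchings - branching$control_mean,
                        na.rm = TRUE),
       boot_ci = if (!is.null(boot_diff))
         unname(quantile(boot_diff, c(0.025, 0.975))) else c(NA, NA),
       ratio_ge10 = ratio_ge10,
       distances = distances)
}
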