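# Clone-tree enumeration, scoring and copy-number event calling.
#
# Trees are represented as integer parent vectors over cluster indices,
# with 0 marking the parent of the truncal root (conceptually the germline
# node GL sitting above the tumour clone tree).

#' Enumerate clone trees consistent with the sum rule
#'
#' Generates every rooted labelled tree over the CCF clusters, rooted at
#' the single clonal (truncal) cluster, in which for every node and every
#' region the mean CCFs of its children sum to at most the parent's mean
#' CCF plus `tol` (pigeonhole/sum-rule constraint).
#'
#' @param means Cluster-by-region matrix of mean CCFs.
#' @param tol Sum-rule tolerance (default 0.05).
#' @param clonal_threshold Threshold used to identify the truncal cluster
#'   (see [classify_clonality()]).
#' @param k_max Maximum cluster count for exhaustive enumeration.
#' @param truncal Optional row index forcing the truncal root (bypasses
#'   clonal-cluster detection).
#' @return List of parent vectors (each of length `k`, root entry 0).
#' @export
enumerate_feasible_trees <- function(means, tol = 0.05,
                                     clonal_threshold = 0.9, k_max = 9,
                                     truncal = NULL) {
  stopifnot(is.matrix(means))
  k <- nrow(means)
  clonal <- truncal %||%
    which(classify_clonality(means, clonal_threshold) == "clonal")
  if (length(clonal) != 1) {
    stop("no truncal cluster: expected exactly one clonal cluster, found ",
         length(clonal), call. = FALSE)
  }
  if (k > k_max) {
    stop("k = ", k, " exceeds k_max = ", k_max,
         "; exhaustive enumeration disabled (reduce clusters or raise k_max)",
         call. = FALSE)
  }
  root <- clonal
  if (k == 1) return(list(structure(0L, names = rownames(means))))
  others <- setdiff(seq_len(k), root)
  # per-edge necessary condition: child CCF <= parent CCF + tol everywhere
  edge_ok <- matrix(FALSE, k, k)  # [parent, child]
  for (p in seq_len(k)) {
    for (c2 in others) {
      if (c2 != p) edge_ok[p, c2] <- all(means[c2, ] <= means[p, ] + tol)
    }
  }
  results <- list()
  parent <- integer(k)
  parent[root] <- 0L
  recurse <- function(i) {
    if (i > length(others)) {
      if (tree_is_valid(parent, root) &&
          sum_rule_ok(parent, means, tol)) {
        results[[length(results) + 1L]] <<- parent
      }
      return(invisible())
    }
    v <- others[i]
    for (p in seq_len(k)) {
      if (p == v || !edge_ok[p, v]) next
      parent[v] <<- p
      recurse(i + 1L)
    }
    parent[v] <<- 0L
  }
  recurse(1L)
  results
}

# All non-root nodes reach the root (no cycles among subclones).
tree_is_valid <- function(parent, root) {
  k <- length(parent)
  for (v in seq_len(k)) {
    if (v == root) next
    seen <- 0L
    u <- v
    while (u != root) {
      u <- parent[u]
      seen <- seen + 1L
      if (u == 0L || seen > k) return(FALSE)
    }
  }
  TRUE
}

# Sum rule: children CCFs sum to <= parent CCF + tol in every region.
sum_rule_ok <- function(parent, means, tol) {
  for (v in seq_along(parent)) {
    kids <- which(parent == v)
    if (!length(kids)) next
    child_sum <- colSums(means[kids, , drop = FALSE])
    if (any(child_sum > means[v, ] + tol)) return(FALSE)
  }
  TRUE
}

# Least-squares projection of one region's cluster CCFs onto the tree's
# sum-rule polytope {x >= 0, x_root <= 1, sum(children) <= parent}, by
# Dykstra's alternating-projection algorithm over the halfspaces.
project_region <- function(x, parent, iters = 400, eps = 1e-12) {
  k <- length(x)
  root <- which(parent == 0L)
  # halfspaces as rows a' x <= b
  A <- list(); b <- c()
  for (v in seq_len(k)) {
    kids <- which(parent == v)
    if (length(kids)) {
      a <- rep(0, k); a[kids] <- 1; a[v] <- -1
      A[[length(A) + 1L]] <- a; b <- c(b, 0)
    }
  }
  a <- rep(0, k); a[root] <- 1
  A[[length(A) + 1L]] <- a; b <- c(b, 1)
  for (v in seq_len(k)) {
    a <- rep(0, k); a[v] <- -1
    A[[length(A) + 1L]] <- a; b <- c(b, 0)
  }
  m <- length(A)
  Amat <- do.call(rbind, A)
  nrm2 <- rowSums(Amat^2)
  y <- x
  corr <- matrix(0, m, k)
  for (it in seq_len(iters)) {
    y_prev <- y
    for (j in seq_len(m)) {
      z <- y + corr[j, ]
      viol <- sum(Amat[j, ] * z) - b[j]
      if (viol > 0) {
        proj <- z - viol / nrm2[j] * Amat[j, ]
      } else {
        proj <- z
      }
      corr[j, ] <- z - proj
      y <- proj
    }
    if (sum((y - y_prev)^2) < eps) break
  }
  y
}

#' Score candidate clone trees and select the minimum-BIC tree
#'
#' For each candidate tree the observed cluster means are projected (least
#' squares, per region) onto the tree's sum-rule polytope; the residual sum
#' of squares feeds `BIC = n * ln(RSS / n) + q * ln(n)` with
#' `n = clusters x regions` and `q` the number of edges. The tree with
#' minimal BIC wins; ties break to fewer edges, then to the
#' lexicographically smallest parent vector.
#'
#' @param trees List of parent vectors (from [enumerate_feasible_trees()]).
#' @param means Observed cluster-by-region mean CCF matrix.
#' @return List of `clone_tree` objects sorted by rank (best first); each
#'   has `parent`, `fitted`, `rss`, `bic`.
#' @export
score_trees <- function(trees, means) {
  if (!length(trees)) stop("empty tree list", call. = FALSE)
  n <- nrow(means) * ncol(means)
  scored <- lapply(trees, function(parent) {
    fitted <- means
    for (r in seq_len(ncol(means))) {
      fitted[, r] <- project_region(means[, r], parent)
    }
    rss <- sum((fitted - means)^2)
    q <- sum(parent != 0L)
    bic <- if (rss <= 0) -Inf else n * log(rss / n) + q * log(n)
    structure(list(parent = parent, fitted = fitted, rss = rss,
                   bic = bic, n_edges = q),
              class = "clone_tree")
  })
  key <- vapply(scored, function(t)
    paste(sprintf("%03d", t$parent), collapse = ","), "")
  ord <- order(vapply(scored, `[[`, 0, "bic"),
               vapply(scored, `[[`, 0L, "n_edges"), key)
  scored[ord]
}

#' @rdname score_trees
#' @export
score_and_select <- function(trees, means) {
  score_trees(trees, means)[[1]]
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clone tree:", tree_newick(x$parent), "\n")
  cat(sprintf("RSS %.4g, BIC %.4g\n", x$rss, x$bic))
  invisible(x)
}

#' Classify clone-tree topology as linear or branched
#'
#' A tree is branched when some subclonal (non-truncal) node has two or
#' more children; trees whose only branch point is the truncal most recent
#' common ancestor are linear, reflecting monophyletic subclones all
#' arising from the common node. With `strict = TRUE` only pure chains are
#' linear.
#'
#' @param parent Parent vector (or a `clone_tree`).
#' @param strict Treat any branching (including at the truncal node) as
#'   branched.
#' @return `"linear"` or `"branched"`.
#' @export
classify_topology <- function(parent, strict = FALSE) {
  if (inherits(parent, "clone_tree")) parent <- parent$parent
  root <- which(parent == 0L)
  n_children <- tabulate(parent[parent != 0L], nbins = length(parent))
  branch_nodes <- which(n_children >= 2)
  if (strict) {
    if (length(branch_nodes)) "branched" else "linear"
  } else {
    if (any(branch_nodes != root)) "branched" else "linear"
  }
}

#' Newick export of a clone tree
#'
#' @param parent Parent vector.
#' @param labels Optional node labels (default `C1..Ck`).
#' @return A Newick string rooted at GL.
#' @export
tree_newick <- function(parent, labels = NULL) {
  if (inherits(parent, "clone_tree")) parent <- parent$parent
  k <- length(parent)
  if (is.null(labels)) labels <- paste0("C", seq_len(k))
  ch <- tree_children(parent)
  fmt <- function(v) {
    kids <- ch[[v]]
    if (!length(kids)) return(labels[v])
    paste0("(", paste(vapply(kids, fmt, ""), collapse = ","), ")",
           labels[v])
  }
  root <- which(parent == 0L)
  paste0("(", fmt(root), ")GL;")
}

#' Call somatic copy-number event classes from segment tables
#'
#' Classifies allele-specific segments (per region) into the event classes
#' used for trajectory analysis: interval loss, arm-level loss (>= 50% of
#' the arm lost by default), whole-chromosome loss (>= 60% of the
#' chromosome), copy-neutral LOH (major >= 2, minor = 0, total = 2),
#' homozygous deletion (total = 0), gain/amplification (total above
#' ploidy / at least twice ploidy), and mirrored subclonal allelic
#' imbalance (the same interval lost on opposite parental alleles in
#' different regions; requires phased columns `cn_a`/`cn_b`). An event is
#' clonal when observed in every region.
#'
#' @param segments Segment table with columns `chrom`, `start`, `end`,
#'   `major`, `minor`, `region_id` and optionally `cn_a`, `cn_b`.
#' @param arms Arm coordinate table (default [arm_table()]).
#' @param genome Genome table (default [synthetic_genome()]).
#' @param ploidy Baseline ploidy (default 2).
#' @param arm_loss_frac Fraction of arm length lost to call an arm loss.
#' @param chr_loss_frac Fraction of chromosome length lost to call a
#'   whole-chromosome loss.
#' @return Data frame of events: `class`, `location`, `chrom`, `start`,
#'   `end`, `regions`, `clonality`.
#' @export
call_scna_events <- function(segments, arms = arm_table(),
                             genome = synthetic_genome(), ploidy = 2,
                             arm_loss_frac = 0.5, chr_loss_frac = 0.6) {
  regions <- unique(segments$region_id)
  # overlap sanity check within each region
  for (r in regions) {
    seg_r <- segments[segments$region_id == r, , drop = FALSE]
    for (cc in unique(seg_r$chrom)) {
      s <- seg_r[seg_r$chrom == cc, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
        stop("overlapping segments in region ", r, " on ", cc,
             call. = FALSE)
      }
    }
  }
  events <- list()
  add <- function(class, location, chrom, start, end, regs) {
    events[[length(events) + 1L]] <<- data.frame(
      class = class, location = location, chrom = chrom,
      start = start, end = end,
      regions = paste(sort(regs), collapse = ","),
      clonality = if (setequal(regs, regions)) "clonal" else "subclonal",
      stringsAsFactors = FALSE)
  }
  total <- segments$major + segments$minor

  # interval-keyed classes: group identical intervals across regions
  seg_key <- paste(segments$chrom, segments$start, segments$end)
  for (key in unique(seg_key)) {
    idx <- which(seg_key == key)
    s1 <- segments[idx[1], ]
    tot <- total[idx]
    loss_r <- segments$region_id[idx][tot < ploidy & tot > 0]
    homdel_r <- segments$region_id[idx][tot == 0]
    cnloh_r <- segments$region_id[idx][segments$major[idx] >= 2 &
                                         segments$minor[idx] == 0 &
                                         tot == ploidy]
    gain_r <- segments$region_id[idx][tot > ploidy & tot < 2 * ploidy]
    amp_r <- segments$region_id[idx][tot >= 2 * ploidy]
    loc <- sprintf("%s:%.0f-%.0f", s1$chrom, s1$start, s1$end)
    if (length(loss_r)) add("loss", loc, s1$chrom, s1$start, s1$end, loss_r)
    if (length(homdel_r)) {
      add("homozygous_deletion", loc, s1$chrom, s1$start, s1$end, homdel_r)
    }
    if (length(cnloh_r)) add("cnloh", loc, s1$chrom, s1$start, s1$end,
                             cnloh_r)
    if (length(gain_r)) add("gain", loc, s1$chrom, s1$start, s1$end, gain_r)
    if (length(amp_r)) add("amplification", loc, s1$chrom, s1$start, s1$end,
                           amp_r)
    # MSAI: same interval, minor = 0 in >= 2 regions, opposite allele lost
    if (all(c("cn_a", "cn_b") %in% names(segments))) {
      min0 <- idx[segments$minor[idx] == 0 & tot > 0]
      if (length(min0) >= 2) {
        a_lost <- segments$region_id[min0][segments$cn_a[min0] == 0]
        b_lost <- segments$region_id[min0][segments$cn_b[min0] == 0]
        if (length(a_lost) && length(b_lost)) {
          add("msai", loc, s1$chrom, s1$start, s1$end,
              union(a_lost, b_lost))
        }
      }
    }
  }

  # arm-level and whole-chromosome losses per region, then merged
  arm_loss <- list(); chr_loss <- list()
  for (r in regions) {
    seg_r <- segments[segments$region_id == r, , drop = FALSE]
    tot_r <- seg_r$major + seg_r$minor
    lost <- seg_r[tot_r < ploidy, , drop = FALSE]
    if (!nrow(lost)) next
    for (ai in seq_len(nrow(arms))) {
      a <- arms[ai, ]
      ov <- pmax(0, pmin(lost$end, a$end) - pmax(lost$start, a$start))
      ov <- sum(ov[lost$chrom == a$chrom &
                     pmin(lost$end, a$end) > pmax(lost$start, a$start)])
      if (ov >= arm_loss_frac * (a$end - a$start)) {
        id <- paste0(sub("chr", "", a$chrom), a$arm)
        arm_loss[[id]] <- c(arm_loss[[id]], r)
      }
    }
    for (gi in seq_len(nrow(genome))) {
      g <- genome[gi, ]
      sel <- lost$chrom == g$chrom
      ov <- sum(pmin(lost$end[sel], g$length) - pmax(lost$start[sel], 0))
      if (length(ov) && ov >= chr_loss_frac * g$length) {
        chr_loss[[g$chrom]] <- c(chr_loss[[g$chrom]], r)
      }
    }
  }
  for (id in names(arm_loss)) {
    a <- arms[paste0(sub("chr", "", arms$chrom), arms$arm) == id, ]
    add("arm_loss", paste0("-", id), a$chrom, a$start, a$end,
        unique(arm_loss[[id]]))
  }
  for (id in names(chr_loss)) {
    g <- genome[genome$chrom == id, ]
    add("chr_loss", paste0("-", id), id, 0, g$length,
        unique(chr_loss[[id]]))
  }

  if (!length(events)) {
    return(data.frame(class = character(), location = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), regions = character(),
                      clonality = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Detect bi-allelic inactivation ("double hits") of driver genes
#'
#' A gene is doubly hit when a deleterious mutation coincides with loss of
#' the other allele (overlapping `minor = 0` segment), when two distinct
#' deleterious mutations are present, or when the gene is homozygously
#' deleted. The event is clonal only when every component event is clonal.
#'
#' @param driver_muts Data frame of driver mutations: `gene`, `mutation`,
#'   `deleterious` (logical), `clonality` (`"clonal"`/`"subclonal"`).
#' @param segments Segment table across regions.
#' @param genes Gene coordinate table (default [driver_genes()]).
#' @return Data frame: `gene`, `double_hit`, `mechanism`, `timing`.
#' @export
detect_double_hits <- function(driver_muts, segments,
                               genes = driver_genes()) {
  regions <- unique(segments$region_id)
  out <- lapply(seq_len(nrow(genes)), function(gi) {
    g <- genes[gi, ]
    muts <- driver_muts[driver_muts$gene == g$gene &
                          driver_muts$deleterious, , drop = FALSE]
    ov <- segments$chrom == g$chrom & segments$start < g$end &
      segments$end > g$start
    seg_g <- segments[ov, , drop = FALSE]
    loh_regions <- unique(seg_g$region_id[seg_g$minor == 0 &
                                            seg_g$major > 0])
    homdel_regions <- unique(seg_g$region_id[seg_g$major + seg_g$minor == 0])
    n_mut <- length(unique(muts$mutation))
    mech <- NULL
    if (length(homdel_regions)) mech <- "homozygous_deletion"
    else if (n_mut >= 1 && length(loh_regions)) mech <- "mutation_plus_loss"
    else if (n_mut >= 2) mech <- "two_mutations"
    if (is.null(mech)) {
      return(data.frame(gene = g$gene, double_hit = FALSE,
                        mechanism = NA_character_, timing = NA_character_,
                        stringsAsFactors = FALSE))
    }
    cn_clonal <- switch(mech,
      homozygous_deletion = setequal(homdel_regions, regions),
      mutation_plus_loss = setequal(loh_regions, regions),
      two_mutations = TRUE)
    mut_clonal <- if (mech == "homozygous_deletion") TRUE else
      all(muts$clonality == "clonal")
    data.frame(gene = g$gene, double_hit = TRUE, mechanism = mech,
               timing = if (cn_clonal && mut_clonal) "clonal" else
                 "subclonal",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
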