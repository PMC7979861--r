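# Shared fixture builders and independent oracles.

# A single SNV evidence row with pass-by-default values.
make_snv <- function(chrom = "chr1", pos = 1000, ref = "C", alt = "T",
                     region_id = "R1", called_by = "both",
                     somatic_p = 0.05, tumour_depth = 100, tumour_alt = 10,
                     normal_depth = 100, normal_alt = 0,
                     mapping_quality = 60, blacklist_flag = FALSE,
                     pop_freq_db1 = 0, pop_freq_db2 = 0) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             region_id = region_id, called_by = called_by,
             somatic_p = somatic_p, tumour_depth = tumour_depth,
             tumour_alt = tumour_alt, normal_depth = normal_depth,
             normal_alt = normal_alt, mapping_quality = mapping_quality,
             blacklist_flag = blacklist_flag, pop_freq_db1 = pop_freq_db1,
             pop_freq_db2 = pop_freq_db2, stringsAsFactors = FALSE)
}

# Independent brute-force enumeration of sum-rule-feasible rooted trees:
# every parent vector over the non-root clusters, filtered for
# reachability and the sum rule. Deliberately naive.
bf_trees <- function(means, tol, root) {
  k <- nrow(means)
  if (k == 1) return(list(structure(0L)))
  others <- setdiff(seq_len(k), root)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)),
                                             length(others))))
  res <- list()
  for (gi in seq_len(nrow(grid))) {
    parent <- integer(k)
    parent[others] <- grid[gi, ]
    if (any(parent[others] == others)) next
    ok <- TRUE
    for (v in others) {
      u <- v
      steps <- 0
      while (u != root) {
        u <- parent[u]
        steps <- steps + 1
        if (steps > k) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (!ok) next
    for (v in seq_len(k)) {
      kids <- which(parent == v)
      if (length(kids)) {
        cs <- colSums(means[kids, , drop = FALSE])
        if (any(cs > means[v, ] + tol)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) res[[length(res) + 1L]] <- parent
  }
  res
}

tree_key <- function(parent) paste(parent, collapse = ",")

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Planted-cluster CCF data generated through the binomial read model and
# the package's own CCF transform.
planted_ccf_data <- function(ccf_true, z, purity, depth, seed) {
  set.seed(seed)
  n <- length(z)
  R <- ncol(ccf_true)
  vaf <- matrix(purity * ccf_true[z, ] / (purity * 2 + 2 * (1 - purity)),
                n, R)
  dep <- matrix(stats::rpois(n * R, depth), n, R)
  alt <- matrix(stats::rbinom(n * R, dep, vaf), n, R)
  ccf_hat <- matrix(pmin(1, (alt / pmax(dep, 1)) * (1 / purity) *
                           (purity * 2 + 2 * (1 - purity))), n, R)
  eff <- matrix(effective_depth(dep, purity, 2, 1, ccf_hat), n, R)
  list(ccf = ccf_hat, depth = eff, z = z)
}

# Noisy cluster-mean CCFs for a planted tree: each cluster mean is the
# average of `n_mut` per-mutation CCF estimates at the given depth/purity.
noisy_cluster_means <- function(ccf_true, n_mut, purity, depth) {
  k <- nrow(ccf_true)
  R <- ncol(ccf_true)
  out <- matrix(0, k, R, dimnames = dimnames(ccf_true))
  for (i in seq_len(k)) {
    for (r in seq_len(R)) {
      v <- purity * ccf_true[i, r] / (purity * 2 + 2 * (1 - purity))
      dep <- stats::rpois(n_mut, depth)
      alt <- stats::rbinom(n_mut, dep, v)
      out[i, r] <- mean((alt / pmax(dep, 1)) * (1 / purity) *
                          (purity * 2 + 2 * (1 - purity)))
    }
  }
  pmin(out, 1)
}

# Archetype-structured candidate sets for trajectory tests: per patient,
# candidates derived from the package's own tree enumeration on noisy
# means, with orderings extracted from the archetype's driver placement.
archetype_cohort_candidates <- function(n_per_arch = 5, seed = 1,
                                        noise_n_mut = 40, depth = 250,
                                        purity = 0.6) {
  set.seed(seed)
  archs <- default_archetypes()
  cands <- list()
  labels <- character(0)
  pid <- 0
  for (rep in seq_len(n_per_arch)) {
    for (a in archs) {
      pid <- pid + 1
      id <- sprintf("P%02d", pid)
      has_late <- length(a$late) > 0
      ccf_true <- if (has_late) {
        rbind(c(1, 1), c(0.6, 0.55))
      } else {
        matrix(c(1, 1), 1, 2)
      }
      means <- noisy_cluster_means(ccf_true, noise_n_mut, purity, depth)
      trees <- enumerate_feasible_trees(means, tol = 0.05, truncal = 1)
      scored <- score_trees(trees, means)
      best_bic <- scored[[1]]$bic
      scored <- Filter(function(t) t$bic <= best_bic + 2, scored)
      dm <- data.frame(
        event = c(a$truncal, a$late),
        cluster = c(rep(1L, length(a$truncal)),
                    rep(2L, length(a$late))),
        stringsAsFactors = FALSE)
      cands[[id]] <- lapply(scored, function(t) {
        list(orderings = extract_orderings(t$parent, dm), bic = t$bic)
      })
      labels <- c(labels, a$name)
    }
  }
  list(candidates = cands, archetype = stats::setNames(labels,
                                                       names(cands)))
}
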