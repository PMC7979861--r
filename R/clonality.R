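# Cancer-cell-fraction estimation and Dirichlet-process clustering.

#' Mutation copy number from VAF, purity and local copy number
#'
#' `n_mut = VAF * (1/p) * (p * CN_t + CN_n * (1 - p))`: the expected number
#' of mutant-allele copies per tumour cell, which decomposes as the product
#' of multiplicity and cancer cell fraction.
#'
#' @param vaf Variant allele frequency in `[0, 1]`.
#' @param purity Tumour purity `p` in `(0, 1]`.
#' @param cn_t Local tumour total copy number (>= 0).
#' @param cn_n Normal copy number (default 2, autosomes).
#' @return Numeric `n_mut` (vectorised).
#' @export
mutation_copy_number <- function(vaf, purity, cn_t, cn_n = 2) {
  if (any(purity <= 0) || any(purity > 1)) {
    stop("`purity` must lie in (0, 1]", call. = FALSE)
  }
  assert_fraction(vaf, "vaf")
  if (any(cn_t < 0)) stop("`cn_t` must be >= 0", call. = FALSE)
  vaf * (1 / purity) * (purity * cn_t + cn_n * (1 - purity))
}

#' Maximum-likelihood multiplicity assignment
#'
#' Assigns each mutation to an integer multiplicity `m` in `1..major` by
#' maximising the binomial likelihood of the observed alt count under the
#' expected VAF for a clonal mutation carried on `m` copies
#' (`VAF_m = p * m / (p * CN_t + 2 * (1 - p))`, capped at 1). Ties go to
#' the smaller `m`.
#'
#' @param alt,depth Observed alt and total read counts (vectorised).
#' @param purity Tumour purity.
#' @param cn_t Local total copy number.
#' @param major Major-allele copy number (upper bound on `m`).
#' @return Integer multiplicities.
#' @export
assign_multiplicity <- function(alt, depth, purity, cn_t, major) {
  stopifnot(all(major >= 1))
  n <- max(length(alt), length(depth), length(cn_t), length(major))
  alt <- rep_len(alt, n); depth <- rep_len(depth, n)
  purity <- rep_len(purity, n); cn_t <- rep_len(cn_t, n)
  major <- rep_len(as.integer(major), n)
  out <- integer(n)
  for (i in seq_len(n)) {
    ms <- seq_len(major[i])
    vafs <- pmin(1, purity[i] * ms / (purity[i] * cn_t[i] +
                                        2 * (1 - purity[i])))
    ll <- stats::dbinom(alt[i], depth[i], vafs, log = TRUE)
    out[i] <- ms[which.max(ll)]  # which.max takes the first (smallest) tie
  }
  out
}

#' Cancer cell fraction from mutation copy number and multiplicity
#'
#' `CCF = n_mut / m`, clipped into `[0, 1]`. Values in `(1, 1 + tol]` are
#' treated as sampling noise around a clonal mutation and clipped with a
#' warning; values above `1 + tol` are flagged inconsistent (attribute
#' `inconsistent`) and still clipped.
#'
#' @param n_mut Mutation copy number.
#' @param m Multiplicity (>= 1).
#' @param tol Clipping tolerance above 1.
#' @return CCF values in `[0, 1]` with logical attribute `inconsistent`.
#' @export
ccf_from_nmut <- function(n_mut, m, tol = 0.1) {
  stopifnot(all(m >= 1))
  raw <- n_mut / m
  inconsistent <- raw > 1 + tol
  if (any(raw > 1 & !inconsistent)) {
    warning("CCF values in (1, 1 + tol] clipped to 1")
  }
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "inconsistent") <- inconsistent
  out
}

#' Per-mutation, per-region CCF table
#'
#' Joins a variant table to allele-specific copy-number segments and
#' per-region purity, then computes mutation copy number, maximum-likelihood
#' multiplicity, CCF and a 95% interval obtained by propagating a
#' Jeffreys beta posterior on the VAF through the copy-number relation.
#'
#' @param variants Long variant table (one row per mutation x region) with
#'   columns `mutation`, `region_id`, `chrom`, `pos`, `tumour_depth`,
#'   `tumour_alt`.
#' @param segments Segment table (`chrom`, `start`, `end`, `major`, `minor`,
#'   `region_id`, 0-based half-open).
#' @param purity Named per-region purity vector.
#' @return Data frame with columns `mutation`, `region_id`, `vaf`, `purity`,
#'   `cn_t`, `major`, `multiplicity`, `n_mut`, `ccf`, `ccf_lo`, `ccf_hi`.
#' @export
compute_ccf_table <- function(variants, segments, purity) {
  rows <- lapply(split(variants, variants$region_id), function(v) {
    r <- v$region_id[1]
    p <- purity[[r]]
    seg_r <- segments[segments$region_id == r, , drop = FALSE]
    cn <- segment_cn_at(seg_r, v$chrom, v$pos)
    cn_t <- cn$major + cn$minor
    # deleted sites carry no observable mutation: skip CCF there
    usable <- cn_t > 0 & cn$major > 0
    vaf <- ifelse(v$tumour_depth > 0, v$tumour_alt / v$tumour_depth, 0)
    n_mut <- ifelse(usable, mutation_copy_number(vaf, p, cn_t), NA_real_)
    m <- rep(NA_integer_, nrow(v))
    m[usable] <- assign_multiplicity(v$tumour_alt[usable],
                                     v$tumour_depth[usable], p,
                                     cn_t[usable], cn$major[usable])
    ccf <- ccf_raw <- rep(NA_real_, nrow(v))
    ccf_raw[usable] <- n_mut[usable] / m[usable]
    ccf[usable] <- suppressWarnings(
      as.numeric(ccf_from_nmut(n_mut[usable], m[usable])))
    # Jeffreys interval on VAF propagated through the same transform
    lo <- stats::qbeta(0.025, v$tumour_alt + 0.5,
                       v$tumour_depth - v$tumour_alt + 0.5)
    hi <- stats::qbeta(0.975, v$tumour_alt + 0.5,
                       v$tumour_depth - v$tumour_alt + 0.5)
    ccf_lo <- ccf_hi <- rep(NA_real_, nrow(v))
    ccf_lo[usable] <- pmin(1, pmax(0,
      mutation_copy_number(lo[usable], p, cn_t[usable]) / m[usable]))
    ccf_hi[usable] <- pmin(1, pmax(0,
      mutation_copy_number(hi[usable], p, cn_t[usable]) / m[usable]))
    data.frame(mutation = v$mutation, region_id = r, vaf = vaf,
               purity = p, cn_t = cn_t, major = cn$major,
               multiplicity = m, n_mut = n_mut, ccf = ccf,
               ccf_raw = ccf_raw, ccf_lo = ccf_lo, ccf_hi = ccf_hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Information-matched pseudo-depth for CCF clustering
#'
#' The clustering likelihood treats a CCF as a binomial proportion under
#' the reference transform `VAF* = CCF / 2`. A CCF estimated from `depth`
#' reads at purity `p` and copy number `cn_t` is noisier than a raw
#' proportion at that depth, because the VAF-to-CCF rescaling factor
#' `c = (1/p)(p CN_t + CN_n (1-p)) / m` inflates the sampling variance by
#' `c^2`. This helper returns the pseudo-depth at which the reference
#' binomial has the same variance as the actual CCF estimate, so cluster
#' assignments neither over- nor under-split.
#'
#' @param depth Observed read depth.
#' @param purity Tumour purity.
#' @param cn_t Local total copy number.
#' @param m Multiplicity.
#' @param ccf Estimated CCF.
#' @param cn_n Normal copy number.
#' @return Integer effective depths (0 where `depth` is 0).
#' @export
effective_depth <- function(depth, purity, cn_t, m = 1, ccf, cn_n = 2) {
  cfac <- (1 / purity) * (purity * cn_t + cn_n * (1 - purity)) / m
  d <- pmax(depth, 1)
  v <- pmin(pmax(ccf / cfac, 1 / d), 1 - 1 / d)
  q <- pmin(cfac * v / 2, 0.999)
  out <- pmax(1, round(4 * q * (1 - q) * d / (cfac^2 * v * (1 - v))))
  out[depth == 0] <- 0L
  as.integer(out)
}

#' Cluster a long CCF table across regions
#'
#' Convenience wrapper: reshapes the output of [compute_ccf_table()] into
#' mutation-by-region matrices, computes information-matched pseudo-depths
#' with [effective_depth()] and runs [cluster_ccfs()]. Mutations missing
#' from a region enter with CCF 0 and pseudo-depth 0.
#'
#' @param ccf_table Long table from [compute_ccf_table()] with an
#'   additional `depth` column (observed tumour depth).
#' @param ... Passed to [cluster_ccfs()].
#' @return A `ccf_clusters` object.
#' @export
cluster_ccf_table <- function(ccf_table, ...) {
  stopifnot(all(c("mutation", "region_id", "ccf", "depth", "purity",
                  "cn_t", "multiplicity") %in% names(ccf_table)))
  ok <- !is.na(ccf_table$ccf)
  eff <- integer(nrow(ccf_table))
  eff[ok] <- effective_depth(ccf_table$depth[ok], ccf_table$purity[ok],
                             ccf_table$cn_t[ok],
                             ccf_table$multiplicity[ok],
                             ccf_table$ccf[ok])
  mats <- ccf_long_to_matrices(ccf_table, eff)
  cl <- cluster_ccfs(mats$ccf, mats$depth, ...)
  # cluster means from unclipped per-site CCFs, so clipping at 1 does not
  # bias the clonal cluster downwards; means themselves are then clipped
  if ("ccf_raw" %in% names(ccf_table)) {
    raw <- mats$ccf
    idx <- cbind(match(ccf_table$mutation, rownames(raw)),
                 match(ccf_table$region_id, colnames(raw)))
    raw[idx] <- ifelse(is.na(ccf_table$ccf_raw), 0, ccf_table$ccf_raw)
    means_raw <- rowsum(raw, cl$assignment) /
      as.vector(table(cl$assignment))
    cl$means <- pmin(pmax(means_raw, 0), 1)
    rownames(cl$means) <- seq_len(nrow(cl$means))
  }
  cl
}

# Long CCF table -> mutation x region matrices of CCF and depth.
ccf_long_to_matrices <- function(ccf_table, depth_table = NULL) {
  muts <- unique(ccf_table$mutation)
  regs <- unique(ccf_table$region_id)
  ccf <- matrix(0, length(muts), length(regs),
                dimnames = list(muts, regs))
  dep <- matrix(0L, length(muts), length(regs),
                dimnames = list(muts, regs))
  idx <- cbind(match(ccf_table$mutation, muts),
               match(ccf_table$region_id, regs))
  ccf[idx] <- ifelse(is.na(ccf_table$ccf), 0, ccf_table$ccf)
  if (!is.null(depth_table)) {
    dep[idx] <- depth_table
  }
  list(ccf = ccf, depth = dep)
}

#' Dirichlet-process clustering of mutations by multi-region CCF
#'
#' Clusters mutations whose CCF profiles agree across regions, using a
#' Chinese-restaurant-process mixture of independent per-region binomials
#' over pseudo-counts: each (mutation, region) contributes
#' `alt* = round(depth * CCF / 2)` successes out of `depth` trials, the
#' transform that maps a CCF back to the VAF of a heterozygous mutation in
#' a diploid genome at purity 0.5. Component parameters are collapsed under
#' a Beta(1, 1) prior and the partition is sampled by Gibbs sweeps; the
#' returned partition is the maximum-posterior state visited after burn-in.
#'
#' @param ccf_mat Mutation-by-region CCF matrix (force-called absences as 0).
#' @param depth_mat Matching matrix of observed depths.
#' @param iters Total Gibbs sweeps (default 10000).
#' @param burnin Burn-in sweeps discarded before tracking the posterior
#'   mode (default 1000).
#' @param alpha DP concentration parameter (default 1).
#' @param seed Optional integer seed; fixed seed gives an identical
#'   partition.
#' @return An object of class `ccf_clusters`: list with `assignment`
#'   (integer cluster per mutation), `means` (cluster-by-region mean CCF),
#'   `sizes`, `log_posterior`, and the call parameters.
#' @export
cluster_ccfs <- function(ccf_mat, depth_mat, iters = 10000, burnin = 1000,
                         alpha = 1, seed = NULL) {
  stopifnot(is.matrix(ccf_mat), all(dim(ccf_mat) == dim(depth_mat)),
            iters > burnin, alpha > 0)
  n <- nrow(ccf_mat)
  if (n < 2) {
    means <- matrix(ccf_mat, nrow = 1,
                    dimnames = list("1", colnames(ccf_mat)))
    return(structure(list(assignment = rep(1L, n), means = means,
                          sizes = n, log_posterior = 0,
                          alpha = alpha, iters = 0L, burnin = 0L),
                     class = "ccf_clusters"))
  }
  a_mat <- round(depth_mat * ccf_mat / 2)
  b_mat <- depth_mat - a_mat
  out <- with_seed(seed, dp_gibbs(a_mat, b_mat, iters, burnin, alpha))
  means <- rowsum(ccf_mat, out$assignment) /
    as.vector(table(out$assignment))
  rownames(means) <- seq_len(nrow(means))
  structure(list(assignment = out$assignment, means = means,
                 sizes = as.integer(table(out$assignment)),
                 log_posterior = out$log_posterior, alpha = alpha,
                 iters = iters, burnin = burnin),
            class = "ccf_clusters")
}

# Collapsed Gibbs sampler for a CRP mixture of per-region Beta(1,1)
# binomials. a/b are success/failure pseudo-count matrices.
dp_gibbs <- function(a, b, iters, burnin, alpha) {
  n <- nrow(a); R <- ncol(a)
  z <- rep(1L, n)
  # sufficient statistics per cluster: sums of a and b per region
  A <- matrix(colSums(a), nrow = 1)
  B <- matrix(colSums(b), nrow = 1)
  sizes <- n
  best_lp <- -Inf
  best_z <- z
  lbeta11 <- lbeta(1, 1)
  for (it in seq_len(iters)) {
    for (i in seq_len(n)) {
      ci <- z[i]
      A[ci, ] <- A[ci, ] - a[i, ]
      B[ci, ] <- B[ci, ] - b[i, ]
      sizes[ci] <- sizes[ci] - 1L
      if (sizes[ci] == 0L) {
        A <- A[-ci, , drop = FALSE]
        B <- B[-ci, , drop = FALSE]
        sizes <- sizes[-ci]
        z[z > ci] <- z[z > ci] - 1L
      }
      K <- length(sizes)
      # beta-binomial predictive per existing cluster (choose term constant)
      ai <- matrix(a[i, ], K, R, byrow = TRUE)
      bi <- matrix(b[i, ], K, R, byrow = TRUE)
      lp_exist <- rowSums(lbeta(1 + A + ai, 1 + B + bi) -
                            lbeta(1 + A, 1 + B)) + log(sizes)
      lp_new <- sum(lbeta(1 + a[i, ], 1 + b[i, ]) - lbeta11) + log(alpha)
      lp <- c(lp_exist, lp_new)
      pr <- exp(lp - max(lp))
      ki <- sample.int(K + 1L, 1L, prob = pr)
      if (ki > K) {
        A <- rbind(A, a[i, ])
        B <- rbind(B, b[i, ])
        sizes <- c(sizes, 1L)
      } else {
        A[ki, ] <- A[ki, ] + a[i, ]
        B[ki, ] <- B[ki, ] + b[i, ]
        sizes[ki] <- sizes[ki] + 1L
      }
      z[i] <- ki
    }
    if (it > burnin) {
      lp_now <- length(sizes) * log(alpha) + sum(lgamma(sizes)) +
        sum(lbeta(1 + A, 1 + B) - lbeta11)
      if (lp_now > best_lp) {
        best_lp <- lp_now
        best_z <- z
      }
    }
  }
  # canonical labels: order of first appearance
  lab <- match(best_z, unique(best_z))
  list(assignment = as.integer(lab), log_posterior = best_lp)
}

#' @export
print.ccf_clusters <- function(x, ...) {
  cat(sprintf("CCF clustering: %d clusters over %d mutations x %d regions\n",
              nrow(x$means), length(x$assignment), ncol(x$means)))
  print(round(x$means, 3))
  invisible(x)
}

#' Classify a cluster as clonal or subclonal
#'
#' A cluster is clonal when its mean CCF reaches `threshold` in every
#' region (hence present in all regions); otherwise subclonal.
#'
#' @param means Numeric vector of per-region mean CCFs (or a matrix,
#'   classified row-wise).
#' @param threshold Clonality threshold (default 0.9).
#' @return `"clonal"` or `"subclonal"` (vector for matrix input).
#' @export
classify_clonality <- function(means, threshold = 0.9) {
  if (is.matrix(means)) {
    return(apply(means, 1, classify_clonality, threshold = threshold))
  }
  if (all(means >= threshold)) "clonal" else "subclonal"
}
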