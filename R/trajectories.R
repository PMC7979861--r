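# Cohort-level repeated evolutionary trajectories: driver orderings,
# transfer-learning tree re-selection, evolutionary distances, cohort
# clustering and jackknife stability.

pair_id <- function(from, to) paste(from, to, sep = "->")

#' Extract driver-event orderings from a clone tree
#'
#' Turns a clone tree plus a driver-to-cluster map into a set of ordered
#' event pairs: `GL -> x` for every driver on the truncal (root) cluster,
#' and `x -> y` whenever `x` sits on a strict ancestor of `y`'s cluster.
#' Drivers co-resident on one cluster are left unordered.
#'
#' @param parent Parent vector of the clone tree (root entry 0).
#' @param driver_map Data frame with columns `event` and `cluster`.
#' @return Character vector of ordered pairs (`"x->y"`).
#' @export
extract_orderings <- function(parent, driver_map) {
  if (inherits(parent, "clone_tree")) parent <- parent$parent
  k <- length(parent)
  if (any(driver_map$cluster < 1 | driver_map$cluster > k)) {
    stop("driver mapped to unknown tree node", call. = FALSE)
  }
  root <- which(parent == 0L)
  pairs <- character(0)
  for (i in seq_len(nrow(driver_map))) {
    if (driver_map$cluster[i] == root) {
      pairs <- c(pairs, pair_id("GL", driver_map$event[i]))
    }
  }
  if (nrow(driver_map) >= 2) {
    for (i in seq_len(nrow(driver_map))) {
      for (j in seq_len(nrow(driver_map))) {
        if (i == j) next
        if (is_ancestor(parent, driver_map$cluster[i],
                        driver_map$cluster[j])) {
          pairs <- c(pairs, pair_id(driver_map$event[i],
                                    driver_map$event[j]))
        }
      }
    }
  }
  sort(unique(pairs))
}

# Transition counts over patients: each pair counted once per patient.
count_transitions <- function(ordering_sets) {
  tab <- table(unlist(lapply(ordering_sets, unique)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Jointly re-select clone trees across a cohort by transfer learning
#'
#' Starting from each patient's minimum-BIC candidate, iteratively (1)
#' counts how many patients support each ordered driver transition and (2)
#' lets each patient re-select, among its near-optimal candidates, the tree
#' whose orderings are best supported by the rest of the cohort (ties break
#' to lower BIC, then candidate order). Patients are visited in id order;
#' iteration stops at a fixed point or after `max_iter` passes.
#'
#' @param candidates Named list (one entry per patient) of candidate lists;
#'   each candidate is a list with elements `orderings` (character pair
#'   vector from [extract_orderings()]) and `bic`.
#' @param max_iter Maximum passes (default 10).
#' @return List with `selection` (chosen candidate index per patient),
#'   `orderings` (selected pair sets), `w` (named transition counts over
#'   the final selections) and `iterations`.
#' @export
transfer_fit <- function(candidates, max_iter = 10) {
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  if (any(lengths(candidates) == 0)) {
    stop("every patient needs at least one candidate tree", call. = FALSE)
  }
  ids <- names(candidates) %||% as.character(seq_along(candidates))
  ord <- order(ids)
  sel <- vapply(candidates, function(cl)
    which.min(vapply(cl, `[[`, 0, "bic")), 0L)
  get_orderings <- function() {
    lapply(seq_along(candidates), function(i)
      candidates[[i]][[sel[i]]]$orderings)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    changed <- FALSE
    for (i in ord) {
      others <- get_orderings()[-i]
      w <- count_transitions(others)
      cl <- candidates[[i]]
      support <- vapply(cl, function(cand) {
        sum(w[cand$orderings], na.rm = TRUE)
      }, 0)
      bics <- vapply(cl, `[[`, 0, "bic")
      best <- order(-support, bics, seq_along(cl))[1]
      if (best != sel[i]) {
        sel[i] <- best
        changed <- TRUE
      }
    }
    if (!changed || it >= max_iter) break
  }
  orderings <- stats::setNames(get_orderings(), ids)
  list(selection = stats::setNames(sel, ids), orderings = orderings,
       w = count_transitions(orderings), iterations = it)
}

#' Repeated evolutionary transitions
#'
#' Transitions supported by more than three patients (i.e. at least four)
#' are considered repeated.
#'
#' @param w Named transition counts (from [transfer_fit()] or
#'   [count_transitions()]).
#' @param min_patients Minimum supporting patients (default 4).
#' @return Character vector of repeated transition pairs.
#' @export
repeated_transitions <- function(w, min_patients = 4) {
  names(w)[w >= min_patients]
}

#' Evolutionary distance between two trajectory ordering sets
#'
#' Jaccard distance `1 - |intersection| / |union|` over ordered driver
#' pairs; two empty trajectories are at distance 0.
#'
#' @param ti,tj Character pair vectors.
#' @return Distance in `[0, 1]`.
#' @export
evolutionary_distance <- function(ti, tj) {
  u <- union(ti, tj)
  if (!length(u)) return(0)
  1 - length(intersect(ti, tj)) / length(u)
}

#' Pairwise evolutionary distance matrix for a cohort
#'
#' @param ordering_sets Named list of pair vectors.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
trajectory_distances <- function(ordering_sets) {
  n <- length(ordering_sets)
  D <- matrix(0, n, n, dimnames = list(names(ordering_sets),
                                       names(ordering_sets)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- evolutionary_distance(ordering_sets[[i]],
                                                  ordering_sets[[j]])
    }
  }
  D
}

#' Cluster a cohort by evolutionary distance
#'
#' Average-linkage hierarchical clustering of the evolutionary distance
#' matrix, cut at `k` clusters. When a per-patient complexity measure
#' (event count) is supplied, cluster labels are renumbered so that cluster
#' 1 has the lowest mean complexity and cluster `k` the highest.
#'
#' @param D Symmetric distance matrix.
#' @param k Number of clusters (default 5).
#' @param complexity Optional numeric vector (per patient) used to order
#'   labels by increasing mean intra-cluster complexity.
#' @return Integer cluster labels named by patient.
#' @export
cluster_cohort <- function(D, k = 5, complexity = NULL) {
  n <- nrow(D)
  if (k > n) stop("k exceeds the number of patients", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- stats::cutree(hc, k = k)
  if (!is.null(complexity)) {
    mean_cx <- tapply(complexity, labels, mean)
    remap <- stats::setNames(rank(mean_cx, ties.method = "first"),
                             names(mean_cx))
    labels <- stats::setNames(as.integer(remap[as.character(labels)]),
                              names(labels))
  }
  labels
}

#' Jackknife stability of evolutionary clusters
#'
#' Repeatedly drops a fraction of patients, re-runs the transfer fit and
#' cohort clustering on the remainder, and tallies how often each pair of
#' patients lands in the same cluster among runs where both were retained.
#' Cluster stability is the median pairwise co-clustering frequency within
#' each original cluster.
#'
#' @param candidates Candidate sets as for [transfer_fit()].
#' @param k Number of clusters.
#' @param leave_fraction Fraction of patients dropped per replicate
#'   (default 0.1).
#' @param reps Number of replicates (default 100).
#' @param seed Optional integer seed.
#' @return List with `labels` (full-cohort clustering), `coclustering`
#'   (pairwise frequency matrix) and `stability` (per-cluster medians).
#' @export
jackknife_stability <- function(candidates, k, leave_fraction = 0.1,
                                reps = 100, seed = NULL) {
  stopifnot(leave_fraction > 0, leave_fraction <= 0.5, reps >= 1)
  n <- length(candidates)
  ids <- names(candidates) %||% as.character(seq_len(n))
  full <- transfer_fit(candidates)
  labels <- cluster_cohort(trajectory_distances(full$orderings), k,
                           complexity = lengths(full$orderings))
  n_drop <- ceiling(leave_fraction * n)
  co <- matrix(0, n, n, dimnames = list(ids, ids))
  both <- matrix(0, n, n, dimnames = list(ids, ids))
  with_seed(seed, {
    for (rep in seq_len(reps)) {
      keep <- sort(sample.int(n, n - n_drop))
      if (length(keep) < k) next
      fit <- transfer_fit(candidates[keep])
      lab <- cluster_cohort(trajectory_distances(fit$orderings), k,
                            complexity = lengths(fit$orderings))
      same <- outer(lab, lab, "==") * 1
      both[keep, keep] <- both[keep, keep] + 1
      co[keep, keep] <- co[keep, keep] + same
    }
  })
  freq <- ifelse(both > 0, co / both, NA)
  stability <- vapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    if (length(members) < 2) return(1)
    pairs <- freq[members, members][upper.tri(diag(length(members)))]
    stats::median(pairs, na.rm = TRUE)
  }, 0)
  list(labels = labels, coclustering = freq,
       stability = stats::setNames(stability, sort(unique(labels))))
}

#' Train a decision-tree classifier binning patients into clusters
#'
#' Fits a CART tree (depth at most 4) on binary driver-event profiles with
#' known evolutionary-cluster labels, so that external cohorts with driver
#' profiles only can be binned into the discovered clusters.
#'
#' @param profiles Data frame or matrix of 0/1 driver-event indicators
#'   (patients x events).
#' @param labels Cluster labels (coerced to factor).
#' @param maxdepth Maximum tree depth (default 4).
#' @return An `rpart` fit.
#' @export
train_cluster_classifier <- function(profiles, labels, maxdepth = 4) {
  df <- as.data.frame(profiles)
  names(df) <- make.names(names(df))
  df$.cluster <- factor(labels)
  rpart::rpart(.cluster ~ ., data = df, method = "class",
               control = rpart::rpart.control(maxdepth = maxdepth,
                                              minsplit = 2, cp = 0,
                                              xval = 0))
}

#' Assign driver profiles to evolutionary clusters with a trained tree
#'
#' Features unseen at training time are ignored; features missing from the
#' profile are treated as absent (0).
#'
#' @param fit Tree from [train_cluster_classifier()].
#' @param profiles Data frame/matrix of 0/1 driver-event indicators.
#' @return Predicted cluster labels.
#' @export
assign_by_decision_tree <- function(fit, profiles) {
  df <- as.data.frame(profiles)
  names(df) <- make.names(names(df))
  needed <- setdiff(attr(fit$terms, "term.labels"), names(df))
  for (v in needed) df[[v]] <- 0
  as.character(stats::predict(fit, newdata = df, type = "class"))
}
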