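# End-to-end orchestration: simulate (or accept) a cohort, then run
# filtering -> CCF -> clustering -> trees -> SCNA events -> trajectories ->
# dN/dS & signatures -> neoantigen / HLA-LOH -> cohort statistics.

driver_vocabulary <- function() {
  c(driver_genes()$gene, "-3p21", "-22q", "-chr4", "9p21-loss")
}

# Map called copy-number events to driver-vocabulary SCNA ids.
scna_driver_events <- function(events) {
  if (!nrow(events)) {
    return(data.frame(event = character(), regions = character(),
                      clonality = character(), stringsAsFactors = FALSE))
  }
  out <- list()
  add <- function(id, rows) {
    regs <- unique(unlist(strsplit(events$regions[rows], ",")))
    out[[id]] <<- data.frame(
      event = id, regions = paste(sort(regs), collapse = ","),
      clonality = if (all(events$clonality[rows] == "clonal")) "clonal"
                  else "subclonal",
      stringsAsFactors = FALSE)
  }
  r <- which(events$class == "chr_loss" & events$chrom == "chr4")
  if (length(r)) add("-chr4", r)
  r <- which(events$class %in% c("loss", "arm_loss") &
               events$chrom == "chr22" & events$end > 20e6)
  if (length(r)) add("-22q", r)
  r <- which(events$class %in% c("loss", "arm_loss") &
               events$chrom == "chr3" & events$start < 60e6)
  if (length(r)) add("-3p21", r)
  r <- which(events$class == "homozygous_deletion" &
               events$chrom == "chr9" & events$start < 23e6 &
               events$end > 21e6)
  if (length(r)) add("9p21-loss", r)
  if (!length(out)) {
    return(data.frame(event = character(), regions = character(),
                      clonality = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Assign an SCNA (observed in `present_regions`) to the CCF cluster whose
# regional presence pattern agrees best; ties prefer the higher-CCF
# (earlier) cluster.
map_scna_to_cluster <- function(present_regions, means,
                                presence_ccf = 0.1) {
  pres <- colnames(means) %in% present_regions
  cluster_pres <- means > presence_ccf
  agree <- apply(cluster_pres, 1, function(x) sum(x == pres))
  mean_ccf <- rowMeans(means)
  order(-agree, -mean_ccf)[1]
}

analyse_patient <- function(p, cluster_iters, cluster_burnin, tree_tol,
                            delta_bic, min_cluster_size, seed) {
  decisions <- filter_variants(p$variants)
  keep_keys <- paste(decisions$key, decisions$region_id)[
    decisions$status %in% c("pass", "force_called")]
  vkeys <- paste(variant_key(p$variants$chrom, p$variants$pos,
                             p$variants$ref, p$variants$alt),
                 p$variants$region_id)
  kept <- p$variants[vkeys %in% keep_keys, , drop = FALSE]
  # only mutations observed in every region enter CCF clustering (absences
  # get CCF 0 through force-calling of read counts)
  ccf_tab <- compute_ccf_table(kept, p$segments, p$purity)
  ccf_tab$depth <- kept$tumour_depth[match(
    paste(ccf_tab$mutation, ccf_tab$region_id),
    paste(kept$mutation, kept$region_id))]
  mats <- ccf_long_to_matrices(ccf_tab)
  clusters <- cluster_ccf_table(ccf_tab, iters = cluster_iters,
                                burnin = cluster_burnin, seed = seed)
  keep_cl <- which(clusters$sizes >= min_cluster_size)
  means <- clusters$means[keep_cl, , drop = FALSE]
  rownames(means) <- as.character(keep_cl)
  tree <- NULL
  candidates <- list()
  topology <- NA_character_
  scored <- tryCatch({
    clonal <- which(classify_clonality(means) == "clonal")
    # fall back to the highest minimum-CCF cluster when noise pushes the
    # truncal cluster below the clonality threshold in some region
    truncal <- if (length(clonal) == 1) clonal else
      unname(which.max(apply(means, 1, min)))
    trees <- enumerate_feasible_trees(means, tol = tree_tol,
                                      truncal = truncal)
    score_trees(trees, means)
  }, error = function(e) NULL)
  if (!is.null(scored)) {
    tree <- scored[[1]]
    topology <- classify_topology(tree)
    best_bic <- tree$bic
    candidates <- Filter(function(t) t$bic <= best_bic + delta_bic, scored)
  }
  events <- call_scna_events(p$segments)

  # driver -> tree-node map
  clonality_by_cluster <- classify_clonality(clusters$means)
  mut_clonality <- stats::setNames(
    clonality_by_cluster[clusters$assignment], rownames(mats$ccf))
  driver_map <- NULL
  if (!is.null(tree)) {
    gene_rows <- kept[!duplicated(kept$mutation) &
                        kept$gene %in% driver_genes()$gene, , drop = FALSE]
    dm <- list()
    for (i in seq_len(nrow(gene_rows))) {
      cl <- clusters$assignment[match(gene_rows$mutation[i],
                                      rownames(mats$ccf))]
      node <- match(as.character(cl), rownames(means))
      if (!is.na(node)) {
        dm[[length(dm) + 1L]] <- data.frame(
          event = gene_rows$gene[i], cluster = node,
          stringsAsFactors = FALSE)
      }
    }
    sd_ev <- scna_driver_events(events)
    for (i in seq_len(nrow(sd_ev))) {
      node <- map_scna_to_cluster(strsplit(sd_ev$regions[i], ",")[[1]],
                                  means)
      dm[[length(dm) + 1L]] <- data.frame(
        event = sd_ev$event[i], cluster = node, stringsAsFactors = FALSE)
    }
    driver_map <- if (length(dm)) unique(do.call(rbind, dm)) else
      data.frame(event = character(), cluster = integer(),
                 stringsAsFactors = FALSE)
  }
  cand_list <- lapply(candidates, function(t) {
    list(orderings = if (is.null(driver_map) || !nrow(driver_map))
      character(0) else extract_orderings(t$parent, driver_map),
      bic = t$bic)
  })
  list(id = p$id, decisions = decisions, ccf = ccf_tab,
       clusters = clusters, means = means, tree = tree,
       topology = topology, candidates = cand_list,
       driver_map = driver_map, events = events,
       mut_clonality = mut_clonality)
}

#' Run the full multi-region evolution pipeline on a synthetic cohort
#'
#' Simulates a cohort under `config`, then runs every analysis stage:
#' variant filtering with force-calling, CCF estimation, Dirichlet-process
#' clustering, clone-tree enumeration and BIC selection, topology
#' classification, copy-number event calling, cohort trajectory inference
#' by transfer learning with hierarchical clustering, per-sample signature
#' fitting, cohort clonal/subclonal dN/dS on the coding panel, neoantigen
#' filtering and burden, HLA-LOH calling, and the survival/association
#' statistics. Optionally writes all stage outputs (TSV/VCF/JSON) plus a
#' run manifest with per-file checksums.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param cluster_iters,cluster_burnin Gibbs sweeps for CCF clustering.
#' @param k_trajectory Number of evolutionary clusters (default 5).
#' @param tree_tol Sum-rule tolerance.
#' @param delta_bic BIC window for near-optimal candidate trees.
#' @param min_cluster_size Minimum mutations per cluster entering tree
#'   inference.
#' @return List with `cohort`, `patients` (per-patient stage outputs),
#'   `trajectory`, `signatures`, `dnds`, `neoantigens`, `burden`, `hla`,
#'   `stats` and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         cluster_iters = 2000, cluster_burnin = 200,
                         k_trajectory = 5, tree_tol = 0.05, delta_bic = 2,
                         min_cluster_size = 5) {
  cohort <- simulate_cohort(config)
  res <- lapply(cohort$patients, function(p) {
    analyse_patient(p, cluster_iters, cluster_burnin, tree_tol, delta_bic,
                    min_cluster_size,
                    seed = derive_seed(config$seed, paste0("cluster-",
                                                           p$id)))
  })

  # trajectories over patients with candidate trees
  with_cand <- Filter(function(r) length(r$candidates) > 0, res)
  trajectory <- NULL
  if (length(with_cand) >= 2) {
    cands <- lapply(with_cand, `[[`, "candidates")
    fit <- transfer_fit(cands)
    D <- trajectory_distances(fit$orderings)
    k_use <- min(k_trajectory, length(with_cand))
    labels <- cluster_cohort(D, k_use, complexity = lengths(fit$orderings))
    trajectory <- list(fit = fit, distances = D, labels = labels,
                       repeated = repeated_transitions(fit$w))
  }

  # per-patient signature fits on pooled unique mutations
  sig_basis <- toy_signatures()
  signatures <- lapply(cohort$patients, function(p) {
    v <- p$variants[!duplicated(p$variants$mutation), ]
    fit_signatures(count_contexts(v$ref, v$alt, v$context), sig_basis)
  })

  # cohort clonal/subclonal dN/dS on the coding panel
  panel <- cohort$cds_panel
  L <- rowSums(vapply(panel$cds, expected_site_counts,
                      c(L_non = 0, L_syn = 0)))
  scope_counts <- function(scope) {
    n_non <- 0L; n_syn <- 0L
    for (r in res) {
      p <- cohort$patients[[r$id]]
      v <- p$variants[!duplicated(p$variants$mutation), ]
      lab <- r$mut_clonality[v$mutation]
      sel <- !is.na(v$coding_class) & v$gene %in% names(panel$cds) &
        !is.na(lab) & (scope == "all" | lab == scope)
      n_non <- n_non + sum(v$coding_class[sel] == "nonsynonymous")
      n_syn <- n_syn + sum(v$coding_class[sel] == "synonymous")
    }
    c(n_non = n_non, n_syn = n_syn)
  }
  dnds <- lapply(c(clonal = "clonal", subclonal = "subclonal",
                   all = "all"), function(s) {
    cn <- scope_counts(s)
    if (sum(cn) == 0) return(NULL)
    dnds_test(cn[["n_non"]], cn[["n_syn"]], L[["L_non"]], L[["L_syn"]])
  })

  # immune analyses
  clonality_all <- do.call(c, unname(lapply(res, `[[`, "mut_clonality")))
  neo <- filter_neoantigens(cohort$neoantigens)
  neo_lab <- neo[neo$mutation %in% names(clonality_all), , drop = FALSE]
  burden <- neoantigen_burden(neo_lab, clonality_all)
  hla <- call_hla_loh_cohort(cohort$hla)

  # cohort statistics
  cl <- cohort$clinical
  indices <- clinical_indices(cl$neutrophils, cl$lymphocytes, cl$platelets)
  stats_out <- list(indices = cbind(cl["patient"], indices))
  if (!is.null(trajectory)) {
    top <- max(trajectory$labels)
    grp <- ifelse(trajectory$labels == top, "complex", "other")
    sel <- match(names(trajectory$labels), cl$patient)
    if (length(unique(grp)) == 2 && sum(cl$event[sel]) >= 1) {
      stats_out$survival_by_cluster <- tryCatch(
        km_logrank(cl$time[sel], cl$event[sel], factor(grp,
          levels = c("other", "complex"))), error = function(e) NULL)
    }
  }
  loh_pat <- names(hla$by_patient)[hla$by_patient]
  if (nrow(burden)) {
    subcl <- stats::setNames(burden$subclonal, burden$patient)
    g1 <- subcl[names(subcl) %in% loh_pat]
    g2 <- subcl[!names(subcl) %in% loh_pat]
    if (length(g1) && length(g2)) {
      stats_out$subclonal_burden_by_hla_loh <- mann_whitney(g1, g2)
    }
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- write_pipeline_outputs(cohort, res, trajectory, burden,
                                       hla, stats_out, out_dir)
  }
  list(cohort = cohort, patients = res, trajectory = trajectory,
       signatures = signatures, dnds = dnds, neoantigens = neo,
       burden = burden, hla = hla, stats = stats_out, manifest = manifest)
}

write_pipeline_outputs <- function(cohort, res, trajectory, burden, hla,
                                   stats_out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, path)
  }
  for (p in cohort$patients) {
    vp <- file.path(out_dir, paste0(p$id, ".vcf"))
    write_variants_vcf(p$variants, vp)
    paths <- c(paths, vp)
    write_segments(p$segments, file.path(out_dir,
                                         paste0(p$id, "_segments.tsv")))
    paths <- c(paths, file.path(out_dir, paste0(p$id, "_segments.tsv")))
  }
  wt(do.call(rbind, lapply(res, function(r)
    cbind(patient = r$id, r$decisions))), "decisions.tsv")
  wt(do.call(rbind, lapply(res, function(r)
    cbind(patient = r$id, r$ccf))), "ccf.tsv")
  for (r in res) {
    if (!is.null(r$tree)) {
      tp <- file.path(out_dir, paste0(r$id, "_tree.json"))
      write_tree_json(r$tree, tp)
      paths <- c(paths, tp)
    }
  }
  wt(do.call(rbind, lapply(res, function(r)
    if (nrow(r$events)) cbind(patient = r$id, r$events) else NULL)),
    "scna_events.tsv")
  if (!is.null(trajectory)) {
    wt(data.frame(patient = names(trajectory$labels),
                  cluster = trajectory$labels), "trajectory_clusters.tsv")
    wt(data.frame(transition = names(trajectory$fit$w),
                  n_patients = as.integer(trajectory$fit$w)),
       "transitions.tsv")
  }
  wt(burden, "neoantigen_burden.tsv")
  wt(hla$by_gene, "hla_loh.tsv")
  wt(cohort$clinical, "clinical.tsv")
  manifest <- list(
    seed = cohort$config$seed,
    n_patients = length(cohort$patients),
    files = as.list(tools::md5sum(sort(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
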