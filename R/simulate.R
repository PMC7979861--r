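# Synthetic multi-region cohort simulator.
#
# Every downstream stage (filtering, CCF estimation, clustering, tree
# inference, trajectories, immune analyses, survival) can be exercised on
# cohorts generated here, with the planted clone trees, cluster CCFs,
# multiplicities, driver placements and survival hazards returned as ground
# truth.

#' Default evolutionary archetypes for the simulator
#'
#' Five archetypes of increasing complexity, qualitatively mirroring the
#' recurrent mesothelioma trajectories: BAP1/3p21 disruption as an early
#' clonal event, chromosome 4 loss (spanning FBXW7) as an alternative early
#' route, and NF2/22q loss or CDKN2A (9p21) deletion as late subclonal
#' events. The most complex archetype carries an elevated exponential
#' survival hazard.
#'
#' Each archetype is a list with elements `name`, `truncal` (driver events
#' placed on the truncal cluster), `late` (driver events placed on a
#' subclonal cluster) and `hazard` (exponential rate per day).
#'
#' @return A list of archetype definitions.
#' @export
default_archetypes <- function() {
  base <- log(2) / 500  # median overall survival ~500 days
  list(
    list(name = "A1", truncal = "SETD2", late = character(0), hazard = base),
    list(name = "A2", truncal = c("-chr4", "FBXW7"), late = character(0),
         hazard = base),
    list(name = "A3", truncal = c("-chr4", "NF2"), late = "-22q",
         hazard = base),
    list(name = "A4", truncal = c("BAP1", "-3p21"), late = "SETD2",
         hazard = base),
    list(name = "A5", truncal = c("BAP1", "-3p21"),
         late = c("NF2", "-22q", "CDKN2A"), hazard = 4.43 * base)
  )
}

#' Read archetype definitions from YAML
#'
#' The bundled archetype table lives at
#' `system.file("extdata", "driver_archetypes.yaml", package = "mesoevolve")`
#' and matches [default_archetypes()]; edit a copy to simulate different
#' evolutionary structures.
#'
#' @param path YAML file: a list of entries with `name`, `truncal`,
#'   `late`, `hazard`.
#' @return A list of archetype definitions as for [default_archetypes()].
#' @export
read_archetypes <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(a) {
    list(name = a$name, truncal = as.character(a$truncal %||% character(0)),
         late = as.character(a$late %||% character(0)),
         hazard = as.numeric(a$hazard))
  })
}

#' Simulation configuration
#'
#' Bundles all simulator parameters. Defaults reproduce the bundled study
#' conditions: 22 patients with 4-5 anatomically distinct regions each,
#' mean depth 250x, per-region purity uniform on 0.3-0.9, 86-204 somatic
#' mutations per patient, and the five driver archetypes of
#' [default_archetypes()].
#'
#' @param n_patients Number of patients.
#' @param n_regions Candidate numbers of regions per patient (sampled
#'   uniformly).
#' @param n_clusters_range Integer `(min, max)` clone clusters per patient.
#' @param depth Mean sequencing depth (reads); per-site depths are Poisson.
#' @param purity_range `(min, max)` tumour purity; drawn per region.
#' @param n_mutations_range `(min, max)` somatic mutations per patient.
#' @param driver_archetypes List of archetypes (see [default_archetypes()]);
#'   patients are assigned archetypes in round-robin order.
#' @param error_rate Sequencing error rate driving alt reads in the matched
#'   normal sample.
#' @param coding_fraction Fraction of passenger mutations placed on the
#'   synthetic CDS panel (and so annotated synonymous/non-synonymous).
#' @param hla_loh_prob Probability that a patient carries HLA LOH.
#' @param msai_patients Number of patients planted with a mirrored
#'   subclonal allelic-imbalance interval on chromosome 1p.
#' @param absence_prob Probability that a subclonal cluster is absent from a
#'   given region (spatial heterogeneity model; see the methods vignette).
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 22, n_regions = 4:5,
                       n_clusters_range = c(2, 5), depth = 250,
                       purity_range = c(0.3, 0.9),
                       n_mutations_range = c(86, 204),
                       driver_archetypes = default_archetypes(),
                       error_rate = 0.001, coding_fraction = 0.25,
                       hla_loh_prob = 0.3, msai_patients = 2,
                       absence_prob = 0.25, seed = 1L) {
  stopifnot(n_patients >= 1, all(n_regions >= 1), depth > 0,
            length(n_clusters_range) == 2,
            n_clusters_range[1] >= 1,
            n_clusters_range[2] >= n_clusters_range[1],
            length(purity_range) == 2,
            purity_range[1] > 0, purity_range[2] <= 1,
            length(n_mutations_range) == 2,
            n_mutations_range[1] >= 1, error_rate >= 0, error_rate < 1)
  assert_fraction(hla_loh_prob, "hla_loh_prob")
  assert_fraction(coding_fraction, "coding_fraction")
  assert_fraction(absence_prob, "absence_prob")
  structure(list(
    n_patients = as.integer(n_patients), n_regions = as.integer(n_regions),
    n_clusters_range = as.integer(n_clusters_range), depth = depth,
    purity_range = purity_range,
    n_mutations_range = as.integer(n_mutations_range),
    driver_archetypes = driver_archetypes, error_rate = error_rate,
    coding_fraction = coding_fraction, hla_loh_prob = hla_loh_prob,
    msai_patients = as.integer(msai_patients),
    absence_prob = absence_prob, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a rooted labelled clone tree
#'
#' Draws uniformly over the `k^(k-2)` rooted labelled trees on `k` clusters
#' with cluster 1 fixed as the truncal root, via a uniform random Pruefer
#' sequence.
#'
#' @param k Number of clone clusters (>= 1).
#' @param seed Optional integer seed.
#' @return An integer parent vector of length `k`; entry `i` is the parent
#'   of cluster `i`, with `0` marking the truncal root (cluster 1).
#' @export
simulate_clone_tree <- function(k, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  with_seed(seed, {
    if (k == 1L) return(0L)
    if (k == 2L) return(c(0L, 1L))
    code <- sample.int(k, k - 2L, replace = TRUE)
    edges <- prufer_decode(code, k)
    orient_tree(edges, root = 1L, k = k)
  })
}

# Decode a Pruefer sequence into an undirected edge list (2-column matrix).
prufer_decode <- function(code, k) {
  deg <- tabulate(code, nbins = k) + 1L
  edges <- matrix(0L, nrow = k - 1L, ncol = 2L)
  for (i in seq_along(code)) {
    leaf <- which.max(deg == 1L)  # smallest remaining leaf
    edges[i, ] <- c(leaf, code[i])
    deg[leaf] <- 0L
    deg[code[i]] <- deg[code[i]] - 1L
  }
  edges[k - 1L, ] <- which(deg == 1L)
  edges
}

# Orient an undirected tree away from `root`, returning a parent vector.
orient_tree <- function(edges, root, k) {
  adj <- vector("list", k)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, k)
  parent[root] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(parent[w])) {
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  parent
}

# Children lists from a parent vector.
tree_children <- function(parent) {
  k <- length(parent)
  lapply(seq_len(k), function(v) which(parent == v))
}

# Nodes in breadth-first order from the root.
tree_bfs <- function(parent) {
  root <- which(parent == 0L)
  ch <- tree_children(parent)
  order <- root
  i <- 1L
  while (i <= length(order)) {
    order <- c(order, ch[[order[i]]])
    i <- i + 1L
  }
  order
}

# TRUE iff node `a` is a strict ancestor of node `b`.
is_ancestor <- function(parent, a, b) {
  v <- parent[b]
  while (v != 0L) {
    if (v == a) return(TRUE)
    v <- parent[v]
  }
  FALSE
}

#' Assign per-region cluster CCFs down a clone tree
#'
#' Draws a cluster-by-region cancer-cell-fraction matrix obeying the sum
#' rule by construction: the truncal root has CCF 1 in every region, and
#' the CCFs of a node's children are produced by stick-breaking of the
#' parent's CCF, so children never sum above their parent. Subclonal
#' clusters are absent (CCF 0) from individual regions with probability
#' `absence_prob`, modelling spatial heterogeneity; when `k >= 3` at least
#' one absence is guaranteed.
#'
#' @param parent Parent vector from [simulate_clone_tree()].
#' @param n_regions Number of regions.
#' @param seed Optional integer seed.
#' @param absence_prob Per-(cluster, region) absence probability.
#' @return A `k x n_regions` matrix of CCFs in `[0, 1]`.
#' @export
assign_region_ccfs <- function(parent, n_regions, seed = NULL,
                               absence_prob = 0.25) {
  k <- length(parent)
  stopifnot(k >= 1, n_regions >= 1)
  with_seed(seed, {
    ccf <- matrix(0, nrow = k, ncol = n_regions,
                  dimnames = list(paste0("C", seq_len(k)),
                                  paste0("R", seq_len(n_regions))))
    root <- which(parent == 0L)
    ccf[root, ] <- 1
    ch <- tree_children(parent)
    for (v in tree_bfs(parent)) {
      kids <- ch[[v]]
      if (!length(kids)) next
      for (r in seq_len(n_regions)) {
        remaining <- 1
        for (w in kids) {
          stick <- stats::rbeta(1, 2, 2)
          frac <- stick * remaining
          remaining <- remaining - frac
          val <- ccf[v, r] * frac
          if (stats::runif(1) < absence_prob) val <- 0
          ccf[w, r] <- val
        }
      }
    }
    # guarantee spatial heterogeneity for k >= 3
    if (k >= 3 && !any(ccf == 0)) {
      leaf <- max(which(lengths(ch) == 0))
      ccf[leaf, 1] <- 0
    }
    ccf
  })
}

#' Expected variant allele frequency under the CCF model
#'
#' `VAF = p * m * CCF / (p * CN_t + CN_n * (1 - p))`, the inverse of the
#' mutation-copy-number relation used for CCF estimation.
#'
#' @param purity Tumour purity `p` in `(0, 1]`.
#' @param m Integer multiplicity (mutant-allele copies per tumour cell).
#' @param ccf Cancer cell fraction.
#' @param cn_t Local tumour total copy number.
#' @param cn_n Normal copy number (2 for autosomes).
#' @return Expected VAF.
#' @export
expected_vaf <- function(purity, m, ccf, cn_t, cn_n = 2) {
  v <- purity * m * ccf / (purity * cn_t + cn_n * (1 - purity))
  if (any(v > 1 + 1e-9, na.rm = TRUE)) {
    stop("invalid configuration: expected VAF exceeds 1", call. = FALSE)
  }
  pmin(v, 1)
}

#' Simulate read counts for a set of mutations across regions
#'
#' For each mutation and region, looks up the local allele-specific copy
#' number, computes the expected VAF from purity, multiplicity and the
#' cluster CCF, then draws `depth_site ~ Poisson(depth)` and
#' `alt ~ Binomial(depth_site, VAF)`. Matched-normal alt counts are
#' sequencing errors, `Binomial(depth, error_rate)`.
#'
#' @param ccf_matrix Cluster-by-region CCF matrix.
#' @param assignments Data frame with one row per mutation: columns
#'   `mutation`, `cluster`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `context`, `multiplicity`, optionally `gene`.
#' @param purity Named per-region purity vector (or scalar recycled).
#' @param segments Segment table (`chrom`, `start`, `end`, `major`, `minor`,
#'   `region_id`; 0-based half-open).
#' @param depth Mean depth.
#' @param seed Optional seed.
#' @param error_rate Normal-sample error rate.
#' @return A long data.frame, one row per mutation x region, with read
#'   counts, copy number and caller-evidence columns.
#' @export
simulate_reads <- function(ccf_matrix, assignments, purity, segments, depth,
                           seed = NULL, error_rate = 0.001) {
  regions <- colnames(ccf_matrix)
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(ccf_matrix)))
  if (length(purity) == 1) purity <- stats::setNames(rep(purity,
    length(regions)), regions)
  with_seed(seed, {
    # one matched normal per patient: normal counts drawn once per site
    ndep <- stats::rpois(nrow(assignments), depth)
    nalt <- stats::rbinom(nrow(assignments), ndep, error_rate)
    rows <- vector("list", length(regions))
    for (ri in seq_along(regions)) {
      r <- regions[ri]
      p <- purity[[r]]
      seg_r <- segments[segments$region_id == r, , drop = FALSE]
      cn <- segment_cn_at(seg_r, assignments$chrom, assignments$pos)
      m <- pmin(assignments$multiplicity, pmax(cn$major, 1L))
      ccf <- ccf_matrix[assignments$cluster, ri]
      total <- cn$major + cn$minor
      evaf <- ifelse(total > 0 & cn$major > 0,
                     expected_vaf(p, m, ccf, total), 0)
      dep <- stats::rpois(nrow(assignments), depth)
      alt <- stats::rbinom(nrow(assignments), dep, evaf)
      rows[[ri]] <- data.frame(
        mutation = assignments$mutation, region_id = r,
        chrom = assignments$chrom, pos = assignments$pos,
        ref = assignments$ref, alt = assignments$alt,
        context = assignments$context,
        gene = if ("gene" %in% names(assignments)) assignments$gene
               else NA_character_,
        coding_class = if ("coding_class" %in% names(assignments))
          assignments$coding_class else NA_character_,
        cluster_true = assignments$cluster,
        multiplicity_true = m, ccf_true = ccf,
        cn_major = cn$major, cn_minor = cn$minor,
        tumour_depth = dep, tumour_alt = alt,
        normal_depth = ndep, normal_alt = nalt,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    # caller evidence consistent with a clean dual-caller run
    out$called_by <- "both"
    out$somatic_p <- stats::runif(nrow(out), 0, 0.1)
    out$mapping_quality <- 60
    out$blacklist_flag <- FALSE
    out$pop_freq_max <- 0
    rownames(out) <- NULL
    out
  })
}

# Allele-specific copy number of the segment containing each 1-based
# position (segments 0-based half-open). Positions outside any segment get
# the diploid default.
segment_cn_at <- function(segments, chrom, pos) {
  n <- length(chrom)
  major <- rep(1L, n); minor <- rep(1L, n)
  if (nrow(segments)) {
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      seg <- segments[segments$chrom == cc, , drop = FALSE]
      if (!nrow(seg)) next
      for (i in idx) {
        hit <- which(seg$start < pos[i] & pos[i] <= seg$end)
        if (length(hit)) {
          major[i] <- seg$major[hit[1]]
          minor[i] <- seg$minor[hit[1]]
        }
      }
    }
  }
  list(major = major, minor = minor)
}

random_mutation_sites <- function(n, genome = synthetic_genome()) {
  chr_i <- sample.int(nrow(genome), n, replace = TRUE,
                      prob = genome$length)
  pos <- floor(stats::runif(n, 1, genome$length[chr_i])) + 1
  bases <- c("A", "C", "G", "T")
  ctx <- sbs_channels()
  pick <- sample.int(96, n, replace = TRUE)
  ref <- substr(ctx$sub[pick], 1, 1)
  alt <- substr(ctx$sub[pick], 3, 3)
  # emit genomic strand at random so both purine and pyrimidine refs occur
  flip <- stats::runif(n) < 0.5
  ref_g <- ifelse(flip, revcomp(ref), ref)
  alt_g <- ifelse(flip, revcomp(alt), alt)
  context <- ifelse(flip, revcomp(ctx$context[pick]), ctx$context[pick])
  data.frame(chrom = genome$chrom[chr_i], pos = pos, ref = ref_g,
             alt = alt_g, context = context, stringsAsFactors = FALSE)
}

# Archetype-driven segment table for one patient. Truncal SCNAs appear in
# all regions; late SCNAs only in regions where the carrying cluster is
# present.
archetype_segments <- function(archetype, regions, late_present,
                               genome = synthetic_genome(),
                               msai = FALSE) {
  seg_rows <- list()
  add <- function(chrom, start, end, major, minor, cn_a, cn_b, region) {
    seg_rows[[length(seg_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, major = major, minor = minor,
      cn_a = cn_a, cn_b = cn_b, region_id = region,
      stringsAsFactors = FALSE)
  }
  events <- c(archetype$truncal, archetype$late)
  for (r in regions) {
    late_ok <- late_present[[r]]
    for (ev in events) {
      truncal <- ev %in% archetype$truncal
      if (!truncal && !late_ok) next
      if (ev == "-3p21") add("chr3", 40e6, 60e6, 1L, 0L, 1L, 0L, r)
      if (ev == "-22q") add("chr22", 15e6, 51e6, 1L, 0L, 1L, 0L, r)
      if (ev == "-chr4") add("chr4", 0, 120e6, 1L, 0L, 1L, 0L, r)  # 63%
      if (ev == "CDKN2A") add("chr9", 21.8e6, 22.1e6, 0L, 0L, 0L, 0L, r)
    }
    if (msai) {
      # mirrored 1p36 loss: allele A lost in region 1, allele B elsewhere
      if (r == regions[1]) add("chr1", 10e6, 30e6, 1L, 0L, 0L, 1L, r)
      else add("chr1", 10e6, 30e6, 1L, 0L, 1L, 0L, r)
    }
  }
  if (!length(seg_rows)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), major = integer(), minor = integer(),
                      cn_a = integer(), cn_b = integer(),
                      region_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, seg_rows)
}

#' Simulate a complete multi-region cohort with ground truth
#'
#' Generates, per patient: a planted clone tree and per-region cluster CCF
#' matrix, mutations assigned to clusters and placed on a synthetic
#' autosomal genome, archetype-driven driver mutations and copy-number
#' events, read counts at the configured depth, a clinical table with
#' exponential survival under the archetype hazard, HLA allele-specific
#' coverage (imbalanced for LOH patients) and neoantigen candidates with
#' synthetic binding affinities.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `meso_cohort`: a list with elements
#'   `patients` (per-patient inputs: `variants`, `segments`, `purity`,
#'   `regions`), `clinical`, `hla`, `neoantigens` and `truth` (per-patient
#'   ground truth: tree, CCF matrix, assignments, drivers, archetype,
#'   survival, HLA LOH flag).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- synthetic_genome()
  gene_tab <- driver_genes()
  panel <- synthetic_cds_panel(30, 200)
  archetypes <- config$driver_archetypes
  n_arch <- length(archetypes)
  patients <- vector("list", config$n_patients)
  truth <- vector("list", config$n_patients)
  clinical <- list()
  hla <- list()
  neo <- list()
  censor_at <- 1825  # administrative censoring at 5 years

  for (pi in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", pi)
    arch <- archetypes[[(pi - 1L) %% n_arch + 1L]]
    nreg <- if (length(config$n_regions) == 1) config$n_regions else
      sample(config$n_regions, 1)
    regions <- paste0("R", seq_len(nreg))
    k_min <- max(config$n_clusters_range[1], 1L + (length(arch$late) > 0))
    k <- sample(seq(k_min, max(k_min, config$n_clusters_range[2])), 1)
    parent <- simulate_clone_tree(k)
    ccf <- assign_region_ccfs(parent, nreg,
                              absence_prob = config$absence_prob)
    purity <- stats::setNames(
      stats::runif(nreg, config$purity_range[1], config$purity_range[2]),
      regions)

    # driver placement: truncal events on the root; late events on the
    # root's first child (guaranteed to exist when late events are present)
    root <- which(parent == 0L)
    first_child <- which(parent == root)[1]
    drivers <- data.frame(
      event = c(arch$truncal, arch$late),
      cluster = c(rep(root, length(arch$truncal)),
                  rep(first_child, length(arch$late))),
      kind = ifelse(startsWith(c(arch$truncal, arch$late), "-") |
                      c(arch$truncal, arch$late) %in% "CDKN2A",
                    "scna", "mutation"),
      stringsAsFactors = FALSE)
    # CDKN2A modelled as 9p21 homozygous deletion (copy-number event)

    late_cluster_present <- stats::setNames(
      as.list(if (is.na(first_child)) rep(TRUE, nreg)
              else ccf[first_child, ] > 0), regions)
    segments <- archetype_segments(arch, regions, late_cluster_present,
                                   genome,
                                   msai = pi <= config$msai_patients)

    # mutations: drivers of kind "mutation" plus passengers
    n_mut <- sample(seq(config$n_mutations_range[1],
                        config$n_mutations_range[2]), 1)
    mut_drivers <- drivers[drivers$kind == "mutation", , drop = FALSE]
    n_pass <- max(n_mut - nrow(mut_drivers), k * 5L)
    sites <- random_mutation_sites(n_pass, genome)
    # keep passengers off driver loci so driver annotation is unambiguous
    pass <- data.frame(
      mutation = sprintf("%s_M%04d", pid, seq_len(n_pass)),
      cluster = sample.int(k, n_pass, replace = TRUE,
                           prob = c(2, rep(1, k - 1))[seq_len(k)]),
      sites, multiplicity = 1L, gene = NA_character_,
      coding_class = NA_character_, stringsAsFactors = FALSE)
    # every cluster needs members for downstream clustering
    short <- setdiff(seq_len(k), unique(pass$cluster))
    for (s in short) pass$cluster[sample.int(n_pass, 5)] <- s
    # plant a fraction of passengers on the coding panel (neutral)
    n_cod <- round(n_pass * config$coding_fraction)
    if (n_cod > 0) {
      cod <- simulate_neutral_coding_mutations(panel, n_cod)
      ci2 <- seq_len(n_cod)
      gidx <- match(cod$gene, panel$coords$gene)
      pass$chrom[ci2] <- panel$coords$chrom[gidx]
      pass$pos[ci2] <- panel$coords$start[gidx] + cod$cds_pos
      pass$ref[ci2] <- cod$ref
      pass$alt[ci2] <- cod$alt
      pass$context[ci2] <- cod$context
      pass$gene[ci2] <- cod$gene
      pass$coding_class[ci2] <- cod$coding_class
    }
    drv_rows <- NULL
    if (nrow(mut_drivers)) {
      g <- gene_tab[match(mut_drivers$event, gene_tab$gene), , drop = FALSE]
      drv_sites <- random_mutation_sites(nrow(mut_drivers), genome)
      drv_rows <- data.frame(
        mutation = sprintf("%s_D_%s", pid, mut_drivers$event),
        cluster = mut_drivers$cluster,
        chrom = g$chrom, pos = floor((g$start + g$end) / 2),
        ref = drv_sites$ref, alt = drv_sites$alt,
        context = drv_sites$context,
        multiplicity = 1L, gene = mut_drivers$event,
        coding_class = "nonsynonymous", stringsAsFactors = FALSE)
    }
    assignments <- rbind(drv_rows, pass)
    variants <- simulate_reads(ccf, assignments, purity, segments,
                               config$depth, error_rate = config$error_rate)
    variants$patient <- pid

    patients[[pi]] <- list(id = pid, regions = regions,
                           variants = variants, segments = segments,
                           purity = purity)

    # survival under the archetype hazard
    t_raw <- stats::rexp(1, arch$hazard)
    clinical[[pi]] <- data.frame(
      patient = pid, archetype = arch$name,
      time = min(t_raw, censor_at), event = as.integer(t_raw <= censor_at),
      neutrophils = stats::rlnorm(1, log(4), 0.3),
      lymphocytes = stats::rlnorm(1, log(1.5), 0.3),
      platelets = stats::rlnorm(1, log(300), 0.2),
      stringsAsFactors = FALSE)

    # HLA allele-specific coverage at mismatch positions
    loh <- stats::runif(1) < config$hla_loh_prob
    mean_purity <- mean(purity)
    for (gene in c("HLA-A", "HLA-B", "HLA-C")) {
      lost <- loh && gene == "HLA-A"
      a1 <- stats::rpois(20, 50)
      a2 <- stats::rpois(20, if (lost) 50 * (1 - mean_purity) else 50)
      hla[[length(hla) + 1L]] <- data.frame(
        patient = pid, gene = gene, position = seq_len(20),
        allele1_depth = a1, allele2_depth = a2,
        loh_true = lost, stringsAsFactors = FALSE)
    }

    # neoantigen candidates from a subset of mutations (region 1 counts)
    v1 <- variants[variants$region_id == regions[1], , drop = FALSE]
    n_cand <- max(1L, round(nrow(v1) * 0.12))
    ci <- sample.int(nrow(v1), n_cand)
    aff <- stats::rlnorm(n_cand, log(300), 1)
    neo[[pi]] <- data.frame(
      patient = pid, mutation = v1$mutation[ci],
      peptide_length = sample(8:11, n_cand, replace = TRUE),
      affinity_mut = aff,
      affinity_wt = aff * stats::rlnorm(n_cand, log(2), 0.7),
      tumour_depth = v1$tumour_depth[ci], tumour_alt = v1$tumour_alt[ci],
      normal_depth = v1$normal_depth[ci], normal_alt = v1$normal_alt[ci],
      stringsAsFactors = FALSE)

    truth[[pi]] <- list(
      patient = pid, tree = parent, ccf = ccf,
      assignments = assignments[, c("mutation", "cluster", "multiplicity")],
      drivers = drivers, archetype = arch$name,
      survival = clinical[[pi]][, c("time", "event")],
      hla_loh = loh)
  }

  structure(list(
    patients = stats::setNames(patients, vapply(patients, `[[`, "", "id")),
    clinical = do.call(rbind, clinical),
    hla = do.call(rbind, hla),
    neoantigens = do.call(rbind, neo),
    truth = stats::setNames(truth, vapply(truth, `[[`, "", "patient")),
    cds_panel = panel, config = config
  ), class = "meso_cohort")
}

#' @export
print.meso_cohort <- function(x, ...) {
  nreg <- vapply(x$patients, function(p) length(p$regions), 1L)
  cat(sprintf("Synthetic multi-region cohort: %d patients, %d regions\n",
              length(x$patients), sum(nreg)))
  invisible(x)
}
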