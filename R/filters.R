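# Consensus SNV/indel filtering, force-calling and sample sanity checks.
#
# Boundary semantics (documented and tested): the dual-caller VAF rule is
# inclusive (VAF >= 2%), the single-caller rescue strict (VAF > 5%); the
# normal-evidence rules are `normal VAF < 1%` and `normal alt reads < 5`
# for SNVs. Each caller's VAF must individually satisfy the dual-caller
# threshold; with one observed count per row the row VAF stands for both.

snv_thresholds <- function() {
  list(vaf_dual = 0.02, vaf_single = 0.05, somatic_p_max = 0.1,
       normal_vaf_max = 0.01, normal_alt_max = 5, pop_freq_max = 0.01)
}

indel_thresholds <- function() {
  list(vaf_min = 0.05, somatic_p_max = 0.05, tumour_depth_min = 50,
       tumour_alt_min = 10, normal_alt_max = 2, pop_freq_max = 0.01)
}

filter_decision <- function(key, failed) {
  data.frame(key = key,
             status = ifelse(lengths(failed) == 0, "pass", "fail"),
             failed_rules = vapply(failed, paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
}

pop_freq_columns <- function(variants) {
  grep("^pop_freq", names(variants), value = TRUE)
}

#' Consensus filter for somatic SNVs
#'
#' A SNV passes when the caller evidence is sufficient - called by both
#' callers with somatic p <= 0.1 and VAF >= 2%, or rescued as a
#' single-caller (VarScan2-style) call with VAF > 5% - and the matched
#' normal is clean (normal VAF < 1% and fewer than 5 alt reads), the site
#' is not blacklisted (simple repeats / segmental duplications), and no
#' population database frequency exceeds 1%.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `called_by` (`"both"`, `"callerB"`, `"callerA"`), `somatic_p`,
#'   `tumour_depth`, `tumour_alt`, `normal_depth`, `normal_alt`,
#'   `blacklist_flag`, and zero or more `pop_freq*` columns (missing
#'   frequencies are treated as 0, i.e. novel).
#' @return A decision data frame: `key`, `status`, `failed_rules`.
#' @export
consensus_filter_snv <- function(variants) {
  th <- snv_thresholds()
  n <- nrow(variants)
  key <- variant_key(variants$chrom, variants$pos, variants$ref,
                     variants$alt)
  somatic_p <- variants$somatic_p
  somatic_p[is.na(somatic_p)] <- 1  # missing p fails the dual-caller test
  failed <- vector("list", n)
  vaf <- ifelse(variants$tumour_depth > 0,
                variants$tumour_alt / variants$tumour_depth, NA)
  nvaf <- ifelse(variants$normal_depth > 0,
                 variants$normal_alt / variants$normal_depth, 0)
  pf_cols <- pop_freq_columns(variants)
  for (i in seq_len(n)) {
    f <- character(0)
    if (variants$tumour_depth[i] == 0) {
      failed[[i]] <- "no-coverage"
      next
    }
    dual <- variants$called_by[i] == "both" &&
      somatic_p[i] <= th$somatic_p_max && vaf[i] >= th$vaf_dual
    single <- variants$called_by[i] == "callerB" && vaf[i] > th$vaf_single
    if (!dual && !single) f <- c(f, "caller-evidence")
    if (nvaf[i] >= th$normal_vaf_max) f <- c(f, "normal-vaf")
    if (variants$normal_alt[i] >= th$normal_alt_max) {
      f <- c(f, "normal-alt-reads")
    }
    if (isTRUE(variants$blacklist_flag[i])) f <- c(f, "blacklist")
    if (length(pf_cols)) {
      pf <- unlist(variants[i, pf_cols])
      pf[is.na(pf)] <- 0
      if (any(pf > th$pop_freq_max)) f <- c(f, "population-frequency")
    }
    failed[[i]] <- f
  }
  filter_decision(key, failed)
}

#' Filter somatic indels
#'
#' An indel passes with VAF >= 5%, somatic p <= 0.05, tumour depth > 50,
#' more than 10 alt reads in the tumour and fewer than 2 in the matched
#' normal; blacklist and population-frequency rules as for SNVs.
#'
#' @inheritParams consensus_filter_snv
#' @return A decision data frame: `key`, `status`, `failed_rules`.
#' @export
filter_indel <- function(variants) {
  th <- indel_thresholds()
  n <- nrow(variants)
  key <- variant_key(variants$chrom, variants$pos, variants$ref,
                     variants$alt)
  failed <- vector("list", n)
  vaf <- ifelse(variants$tumour_depth > 0,
                variants$tumour_alt / variants$tumour_depth, NA)
  pf_cols <- pop_freq_columns(variants)
  for (i in seq_len(n)) {
    f <- character(0)
    if (variants$tumour_depth[i] == 0) {
      failed[[i]] <- "no-coverage"
      next
    }
    if (vaf[i] < th$vaf_min) f <- c(f, "vaf")
    p <- variants$somatic_p[i]
    if (is.na(p) || p > th$somatic_p_max) f <- c(f, "somatic-p")
    if (variants$tumour_depth[i] <= th$tumour_depth_min) {
      f <- c(f, "tumour-depth")
    }
    if (variants$tumour_alt[i] <= th$tumour_alt_min) {
      f <- c(f, "tumour-alt-reads")
    }
    if (variants$normal_alt[i] >= th$normal_alt_max) {
      f <- c(f, "normal-alt-reads")
    }
    if (isTRUE(variants$blacklist_flag[i])) f <- c(f, "blacklist")
    if (length(pf_cols)) {
      pf <- unlist(variants[i, pf_cols])
      pf[is.na(pf)] <- 0
      if (any(pf > th$pop_freq_max)) f <- c(f, "population-frequency")
    }
    failed[[i]] <- f
  }
  filter_decision(key, failed)
}

is_indel <- function(ref, alt) nchar(ref) != nchar(alt)

#' Filter a multi-region variant table with force-calling
#'
#' Applies [consensus_filter_snv()] / [filter_indel()] per region, then
#' rescues sites that passed in at least one region of the patient:
#' in each negative region the site becomes `force_called` when its
#' mapping quality exceeds 20 and its VAF exceeds 2%. Force-calling only
#' adds presence. Regions without read-count data stay negative with a
#' warning.
#'
#' @param variants Long per-patient variant table (one row per
#'   mutation x region) with a `region_id` and `mapping_quality` column in
#'   addition to the columns of [consensus_filter_snv()].
#' @return The decision table with columns `key`, `region_id`, `status`
#'   (`pass`/`fail`/`force_called`), `failed_rules`.
#' @export
filter_variants <- function(variants) {
  indel <- is_indel(variants$ref, variants$alt)
  dec_parts <- list()
  if (any(!indel)) {
    d <- consensus_filter_snv(variants[!indel, , drop = FALSE])
    d$region_id <- variants$region_id[!indel]
    dec_parts$snv <- d
  }
  if (any(indel)) {
    d <- filter_indel(variants[indel, , drop = FALSE])
    d$region_id <- variants$region_id[indel]
    dec_parts$indel <- d
  }
  dec <- do.call(rbind, dec_parts)
  rownames(dec) <- NULL
  force_call(dec, variants)
}

#' Force-call sites across regions of one patient
#'
#' @param decisions Per-region decision table (`key`, `region_id`,
#'   `status`, `failed_rules`).
#' @param variants Matching variant table with `mapping_quality`,
#'   `tumour_depth`, `tumour_alt`.
#' @param mq_min Mapping-quality threshold (default 20, strict).
#' @param vaf_min VAF threshold (default 2%, strict).
#' @return The decision table with qualifying negatives set to
#'   `force_called`.
#' @export
force_call <- function(decisions, variants, mq_min = 20, vaf_min = 0.02) {
  vkey <- variant_key(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
  idx <- match(paste(decisions$key, decisions$region_id),
               paste(vkey, variants$region_id))
  if (any(is.na(idx))) {
    warning("region(s) without read-count data remain negative")
  }
  pass_sites <- unique(decisions$key[decisions$status == "pass"])
  cand <- which(decisions$status == "fail" &
                  decisions$key %in% pass_sites & !is.na(idx))
  if (length(cand)) {
    v <- variants[idx[cand], ]
    vaf <- ifelse(v$tumour_depth > 0, v$tumour_alt / v$tumour_depth, 0)
    ok <- v$mapping_quality > mq_min & vaf > vaf_min
    decisions$status[cand[ok]] <- "force_called"
    decisions$failed_rules[cand[ok]] <- ""
  }
  decisions
}

#' Purity sanity check from the VAF distribution
#'
#' For a sample dominated by clonal heterozygous mutations the mode of the
#' VAF distribution should sit near half the tumour purity. The mode is
#' located by kernel density estimation; samples whose VAF peak falls
#' below 0.1 are flagged for exclusion as low purity. Fewer than 20 VAFs
#' give an indeterminate call.
#'
#' @param vafs Numeric VAFs in `[0, 1]`.
#' @param purity Reported tumour purity.
#' @param min_vafs Minimum VAFs for a determinate call (default 20).
#' @return List: `status` (`pass`/`exclude`/`indeterminate`), `vaf_mode`,
#'   `deviation` = `|mode - purity/2|`.
#' @export
purity_sanity_check <- function(vafs, purity, min_vafs = 20) {
  if (length(vafs) < min_vafs) {
    return(list(status = "indeterminate", vaf_mode = NA_real_,
                deviation = NA_real_))
  }
  d <- stats::density(vafs, from = 0, to = 1)
  mode <- d$x[which.max(d$y)]
  list(status = if (mode < 0.1) "exclude" else "pass",
       vaf_mode = mode, deviation = abs(mode - purity / 2))
}

#' Deleteriousness consensus over four predictors
#'
#' A variant is deleterious when CScape and MutationTaster both call it
#' deleterious, or when CScape is low-confidence deleterious and the other
#' three predictors (MutationTaster, SIFT, PolyPhen) all call it
#' deleterious. Missing predictions count as tolerated.
#'
#' @param cscape,mutationtaster,sift,polyphen Predictor calls: `"D"`
#'   (deleterious), `"low-D"` (CScape low-confidence deleterious), `"T"`
#'   (tolerated) or `NA`.
#' @return Logical vector: `TRUE` = deleterious.
#' @export
deleteriousness_consensus <- function(cscape, mutationtaster, sift,
                                      polyphen) {
  cs <- ifelse(is.na(cscape), "T", cscape)
  mt <- ifelse(is.na(mutationtaster), "T", mutationtaster)
  sf <- ifelse(is.na(sift), "T", sift)
  pp <- ifelse(is.na(polyphen), "T", polyphen)
  (cs == "D" & mt == "D") |
    (cs == "low-D" & mt == "D" & sf == "D" & pp == "D")
}

#' Flag candidate driver genes
#'
#' Union of genes significant at q < 0.05 by either supplied discovery
#' method and genes on the curated driver list that carry a non-silent
#' variant in the cohort.
#'
#' @param gene_qvalues Data frame with columns `gene`, `q_method1`,
#'   `q_method2` (`NA` allowed).
#' @param mutated_genes Genes carrying non-silent variants.
#' @param curated Curated driver gene list.
#' @param q_max Significance threshold (default 0.05).
#' @return Character vector of flagged driver genes.
#' @export
flag_drivers <- function(gene_qvalues, mutated_genes,
                         curated = driver_genes()$gene, q_max = 0.05) {
  q1 <- gene_qvalues$q_method1
  q2 <- gene_qvalues$q_method2
  stopifnot(all(q1 >= 0 & q1 <= 1, na.rm = TRUE),
            all(q2 >= 0 & q2 <= 1, na.rm = TRUE))
  sig <- gene_qvalues$gene[(!is.na(q1) & q1 < q_max) |
                             (!is.na(q2) & q2 < q_max)]
  sort(union(sig, intersect(curated, mutated_genes)))
}
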