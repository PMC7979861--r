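# Neoantigen filtering/burden and HLA loss-of-heterozygosity calling.

#' Filter neoantigen candidates
#'
#' Keeps candidates with predicted mutant-peptide binding affinity below
#' 500 nM that also satisfy the sequencing-evidence rules: normal coverage
#' >= 5x with normal VAF <= 2%, tumour coverage >= 10x with tumour VAF
#' >= 10%. Candidates whose wild-type/mutant affinity fold change exceeds 2
#' are flagged higher priority.
#'
#' @param candidates Data frame with columns `affinity_mut`, `affinity_wt`,
#'   `tumour_depth`, `tumour_alt`, `normal_depth`, `normal_alt` (plus any
#'   identifier columns, carried through).
#' @param affinity_max Affinity cutoff in nM (default 500).
#' @param fold_change_min Priority fold-change threshold (default 2).
#' @return The input with logical columns `kept` and `priority` appended.
#' @export
filter_neoantigens <- function(candidates, affinity_max = 500,
                               fold_change_min = 2) {
  stopifnot(all(candidates$affinity_mut > 0),
            all(candidates$affinity_wt > 0))
  t_vaf <- ifelse(candidates$tumour_depth > 0,
                  candidates$tumour_alt / candidates$tumour_depth, 0)
  n_vaf <- ifelse(candidates$normal_depth > 0,
                  candidates$normal_alt / candidates$normal_depth, 1)
  kept <- candidates$affinity_mut < affinity_max &
    candidates$tumour_depth >= 10 & t_vaf >= 0.10 &
    candidates$normal_depth >= 5 & n_vaf <= 0.02
  priority <- kept &
    candidates$affinity_wt / candidates$affinity_mut > fold_change_min
  out <- candidates
  out$kept <- kept
  out$priority <- priority
  out
}

#' Per-patient clonal and subclonal neoantigen burden
#'
#' Counts kept neoantigens per patient by the clonality of the source
#' mutation. A mutation presented as several peptide lengths counts once.
#'
#' @param kept Filtered candidates (rows with `kept = TRUE` are counted)
#'   with columns `patient`, `mutation`.
#' @param clonality Named character vector mapping mutation keys to
#'   `"clonal"`/`"subclonal"`.
#' @return Data frame: `patient`, `clonal`, `subclonal`.
#' @export
neoantigen_burden <- function(kept, clonality) {
  kept <- kept[if ("kept" %in% names(kept)) kept$kept else TRUE, ,
               drop = FALSE]
  if (!nrow(kept)) {
    return(data.frame(patient = character(), clonal = integer(),
                      subclonal = integer(), stringsAsFactors = FALSE))
  }
  uniq <- unique(kept[, c("patient", "mutation")])
  cl <- clonality[uniq$mutation]
  if (any(is.na(cl))) {
    stop("unlabelled mutation(s): ",
         paste(utils::head(uniq$mutation[is.na(cl)], 3), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(cl, uniq$patient), function(x) {
    data.frame(clonal = sum(x == "clonal"),
               subclonal = sum(x == "subclonal"))
  })
  cbind(data.frame(patient = names(out), stringsAsFactors = FALSE),
        do.call(rbind, out), row.names = NULL)
}

#' Call HLA loss of heterozygosity from allele-specific coverage
#'
#' Computes per-mismatch-position log2 coverage ratios between the two
#' homologous HLA alleles and tests them against 0 with a two-sided
#' Wilcoxon signed-rank test. LOH is called when the test is significant
#' at `p_cut` and the median absolute log-ratio clears an effect-size
#' floor; the lost allele is the one with lower total coverage.
#'
#' @param allele1_depth,allele2_depth Coverage vectors at the mismatch
#'   positions between the two alleles (equal length, >= 5 positions).
#' @param p_cut Significance cutoff (default 0.01).
#' @param min_effect Minimum median `|log2 ratio|` (default 0.3).
#' @param min_positions Minimum number of mismatch positions (default 5).
#' @return List: `status` (`"called"`/`"indeterminate"`), `loh` (logical),
#'   `log_ratio_median`, `p`, `lost_allele` (1, 2 or `NA`).
#' @export
call_hla_loh <- function(allele1_depth, allele2_depth, p_cut = 0.01,
                         min_effect = 0.3, min_positions = 5) {
  stopifnot(length(allele1_depth) == length(allele2_depth),
            all(allele1_depth >= 0), all(allele2_depth >= 0))
  n <- length(allele1_depth)
  if (n < min_positions) {
    return(list(status = "indeterminate", loh = NA,
                log_ratio_median = NA_real_, p = NA_real_,
                lost_allele = NA_integer_))
  }
  logr <- log2((allele1_depth + 0.5) / (allele2_depth + 0.5))
  if (all(logr == 0)) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(logr, mu = 0, alternative = "two.sided")$p.value)
  }
  med <- stats::median(logr)
  loh <- p <= p_cut && abs(med) >= min_effect
  list(status = "called", loh = loh, log_ratio_median = med, p = p,
       lost_allele = if (!loh) NA_integer_ else if (med > 0) 2L else 1L)
}

#' HLA LOH calls for a cohort coverage table
#'
#' Applies [call_hla_loh()] per patient and gene; the patient-level call is
#' positive when any gene is positive.
#'
#' @param hla Data frame with columns `patient`, `gene`, `position`,
#'   `allele1_depth`, `allele2_depth`.
#' @param ... Passed to [call_hla_loh()].
#' @return List with `by_gene` (per patient x gene data frame) and
#'   `by_patient` (named logical vector).
#' @export
call_hla_loh_cohort <- function(hla, ...) {
  groups <- split(hla, list(hla$patient, hla$gene), drop = TRUE)
  rows <- lapply(groups, function(g) {
    res <- call_hla_loh(g$allele1_depth, g$allele2_depth, ...)
    data.frame(patient = g$patient[1], gene = g$gene[1],
               loh = isTRUE(res$loh), p = res$p,
               log_ratio_median = res$log_ratio_median,
               stringsAsFactors = FALSE)
  })
  by_gene <- do.call(rbind, rows)
  rownames(by_gene) <- NULL
  by_patient <- tapply(by_gene$loh, by_gene$patient, any)
  list(by_gene = by_gene, by_patient = by_patient)
}
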