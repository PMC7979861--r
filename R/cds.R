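# Synthetic coding-sequence panel used for dN/dS analyses and for planting
# coding mutations in the simulator.

sense_codons <- function() {
  code <- genetic_code()
  names(code)[unlist(code) != "*"]
}

#' Generate a synthetic CDS panel
#'
#' Random coding sequences assembled from sense codons (so no internal
#' stop codons), with genomic coordinates on chromosome 2 spaced so panel
#' genes never overlap the simulator's copy-number events.
#'
#' @param n_genes Number of genes.
#' @param n_codons Codons per gene.
#' @param seed Optional seed.
#' @return List with `cds` (named character vector) and `coords`
#'   (data frame `gene`, `chrom`, `start`, `end`, 0-based half-open).
#' @export
synthetic_cds_panel <- function(n_genes = 30, n_codons = 200, seed = NULL) {
  with_seed(seed, {
    codons <- sense_codons()
    cds <- vapply(seq_len(n_genes), function(i) {
      paste(sample(codons, n_codons, replace = TRUE), collapse = "")
    }, "")
    names(cds) <- sprintf("PG%02d", seq_len(n_genes))
    len <- n_codons * 3
    start <- 20e6 + (seq_len(n_genes) - 1) * 1e5
    coords <- data.frame(gene = names(cds), chrom = "chr2",
                         start = start, end = start + len,
                         stringsAsFactors = FALSE)
    list(cds = cds, coords = coords)
  })
}

#' Simulate neutral coding mutations on a CDS panel
#'
#' Sites and alternate bases are drawn uniformly, matching the uniform
#' rate model of [expected_site_counts()], so the expected dN/dS is 1.
#'
#' @param panel Panel from [synthetic_cds_panel()].
#' @param n Number of mutations.
#' @param seed Optional seed.
#' @return Data frame: `gene`, `cds_pos` (1-based within the CDS), `ref`,
#'   `alt`, `context`, `coding_class`.
#' @export
simulate_neutral_coding_mutations <- function(panel, n, seed = NULL) {
  with_seed(seed, {
    genes <- names(panel$cds)
    lens <- nchar(panel$cds)
    gi <- sample.int(length(genes), n, replace = TRUE, prob = lens)
    pos <- vapply(gi, function(g) sample.int(lens[g], 1), 1L)
    ref <- substr(panel$cds[gi], pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "",
                  USE.NAMES = FALSE)
    ctx <- paste0(
      ifelse(pos > 1, substr(panel$cds[gi], pos - 1, pos - 1), "N"),
      ref,
      ifelse(pos < lens[gi], substr(panel$cds[gi], pos + 1, pos + 1), "N"))
    cls <- vapply(seq_len(n), function(i) {
      classify_coding_change(panel$cds[[gi[i]]], pos[i], alt[i])
    }, "")
    data.frame(gene = genes[gi], cds_pos = pos, ref = ref, alt = alt,
               context = ctx, coding_class = cls,
               stringsAsFactors = FALSE)
  })
}
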