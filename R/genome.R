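#' Synthetic autosomal genome model
#'
#' A simplified model of the 22 human autosomes (approximate GRCh37 lengths,
#' rounded to the nearest megabase) with centromere positions used to split
#' chromosomes into p and q arms. All simulator coordinates live on this
#' genome; sex chromosomes are excluded so the normal copy number is 2
#' everywhere.
#'
#' @return A data.frame with columns `chrom`, `length`, `centromere` (bp).
#' @export
synthetic_genome <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    length = c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
               134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51) * 1e6,
    centromere = c(125, 93, 91, 50, 48, 61, 60, 45, 49, 40, 53,
                   36, 18, 17, 19, 37, 24, 17, 26, 28, 13, 15) * 1e6,
    stringsAsFactors = FALSE
  )
}

#' Chromosome-arm coordinate table
#'
#' Expands [synthetic_genome()] into one row per chromosome arm, 0-based
#' half-open coordinates.
#'
#' @param genome Genome table as returned by [synthetic_genome()].
#' @return A data.frame with columns `chrom`, `arm` (`"p"`/`"q"`), `start`,
#'   `end`.
#' @export
arm_table <- function(genome = synthetic_genome()) {
  p <- data.frame(chrom = genome$chrom, arm = "p", start = 0,
                  end = genome$centromere, stringsAsFactors = FALSE)
  q <- data.frame(chrom = genome$chrom, arm = "q", start = genome$centromere,
                  end = genome$length, stringsAsFactors = FALSE)
  out <- rbind(p, q)
  out[order(match(out$chrom, genome$chrom), out$arm), , drop = FALSE]
}

#' Driver gene loci used by the simulator and event callers
#'
#' Approximate loci (GRCh37 megabase resolution) for the mesothelioma driver
#' vocabulary: NF2, BAP1, FBXW7, SETD2, LATS2, PTEN and CDKN2A, with the
#' cytoband each is associated with in copy-number event calling.
#'
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), `cytoband`.
#' @export
driver_genes <- function() {
  data.frame(
    gene = c("BAP1", "SETD2", "FBXW7", "CDKN2A", "PTEN", "LATS2", "NF2"),
    chrom = c("chr3", "chr3", "chr4", "chr9", "chr10", "chr13", "chr22"),
    start = c(52.4e6, 47.0e6, 153.2e6, 21.9e6, 89.6e6, 21.5e6, 29.9e6),
    end = c(52.45e6, 47.15e6, 153.33e6, 21.995e6, 89.73e6, 21.6e6, 30.0e6),
    cytoband = c("3p21", "3p21", "4q31.3", "9p21.3", "10q23.31", "13q12",
                 "22q12"),
    stringsAsFactors = FALSE
  )
}
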