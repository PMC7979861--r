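# Format handling: minimal multi-sample VCF dialect, TSV tables, BED
# blacklists, tree JSON/Newick export.
#
# Conventions: VCF positions are 1-based; segment and BED coordinates are
# 0-based half-open. Conversion happens only at these boundaries.

#' Write a per-patient variant table as minimal VCF v4.2
#'
#' One sample column per region; FORMAT fields `TALT`/`TDEP` carry the
#' tumour alt/total counts per region, INFO fields `CALLER`, `NALT` and
#' `NDEP` carry the caller evidence and matched-normal counts.
#'
#' @param variants Long variant table (one row per mutation x region).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  regions <- sort(unique(variants$region_id))
  keys <- variant_key(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
  ord <- !duplicated(keys)
  sites <- variants[ord, c("chrom", "pos", "ref", "alt", "called_by",
                           "normal_alt", "normal_depth")]
  site_keys <- keys[ord]
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Caller evidence\">",
    "##INFO=<ID=NALT,Number=1,Type=Integer,Description=\"Normal alt reads\">",
    "##INFO=<ID=NDEP,Number=1,Type=Integer,Description=\"Normal depth\">",
    "##FORMAT=<ID=TALT,Number=1,Type=Integer,Description=\"Tumour alt reads\">",
    "##FORMAT=<ID=TDEP,Number=1,Type=Integer,Description=\"Tumour depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", regions), collapse = "\t"))
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    rows_i <- variants[keys == site_keys[i], ]
    fmt <- vapply(regions, function(r) {
      ri <- which(rows_i$region_id == r)
      if (!length(ri)) return(".:.")
      sprintf("%d:%d", rows_i$tumour_alt[ri[1]], rows_i$tumour_depth[ri[1]])
    }, "")
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
            sprintf("CALLER=%s;NALT=%d;NDEP=%d", s$called_by,
                    s$normal_alt, s$normal_depth),
            "TALT:TDEP", fmt), collapse = "\t")
  }, "")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read the minimal VCF dialect back into a long variant table
#'
#' @param path VCF path.
#' @return Long variant table (one row per mutation x region with
#'   observed counts).
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("malformed VCF header in ", path, call. = FALSE)
  }
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1) stop("missing #CHROM line in ", path,
                               call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[hdr_i]), "\t")[[1]]
  regions <- cols[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  out <- list()
  for (li in seq_along(body)) {
    f <- strsplit(body[li], "\t")[[1]]
    if (length(f) != length(cols)) {
      stop(sprintf("malformed VCF record at line %d of %s",
                   hdr_i + li, path), call. = FALSE)
    }
    info <- strsplit(f[8], ";")[[1]]
    get_info <- function(k) {
      v <- sub(paste0("^", k, "="), "", grep(paste0("^", k, "="), info,
                                             value = TRUE))
      if (length(v)) v else NA_character_
    }
    for (ri in seq_along(regions)) {
      val <- strsplit(f[9 + ri], ":")[[1]]
      if (val[1] == ".") next
      out[[length(out) + 1L]] <- data.frame(
        chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = f[5],
        region_id = regions[ri], called_by = get_info("CALLER"),
        tumour_alt = as.integer(val[1]), tumour_depth = as.integer(val[2]),
        normal_alt = as.integer(get_info("NALT")),
        normal_depth = as.integer(get_info("NDEP")),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @rdname read_segments
#' @param segments Segment table.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write allele-specific copy-number segment tables
#'
#' TSV with columns `chrom`, `start`, `end` (0-based half-open), `major`,
#' `minor`, `region_id` and optional phased columns `cn_a`, `cn_b`.
#'
#' @param path File path.
#' @return Segment data frame.
#' @export
read_segments <- function(path) {
  seg <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "major", "minor", "region_id")
  missing <- setdiff(required, names(seg))
  if (length(missing)) {
    stop("segment table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(seg$end <= seg$start) || any(seg$minor > seg$major)) {
    stop("invalid segment(s): require end > start and major >= minor",
         call. = FALSE)
  }
  seg
}

#' Read a blacklist BED file (0-based half-open)
#'
#' @param path BED path.
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_blacklist_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed
}

#' Flag variants overlapping blacklist intervals
#'
#' Converts the 1-based variant position to the BED convention before the
#' overlap test.
#'
#' @param chrom,pos Variant coordinates (1-based).
#' @param bed Blacklist intervals from [read_blacklist_bed()].
#' @return Logical vector.
#' @export
in_blacklist <- function(chrom, pos, bed) {
  vapply(seq_along(chrom), function(i) {
    any(bed$chrom == chrom[i] & bed$start < pos[i] & pos[i] <= bed$end)
  }, TRUE)
}

#' Export a scored clone tree as JSON
#'
#' @param tree A `clone_tree` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(nodes = rownames(tree$fitted) %||%
                paste0("C", seq_along(tree$parent)),
              parent = as.integer(tree$parent),
              fitted_ccf = as.data.frame(tree$fitted),
              rss = tree$rss, bic = tree$bic,
              newick = tree_newick(tree$parent))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a 96 x S signature matrix from TSV
#'
#' @param path TSV with channel labels in the first column and one column
#'   per signature.
#' @return Numeric matrix (96 rows, channel labels as rownames).
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ch <- sbs_channels()$label
  if (!identical(sort(rownames(m)), sort(ch))) {
    stop("signature matrix must cover the 96 SBS channels", call. = FALSE)
  }
  m[ch, , drop = FALSE]
}
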