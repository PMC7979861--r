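# Simplified dN/dS selection scan and mutational-signature fitting.

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

genetic_code <- function() {
  as.list(Biostrings::GENETIC_CODE)
}

#' The 96 single-base-substitution channels
#'
#' Pyrimidine-strand convention: six substitution types (C>A, C>G, C>T,
#' T>A, T>C, T>G) by 16 flanking-base contexts, grouped by substitution
#' with the 5' base varying slower than the 3' base.
#'
#' @return Data frame with columns `index`, `sub`, `context` (5'-ref-3'),
#'   `label` (e.g. `"A[C>T]G"`).
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  grid <- expand.grid(p3 = BASES, p5 = BASES, sub = subs,
                      stringsAsFactors = FALSE)[, c("sub", "p5", "p3")]
  ref <- substr(grid$sub, 1, 1)
  data.frame(index = seq_len(96), sub = grid$sub,
             context = paste0(grid$p5, ref, grid$p3),
             label = sprintf("%s[%s]%s", grid$p5, grid$sub, grid$p3),
             stringsAsFactors = FALSE)
}

#' Classify mutations into 96 trinucleotide channels
#'
#' Mutations with a purine reference base are reverse-complemented onto
#' the pyrimidine strand before classification.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Trinucleotide context centred on the reference base (on
#'   the same strand as `ref`).
#' @return Integer channel indices (1-96) named by channel label; `NA` for
#'   ambiguous bases.
#' @export
classify_context <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  purine <- ref %in% c("A", "G")
  ref2 <- ifelse(purine, chartr("ACGT", "TGCA", ref), ref)
  alt2 <- ifelse(purine, chartr("ACGT", "TGCA", alt), alt)
  ctx2 <- ifelse(purine, revcomp(context), context)
  ok <- ref2 %in% c("C", "T") & alt2 %in% BASES & nchar(ctx2) == 3 &
    !grepl("[^ACGT]", ctx2) & substr(ctx2, 2, 2) == ref2 & ref2 != alt2
  if (any(!ok)) warning(sum(!ok), " mutation(s) skipped: ambiguous base ",
                        "or inconsistent context")
  ch <- sbs_channels()
  lab <- sprintf("%s[%s>%s]%s", substr(ctx2, 1, 1), ref2, alt2,
                 substr(ctx2, 3, 3))
  idx <- match(lab, ch$label)
  idx[!ok] <- NA_integer_
  stats::setNames(idx, ifelse(ok, lab, NA))
}

#' Tally mutations into a 96-channel count vector
#'
#' @inheritParams classify_context
#' @return Named integer vector of length 96 (channel labels).
#' @export
count_contexts <- function(ref, alt, context) {
  idx <- suppressWarnings(classify_context(ref, alt, context))
  counts <- tabulate(idx[!is.na(idx)], nbins = 96)
  stats::setNames(counts, sbs_channels()$label)
}

#' Expected synonymous and non-synonymous site counts for a CDS
#'
#' Enumerates every possible single-base substitution in the coding
#' sequence, classifies it through the standard genetic code, and
#' accumulates substitution weights into expected non-synonymous and
#' synonymous site masses. Under the default uniform rate model each site
#' carries total mass 1 (1/3 per alternate base), so `L_non + L_syn`
#' equals the number of counted sites. A trinucleotide rate model can be
#' supplied as a named vector over the 96 channel labels of
#' [sbs_channels()]; rates are applied via the pyrimidine-strand channel of
#' each substitution.
#'
#' @param cds Coding sequence (character string, length divisible by 3).
#'   A terminal stop codon is allowed and excluded from the site counts.
#' @param rates Optional named rate vector over channel labels.
#' @return Named numeric `c(L_non, L_syn)`.
#' @export
expected_site_counts <- function(cds, rates = NULL) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3", call. = FALSE)
  code <- genetic_code()
  seqv <- strsplit(cds, "")[[1]]
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aas <- unlist(code[codons])
  if (any(aas[-length(aas)] == "*")) {
    stop("internal stop codon in CDS", call. = FALSE)
  }
  last <- if (aas[length(aas)] == "*") n - 3 else n
  L_non <- 0; L_syn <- 0
  for (i in seq_len(last)) {
    ci <- (i - 1) %/% 3 + 1
    off <- (i - 1) %% 3 + 1
    codon <- codons[ci]
    ref <- seqv[i]
    ctx <- paste0(if (i > 1) seqv[i - 1] else "N", ref,
                  if (i < n) seqv[i + 1] else "N")
    for (alt in setdiff(BASES, ref)) {
      w <- if (is.null(rates)) 1 / 3 else {
        lab <- names(suppressWarnings(classify_context(ref, alt, ctx)))
        if (is.na(lab) || !(lab %in% names(rates))) mean(rates) else
          rates[[lab]]
      }
      new_codon <- codon
      substr(new_codon, off, off) <- alt
      if (code[[new_codon]] == aas[ci]) L_syn <- L_syn + w
      else L_non <- L_non + w
    }
  }
  c(L_non = L_non, L_syn = L_syn)
}

#' Classify a coding change as synonymous or non-synonymous
#'
#' @param cds Coding sequence.
#' @param pos 1-based position within the CDS.
#' @param alt Alternate base.
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_coding_change <- function(cds, pos, alt) {
  code <- genetic_code()
  n <- length(pos)
  out <- character(n)
  for (i in seq_len(n)) {
    ci <- (pos[i] - 1) %/% 3
    codon <- substr(cds, ci * 3 + 1, ci * 3 + 3)
    new_codon <- codon
    substr(new_codon, (pos[i] - 1) %% 3 + 1, (pos[i] - 1) %% 3 + 1) <-
      alt[i]
    out[i] <- if (code[[new_codon]] == code[[codon]]) "synonymous" else
      "nonsynonymous"
  }
  out
}

#' dN/dS ratio with exact binomial test
#'
#' `dN/dS = (n_non / L_non) / (n_syn / L_syn)`. Significance and the 95%
#' interval come from a conditional binomial test of the non-synonymous
#' count among all counted mutations against the null proportion
#' `L_non / (L_non + L_syn)`; the proportion interval is transformed back
#' to the dN/dS scale.
#'
#' @param n_non,n_syn Observed non-synonymous / synonymous counts.
#' @param l_non,l_syn Expected site masses from [expected_site_counts()].
#' @return List with `dnds`, `ci95`, `p`, and the inputs. `dnds` is `Inf`
#'   (flagged `infinite = TRUE`) when `n_syn = 0`.
#' @export
dnds_test <- function(n_non, n_syn, l_non, l_syn) {
  stopifnot(l_syn > 0, l_non > 0, n_non >= 0, n_syn >= 0)
  site_ratio <- l_non / l_syn
  total <- n_non + n_syn
  if (total == 0) {
    return(list(dnds = NA_real_, ci95 = c(NA, NA), p = NA_real_,
                n_non = n_non, n_syn = n_syn, infinite = FALSE))
  }
  bt <- stats::binom.test(n_non, total, p = l_non / (l_non + l_syn))
  to_dnds <- function(theta) ifelse(theta >= 1, Inf,
                                    (theta / (1 - theta)) / site_ratio)
  list(dnds = if (n_syn == 0) Inf else (n_non / l_non) / (n_syn / l_syn),
       ci95 = to_dnds(bt$conf.int), p = bt$p.value,
       n_non = n_non, n_syn = n_syn, infinite = n_syn == 0)
}

#' Gene-level dN/dS scan with BH correction
#'
#' @param counts Data frame with columns `gene`, `n_non`, `n_syn`,
#'   `l_non`, `l_syn` (and optionally `scope`).
#' @return The input with `dnds`, `p` and BH `q` columns appended.
#' @export
dnds_scan <- function(counts) {
  res <- lapply(seq_len(nrow(counts)), function(i) {
    r <- dnds_test(counts$n_non[i], counts$n_syn[i], counts$l_non[i],
                   counts$l_syn[i])
    data.frame(dnds = r$dnds, p = r$p)
  })
  out <- cbind(counts, do.call(rbind, res))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Fit signature exposures by non-negative least squares
#'
#' Regresses a sample's normalised 96-channel mutation spectrum onto a
#' matrix of signature probability columns by NNLS; exposures are scaled
#' down to sum at most 1 when the unconstrained solution overshoots.
#' Samples with fewer than `min_mutations` classified mutations are
#' excluded from fitting (too few counts for a stable spectrum).
#'
#' @param counts Named numeric vector of 96 channel counts.
#' @param signatures 96 x S matrix; each column a probability vector.
#' @param min_mutations Minimum mutations required (default 50).
#' @return Object of class `signature_fit`: `exposures`, `residual`
#'   (Euclidean, on the normalised spectrum), `n_mutations`, `status`
#'   (`"ok"` or `"excluded"`).
#' @export
fit_signatures <- function(counts, signatures, min_mutations = 50) {
  stopifnot(length(counts) == 96, nrow(signatures) == 96)
  csums <- colSums(signatures)
  if (any(abs(csums - 1) > 1e-6)) {
    stop("signature columns must sum to 1", call. = FALSE)
  }
  n <- sum(counts)
  sig_names <- colnames(signatures) %||%
    paste0("S", seq_len(ncol(signatures)))
  if (n < min_mutations) {
    return(structure(list(
      exposures = stats::setNames(rep(NA_real_, ncol(signatures)),
                                  sig_names),
      residual = NA_real_, n_mutations = n, status = "excluded"),
      class = "signature_fit"))
  }
  target <- counts / n
  x <- pracma::lsqnonneg(signatures, as.numeric(target))$x
  if (sum(x) > 1) x <- x / sum(x)
  structure(list(
    exposures = stats::setNames(x, sig_names),
    residual = sqrt(sum((signatures %*% x - target)^2)),
    n_mutations = n, status = "ok"), class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("Signature fit (%s): n = %d mutations\n", x$status,
              x$n_mutations))
  if (x$status == "ok") print(round(x$exposures, 3))
  invisible(x)
}

#' A five-signature toy basis
#'
#' Deterministic, well-separated signature columns for demonstrations and
#' simulation: a flat background, a CpG-deamination-like C>T signature, a
#' C>A-dominated signature, a T>C-dominated signature and a T>G peak
#' signature. Also shipped as `extdata/signatures_toy.tsv`.
#'
#' @return A 96 x 5 matrix of probability columns.
#' @export
toy_signatures <- function() {
  ch <- sbs_channels()
  peak <- function(sel, w) {
    v <- rep(0.1 / 96, 96)
    v[sel] <- v[sel] + w / sum(sel)
    v / sum(v)
  }
  S <- cbind(
    flat = rep(1 / 96, 96),
    cpg_ct = peak(ch$sub == "C>T" & substr(ch$context, 3, 3) == "G", 0.9),
    c_to_a = peak(ch$sub == "C>A", 0.9),
    t_to_c = peak(ch$sub == "T>C", 0.9),
    t_to_g = peak(ch$sub == "T>G" & substr(ch$context, 1, 1) == "T", 0.9)
  )
  rownames(S) <- ch$label
  S
}
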