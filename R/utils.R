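# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a global seed
#'
#' Fans a single user-facing seed out into independent per-stage seeds so that
#' changing the iteration order of one pipeline stage does not perturb the
#' random stream of another. The result is always a valid 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"cluster"`).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("`%s` must lie in [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}

# variant key shared by filters / clonality / io
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
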