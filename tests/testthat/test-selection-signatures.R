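test_that("expected site counts follow the codon table", {
  # ATG (Met): no synonymous change possible
  L <- expected_site_counts("ATG")
  expect_equal(unname(L), c(3, 0))
  # GGG (Gly): all three third-position changes synonymous
  L2 <- expected_site_counts("GGG")
  expect_equal(L2[["L_syn"]], 1)
  expect_equal(L2[["L_non"]], 2)
  # conservation: total site mass equals the number of counted sites
  cds <- "ATGGGGTTTAAACCC"
  L3 <- expected_site_counts(cds)
  expect_equal(sum(L3), nchar(cds))
  expect_error(expected_site_counts("ATGTAAAAA"), "stop codon")
  # a terminal stop codon is excluded, not an error
  L4 <- expected_site_counts("ATGTAA")
  expect_equal(sum(L4), 3)
})

test_that("coding changes classify through the genetic code", {
  expect_equal(classify_coding_change("GGG", 3, "A"), "synonymous")
  expect_equal(classify_coding_change("GGG", 1, "A"), "nonsynonymous")
  expect_equal(classify_coding_change("ATGGGG", c(6, 2), c("T", "C")),
               c("synonymous", "nonsynonymous"))
})

test_that("dN/dS arithmetic and flags are exact", {
  r <- dnds_test(60, 20, 3, 1)
  expect_equal(r$dnds, 1)
  r2 <- dnds_test(90, 20, 3, 1)
  expect_equal(r2$dnds, 1.5)
  r3 <- dnds_test(10, 0, 3, 1)
  expect_true(is.infinite(r3$dnds))
  expect_true(r3$infinite)
  expect_true(is.finite(r3$ci95[1]))
})

test_that("the gene-level scan applies BH correction", {
  counts <- data.frame(gene = c("g1", "g2", "g3"),
                       n_non = c(90, 30, 31), n_syn = c(10, 10, 9),
                       l_non = 3, l_syn = 1)
  out <- dnds_scan(counts)
  expect_equal(out$q, stats::p.adjust(out$p, "BH"))
  expect_equal(out$dnds[2], 1)
})

test_that("96-channel classification uses the pyrimidine strand", {
  # A[G>T]A complements to T[C>A]T
  idx <- classify_context("G", "T", "AGA")
  expect_equal(names(idx), "T[C>A]T")
  ch <- sbs_channels()
  expect_equal(nrow(ch), 96)
  expect_equal(anyDuplicated(ch$label), 0)
  # every (pyrimidine ref, alt, context) combination maps to a channel
  combos <- expand.grid(p5 = c("A", "C", "G", "T"), ref = c("C", "T"),
                        p3 = c("A", "C", "G", "T"),
                        alt = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  idx_all <- classify_context(combos$ref, combos$alt,
                              paste0(combos$p5, combos$ref, combos$p3))
  expect_equal(sort(unique(idx_all)), 1:96)
  # involution: reverse-complemented records land in the same channel
  idx_rc <- classify_context("G", "T", "TGA")  # revcomp of T[C>A]A record
  expect_equal(unname(idx_rc), unname(classify_context("C", "A", "TCA")))
})

test_that("context counting conserves the classified mutations", {
  set.seed(41)
  sites <- mesoevolve:::random_mutation_sites(500)
  counts <- count_contexts(sites$ref, sites$alt, sites$context)
  expect_equal(sum(counts), 500)
  expect_warning(classify_context("N", "A", "NNN"), "skipped")
  expect_equal(sum(count_contexts("N", "A", "NNN")), 0)
})

test_that("NNLS recovers exact signature mixtures", {
  S <- toy_signatures()
  counts <- 1000 * (0.7 * S[, 1] + 0.3 * S[, 2])
  fit <- fit_signatures(counts, S)
  expect_equal(fit$status, "ok")
  expect_lt(sum(abs(fit$exposures - c(0.7, 0.3, 0, 0, 0))), 0.01)
  expect_lt(fit$residual, 1e-8)

  # identity basis returns the normalised counts
  I96 <- diag(96)
  fit2 <- fit_signatures(counts, I96)
  expect_equal(unname(fit2$exposures), unname(counts / sum(counts)),
               tolerance = 1e-8)
})

test_that("samples under 50 mutations are excluded from fitting", {
  S <- toy_signatures()
  counts <- round(49 * S[, 1])
  counts[1] <- counts[1] + (49 - sum(counts))
  fit <- fit_signatures(counts, S)
  expect_equal(fit$status, "excluded")
  expect_true(all(is.na(fit$exposures)))
})

test_that("adding a true signature to the basis cannot worsen the fit", {
  S <- toy_signatures()
  target <- 500 * (0.5 * S[, 2] + 0.5 * S[, 3])
  r_partial <- fit_signatures(target, S[, c(1, 2), drop = FALSE])$residual
  r_full <- fit_signatures(target, S[, 1:3])$residual
  expect_lte(r_full, r_partial + 1e-12)
})
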