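test_that("mutation copy number reproduces hand-computed values", {
  expect_equal(mutation_copy_number(0.5, 1, 2), 1)
  expect_equal(mutation_copy_number(0.25, 0.5, 2), 1)
  expect_equal(mutation_copy_number(0.3, 0.6, 3), 1.3)
  expect_error(mutation_copy_number(0.5, 0, 2), "purity")
})

test_that("multiplicity is assigned by maximum binomial likelihood", {
  expect_equal(assign_multiplicity(50, 100, 1, 2, major = 1), 1L)
  expect_equal(assign_multiplicity(100, 100, 1, 2, major = 2), 2L)
  expect_equal(assign_multiplicity(50, 100, 1, 2, major = 2), 1L)
  # ties go to the smaller m: alt exactly between the two expected VAFs
  expect_equal(assign_multiplicity(0, 0, 1, 2, major = 2), 1L)
})

test_that("CCF clips according to the tolerance rule", {
  expect_equal(as.numeric(ccf_from_nmut(1, 1)), 1)
  expect_equal(as.numeric(ccf_from_nmut(1.3, 2)), 0.65)
  expect_warning(out <- ccf_from_nmut(1.08, 1, tol = 0.1), "clipped")
  expect_equal(as.numeric(out), 1)
  expect_false(attr(out, "inconsistent"))
  out2 <- suppressWarnings(ccf_from_nmut(1.5, 1, tol = 0.1))
  expect_true(attr(out2, "inconsistent"))
  expect_equal(as.numeric(out2), 1)
})

test_that("the CCF table reproduces truth on noiseless input", {
  # hand-built two-region patient: diploid genome, known purity
  purity <- c(R1 = 0.5, R2 = 0.5)
  segments <- data.frame(chrom = "chr1", start = 0, end = 2e6,
                         major = 1L, minor = 1L,
                         region_id = rep(c("R1", "R2"), each = 1))
  ccf_true <- c(1, 0.5)
  v <- data.frame(mutation = rep(c("m1", "m2"), 2),
                  region_id = rep(c("R1", "R2"), each = 2),
                  chrom = "chr1", pos = c(100, 200, 100, 200),
                  tumour_depth = 1000,
                  tumour_alt = round(1000 * 0.5 * ccf_true / 2),
                  stringsAsFactors = FALSE)
  tab <- compute_ccf_table(v, segments, purity)
  expect_equal(tab$ccf[tab$mutation == "m1"], c(1, 1))
  expect_equal(tab$ccf[tab$mutation == "m2"], c(0.5, 0.5))
  expect_equal(tab$multiplicity, rep(1L, 4))
})

test_that("effective depth matches the observed depth when no rescaling", {
  # pure tumour, CN 2, m 1: the CCF is 2x the VAF, so a quarter the info
  expect_equal(effective_depth(400, 1, 2, 1, 1), 400L, tolerance = 0.05)
  # at purity 0.5 the rescaling factor doubles and information drops
  expect_lt(effective_depth(400, 0.5, 2, 1, 0.5), 200)
  expect_equal(effective_depth(0, 0.5, 2, 1, 0.5), 0L)
})

test_that("identical CCF profiles collapse to one cluster", {
  ccf <- matrix(0.8, 5, 3)
  dep <- matrix(200L, 5, 3)
  cl <- cluster_ccfs(ccf, dep, iters = 200, burnin = 50, seed = 1)
  expect_equal(nrow(cl$means), 1)
  expect_equal(cl$assignment, rep(1L, 5))
})

test_that("a single mutation forms a single cluster without sampling", {
  ccf <- matrix(c(0.4, 0.2), 1, 2)
  cl <- cluster_ccfs(ccf, matrix(100L, 1, 2))
  expect_equal(cl$assignment, 1L)
})

test_that("clustering is deterministic given a seed and recovers truth", {
  ccf_true <- rbind(c(1, 1), c(0.4, 0))
  dat <- planted_ccf_data(ccf_true, rep(1:2, each = 50), purity = 0.5,
                          depth = 250, seed = 4)
  cl1 <- cluster_ccfs(dat$ccf, dat$depth, iters = 600, burnin = 100,
                      seed = 8)
  cl2 <- cluster_ccfs(dat$ccf, dat$depth, iters = 600, burnin = 100,
                      seed = 8)
  expect_identical(cl1$assignment, cl2$assignment)
  expect_gte(ari(cl1$assignment, dat$z), 0.9)
})

test_that("the partition is invariant to mutation input order", {
  ccf_true <- rbind(c(1, 1), c(0.4, 0))
  dat <- planted_ccf_data(ccf_true, rep(1:2, each = 40), purity = 0.6,
                          depth = 250, seed = 5)
  cl <- cluster_ccfs(dat$ccf, dat$depth, iters = 600, burnin = 100,
                     seed = 2)
  perm <- sample(nrow(dat$ccf))
  clp <- cluster_ccfs(dat$ccf[perm, ], dat$depth[perm, ], iters = 600,
                      burnin = 100, seed = 2)
  expect_equal(ari(clp$assignment, cl$assignment[perm]), 1)
})

test_that("the DP concentration controls the number of clusters", {
  ccf_true <- rbind(c(1, 1), c(0.5, 0.5), c(0.2, 0))
  dat <- planted_ccf_data(ccf_true, rep(1:3, each = 30), purity = 0.6,
                          depth = 250, seed = 6)
  k_small <- nrow(cluster_ccfs(dat$ccf, dat$depth, iters = 400,
                               burnin = 100, alpha = 1e-4,
                               seed = 3)$means)
  k_big <- nrow(cluster_ccfs(dat$ccf, dat$depth, iters = 400,
                             burnin = 100, alpha = 50, seed = 3)$means)
  expect_lte(k_small, k_big)
})

test_that("clonality classification respects threshold and presence", {
  expect_equal(classify_clonality(c(1, 0.98, 0.95)), "clonal")
  expect_equal(classify_clonality(c(1, 0.2)), "subclonal")
  expect_equal(classify_clonality(c(0.92, 0.91), threshold = 0.9),
               "clonal")
  expect_equal(classify_clonality(c(0.92, 0.91), threshold = 0.95),
               "subclonal")
  m <- rbind(a = c(1, 1), b = c(0.5, 1))
  expect_equal(unname(classify_clonality(m)), c("clonal", "subclonal"))
})
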