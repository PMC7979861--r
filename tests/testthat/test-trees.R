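test_that("feasible-tree enumeration honours the sum rule", {
  means <- rbind(T = c(1, 1), A = c(0.6, 0.5), B = c(0.3, 0.4))
  trees <- enumerate_feasible_trees(means, tol = 0.05)
  keys <- vapply(trees, tree_key, "")
  expect_setequal(keys, c("0,1,1", "0,1,2"))  # star and chain T->A->B
  expect_false("0,3,1" %in% keys)             # chain T->B->A infeasible

  single <- matrix(1, 1, 2, dimnames = list("T", NULL))
  expect_length(enumerate_feasible_trees(single), 1)

  no_clonal <- rbind(c(0.5, 0.5), c(0.3, 0.3))
  expect_error(enumerate_feasible_trees(no_clonal), "no truncal cluster")
})

test_that("enumeration equals the brute-force parent-vector oracle", {
  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    R <- sample(2:3, 1)
    means <- rbind(rep(1, R),
                   matrix(stats::runif((k - 1) * R, 0, 0.85),
                          k - 1, R))
    got <- sort(vapply(enumerate_feasible_trees(means, tol = 0.05),
                       tree_key, ""))
    want <- sort(vapply(bf_trees(means, tol = 0.05, root = 1),
                        tree_key, ""))
    expect_identical(got, want)
  }
})

test_that("minimum-BIC selection fits noiseless planted trees exactly", {
  # identifiable chain: children sum above the root, so the star is
  # infeasible and the reversed chain violates the sum rule
  means <- rbind(T = c(1, 1), A = c(0.7, 0.7), B = c(0.45, 0.45))
  trees <- enumerate_feasible_trees(means)
  best <- score_and_select(trees, means)
  expect_equal(unname(best$parent), c(0L, 1L, 2L))
  expect_equal(best$rss, 0)
  expect_equal(best$fitted, means)
})

test_that("BIC ties break to the lexicographically smaller parent vector", {
  means <- rbind(T = c(1, 1), A = c(0.6, 0.5), B = c(0.3, 0.4))
  trees <- enumerate_feasible_trees(means, tol = 0.05)
  best <- score_and_select(trees, means)
  # both candidates have RSS 0 and equal edges; star (0,1,1) < chain (0,1,2)
  expect_equal(unname(best$parent), c(0L, 1L, 1L))
})

test_that("projection repairs sum-rule violations without inflating RSS", {
  means <- rbind(T = c(1, 1), A = c(0.8, 0.7), B = c(0.5, 0.6))
  star <- list(c(0L, 1L, 1L))
  scored <- score_trees(star, means)[[1]]
  # fitted CCFs satisfy the sum rule
  expect_true(all(colSums(scored$fitted[2:3, ]) <=
                    scored$fitted[1, ] + 1e-6))
  # chain is feasible without projection: its RSS is 0 and it must win
  trees <- enumerate_feasible_trees(means, tol = 0.05)
  best <- score_and_select(trees, means)
  expect_lte(best$rss, scored$rss)
})

test_that("topology classification separates subclonal branching", {
  expect_equal(classify_topology(c(0L, 1L, 2L)), "linear")
  expect_equal(classify_topology(c(0L, 1L, 1L)), "linear")  # truncal star
  expect_equal(classify_topology(c(0L, 1L, 2L, 2L)), "branched")
  expect_equal(classify_topology(c(0L, 1L, 1L), strict = TRUE),
               "branched")
  # invariant under relabelling of the subclones
  parent <- c(0L, 1L, 2L, 2L)
  relab <- c(0L, 1L, 2L, 2L)[c(1, 2, 3, 4)]
  perm_parent <- c(0L, 1L, 2L, 2L)
  expect_equal(classify_topology(perm_parent),
               classify_topology(parent))
})

test_that("Newick export is well-formed", {
  nw <- tree_newick(c(0L, 1L, 1L, 3L))
  expect_equal(nw, "((C2,(C4)C3)C1)GL;")
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = nw)
  expect_s3_class(tr, "phylo")
})

test_that("SCNA event classes match their defining predicates", {
  regions <- c("R1", "R2")
  seg <- rbind(
    # 62% of chr4 lost in both regions -> chromosome loss, clonal
    data.frame(chrom = "chr4", start = 0, end = 120e6, major = 1L,
               minor = 0L, cn_a = 1L, cn_b = 0L, region_id = regions),
    # CN-LOH segment in R1 only
    data.frame(chrom = "chr5", start = 10e6, end = 20e6, major = 2L,
               minor = 0L, cn_a = 2L, cn_b = 0L, region_id = "R1"),
    # homozygous deletion both regions
    data.frame(chrom = "chr9", start = 21.8e6, end = 22.1e6, major = 0L,
               minor = 0L, cn_a = 0L, cn_b = 0L, region_id = regions),
    # mirrored loss: opposite alleles in the two regions
    data.frame(chrom = "chr1", start = 10e6, end = 30e6, major = 1L,
               minor = 0L, cn_a = c(0L, 1L), cn_b = c(1L, 0L),
               region_id = regions),
    # gain in R2
    data.frame(chrom = "chr7", start = 0, end = 50e6, major = 2L,
               minor = 1L, cn_a = 2L, cn_b = 1L, region_id = "R2"))
  ev <- call_scna_events(seg)
  chr4 <- ev[ev$class == "chr_loss", ]
  expect_equal(chr4$location, "-chr4")
  expect_equal(chr4$clonality, "clonal")
  expect_equal(ev$clonality[ev$class == "cnloh"], "subclonal")
  expect_true(any(ev$class == "homozygous_deletion"))
  expect_true(any(ev$class == "msai"))
  expect_equal(ev$regions[ev$class == "msai"], "R1,R2")
  expect_equal(ev$chrom[ev$class == "gain"], "chr7")
  # chr4 loss spans > 50% of both arms -> arm-loss events too
  expect_true("4p" %in% sub("-", "", ev$location[ev$class == "arm_loss"]))
})

test_that("a 58% chromosome loss stays below the 60% rule", {
  seg <- data.frame(chrom = "chr4", start = 0, end = 110e6, major = 1L,
                    minor = 0L, region_id = "R1")  # 110/191 = 58%
  ev <- call_scna_events(seg)
  expect_false(any(ev$class == "chr_loss"))
  expect_true(any(ev$class == "loss"))
})

test_that("overlapping segments within a region are rejected", {
  seg <- data.frame(chrom = "chr1", start = c(0, 5e6), end = c(10e6, 15e6),
                    major = 1L, minor = 0L, region_id = "R1")
  expect_error(call_scna_events(seg), "overlapping")
})

test_that("double hits combine mutations and allelic loss", {
  regions <- c("R1", "R2")
  seg <- rbind(
    data.frame(chrom = "chr3", start = 40e6, end = 60e6, major = 1L,
               minor = 0L, region_id = regions),   # BAP1 locus LOH
    data.frame(chrom = "chr9", start = 21.8e6, end = 22.1e6, major = 0L,
               minor = 0L, region_id = regions),   # CDKN2A homdel
    data.frame(chrom = "chr10", start = 89e6, end = 90e6, major = 1L,
               minor = 1L, region_id = regions))   # PTEN neutral
  muts <- data.frame(
    gene = c("BAP1", "PTEN", "NF2", "NF2"),
    mutation = c("m1", "m2", "m3", "m4"),
    deleterious = TRUE,
    clonality = c("clonal", "clonal", "clonal", "subclonal"),
    stringsAsFactors = FALSE)
  hits <- detect_double_hits(muts, seg)
  h <- stats::setNames(hits$double_hit, hits$gene)
  expect_true(h[["BAP1"]])     # mutation + loss
  expect_true(h[["CDKN2A"]])   # homozygous deletion alone
  expect_true(h[["NF2"]])      # two distinct mutations
  expect_false(h[["PTEN"]])    # mutation only, (1,1) segment
  tm <- stats::setNames(hits$timing, hits$gene)
  expect_equal(tm[["BAP1"]], "clonal")
  expect_equal(tm[["NF2"]], "subclonal")
})
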