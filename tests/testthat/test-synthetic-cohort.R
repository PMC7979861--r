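test_that("clone-tree simulation covers the degenerate and forced cases", {
  expect_identical(simulate_clone_tree(1, seed = 1), 0L)
  expect_identical(simulate_clone_tree(2, seed = 1), c(0L, 1L))
  expect_error(simulate_clone_tree(0), "integer >= 1")
})

test_that("clone-tree simulation is uniform over rooted labelled trees", {
  k <- 4
  ref <- matrix(1, k, 2)
  # large tolerance: the sum rule never binds, so this enumerates all trees
  all_trees <- vapply(bf_trees(ref, tol = 10, root = 1), tree_key, "")
  expect_length(all_trees, 16)  # Cayley: 4^2 rooted at a fixed node
  set.seed(99)
  draws <- replicate(10000, tree_key(simulate_clone_tree(4)))
  counts <- table(factor(draws, levels = all_trees))
  expect_true(all(counts > 0))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("region CCF assignment obeys the sum rule by construction", {
  parent <- c(0L, 1L)  # chain root -> A
  m <- assign_region_ccfs(parent, 2, seed = 1)
  expect_equal(unname(m[1, ]), c(1, 1))
  expect_true(all(m[2, ] <= m[1, ]))

  set.seed(42)
  violations <- 0
  absences <- 0
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    parent <- simulate_clone_tree(k)
    m <- assign_region_ccfs(parent, sample(2:5, 1))
    expect_equal(unname(m[which(parent == 0L), ]),
                 rep(1, ncol(m)))
    for (v in seq_len(k)) {
      kids <- which(parent == v)
      if (length(kids)) {
        if (any(colSums(m[kids, , drop = FALSE]) > m[v, ] + 1e-12)) {
          violations <- violations + 1
        }
      }
    }
    if (k >= 3 && any(m == 0)) absences <- absences + 1
  }
  expect_identical(violations, 0)
})

test_that("spatial heterogeneity guarantees an absent cluster for k >= 3", {
  for (s in 1:50) {
    parent <- simulate_clone_tree(4, seed = s)
    m <- assign_region_ccfs(parent, 3, seed = s)
    expect_true(any(m == 0))
  }
})

test_that("expected VAF follows the purity/copy-number relation", {
  expect_equal(expected_vaf(1, 1, 1, 2), 0.5)
  expect_equal(expected_vaf(0.5, 1, 1, 2), 0.25)
  expect_equal(expected_vaf(0.5, 2, 0.5, 3), 0.2)
  expect_error(expected_vaf(1, 4, 1, 2), "expected VAF")
})

test_that("simulated read counts match the binomial model", {
  set.seed(7)
  n <- 10000
  dep <- stats::rpois(n, 250)
  alt <- stats::rbinom(n, dep, 0.25)
  vaf_hat <- mean(alt / dep)
  se <- stats::sd(alt / dep) / sqrt(n)
  expect_lt(abs(vaf_hat - 0.25), 3 * se)
})

test_that("the copy-number relation round-trips through noiseless VAFs", {
  for (p in c(0.3, 0.6, 1)) {
    for (cn_t in c(1, 2, 3)) {
      for (ccf in c(0.2, 0.5, 1)) {
        m <- 1
        v <- expected_vaf(p, m, ccf, cn_t)
        expect_equal(mutation_copy_number(v, p, cn_t), m * ccf,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("cohort simulation is deterministic and sized as configured", {
  cfg <- sim_config(n_patients = 4, n_regions = 2:3,
                    n_mutations_range = c(20, 30), seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)

  nreg <- vapply(a$patients, function(p) length(p$regions), 1L)
  expect_true(all(nreg %in% 2:3))
  expect_length(a$patients, 4)
  # ground-truth sum rule holds in every patient
  for (t in a$truth) {
    for (v in seq_along(t$tree)) {
      kids <- which(t$tree == v)
      if (length(kids)) {
        expect_true(all(colSums(t$ccf[kids, , drop = FALSE]) <=
                          t$ccf[v, ] + 1e-12))
      }
    }
  }
})

test_that("the bundled archetype YAML matches the in-code defaults", {
  path <- system.file("extdata", "driver_archetypes.yaml",
                      package = "mesoevolve")
  skip_if(path == "", "fixture not installed")
  a <- default_archetypes()
  b <- read_archetypes(path)
  expect_identical(lapply(b, `[`, c("name", "truncal", "late")),
                   lapply(a, `[`, c("name", "truncal", "late")))
  expect_equal(vapply(b, `[[`, 0, "hazard"),
               vapply(a, `[[`, 0, "hazard"), tolerance = 1e-9)
})

test_that("a doubled archetype hazard halves median survival", {
  base <- log(2) / 500
  archs <- list(
    list(name = "slow", truncal = "SETD2", late = character(0),
         hazard = base),
    list(name = "fast", truncal = "BAP1", late = character(0),
         hazard = 2 * base))
  cfg <- sim_config(n_patients = 400, n_regions = 2,
                    n_clusters_range = c(1, 2),
                    n_mutations_range = c(5, 8),
                    driver_archetypes = archs, coding_fraction = 0,
                    seed = 22)
  co <- simulate_cohort(cfg)
  med <- tapply(co$clinical$time, co$clinical$archetype, stats::median)
  expect_equal(unname(med[["fast"]] / med[["slow"]]), 0.5,
               tolerance = 0.35)
})
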