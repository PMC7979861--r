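test_that("driver orderings follow ancestry on the clone tree", {
  # GL -> T(1) -> A(2): BAP1 truncal, NF2 on the child
  dm <- data.frame(event = c("BAP1", "NF2"), cluster = c(1L, 2L))
  expect_setequal(extract_orderings(c(0L, 1L), dm),
                  c("GL->BAP1", "BAP1->NF2"))
  # single truncal driver
  expect_equal(extract_orderings(0L, data.frame(event = "BAP1",
                                                cluster = 1L)),
               "GL->BAP1")
  # co-resident drivers stay unordered
  dm2 <- data.frame(event = c("a", "b"), cluster = c(1L, 1L))
  expect_setequal(extract_orderings(c(0L, 1L), dm2),
                  c("GL->a", "GL->b"))
  # deeper chain orders across all ancestor levels
  dm3 <- data.frame(event = c("x", "y", "z"), cluster = 1:3)
  expect_setequal(extract_orderings(c(0L, 1L, 2L), dm3),
                  c("GL->x", "x->y", "x->z", "y->z"))
  expect_error(extract_orderings(c(0L, 1L),
                                 data.frame(event = "q", cluster = 5L)),
               "unknown tree node")
})

test_that("transfer fit counts transitions and resolves ambiguity", {
  unambiguous <- lapply(1:5, function(i) {
    list(list(orderings = c("GL->BAP1", "BAP1->NF2"), bic = -10))
  })
  names(unambiguous) <- paste0("P", 1:5)
  fit <- transfer_fit(unambiguous)
  expect_equal(fit$iterations, 1L)
  expect_equal(unname(fit$w[["GL->BAP1"]]), 5L)

  # one ambiguous patient: the cohort-supported candidate wins despite
  # a slightly worse BIC
  ambiguous <- c(unambiguous, list(P6 = list(
    list(orderings = c("GL->SETD2"), bic = -12),
    list(orderings = c("GL->BAP1", "BAP1->NF2"), bic = -11))))
  fit2 <- transfer_fit(ambiguous)
  expect_equal(unname(fit2$selection[["P6"]]), 2L)
  expect_equal(unname(fit2$w[["GL->BAP1"]]), 6L)

  # permuting patient ids leaves the counts unchanged
  fit3 <- transfer_fit(rev(ambiguous))
  expect_equal(sort(fit3$w), sort(fit2$w))
  expect_error(transfer_fit(list()), "empty")
})

test_that("repeated transitions require support from more than 3 patients", {
  w <- c("GL->BAP1" = 5L, "GL->NF2" = 4L, "BAP1->NF2" = 3L,
         "GL->SETD2" = 1L)
  expect_setequal(repeated_transitions(w), c("GL->BAP1", "GL->NF2"))
  expect_length(repeated_transitions(integer(0)), 0)
})

test_that("evolutionary distance is the Jaccard distance on pair sets", {
  expect_equal(evolutionary_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(evolutionary_distance(c("a"), c("b")), 1)
  expect_equal(evolutionary_distance(c("a", "b"), c("a")), 0.5)
  expect_equal(evolutionary_distance(character(0), character(0)), 0)
})

test_that("evolutionary distance is a pseudo-metric", {
  set.seed(23)
  vocab <- paste0("e", 1:8)
  sets <- lapply(1:12, function(i) sample(vocab, sample(0:6, 1)))
  D <- trajectory_distances(stats::setNames(sets, paste0("P", 1:12)))
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  n <- nrow(D)
  for (i in 1:n) for (j in 1:n) for (l in 1:n) {
    expect_lte(D[i, j], D[i, l] + D[l, j] + 1e-12)
  }
})

test_that("cohort clustering recovers block structure and orders labels", {
  # 3 planted blocks: distance 0 within, 1 between
  truth <- rep(1:3, times = c(4, 4, 4))
  D <- 1 - outer(truth, truth, "==")
  dimnames(D) <- list(paste0("P", 1:12), paste0("P", 1:12))
  complexity <- c(rep(9, 4), rep(1, 4), rep(5, 4))
  labels <- cluster_cohort(D, k = 3, complexity = complexity)
  expect_equal(ari(labels, truth), 1)
  # labels ordered by increasing mean complexity
  expect_equal(as.numeric(tapply(complexity, labels, mean)), c(1, 5, 9))
  expect_equal(unique(cluster_cohort(D, k = 1)), 1L)
  expect_error(cluster_cohort(D, k = 20), "exceeds")
})

test_that("jackknife stability is high for well-separated archetypes", {
  co <- archetype_cohort_candidates(n_per_arch = 5, seed = 31)
  jk <- jackknife_stability(co$candidates, k = 5, leave_fraction = 0.1,
                            reps = 25, seed = 7)
  expect_gte(ari(jk$labels, co$archetype[names(jk$labels)]), 0.9)
  expect_true(all(jk$stability >= 0.8))
  jk2 <- jackknife_stability(co$candidates, k = 5, leave_fraction = 0.1,
                             reps = 25, seed = 7)
  expect_identical(jk, jk2)
})

test_that("the decision tree bins separable driver profiles", {
  set.seed(13)
  archs <- default_archetypes()
  events <- unique(unlist(lapply(archs, function(a) c(a$truncal, a$late))))
  profiles <- do.call(rbind, lapply(rep(seq_along(archs), 8), function(i) {
    as.integer(events %in% c(archs[[i]]$truncal, archs[[i]]$late))
  }))
  colnames(profiles) <- events
  labels <- rep(paste0("C", seq_along(archs)), 8)
  fit <- train_cluster_classifier(profiles, labels)
  pred <- assign_by_decision_tree(fit, profiles)
  expect_gte(mean(pred == labels), 0.9)
  # identical profiles get identical labels
  expect_equal(pred[1], pred[6])
  # unseen features are ignored; missing features treated absent
  empty <- matrix(0, 1, 1, dimnames = list(NULL, "NOVEL_EVENT"))
  expect_length(assign_by_decision_tree(fit, empty), 1)
})
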