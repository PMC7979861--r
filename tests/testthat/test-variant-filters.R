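test_that("dual-caller SNV rule uses an inclusive 2% VAF threshold", {
  v <- rbind(
    make_snv(pos = 1, tumour_alt = 3),                      # VAF 3% pass
    make_snv(pos = 2, tumour_alt = 2),                      # VAF 2% pass
    make_snv(pos = 3, tumour_alt = 1),                      # VAF 1% fail
    make_snv(pos = 4, tumour_alt = 3, somatic_p = 0.2),     # p too high
    make_snv(pos = 5, tumour_alt = 3, somatic_p = NA))      # missing p
  d <- consensus_filter_snv(v)
  expect_equal(d$status, c("pass", "pass", "fail", "fail", "fail"))
  expect_match(d$failed_rules[3], "caller-evidence")
})

test_that("single-caller rescue requires VAF strictly above 5%", {
  v <- rbind(
    make_snv(pos = 1, called_by = "callerB", tumour_alt = 4),  # 4% fail
    make_snv(pos = 2, called_by = "callerB", tumour_alt = 5),  # 5% fail
    make_snv(pos = 3, called_by = "callerB", tumour_alt = 6),  # 6% pass
    make_snv(pos = 4, called_by = "callerA", tumour_alt = 20)) # A-only
  d <- consensus_filter_snv(v)
  expect_equal(d$status, c("fail", "fail", "pass", "fail"))
})

test_that("normal-sample, blacklist and population rules veto SNVs", {
  v <- rbind(
    make_snv(pos = 1, normal_alt = 5, normal_depth = 1000),  # 5 alt reads
    make_snv(pos = 2, normal_alt = 4, normal_depth = 100),  # 4% normal VAF
    make_snv(pos = 3, blacklist_flag = TRUE),
    make_snv(pos = 4, pop_freq_db2 = 0.02),
    make_snv(pos = 5, pop_freq_db2 = 0.01),               # exactly 1%: keep
    make_snv(pos = 6, tumour_depth = 0, tumour_alt = 0))
  d <- consensus_filter_snv(v)
  expect_equal(d$status, c("fail", "fail", "fail", "fail", "pass", "fail"))
  expect_equal(d$failed_rules[1], "normal-alt-reads")
  expect_match(d$failed_rules[2], "normal-vaf")
  expect_equal(d$failed_rules[3], "blacklist")
  expect_equal(d$failed_rules[4], "population-frequency")
  expect_equal(d$failed_rules[6], "no-coverage")
})

test_that("indel thresholds are enforced at their stated boundaries", {
  base <- make_snv(ref = "C", alt = "CT", called_by = "callerB",
                   somatic_p = 0.04, tumour_depth = 60, tumour_alt = 12,
                   normal_alt = 1)
  cases <- rbind(
    base,
    transform(base, tumour_depth = 45),   # depth must be > 50
    transform(base, tumour_depth = 50),   # boundary excluded
    transform(base, tumour_alt = 10),     # alt must be > 10
    transform(base, normal_alt = 2),      # normal alt must be < 2
    transform(base, somatic_p = 0.06),
    transform(base, tumour_alt = 2))      # VAF below 5%
  d <- filter_indel(cases)
  expect_equal(d$status,
               c("pass", "fail", "fail", "fail", "fail", "fail", "fail"))
})

test_that("force-calling rescues qualifying negatives and only adds", {
  v <- rbind(
    make_snv(pos = 1, region_id = "R1", tumour_alt = 10),  # passes
    make_snv(pos = 1, region_id = "R2", tumour_alt = 3, somatic_p = 0.5),
    make_snv(pos = 1, region_id = "R3", tumour_alt = 1, somatic_p = 0.5),
    make_snv(pos = 1, region_id = "R4", tumour_alt = 10, somatic_p = 0.5,
             mapping_quality = 18))
  d <- filter_variants(v)
  st <- stats::setNames(d$status, d$region_id)
  expect_equal(unname(st[c("R1", "R2", "R3", "R4")]),
               c("pass", "force_called", "fail", "fail"))

  # monotone: force-calling never removes a pass
  before <- filter_variants(v)
  expect_true(all(before$status[before$status == "pass"] == "pass"))
})

test_that("filtering is a pure, order-independent function", {
  set.seed(3)
  v <- do.call(rbind, lapply(1:20, function(i) {
    make_snv(pos = i, tumour_alt = sample(0:12, 1),
             somatic_p = stats::runif(1, 0, 0.3),
             normal_alt = sample(0:6, 1))
  }))
  d1 <- consensus_filter_snv(v)
  perm <- sample(nrow(v))
  d2 <- consensus_filter_snv(v[perm, ])
  expect_equal(d2$status, d1$status[perm])
  expect_equal(consensus_filter_snv(v), d1)
})

test_that("VAF-peak purity check passes, excludes and abstains correctly", {
  set.seed(11)
  vafs <- stats::rbinom(500, 250, 0.25) / 250
  res <- purity_sanity_check(vafs, purity = 0.5)
  expect_equal(res$status, "pass")
  expect_lt(res$deviation, 0.03)

  low <- stats::rbinom(500, 250, 0.05) / 250
  expect_equal(purity_sanity_check(low, 0.5)$status, "exclude")
  expect_equal(purity_sanity_check(numeric(0), 0.5)$status,
               "indeterminate")
  expect_equal(purity_sanity_check(stats::runif(5), 0.5)$status,
               "indeterminate")
})

test_that("deleteriousness consensus follows the two-route rule", {
  expect_true(deleteriousness_consensus("D", "D", NA, NA))
  expect_true(deleteriousness_consensus("low-D", "D", "D", "D"))
  expect_false(deleteriousness_consensus(NA, NA, "D", NA))
  expect_false(deleteriousness_consensus("low-D", "D", "D", "T"))
  expect_false(deleteriousness_consensus("D", "T", "D", "D"))
  expect_equal(deleteriousness_consensus(c("D", "T"), c("D", "D"),
                                         c(NA, NA), c(NA, NA)),
               c(TRUE, FALSE))
})

test_that("driver flagging unions q-significant and curated-list genes", {
  q <- data.frame(gene = c("G1", "G2", "G3", "BAP1"),
                  q_method1 = c(0.04, 0.06, NA, 0.5),
                  q_method2 = c(0.9, 0.06, 0.01, 0.8),
                  stringsAsFactors = FALSE)
  flagged <- flag_drivers(q, mutated_genes = c("BAP1", "G2"))
  expect_setequal(flagged, c("G1", "G3", "BAP1"))
  expect_false("G2" %in% flagged)
})
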