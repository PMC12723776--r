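# Rare-variant enrichment

pair_fixture <- function(a, b, c, d) {
  # build a pair table with exact 2x2 counts for one class
  data.frame(
    individual_id = paste0("i", seq_len(a + b + c + d)),
    gene_id = "g",
    q_value = c(rep(0.01, a + b), rep(0.5, c + d)),
    outlier = c(rep(TRUE, a + b), rep(FALSE, c + d)),
    carrier_splice = c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c),
                       rep(FALSE, d)),
    stringsAsFactors = FALSE)
}

test_that("relative risk reproduces direct arithmetic and the null", {
  rr <- relative_risk(pair_fixture(4, 6, 99, 891), "splice")
  expect_equal(rr$rr, 4)
  expect_false(rr$haldane)
  expect_equal(rr$a + rr$b + rr$c + rr$d, 1000)
  # equal carrier rates -> rr = 1
  rr0 <- relative_risk(pair_fixture(5, 45, 10, 90), "splice")
  expect_equal(rr0$rr, 1)
  expect_true(rr0$ci_low < 1 && 1 < rr0$ci_high)
  # Katz CI on the 4.0 table, recomputed by hand
  se <- sqrt(1/4 - 1/10 + 1/99 - 1/990)
  expect_equal(rr$ci_low, exp(log(4) - qnorm(0.975) * se))
})

test_that("zero cells take the Haldane-Anscombe path and empty margins skip", {
  rr <- relative_risk(pair_fixture(3, 0, 10, 90), "splice")
  expect_true(rr$haldane)
  expect_true(is.finite(rr$rr) && rr$rr > 0)
  all_out <- pair_fixture(3, 7, 0, 0)[1:10, ]
  expect_warning(res <- relative_risk(all_out, "splice"), "empty margin")
  expect_null(res)
})

test_that("pair construction matches a hand count and closed-world defaults", {
  dots <- data.frame(
    sample_id = rep(c("i1", "i2", "i3"), each = 3),
    gene_id = rep(c("gA", "gB", "gC"), 3),
    a_count = 10, b_count = 10, total = 20, ref_sd_g = 0.2,
    p_value = 0.5, q_value = c(0.01, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    tested = c(rep(TRUE, 8), FALSE),
    outlier = c(TRUE, rep(FALSE, 8)), stringsAsFactors = FALSE)
  vars <- data.frame(individual_id = c("i1", "i2"), gene_id = c("gA", "gA"),
                     consequence_class = "splice", carries_rare = TRUE,
                     stringsAsFactors = FALSE)
  pr <- build_pairs(dots, vars, restrict_to_outlier_genes = TRUE)
  # gA is the only outlier gene; tested in all 3 individuals
  expect_equal(nrow(pr), 3)
  expect_identical(sort(unique(pr$gene_id)), "gA")
  expect_identical(pr$carrier_splice[order(pr$individual_id)],
                   c(TRUE, TRUE, FALSE))
  # without restriction, all tested pairs (8; the untested i3/gC drops)
  pr_all <- build_pairs(dots, vars, restrict_to_outlier_genes = FALSE)
  expect_equal(nrow(pr_all), 8)
  # never-outlier gene contributes nothing under restriction
  expect_false("gB" %in% pr$gene_id)
  expect_error(build_pairs(dots,
    data.frame(individual_id = "nobody", gene_id = "gA",
               consequence_class = "splice", carries_rare = TRUE)),
    "unmatched")
})

test_that("significance stratification nests thresholds and degenerates sanely", {
  set.seed(61)
  pr <- pair_fixture(8, 12, 40, 340)
  pr$q_value <- c(runif(20, 0, 0.05), runif(380, 0.05, 1))
  single <- enrichment_by_significance(pr, 0.05)
  direct <- relative_risk(pr, "splice")
  expect_equal(single$rr, direct$rr)
  expect_warning(es <- enrichment_by_significance(pr, c(0.05, 0.01)),
                 "unsorted")
  expect_equal(es$threshold, sort(es$threshold))
  # threshold 1.0 leaves no non-outlier pairs -> stratum skipped with warning
  expect_warning(out <- enrichment_by_significance(pr, 1.0), "empty margin")
  expect_null(out)
  # margins conserved at every threshold
  for (i in seq_len(nrow(es)))
    expect_equal(es$a[i] + es$b[i] + es$c[i] + es$d[i], nrow(pr))
})

test_that("planted carrier excess produces the expected enrichment", {
  cfg <- sim_config(seed = 62, n_genes = 60, n_individuals = 80,
                    outliers = list(fraction = 0.02, effect = NULL,
                                    monoallelic = TRUE),
                    variants = list(classes = "splice", base_rate = 0.1,
                                    outlier_rate = 0.8))
  sim <- simulate_population(cfg)
  vg <- data.frame(gene_id = names(sim$sd_g), sd_g = sim$sd_g)
  dc <- dot_cohort(sim$counts, vg)
  vt <- simulate_variant_table(sim$truth, cfg)
  pr <- build_pairs(dc$results, vt)
  rr <- relative_risk(pr, "splice")
  expect_gt(rr$ci_low, 1)  # significantly enriched
  # brute-force recount of the 2x2 table
  expect_equal(rr$a, sum(pr$outlier & pr$carrier_splice))
  expect_equal(rr$d, sum(!pr$outlier & !pr$carrier_splice))
})
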