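# Ground-truth simulator

test_that("identical configs give identical cohorts", {
  s1 <- toy_sim(seed = 81, n_genes = 15, n_individuals = 30)
  s2 <- toy_sim(seed = 81, n_genes = 15, n_individuals = 30)
  expect_identical(s1$counts$a, s2$counts$a)
  expect_identical(s1$truth, s2$truth)
  s3 <- toy_sim(seed = 82, n_genes = 15, n_individuals = 30)
  expect_false(identical(s1$counts$a, s3$counts$a))
})

test_that("sd_g = 0 leaves only binomial sampling noise", {
  sim <- toy_sim(seed = 83, n_genes = 50, n_individuals = 400, sd_g = 0,
                 coverage = list(type = "loguniform", min = 200, max = 201))
  tot <- hap_totals(sim$counts)
  r <- sim$counts$a / tot
  # each gene: Var(a/n) should be ~ p(1-p)/n = 0.25/200
  v <- apply(r, 1, var)
  expected <- 0.25 / 200
  se <- expected * sqrt(2 / (400 - 1))  # chi-square SE of a variance estimate
  expect_true(all(abs(v - expected) < 4 * se))
  expect_true(all(sim$truth$delta == 0 | !is.finite(sim$truth$delta) |
                    abs(sim$truth$delta) >= 0))
  expect_equal(unname(sim$sd_g[1]), 0)
})

test_that("logit allelic ratio SD matches the generative sd_g at deep coverage", {
  sim <- toy_sim(seed = 84, n_genes = 1, n_individuals = 10000, sd_g = 0.3,
                 coverage = list(type = "loguniform", min = 500, max = 3000))
  tot <- hap_totals(sim$counts)
  lr <- qlogis((sim$counts$a + 0.5) / (tot + 1))
  expect_lt(abs(sd(lr) - 0.3) / 0.3, 0.05)
})

test_that("planted outliers carry the requested effect", {
  sim <- toy_sim(seed = 85, n_genes = 30, n_individuals = 50,
                 outliers = list(fraction = 0.1, effect = 3,
                                 monoallelic = FALSE))
  tr <- sim$truth
  expect_gt(sum(tr$planted), 0)
  expect_true(all(abs(tr$delta[tr$planted]) == 3))
  mono <- toy_sim(seed = 86, n_genes = 10, n_individuals = 40,
                  outliers = list(fraction = 0.1, effect = NULL,
                                  monoallelic = TRUE))
  tot <- hap_totals(mono$counts)
  idx <- which(matrix(mono$truth$planted, 10, 40))
  expect_true(all(mono$counts$a[idx] == 0 | mono$counts$a[idx] == tot[idx]))
})

test_that("variant tables respect the per-class carrier rates", {
  cfg <- sim_config(seed = 87, n_genes = 50, n_individuals = 100,
                    outliers = list(fraction = 0.05, effect = 2,
                                    monoallelic = FALSE),
                    variants = list(classes = c("splice", "other"),
                                    base_rate = c(0.05, 0.2),
                                    outlier_rate = c(0.8, 0.2)))
  sim <- simulate_population(cfg)
  vt <- simulate_variant_table(sim$truth, cfg)
  key <- paste(sim$truth$sample_id, sim$truth$gene_id)
  planted <- sim$truth$planted
  carrier <- key %in% paste(vt$individual_id[vt$consequence_class == "splice"],
                            vt$gene_id[vt$consequence_class == "splice"])
  rate_out <- mean(carrier[planted])
  rate_base <- mean(carrier[!planted])
  expect_lt(abs(rate_out - 0.8), 3 * sqrt(0.8 * 0.2 / sum(planted)))
  expect_lt(abs(rate_base - 0.05), 3 * sqrt(0.05 * 0.95 / sum(!planted)))
  # determinism under the derived seed
  expect_identical(vt, simulate_variant_table(sim$truth, cfg))
})

test_that("config validation names offending fields", {
  expect_error(sim_config(sd_g = -1), "sd_g")
  expect_error(sim_config(coverage = list(type = "loguniform", min = 100,
                                          max = 10)), "coverage")
  expect_error(sim_config(outliers = list(fraction = 2, effect = 1,
                                          monoallelic = FALSE)), "outliers")
  expect_error(sim_config(variants = list(classes = "x", base_rate = 1.5,
                                          outlier_rate = 0.5)), "variants")
})

test_that("round trip: estimator recovers the simulator's generative SD", {
  sim <- toy_sim(seed = 88, n_genes = 12, n_individuals = 300, sd_g = 0.25)
  fm <- fit_matrix(sim$counts, B = 0)
  expect_equal(nrow(fm$estimates), 12)
  relerr <- abs(fm$estimates$sd_g - 0.25) / 0.25
  expect_lt(median(relerr), 0.15)
})
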