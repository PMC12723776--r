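# Per-gene regulatory SD estimation

make_counts <- function(tot_list) {
  # one gene per element of tot_list; balanced counts at those totals
  genes <- paste0("g", seq_along(tot_list))
  ncol <- max(lengths(tot_list))
  a <- b <- matrix(NA_real_, length(tot_list), ncol)
  for (i in seq_along(tot_list)) {
    t <- tot_list[[i]]
    a[i, seq_along(t)] <- floor(t / 2)
    b[i, seq_along(t)] <- ceiling(t / 2)
  }
  hap_counts(a, b, gene_ids = genes)
}

test_that("eligibility needs total >= 30 in at least six individuals", {
  cnt <- make_counts(list(rep(30, 6), rep(100, 5), rep(29, 200),
                          c(rep(30, 5), 29)))
  expect_identical(eligible_genes(cnt), "g1")
  empty <- hap_counts(matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0),
                      gene_ids = character(0), sample_ids = character(0))
  expect_identical(eligible_genes(empty), character(0))
})

test_that("perfectly balanced data pins sd_g to the lower search bound", {
  f <- fit_gene(rep(500, 50), rep(500, 50))
  expect_equal(f$sd_g, 1e-3)
  expect_true(f$at_bound)
  expect_equal(f$vg, f$sd_g^2 / 2)
})

test_that("bimodal extreme imbalance yields a large sd_g", {
  a <- rep(c(30, 0, 28, 1), 10)
  b <- rep(c(0, 30, 2, 29), 10)
  f <- fit_gene(a, b)
  expect_gt(f$sd_g, 1)
  bal <- fit_gene(rep(15, 40), rep(15, 40))
  expect_gt(f$sd_g, bal$sd_g)
})

test_that("optimum matches a brute-force grid search over sigma", {
  set.seed(21)
  sig_grid <- exp(seq(log(1e-3), log(5), length.out = 2000))
  for (rep in 1:6) {
    n <- round(exp(runif(40, log(30), log(300))))
    true_sd <- runif(1, 0.05, 1)
    a <- rbln(40, n, 0, true_sd)
    f <- fit_gene(a, n - a)
    ll <- vapply(sig_grid, function(s) sum(dbln(a, n, 0, s, log = TRUE)),
                 numeric(1))
    best <- sig_grid[which.max(ll)]
    step <- log(sig_grid[2]) - log(sig_grid[1])
    expect_lt(abs(log(f$sd_g) - log(best)), 1.5 * step)
  }
})

test_that("estimates are invariant to swapping haplotype labels", {
  set.seed(22)
  n <- round(exp(runif(80, log(30), log(1000))))
  a <- rbln(80, n, 0, 0.3)
  b <- n - a
  f1 <- fit_gene(a, b)
  swap <- seq_len(80) %% 3 == 0
  a2 <- ifelse(swap, b, a)
  f2 <- fit_gene(a2, n - a2)
  expect_equal(f1$sd_g, f2$sd_g, tolerance = 1e-8)
})

test_that("too few usable individuals yields a skip, not an estimate", {
  f <- fit_gene(c(20, 20, 20, 20, 20), c(20, 20, 20, 20, 20))
  expect_s3_class(f, "vg_skip")
  expect_match(f$reason, "need 6")
})

test_that("bootstrap CI is deterministic, bracketing, and defined at B = 2", {
  set.seed(23)
  n <- round(exp(runif(100, log(30), log(1000))))
  a <- rbln(100, n, 0, 0.25)
  f <- fit_gene(a, n - a)
  c1 <- bootstrap_ci(f, B = 50, seed = 99)
  c2 <- bootstrap_ci(f, B = 50, seed = 99)
  expect_identical(c1$ci_low, c2$ci_low)
  expect_identical(c1$ci_high, c2$ci_high)
  expect_true(c1$ci_low <= c1$sd_g && c1$sd_g <= c1$ci_high)
  c3 <- bootstrap_ci(f, B = 2, seed = 1)
  expect_equal(c3$ci_low, min(c3$boot_sd, c3$sd_g))
  expect_equal(c3$ci_high, max(c3$boot_sd, c3$sd_g))
  expect_error(bootstrap_ci(f, B = 1), "B")
})

test_that("CI width shrinks with cohort size", {
  set.seed(24)
  widths <- vapply(c(30, 100, 600), function(N) {
    w <- replicate(8, {
      n <- round(exp(runif(N, log(30), log(3000))))
      a <- rbln(N, n, 0, 0.2)
      f <- bootstrap_ci(fit_gene(a, n - a), B = 60, seed = sample.int(1e6, 1))
      f$ci_high - f$ci_low
    })
    mean(w)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("fit_matrix conserves genes, logs skips, and is worker-invariant", {
  sim <- toy_sim(seed = 31, n_genes = 25, n_individuals = 60)
  # force 5 genes below coverage
  low <- sim$counts
  low$a[1:5, ] <- 1; low$b[1:5, ] <- 1
  res <- fit_matrix(low, B = 10, seed = 5)
  expect_equal(nrow(res$estimates), 20)
  expect_equal(nrow(res$skipped), 5)
  expect_identical(res$estimates$gene_id, low$gene_ids[6:25])
  expect_true(all(res$estimates$n_eligible >= 6))
  res4 <- fit_matrix(low, B = 10, seed = 5, workers = 4)
  expect_identical(res, res4)
})

test_that("parameter recovery at moderate scale", {
  set.seed(25)
  ests <- replicate(12, {
    n <- round(exp(runif(600, log(30), log(3000))))
    a <- rbln(600, n, 0, 0.2)
    fit_gene(a, n - a)$sd_g
  })
  expect_lt(median(abs(ests - 0.2) / 0.2), 0.10)
})
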