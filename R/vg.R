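# Per-gene regulatory variance (V^G) estimation ---------------------------

#' Genes eligible for regulatory variance estimation
#'
#' A gene is eligible when at least `min_individuals` individuals have total
#' haplotype coverage (`a + b`) of at least `min_total`.
#'
#' @param counts a [hap_counts()] object.
#' @param min_total minimum per-individual total coverage (default 30).
#' @param min_individuals minimum number of individuals reaching it
#'   (default 6).
#' @return character vector of eligible gene ids, in input order.
#' @export
eligible_genes <- function(counts, min_total = 30, min_individuals = 6) {
  stopifnot(inherits(counts, "hap_counts"))
  stopifnot_scalar_count(min_total, "min_total", min = 1L)
  stopifnot_scalar_count(min_individuals, "min_individuals", min = 1L)
  tot <- hap_totals(counts)
  ok <- rowSums(!is.na(tot) & tot >= min_total) >= min_individuals
  counts$gene_ids[ok]
}

# sigma search bounds in log allelic fold change; estimates at a bound are
# flagged via `converged = FALSE` plus `at_bound`.
SIGMA_MIN <- 1e-3
SIGMA_MAX <- 5

#' Fit the regulatory SD of one gene
#'
#' Maximum-likelihood estimate of `sd_g`, the standard deviation of the latent
#' log allelic fold change across individuals, under the symmetric (`mu = 0`)
#' binomial-logit-normal model.  The likelihood is the product over
#' individuals of the BLN pmf at the observed haplotype-A count given the
#' individual's total, maximized over `sigma` by Brent search on `log(sigma)`
#' within `[1e-3, 5]`.
#'
#' Individuals with total coverage below `min_count_in_fit` are dropped before
#' fitting; if fewer than `min_individuals` remain the gene is skipped and a
#' `vg_skip` record (`gene_id`, `reason`) is returned instead of an estimate.
#'
#' @param a,b per-individual haplotype counts (equal-length integer vectors;
#'   `NA` pairs are dropped).
#' @param gene_id identifier carried into the result.
#' @param min_count_in_fit minimum per-individual total entering the
#'   likelihood (default 10, matching the outlier-test coverage threshold).
#' @param min_individuals minimum usable individuals (default 6).
#' @param quad_order Gauss-Hermite order for the fit (default 25; the
#'   mode-centred rule makes this equivalent to much higher plain orders).
#' @return a `vg_fit` list: `gene_id`, `sd_g`, `vg` (`= sd_g^2 / 2`,
#'   per-haplotype variance convention), `loglik`, `n_used`, `n_eligible`,
#'   `converged`, `at_bound`, `ci_low`/`ci_high` (`NA` until
#'   [bootstrap_ci()]), plus the filtered data for bootstrapping.
#' @seealso [bootstrap_ci()], [fit_matrix()]
#' @export
fit_gene <- function(a, b, gene_id = NA_character_, min_count_in_fit = 10,
                     min_individuals = 6, quad_order = 25) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- as.numeric(a[keep]); b <- as.numeric(b[keep])
  n <- a + b
  n_eligible <- sum(n >= 30)
  use <- n >= min_count_in_fit
  if (sum(use) < min_individuals) {
    return(structure(list(gene_id = gene_id,
                          reason = sprintf(
                            "only %d individuals with total >= %d (need %d)",
                            sum(use), min_count_in_fit, min_individuals)),
                     class = "vg_skip"))
  }
  a <- a[use]; n <- n[use]
  rule <- gh_rule(quad_order)
  fit <- bln_fit_sigma_cpp(a, n, SIGMA_MIN, SIGMA_MAX, rule$t, rule$logw,
                           tol = 1e-6)
  at_bound <- fit$at_lower || fit$at_upper
  structure(list(
    gene_id = gene_id,
    sd_g = fit$sigma,
    vg = fit$sigma^2 / 2,
    ci_low = NA_real_,
    ci_high = NA_real_,
    loglik = fit$loglik,
    n_used = length(a),
    n_eligible = n_eligible,
    converged = TRUE,
    at_bound = at_bound,
    quad_order = quad_order,
    a = a,
    totals = n
  ), class = "vg_fit")
}

#' @export
print.vg_fit <- function(x, ...) {
  cat(sprintf("vg_fit %s: sd_g = %.4g (vg = %.4g), n_used = %d%s\n",
              x$gene_id, x$sd_g, x$vg, x$n_used,
              if (x$at_bound) " [at search bound]" else ""))
  if (!is.na(x$ci_low))
    cat(sprintf("  95%% bootstrap CI: [%.4g, %.4g]\n", x$ci_low, x$ci_high))
  invisible(x)
}

#' Parametric bootstrap confidence interval for sd_g
#'
#' Resamples haplotype counts conditional on the observed totals (coverage is
#' ancillary to regulatory variance) from the fitted BLN law, refits each
#' replicate, and takes the percentile interval of the resampled estimates.
#' `ci_low`/`ci_high` are clipped to bracket the point estimate so the
#' `ci_low <= sd_g <= ci_high` invariant always holds.
#'
#' @param fit a [fit_gene()] result.
#' @param B number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer; when given the CI is a deterministic function
#'   of `(fit, B, level, seed)`.
#' @return the `vg_fit` with `ci_low`, `ci_high` and `boot_sd` (the resampled
#'   estimates) filled in.
#' @export
bootstrap_ci <- function(fit, B = 1000, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "vg_fit"))
  stopifnot_scalar_count(B, "B", min = 2L)
  stopifnot(level > 0, level < 1)
  rule <- gh_rule(fit$quad_order)
  boot <- with_seed(seed,
    bln_bootstrap_cpp(fit$totals, fit$sd_g, B, SIGMA_MIN, SIGMA_MAX,
                      rule$t, rule$logw, tol = 1e-4))
  qs <- unname(quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 1))
  fit$ci_low <- min(qs[1], fit$sd_g)
  fit$ci_high <- max(qs[2], fit$sd_g)
  fit$boot_sd <- boot
  fit
}

vg_estimate_row <- function(fit) {
  data.frame(gene_id = fit$gene_id, sd_g = fit$sd_g, vg = fit$vg,
             ci_low = fit$ci_low, ci_high = fit$ci_high,
             n_used = fit$n_used, n_eligible = fit$n_eligible,
             converged = fit$converged, at_bound = fit$at_bound,
             loglik = fit$loglik, stringsAsFactors = FALSE)
}

#' Fit regulatory variance for every eligible gene in a cohort
#'
#' Applies the eligibility filter (total `>= min_total` in
#' `>= min_individuals` individuals), fits `sd_g` per gene, and optionally
#' attaches parametric-bootstrap CIs.  Genes failing eligibility are returned
#' in a skip log with reasons.  Per-gene bootstrap seeds are derived from
#' `seed` and the gene's position, so results are identical for any number of
#' workers and any merge order.
#'
#' @param counts a [hap_counts()] object.
#' @param min_total,min_individuals eligibility thresholds (defaults 30 / 6).
#' @param min_count_in_fit per-individual coverage floor inside the
#'   likelihood (default 10).
#' @param B bootstrap replicates per gene; `B = 0` skips CIs.
#' @param level CI level.
#' @param seed integer master seed for the bootstrap streams.
#' @param workers number of parallel workers ([parallel::mclapply()]).
#' @param quad_order Gauss-Hermite order for fits.
#' @return list with `estimates` (one data.frame row per fitted gene, input
#'   gene order) and `skipped` (`gene_id`, `reason`).
#' @export
fit_matrix <- function(counts, min_total = 30, min_individuals = 6,
                       min_count_in_fit = 10, B = 1000, level = 0.95,
                       seed = 1L, workers = 1L, quad_order = 25) {
  stopifnot(inherits(counts, "hap_counts"))
  elig <- eligible_genes(counts, min_total, min_individuals)
  inel <- setdiff(counts$gene_ids, elig)
  skipped <- data.frame(gene_id = inel,
                        reason = rep(sprintf("fewer than %d individuals with total >= %d",
                                             min_individuals, min_total),
                                     length(inel)),
                        stringsAsFactors = FALSE)
  if (length(elig) == 0L) {
    warning("no genes pass the eligibility filter")
    return(list(estimates = vg_estimate_row(
      structure(list(gene_id = character(0), sd_g = numeric(0), vg = numeric(0),
                     ci_low = numeric(0), ci_high = numeric(0),
                     n_used = integer(0), n_eligible = integer(0),
                     converged = logical(0), at_bound = logical(0),
                     loglik = numeric(0)), class = "vg_fit")),
      skipped = skipped))
  }
  idx <- match(elig, counts$gene_ids)
  fit_one <- function(k) {
    g <- idx[k]
    fit <- fit_gene(counts$a[g, ], counts$b[g, ], gene_id = counts$gene_ids[g],
                    min_count_in_fit = min_count_in_fit,
                    min_individuals = min_individuals,
                    quad_order = quad_order)
    if (inherits(fit, "vg_skip"))
      return(data.frame(gene_id = fit$gene_id, reason = fit$reason,
                        stringsAsFactors = FALSE))
    if (B > 0)
      fit <- bootstrap_ci(fit, B = B, level = level,
                          seed = (seed + 7919 * k) %% .Machine$integer.max)
    vg_estimate_row(fit)
  }
  res <- if (workers > 1L) {
    parallel::mclapply(seq_along(idx), fit_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_along(idx), fit_one)
  }
  is_skip <- vapply(res, function(r) "reason" %in% names(r), logical(1))
  if (any(is_skip))
    skipped <- rbind(skipped, do.call(rbind, res[is_skip]))
  estimates <- if (all(is_skip)) NULL else do.call(rbind, res[!is_skip])
  if (is.null(estimates))
    warning("no genes could be fitted")
  list(estimates = estimates, skipped = skipped)
}
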