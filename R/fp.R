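# False-positive-prone gene screening -------------------------------------

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided exact interval on a binomial proportion via beta quantiles:
#' `low = qbeta((1 - level)/2, k, m - k + 1)` (0 when `k = 0`) and
#' `high = qbeta(1 - (1 - level)/2, k + 1, m - k)` (1 when `k = m`).
#'
#' @param k successes (vectorized).
#' @param m trials (`>= 1`).
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `low`, `high`.
#' @export
clopper_pearson <- function(k, m, level = 0.95) {
  kk <- max(length(k), length(m))
  k <- rep_len(k, kk); m <- rep_len(m, kk)
  if (any(m < 1) || any(k < 0) || any(k > m))
    stop("need 0 <= k <= m and m >= 1", call. = FALSE)
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  low <- ifelse(k == 0, 0, qbeta(a, k, m - k + 1))
  high <- ifelse(k == m, 1, qbeta(1 - a, k + 1, m - k))
  data.frame(low = low, high = high)
}

#' Screen for false-positive-prone genes
#'
#' A gene repeatedly called a dosage outlier across unrelated cohort samples
#' is more likely a modelling artifact than shared rare regulatory variation.
#' For each gene this computes the cohort outlier rate `k/m` (outlier calls
#' over samples tested), its exact Clopper-Pearson interval, and flags the
#' gene when the lower bound exceeds `threshold` (default 1%).  A two-sided
#' exact binomial test against `rate = threshold` is reported for information;
#' the flag is driven solely by the lower CI bound.
#'
#' @param dot_results cohort test records ([dot_cohort()]`$results` or a
#'   row-bound set of [dot_sample()] tables).
#' @param threshold outlier-rate threshold on the lower bound (default 0.01).
#' @param level confidence level of the interval (default 0.95).
#' @return data.frame with one row per gene tested in at least one sample:
#'   `gene_id`, `m`, `k`, `rate`, `cp_low`, `cp_high`, `binom_p`, `flagged`;
#'   the flagged gene ids are also attached as `attr(, "exclusion_list")`.
#' @export
screen_fp_genes <- function(dot_results, threshold = 0.01, level = 0.95) {
  tested <- dot_results[dot_results$tested, , drop = FALSE]
  if (nrow(tested) == 0L) {
    out <- data.frame(gene_id = character(0), m = integer(0), k = integer(0),
                      rate = numeric(0), cp_low = numeric(0),
                      cp_high = numeric(0), binom_p = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE)
    attr(out, "exclusion_list") <- character(0)
    return(out)
  }
  genes <- unique(tested$gene_id)
  m <- as.integer(table(factor(tested$gene_id, levels = genes)))
  k <- as.integer(tapply(tested$outlier, factor(tested$gene_id, levels = genes),
                         sum))
  ci <- clopper_pearson(k, m, level)
  binom_p <- mapply(function(ki, mi)
    binom.test(ki, mi, p = threshold)$p.value, k, m)
  out <- data.frame(gene_id = genes, m = m, k = k, rate = k / m,
                    cp_low = ci$low, cp_high = ci$high,
                    binom_p = binom_p, flagged = ci$low > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "exclusion_list") <- out$gene_id[out$flagged]
  out
}
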