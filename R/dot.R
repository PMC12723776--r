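# Dosage outlier test (per-sample, BLN null) ------------------------------

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with the standard cumulative-minimum handling of
#' ties, preserving input order (delegates to [stats::p.adjust()]).
#'
#' @param p p-values in `(0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Dosage outlier test for one sample
#'
#' For every gene with total coverage `>= min_coverage`, a reference `sd_g`,
#' and membership in the FDR gene universe (typically protein-coding +
#' lncRNA), tests the observed haplotype imbalance against the population
#' null `BLN(n = a + b, mu = 0, sigma = sd_g)` with the two-sided doubled-tail
#' p-value, then BH-adjusts within the sample over tested genes only.
#' Genes present but untestable are kept with `tested = FALSE` as an audit
#' trail rather than dropped.
#'
#' @param sample_counts data.frame with columns `gene_id`, `a_count`,
#'   `b_count` (one row per gene of one sample).
#' @param vg_reference data.frame keyed by `gene_id` with column `sd_g`
#'   (e.g. `fit_matrix()$estimates` or [read_vg_table()]).
#' @param gene_universe character vector of gene ids over which FDR is
#'   controlled; `NULL` means all genes.
#' @param sample_id identifier carried into the result.
#' @param min_coverage minimum total reads to test a gene (default 10).
#' @param alpha outlier q-value threshold (default 0.05).
#' @param exclude optional gene ids (e.g. a false-positive-prone list) to
#'   leave untested.
#' @return data.frame of per-gene test records: `sample_id`, `gene_id`,
#'   `a_count`, `b_count`, `total`, `ref_sd_g`, `p_value`, `q_value`,
#'   `tested`, `outlier`.
#' @export
dot_sample <- function(sample_counts, vg_reference, gene_universe = NULL,
                       sample_id = NA_character_, min_coverage = 10,
                       alpha = 0.05, exclude = NULL) {
  need <- c("gene_id", "a_count", "b_count")
  if (!all(need %in% names(sample_counts)))
    stop("`sample_counts` needs columns: ",
         paste(setdiff(need, names(sample_counts)), collapse = ", "),
         call. = FALSE)
  sc <- sample_counts[!is.na(sample_counts$a_count) &
                        !is.na(sample_counts$b_count), , drop = FALSE]
  total <- sc$a_count + sc$b_count
  ref <- vg_reference$sd_g[match(sc$gene_id, vg_reference$gene_id)]
  in_univ <- if (is.null(gene_universe)) rep(TRUE, nrow(sc))
             else sc$gene_id %in% gene_universe
  tested <- total >= min_coverage & !is.na(ref) & in_univ &
    !(sc$gene_id %in% exclude)
  out <- data.frame(sample_id = sample_id, gene_id = sc$gene_id,
                    a_count = sc$a_count, b_count = sc$b_count,
                    total = total, ref_sd_g = ref,
                    p_value = NA_real_, q_value = NA_real_,
                    tested = tested, outlier = FALSE,
                    stringsAsFactors = FALSE)
  if (!any(tested)) {
    if (nrow(out) > 0L)
      warning("no testable genes in sample ", sample_id)
    return(out)
  }
  p <- bln_two_sided_p(sc$a_count[tested], total[tested],
                       mu = 0, sigma = ref[tested])
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1] after underflow
  out$p_value[tested] <- p
  out$q_value[tested] <- bh_adjust(p)
  out$outlier[tested] <- out$q_value[tested] <= alpha
  out
}

#' Dosage outlier test across a cohort
#'
#' Applies [dot_sample()] independently to every sample of a count matrix and
#' summarizes tested genes, outliers, and the positivity rate per sample.
#'
#' @param counts a [hap_counts()] object.
#' @inheritParams dot_sample
#' @param workers parallel workers for the per-sample loop; results are merged
#'   in sample order, so the output is independent of `workers`.
#' @return list with `results` (row-bound [dot_sample()] tables) and `summary`
#'   (`sample_id`, `n_tested`, `n_outliers`, `positivity_rate`).
#' @export
dot_cohort <- function(counts, vg_reference, gene_universe = NULL,
                       min_coverage = 10, alpha = 0.05, exclude = NULL,
                       workers = 1L) {
  stopifnot(inherits(counts, "hap_counts"))
  run_one <- function(j) {
    dot_sample(data.frame(gene_id = counts$gene_ids,
                          a_count = counts$a[, j], b_count = counts$b[, j],
                          stringsAsFactors = FALSE),
               vg_reference, gene_universe,
               sample_id = counts$sample_ids[j],
               min_coverage = min_coverage, alpha = alpha, exclude = exclude)
  }
  per_sample <- if (workers > 1L) {
    parallel::mclapply(seq_along(counts$sample_ids), run_one,
                       mc.cores = workers)
  } else {
    lapply(seq_along(counts$sample_ids), run_one)
  }
  results <- do.call(rbind, per_sample)
  summary <- data.frame(
    sample_id = counts$sample_ids,
    n_tested = vapply(per_sample, function(r) sum(r$tested), integer(1)),
    n_outliers = vapply(per_sample, function(r) sum(r$outlier), integer(1)),
    stringsAsFactors = FALSE)
  summary$positivity_rate <-
    ifelse(summary$n_tested > 0, summary$n_outliers / summary$n_tested, NA_real_)
  list(results = results, summary = summary)
}
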