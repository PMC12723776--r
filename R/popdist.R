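# Cross-population comparison of regulatory variance ----------------------

#' Confidence-interval-overlap similarity between populations
#'
#' For each population pair and each gene present in every population's
#' estimate table, scores 1 when the two genes' `[ci_low, ci_high]` intervals
#' intersect (closed intervals: touching endpoints overlap) and 0 otherwise,
#' then averages over the common genes.  A value of 1 means complete overlap
#' of the variance CIs across all common genes; `D = 1 - S` is the matching
#' distance.
#'
#' @param vgs named list mapping population id to a V^G estimate table
#'   (columns `gene_id`, `ci_low`, `ci_high`).
#' @return list with `S` (similarity matrix), `D` (`1 - S`), and
#'   `common_genes`.
#' @export
ci_overlap_similarity <- function(vgs) {
  if (length(vgs) < 2L) stop("need at least two populations", call. = FALSE)
  if (is.null(names(vgs)) || anyDuplicated(names(vgs)))
    stop("`vgs` must be a uniquely named list", call. = FALSE)
  common <- Reduce(intersect, lapply(vgs, function(v) v$gene_id))
  if (length(common) == 0L) stop("no genes common to all populations",
                                 call. = FALSE)
  lows <- vapply(vgs, function(v) v$ci_low[match(common, v$gene_id)],
                 numeric(length(common)))
  highs <- vapply(vgs, function(v) v$ci_high[match(common, v$gene_id)],
                  numeric(length(common)))
  if (length(common) == 1L) { lows <- rbind(lows); highs <- rbind(highs) }
  np <- length(vgs)
  S <- diag(1, np)
  dimnames(S) <- list(names(vgs), names(vgs))
  for (i in seq_len(np - 1L)) {
    for (j in seq(i + 1L, np)) {
      ov <- pmax(lows[, i], lows[, j]) <= pmin(highs[, i], highs[, j])
      S[i, j] <- S[j, i] <- mean(ov)
    }
  }
  list(S = S, D = 1 - S, common_genes = common)
}

#' Cross-population dosage outlier matrix
#'
#' Runs the dosage outlier test on every (test population, reference
#' population) combination and records the median per-sample outlier count,
#' plus the fold increase relative to the ancestry-matched diagonal cell.
#' Ancestry mismatch between the tested samples and the variance reference
#' inflates outlier calls; this matrix quantifies that inflation.
#'
#' @param ase_by_pop named list mapping population id to a [hap_counts()]
#'   object (the samples to test).
#' @param vgs named list mapping population id to a V^G reference table
#'   (columns `gene_id`, `sd_g`).
#' @inheritParams dot_sample
#' @return list with `median_outliers` (test populations in rows, reference
#'   populations in columns; `NA` where a reference is missing) and
#'   `fold_increase` (each row divided by its diagonal entry).
#' @export
cross_population_dot <- function(ase_by_pop, vgs, gene_universe = NULL,
                                 min_coverage = 10, alpha = 0.05) {
  pops_t <- names(ase_by_pop); pops_r <- names(vgs)
  if (is.null(pops_t) || is.null(pops_r))
    stop("`ase_by_pop` and `vgs` must be named lists", call. = FALSE)
  M <- matrix(NA_real_, length(pops_t), length(pops_r),
              dimnames = list(pops_t, pops_r))
  for (tp in pops_t) {
    for (rp in pops_r) {
      if (is.null(vgs[[rp]])) next
      res <- dot_cohort(ase_by_pop[[tp]], vgs[[rp]], gene_universe,
                        min_coverage = min_coverage, alpha = alpha)
      M[tp, rp] <- median(res$summary$n_outliers)
    }
  }
  diag_cells <- vapply(pops_t, function(tp)
    if (tp %in% pops_r) M[tp, tp] else NA_real_, numeric(1))
  fold <- sweep(M, 1L, diag_cells, "/")
  list(median_outliers = M, fold_increase = fold)
}

#' Average-linkage clustering of the CI-overlap distance
#'
#' Convenience wrapper for visualizing population structure in the variance
#' estimates; the linkage choice is cosmetic and not part of any tested
#' contract.
#'
#' @param D distance matrix from [ci_overlap_similarity()].
#' @return an [stats::hclust()] tree.
#' @export
popdist_hclust <- function(D) {
  stats::hclust(stats::as.dist(D), method = "average")
}
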