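# Rare-variant enrichment among dosage outliers ---------------------------

#' Join outlier calls with rare-variant carrier status
#'
#' Builds the (individual, gene) pair table underlying the enrichment
#' statistics: tested pairs only, restricted (by default) to genes that are a
#' significant outlier in at least one individual, each pair labelled
#' outlier/non-outlier and carrier/non-carrier per consequence class.  Pairs
#' with no variant record are non-carriers in every class (closed-world
#' default).
#'
#' @param dot_results cohort test records ([dot_cohort()]`$results`).
#' @param variants data.frame with columns `individual_id`, `gene_id`,
#'   `consequence_class`, `carries_rare`; one row per (individual, gene,
#'   class).
#' @param restrict_to_outlier_genes keep only genes outlying somewhere
#'   (default `TRUE`).
#' @return data.frame of pairs: `individual_id`, `gene_id`, `q_value`,
#'   `outlier`, plus one logical `carrier_<class>` column per consequence
#'   class present in `variants`.
#' @export
build_pairs <- function(dot_results, variants,
                        restrict_to_outlier_genes = TRUE) {
  need <- c("individual_id", "gene_id", "consequence_class", "carries_rare")
  if (!all(need %in% names(variants)))
    stop("`variants` needs columns: ",
         paste(setdiff(need, names(variants)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(variants[c("individual_id", "gene_id",
                               "consequence_class")]))
    stop("duplicate (individual, gene, class) variant records", call. = FALSE)
  tested <- dot_results[dot_results$tested, , drop = FALSE]
  unmatched <- setdiff(unique(variants$individual_id),
                       unique(tested$sample_id))
  if (length(unmatched) == length(unique(variants$individual_id)) &&
      nrow(variants) > 0L && nrow(tested) > 0L)
    stop("no variant individual matches any tested sample; first unmatched: ",
         unmatched[1], call. = FALSE)
  if (restrict_to_outlier_genes) {
    keep <- unique(tested$gene_id[tested$outlier])
    tested <- tested[tested$gene_id %in% keep, , drop = FALSE]
  }
  pairs <- data.frame(individual_id = tested$sample_id,
                      gene_id = tested$gene_id,
                      q_value = tested$q_value,
                      outlier = tested$outlier,
                      stringsAsFactors = FALSE)
  classes <- sort(unique(variants$consequence_class))
  key <- paste(pairs$individual_id, pairs$gene_id, sep = "\r")
  for (cl in classes) {
    v <- variants[variants$consequence_class == cl & variants$carries_rare, ,
                  drop = FALSE]
    pairs[[paste0("carrier_", cl)]] <-
      key %in% paste(v$individual_id, v$gene_id, sep = "\r")
  }
  pairs
}

katz_ci <- function(a, b, c, d, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  lrr <- log((a / (a + b)) / (c / (c + d)))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  c(exp(lrr - z * se), exp(lrr + z * se))
}

#' Relative risk of rare-variant carriage among outliers
#'
#' From the 2x2 table of outlier status versus carrier status for one
#' consequence class, computes the risk ratio
#' `rr = (a / (a + b)) / (c / (c + d))` (carrier rate among outlier pairs over
#' carrier rate among non-outlier pairs) with a 95% Katz log-normal CI.  The
#' sampling odds ratio is reported alongside.  Zero cells are handled by the
#' Haldane-Anscombe correction (+0.5 on all four cells, recorded in the
#' output).
#'
#' @param pairs a [build_pairs()] table.
#' @param class consequence class (matching a `carrier_<class>` column).
#' @param conf CI level.
#' @return one-row data.frame: `stratum`, `a`, `b`, `c`, `d`, `rr`, `ci_low`,
#'   `ci_high`, `odds_ratio`, `haldane`.
#' @export
relative_risk <- function(pairs, class, conf = 0.95) {
  col <- paste0("carrier_", class)
  if (!col %in% names(pairs))
    stop("no carrier column for class ", class, call. = FALSE)
  carrier <- pairs[[col]]
  a <- sum(pairs$outlier & carrier)
  b <- sum(pairs$outlier & !carrier)
  c <- sum(!pairs$outlier & carrier)
  d <- sum(!pairs$outlier & !carrier)
  if (a + b < 1 || c + d < 1) {
    warning("empty margin for class ", class, "; stratum skipped")
    return(NULL)
  }
  haldane <- any(c(a, b, c, d) == 0)
  aa <- a + 0.5 * haldane; bb <- b + 0.5 * haldane
  cc <- c + 0.5 * haldane; dd <- d + 0.5 * haldane
  rr <- (aa / (aa + bb)) / (cc / (cc + dd))
  ci <- katz_ci(aa, bb, cc, dd, conf)
  data.frame(stratum = class, a = a, b = b, c = c, d = d,
             rr = rr, ci_low = ci[1], ci_high = ci[2],
             odds_ratio = (aa * dd) / (bb * cc),
             haldane = haldane, stringsAsFactors = FALSE)
}

#' Enrichment stratified by outlier significance threshold
#'
#' Recomputes the outlier label of every tested pair at each q-value
#' threshold and evaluates [relative_risk()] per (threshold, class).  Pairs
#' outlying at a stricter threshold are a subset of those at a looser one.
#'
#' @param pairs a [build_pairs()] table (its `q_value` column is used).
#' @param thresholds q-value thresholds; sorted internally (with a warning if
#'   unsorted).
#' @param classes consequence classes; default: every carrier column.
#' @param conf CI level.
#' @return data.frame of [relative_risk()] rows with a `threshold` column.
#' @export
enrichment_by_significance <- function(pairs, thresholds = c(0.05),
                                       classes = NULL, conf = 0.95) {
  if (is.unsorted(thresholds)) {
    warning("`thresholds` were unsorted; sorting")
    thresholds <- sort(thresholds)
  }
  if (is.null(classes))
    classes <- sub("^carrier_", "",
                   grep("^carrier_", names(pairs), value = TRUE))
  out <- list()
  for (th in thresholds) {
    p2 <- pairs
    p2$outlier <- !is.na(p2$q_value) & p2$q_value <= th
    for (cl in classes) {
      r <- relative_risk(p2, cl, conf)
      if (!is.null(r)) {
        r$threshold <- th
        out[[length(out) + 1L]] <- r
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}
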