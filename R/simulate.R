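# Ground-truth simulator ---------------------------------------------------
#
# Emulates population haplotype-level ASE under the same generative law the
# estimator assumes: per gene a regulatory SD sd_g, per individual a latent
# log allelic fold change delta ~ Normal(0, sd_g^2), and haplotype-A counts
# binomial given the total coverage.  Planted outlier cells and rare-variant
# carrier tables give every downstream module a known truth to recover.

#' Simulation configuration
#'
#' @param seed integer master seed; identical configs give identical output.
#' @param n_genes,n_individuals cohort dimensions.
#' @param sd_g per-gene regulatory SD law: a single value, a numeric vector
#'   recycled across genes, or `list(type = "lognormal", meanlog, sdlog)`.
#' @param coverage total-read law: `list(type = "loguniform", min = 30,
#'   max = 3000)` (default: spans the eligibility threshold through deep
#'   coverage) or `list(type = "negbin", mu, size, min)`.
#' @param outliers planted dosage-outlier cells: `list(fraction = 0,
#'   effect = NULL, monoallelic = FALSE)`.  A planted cell replaces delta by
#'   `±effect` (random sign; haplotype labels are arbitrary) or forces
#'   complete monoallelic expression.
#' @param variants rare-variant carrier law for [simulate_variant_table()]:
#'   `list(classes, base_rate, outlier_rate)`, with carrier probabilities per
#'   class given non-outlier / planted-outlier status (scalars or per-class
#'   vectors).
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 100L, n_individuals = 200L,
                       sd_g = 0.2,
                       coverage = list(type = "loguniform", min = 30,
                                       max = 3000),
                       outliers = list(fraction = 0, effect = NULL,
                                       monoallelic = FALSE),
                       variants = list(classes = c("splice", "stop_gained",
                                                   "missense", "other"),
                                       base_rate = 0.05,
                                       outlier_rate = 0.05)) {
  stopifnot_scalar_count(seed, "seed")
  stopifnot_scalar_count(n_genes, "n_genes", min = 1L)
  stopifnot_scalar_count(n_individuals, "n_individuals", min = 1L)
  bad <- character(0)
  if (is.list(sd_g)) {
    if (!identical(sd_g$type, "lognormal") || !is.numeric(sd_g$meanlog) ||
        !is.numeric(sd_g$sdlog))
      bad <- c(bad, "sd_g")
  } else if (!is.numeric(sd_g) || any(sd_g < 0) || any(!is.finite(sd_g))) {
    bad <- c(bad, "sd_g")
  }
  if (!is.list(coverage) ||
      !(identical(coverage$type, "loguniform") &&
          is.numeric(coverage$min) && is.numeric(coverage$max) &&
          coverage$min >= 1 && coverage$max >= coverage$min ||
        identical(coverage$type, "negbin") &&
          is.numeric(coverage$mu) && is.numeric(coverage$size)))
    bad <- c(bad, "coverage")
  if (!is.numeric(outliers$fraction) || outliers$fraction < 0 ||
      outliers$fraction > 1 ||
      (!isTRUE(outliers$monoallelic) &&
         outliers$fraction > 0 && !is.numeric(outliers$effect)))
    bad <- c(bad, "outliers")
  if (any(variants$base_rate < 0 | variants$base_rate > 1) ||
      any(variants$outlier_rate < 0 | variants$outlier_rate > 1))
    bad <- c(bad, "variants")
  if (length(bad))
    stop("invalid sim_config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_individuals = as.integer(n_individuals), sd_g = sd_g,
                 coverage = coverage, outliers = outliers,
                 variants = variants),
            class = "sim_config")
}

#' Simulate a population of haplotype-level ASE counts
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [hap_counts()]), `truth` (per-cell
#'   data.frame: `gene_id`, `sample_id`, `delta`, `planted`), and `sd_g`
#'   (named per-gene true SD).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_genes; N <- config$n_individuals
  with_seed(config$seed, {
    sd_g <- if (is.list(config$sd_g)) {
      stats::rlnorm(G, config$sd_g$meanlog, config$sd_g$sdlog)
    } else rep_len(config$sd_g, G)
    gene_ids <- sprintf("GENE%05d", seq_len(G))
    sample_ids <- sprintf("IND%04d", seq_len(N))
    names(sd_g) <- gene_ids
    cov <- config$coverage
    totals <- if (cov$type == "loguniform") {
      round(exp(runif(G * N, log(cov$min), log(cov$max))))
    } else {
      pmax(rnbinom(G * N, mu = cov$mu, size = cov$size),
           if (is.null(cov$min)) 0 else cov$min)
    }
    delta <- rnorm(G * N, 0, rep(sd_g, times = N))
    planted <- runif(G * N) < config$outliers$fraction
    mono <- isTRUE(config$outliers$monoallelic)
    sign_flip <- sample(c(-1, 1), G * N, replace = TRUE)
    if (!mono && any(planted))
      delta[planted] <- sign_flip[planted] * config$outliers$effect
    a <- rbinom(G * N, totals, plogis(delta))
    if (mono && any(planted)) {
      a[planted] <- ifelse(sign_flip[planted] > 0, totals[planted], 0)
      delta[planted] <- sign_flip[planted] * Inf
    }
    counts <- hap_counts(matrix(a, G, N), matrix(totals - a, G, N),
                         gene_ids = gene_ids, sample_ids = sample_ids)
    truth <- data.frame(gene_id = rep(gene_ids, times = N),
                        sample_id = rep(sample_ids, each = G),
                        delta = delta, planted = planted,
                        stringsAsFactors = FALSE)
    list(counts = counts, truth = truth, sd_g = sd_g)
  })
}

#' Simulate a rare-variant annotation table
#'
#' Draws carrier flags per (individual, gene, class) with probability
#' `outlier_rate` for planted-outlier cells and `base_rate` otherwise, so the
#' enrichment module's relative risk has a known expectation.
#'
#' @param truth the `truth` table from [simulate_population()].
#' @param config the same [sim_config()].
#' @param seed optional override (default: `config$seed + 1`).
#' @return data.frame with columns `individual_id`, `gene_id`,
#'   `consequence_class`, `carries_rare` (carriers only).
#' @export
simulate_variant_table <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  vs <- config$variants
  classes <- vs$classes
  base <- rep_len(vs$base_rate, length(classes))
  outl <- rep_len(vs$outlier_rate, length(classes))
  if (is.null(seed)) seed <- config$seed + 1L
  with_seed(seed, {
    out <- lapply(seq_along(classes), function(ci) {
      p <- ifelse(truth$planted, outl[ci], base[ci])
      hit <- runif(nrow(truth)) < p
      if (!any(hit)) return(NULL)
      data.frame(individual_id = truth$sample_id[hit],
                 gene_id = truth$gene_id[hit],
                 consequence_class = classes[ci],
                 carries_rare = TRUE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(individual_id = character(0), gene_id = character(0),
                        consequence_class = character(0),
                        carries_rare = logical(0), stringsAsFactors = FALSE)
    out
  })
}
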