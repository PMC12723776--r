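# HaplotypeCountMatrix container ------------------------------------------

#' Haplotype count matrix
#'
#' Container for gene x sample paired haplotype read counts: `a` and `b` hold
#' the reads assigned to each haplotype after aggregation over the phased
#' heterozygous sites of a gene.  Entries may be `NA` (gene not measurable in
#' that sample) but must be missing in `a` and `b` together.
#'
#' @param a,b non-negative integer matrices of identical shape
#'   (genes in rows, samples in columns).
#' @param gene_ids,sample_ids identifiers; default to the dimnames of `a`.
#' @return an object of class `hap_counts` with fields `a`, `b`, `gene_ids`,
#'   `sample_ids`.
#' @export
hap_counts <- function(a, b, gene_ids = rownames(a),
                       sample_ids = colnames(a)) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("`a` and `b` must have identical dimensions", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(a)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(a)))
  gene_ids <- as.character(gene_ids); sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(a) || anyDuplicated(gene_ids))
    stop("`gene_ids` must be unique and match nrow(a)", call. = FALSE)
  if (length(sample_ids) != ncol(a) || anyDuplicated(sample_ids))
    stop("`sample_ids` must be unique and match ncol(a)", call. = FALSE)
  if (!identical(is.na(a), is.na(b)))
    stop("`a` and `b` must be missing together", call. = FALSE)
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  if (any(a != trunc(a), na.rm = TRUE) || any(b != trunc(b), na.rm = TRUE))
    stop("counts must be integers", call. = FALSE)
  storage.mode(a) <- "double"; storage.mode(b) <- "double"
  dimnames(a) <- dimnames(b) <- list(gene_ids, sample_ids)
  structure(list(a = a, b = b, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "hap_counts")
}

#' Total coverage per gene and sample
#'
#' @param x a [hap_counts()] object.
#' @return matrix of `a + b` totals (the coverage used by all filters).
#' @export
hap_totals <- function(x) {
  stopifnot(inherits(x, "hap_counts"))
  x$a + x$b
}

#' @export
dim.hap_counts <- function(x) dim(x$a)

#' @export
print.hap_counts <- function(x, ...) {
  cat(sprintf("hap_counts: %d genes x %d samples (%.1f%% missing)\n",
              nrow(x$a), ncol(x$a), 100 * mean(is.na(x$a))))
  invisible(x)
}

#' Subset a haplotype count matrix
#'
#' @param x a [hap_counts()] object.
#' @param i,j gene and sample selectors (indices or names).
#' @param ... ignored.
#' @export
`[.hap_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a))
  if (missing(j)) j <- seq_len(ncol(x$a))
  hap_counts(x$a[i, j, drop = FALSE], x$b[i, j, drop = FALSE])
}
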