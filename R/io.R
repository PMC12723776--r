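# Readers and writers ------------------------------------------------------
#
# All writers emit a fixed column order, "\n" line endings, and a
# "# rows=<n>" checksum comment so silently truncated files are rejected on
# read; the comment is tolerated absent for foreign files.

write_tsv_checked <- function(df, path, digits = "%.10g") {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) {
    v <- sprintf(digits, df[[j]])
    v[is.na(df[[j]])] <- "NA"
    out[[j]] <- v
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# rows=%d", nrow(df)),
               paste(names(df), collapse = "\t"),
               do.call(paste, c(out, sep = "\t"))),
             con, sep = "\n")
  invisible(path)
}

read_tsv_checked <- function(path) {
  first <- readLines(path, n = 1L)
  expected <- if (grepl("^# rows=", first))
    as.integer(sub("^# rows=", "", first)) else NA_integer_
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.na(expected) && nrow(df) != expected)
    stop(sprintf("%s: expected %d rows, found %d (truncated file?)",
                 path, expected, nrow(df)), call. = FALSE)
  df
}

#' Read phASER-style per-gene haplotype count tables
#'
#' Accepts one tab-separated `phaser_gene_ae`-style file per sample, or a
#' single combined long table with a `sample` column.  Required columns:
#' `name`, `aCount`, `bCount` (genomic coordinates `contig`/`start`/`stop`
#' are parsed when present but unused by the statistics).
#'
#' @param paths file path(s); for multiple files the sample id is the file
#'   base name (without extension) unless `sample_ids` is given.
#' @param sample_ids optional sample identifiers, one per file.
#' @return a [hap_counts()] matrix; genes absent from a sample's file are
#'   `NA` for that sample.
#' @export
read_phaser_gene_ae <- function(paths, sample_ids = NULL) {
  tabs <- lapply(paths, function(p) {
    tab <- read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
    missing_cols <- setdiff(c("name", "aCount", "bCount"), names(tab))
    if (length(missing_cols))
      stop(p, ": missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if (any(tab$aCount < 0, na.rm = TRUE) || any(tab$bCount < 0, na.rm = TRUE))
      stop(p, ": negative counts", call. = FALSE)
    tab
  })
  if (length(tabs) == 1L && "sample" %in% names(tabs[[1]])) {
    long <- tabs[[1]]
    samples <- unique(long$sample)
    tabs <- lapply(samples, function(s) long[long$sample == s, , drop = FALSE])
    if (is.null(sample_ids)) sample_ids <- samples
  } else if (is.null(sample_ids)) {
    sample_ids <- tools::file_path_sans_ext(basename(paths))
  }
  genes <- unique(unlist(lapply(tabs, `[[`, "name")))
  a <- b <- matrix(NA_real_, length(genes), length(tabs),
                   dimnames = list(genes, sample_ids))
  for (j in seq_along(tabs)) {
    tab <- tabs[[j]]
    if (anyDuplicated(tab$name))
      stop("duplicate gene rows for sample ", sample_ids[j], ": ",
           tab$name[duplicated(tab$name)][1], call. = FALSE)
    a[tab$name, j] <- tab$aCount
    b[tab$name, j] <- tab$bCount
  }
  hap_counts(a, b)
}

#' Write / read the wide "a|b" haplotype count matrix
#'
#' GTEx-style wide layout: rows are genes, columns samples, each cell a
#' `"a|b"` pair of non-negative integers; empty cells are missing.  Writing
#' then reading is an exact round trip.
#'
#' @param counts a [hap_counts()] object.
#' @param path file path.
#' @return `write_wide_matrix()` returns `path` invisibly;
#'   `read_wide_matrix()` returns a [hap_counts()].
#' @export
write_wide_matrix <- function(counts, path) {
  stopifnot(inherits(counts, "hap_counts"))
  cells <- matrix(sprintf("%d|%d", counts$a, counts$b), nrow = nrow(counts$a))
  cells[is.na(counts$a)] <- ""
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# rows=%d", nrow(counts$a)),
               paste(c("gene_id", counts$sample_ids), collapse = "\t"),
               vapply(seq_len(nrow(cells)), function(i)
                 paste(c(counts$gene_ids[i], cells[i, ]), collapse = "\t"),
                 character(1))),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_wide_matrix
#' @export
read_wide_matrix <- function(path) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "gene_id")
    stop(path, ": first column must be `gene_id`", call. = FALSE)
  genes <- as.character(df[[1]])
  samples <- names(df)[-1]
  a <- b <- matrix(NA_real_, length(genes), length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    cell <- as.character(df[[j + 1L]])
    cell[is.na(cell)] <- ""
    filled <- cell != ""
    ok <- grepl("^[0-9]+\\|[0-9]+$", cell[filled])
    if (!all(ok)) {
      bad_row <- which(filled)[which(!ok)[1]]
      stop(sprintf("%s: malformed cell '%s' at gene %s, sample %s",
                   path, cell[filled][which(!ok)[1]], genes[bad_row],
                   samples[j]), call. = FALSE)
    }
    parts <- strsplit(cell[filled], "|", fixed = TRUE)
    a[filled, j] <- as.numeric(vapply(parts, `[[`, character(1), 1L))
    b[filled, j] <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  }
  hap_counts(a, b)
}

#' Read a gene universe (plain list or GTF/GFF3)
#'
#' The FDR gene universe of the outlier test (typically protein-coding plus
#' lncRNA genes).  A plain newline-delimited gene list is read directly; a
#' GTF/GFF3 annotation is read via `rtracklayer::readGFF()`, keeping gene
#' records whose biotype is in `biotypes`.
#'
#' @param path file path.
#' @param biotypes biotype filter applied to annotation input (default
#'   protein_coding + lncRNA conventions); ignored for plain lists.
#' @param strip_versions drop trailing `.N` Ensembl version suffixes
#'   (default `FALSE`; id matching elsewhere is exact-string).
#' @return character vector of unique gene ids.
#' @export
read_gene_universe <- function(path,
                               biotypes = c("protein_coding", "lncRNA",
                                            "lincRNA"),
                               strip_versions = FALSE) {
  is_gtf <- grepl("\\.(gtf|gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE)
  ids <- if (is_gtf) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF/GFF requires the rtracklayer package", call. = FALSE)
    gff <- as.data.frame(rtracklayer::readGFF(path))
    gff <- gff[gff$type == "gene", , drop = FALSE]
    bt_col <- intersect(c("gene_type", "gene_biotype", "biotype"), names(gff))
    if (length(bt_col) == 0L)
      stop(path, ": no gene biotype attribute found", call. = FALSE)
    as.character(gff$gene_id[gff[[bt_col[1]]] %in% biotypes])
  } else {
    ids <- readLines(path)
    ids[nzchar(ids) & !grepl("^#", ids)]
  }
  if (strip_versions) ids <- sub("\\.[0-9]+$", "", ids)
  unique(ids)
}

#' Write / read a V^G reference table
#'
#' The interchange format between the estimator and the outlier test: a TSV
#' with columns `gene_id`, `sd_g`, `vg`, `ci_low`, `ci_high`, `n_used`,
#' `converged`.  `read_vg_table()` also accepts legacy two-column
#' `(gene_id, vg)` tables; `vg_convention` states what the second column
#' holds: `"sd"` (already the SD of the log allelic fold change) or
#' `"variance_half"` (`vg = sd_g^2 / 2`, converted on load).
#'
#' @param estimates a `fit_matrix()$estimates` data.frame.
#' @param path file path.
#' @param vg_convention convention of a legacy two-column table.
#' @return `read_vg_table()` returns a data.frame with at least `gene_id`
#'   and `sd_g`.
#' @export
write_vg_table <- function(estimates, path) {
  cols <- c("gene_id", "sd_g", "vg", "ci_low", "ci_high", "n_used",
            "converged")
  write_tsv_checked(estimates[intersect(cols, names(estimates))], path)
}

#' @rdname write_vg_table
#' @export
read_vg_table <- function(path, vg_convention = c("sd", "variance_half")) {
  vg_convention <- match.arg(vg_convention)
  df <- read_tsv_checked(path)
  if (!"sd_g" %in% names(df)) {
    if (ncol(df) < 2L)
      stop(path, ": need at least (gene_id, value) columns", call. = FALSE)
    names(df)[1] <- "gene_id"
    df$sd_g <- if (vg_convention == "sd") df[[2]] else sqrt(2 * df[[2]])
  }
  df
}

#' Write dosage outlier test results
#'
#' @param results a [dot_cohort()]`$results` (or [dot_sample()]) data.frame.
#' @param path file path.
#' @export
write_dot_results <- function(results, path) {
  write_tsv_checked(results, path)
}

#' Write a newline-delimited gene list
#'
#' @param ids character vector of gene ids.
#' @param path file path.
#' @export
write_gene_list <- function(ids, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(ids, con, sep = "\n")
  invisible(path)
}
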