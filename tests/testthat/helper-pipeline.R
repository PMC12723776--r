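# Shared CLI pipeline driver for determinism checks.

run_pipeline <- function(dir, workers = 1) {
  old <- setwd(dir); on.exit(setwd(old))
  haplodot_cli(c("simulate", "--seed", "17", "--genes", "25",
                 "--individuals", "40", "--outlier-fraction", "0.02",
                 "--monoallelic", "TRUE", "--out", "counts.tsv",
                 "--truth-out", "truth.tsv", "--variants-out", "variants.tsv"))
  haplodot_cli(c("fit", "--counts", "counts.tsv", "--out", "vg.tsv",
                 "--boot", "20", "--seed", "3",
                 "--workers", as.character(workers)))
  haplodot_cli(c("dot", "--counts", "counts.tsv", "--vg", "vg.tsv",
                 "--out", "dot.tsv", "--summary-out", "dot_summary.tsv"))
  haplodot_cli(c("fp-screen", "--dot-results", "dot.tsv", "--out", "fp.tsv",
                 "--exclude-out", "fp_genes.txt"))
  haplodot_cli(c("enrich", "--dot-results", "dot.tsv",
                 "--variants", "variants.tsv", "--thresholds", "0.05",
                 "--out", "enrich.tsv"))
  haplodot_cli(c("popdist", "--vg", "P1=vg.tsv,P2=vg.tsv",
                 "--out", "similarity.tsv", "--dist-out", "distance.tsv"))
  haplodot_cli(c("cross-dot", "--counts", "P1=counts.tsv",
                 "--vg", "P1=vg.tsv", "--out", "cross.tsv"))
  invisible(dir)
}

file_bytes <- function(dir) {
  fs <- sort(list.files(dir, full.names = TRUE))
  setNames(lapply(fs, function(f) readBin(f, "raw", file.size(f))),
           basename(fs))
}
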