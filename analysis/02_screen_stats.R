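#!/usr/bin/env Rscript

# Stage 2: library-representation QC and per-context differential
# abundance. For each screen context, estimates size factors and
# dispersions, runs the construct-level Wald test (treated vs vehicle),
# bins the NTCs into pseudo-genes and aggregates to gene level.
# Reads results/data/, writes results/screen/.

suppressPackageStartupMessages(library(screentriage))

dat <- "results/data"
out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- load_config(file.path(dat, "config.json"))

design <- read_library(file.path(dat, "library.tsv"))
counts_df <- read_tsv_table(file.path(dat, "counts.tsv"))
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$construct_id
meta <- read_tsv_table(file.path(dat, "samples.tsv"))
ct <- structure(list(counts = counts, meta = meta), class = "count_table")

qc <- representation_qc(counts[, 1], design)
print(qc)
jsonlite::write_json(unclass(qc), file.path(out, "qc.json"),
                     auto_unbox = TRUE, digits = NA)

binning <- bin_ntcs(design$construct_id[design$is_ntc], seed = cfg$seed)
for (ctx in unique(meta$context)) {
  res <- analyze_screen_context(ct, design, ctx, ntc_binning = binning,
                                lfc_threshold = cfg$thresholds$essential_lfc,
                                p_threshold = cfg$thresholds$p,
                                min_sig_constructs = cfg$modes$min_sig_constructs)
  write_tsv_table(res$construct_stats,
                  file.path(out, paste0("constructs_", ctx, ".tsv")))
  write_tsv_table(res$gene_stats,
                  file.path(out, paste0("genes_", ctx, ".tsv")))
  ntc <- res$gene_stats[grepl("^NTC", res$gene_stats$gene), ]
  cat(sprintf(
    "%s: %d/%d genes essential (median log2FC < %g, >= %d sig constructs); NTC medians %s\n",
    ctx, sum(res$gene_stats$essential), nrow(res$gene_stats),
    cfg$thresholds$essential_lfc, cfg$modes$min_sig_constructs,
    paste(sprintf("%.2f", ntc$median_log2FC), collapse = ", ")))
}
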