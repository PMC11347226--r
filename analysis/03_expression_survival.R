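#!/usr/bin/env Rscript

# Stage 3: cohort expression analyses. Scales expression per gene across
# tumour samples, computes the gene-set activity score, correlates every
# screen gene's expression with it, estimates tumour-vs-normal
# overexpression, and stratifies survival on the candidate + activity
# scores (top/bottom thirds, log-rank).
# Reads results/data/, writes results/expression/.

suppressPackageStartupMessages(library(screentriage))

dat <- "results/data"
out <- "results/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- load_config(file.path(dat, "config.json"))

fpkm_df <- read_tsv_table(file.path(dat, "fpkm.tsv"))
fpkm <- as.matrix(fpkm_df[, -1])
rownames(fpkm) <- fpkm_df$gene
classes <- read_tsv_table(file.path(dat, "sample_classes.tsv"))
classes <- stats::setNames(classes$class, classes$sample)[colnames(fpkm)]
clinical <- read_tsv_table(file.path(dat, "clinical.tsv"))
gene_set <- read_gene_set(file.path(dat, "activity_geneset.txt"))

tum <- classes == "tumour"
z <- scale_expression(fpkm[, tum, drop = FALSE])
score <- geneset_score(z, gene_set)
write_tsv_table(data.frame(sample = names(score), score = unname(score)),
                file.path(out, "activity_score.tsv"))

screen_genes <- intersect(cfg$screen$gene_names, rownames(fpkm))
coex <- do.call(rbind, lapply(screen_genes, function(g) {
  cc <- correlate_candidate(z[g, ], score)
  data.frame(gene = g, r = cc$r, p = cc$p)
}))
over <- do.call(rbind, lapply(screen_genes, function(g) {
  lf <- tumour_vs_normal_lfc(fpkm, classes, g)
  data.frame(gene = g, log2FC = lf$log2FC, SE = lf$SE)
}))
write_tsv_table(coex, file.path(out, "coexpression.tsv"))
write_tsv_table(over, file.path(out, "overexpression.tsv"))
cat(sprintf("co-expressed with activity score (r > %g): %d/%d genes\n",
            cfg$thresholds$r, sum(coex$r > cfg$thresholds$r), nrow(coex)))
cat(sprintf("overexpressed in tumours (log2FC > %g): %d/%d genes\n",
            cfg$thresholds$overexpression,
            sum(over$log2FC > cfg$thresholds$overexpression), nrow(over)))

surv <- stratify_and_logrank(z[cfg$candidate_gene, ], score, clinical,
                             mode = cfg$modes$survival_mode)
write_tsv_table(surv$km, file.path(out, "km_curves.tsv"))
jsonlite::write_json(list(chi2 = surv$logrank_chi2, p = surv$p,
                          n_high = surv$n_high, n_low = surv$n_low),
                     file.path(out, "logrank.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(
  "survival: high (n=%d) vs low (n=%d) double-third strata, log-rank chi2=%.2f, p=%.2g\n",
  surv$n_high, surv$n_low, surv$logrank_chi2, surv$p))
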