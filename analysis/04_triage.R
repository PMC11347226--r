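#!/usr/bin/env Rscript

# Stage 4: candidate triage. Joins the per-context gene statistics with
# dependency-reference essentiality scores and the expression filters,
# classifies cross-screen quadrants, and ranks the genes that pass all
# four filters (in vivo depletion, tumour selectivity vs fibroblasts,
# co-expression with the activity score, tumour overexpression).
# Reads results/screen/ and results/expression/, writes results/triage/.

suppressPackageStartupMessages(library(screentriage))

out <- "results/triage"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- load_config("results/data/config.json")

gene_stats <- lapply(stats::setNames(cfg$screen$contexts,
                                     cfg$screen$contexts), function(ctx)
  read_tsv_table(file.path("results/screen", paste0("genes_", ctx, ".tsv"))))
cmp <- compare_screens(gene_stats, threshold = cfg$thresholds$essential_lfc)
write_tsv_table(cmp, file.path(out, "comparison.tsv"))
print(table(cmp$class))

dep_df <- read_tsv_table("results/data/dependency.tsv")
dep <- as.matrix(dep_df[, -1])
rownames(dep) <- dep_df$gene
scores <- essentiality_score(dep, threshold = cfg$thresholds$essentiality)
write_tsv_table(scores, file.path(out, "essentiality.tsv"))
cat(sprintf("common essential (score >= %g%%): %d/%d genes\n",
            cfg$thresholds$essentiality, sum(scores$common_essential),
            nrow(scores)))

coex <- read_tsv_table("results/expression/coexpression.tsv")
over <- read_tsv_table("results/expression/overexpression.tsv")
cand <- rank_candidates(cmp, coex, over, scores,
                        lfc_threshold = cfg$thresholds$essential_lfc,
                        r_threshold = cfg$thresholds$r,
                        overexpr_threshold = cfg$thresholds$overexpression)
write_tsv_table(cand, file.path(out, "candidates.tsv"))
pass <- cand[cand$pass_all, ]
cat(sprintf("genes passing all four filters: %d\n", nrow(pass)))
if (nrow(pass)) {
  top <- pass[pass$rank == 1, ]
  cat(sprintf(
    "top candidate: %s (in vivo %.2f, delta vs fibroblast %.2f, r=%.2f, tumour lfc=%.2f, essentiality %.1f%%)\n",
    top$gene, top$median_log2FC.invivo, top$delta_log2FC, top$r_coexpr,
    top$lfc_tumour_vs_normal, top$essentiality_score))
} else {
  print(attr(cand, "filter_diagnostics"))
}
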