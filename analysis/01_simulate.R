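#!/usr/bin/env Rscript

# Stage 1: generate every synthetic input of the triage workflow — the
# shRNA library and screen counts (three contexts), the dependency
# reference, the expression/survival pseudo-cohort and the spike-in
# occupancy experiment — and write them as TSV under results/data/.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>]

suppressPackageStartupMessages(library(screentriage))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(w <- which(args == "--seed"))) args[w + 1] else 1)

cfg <- default_config(seed = seed)
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
save_config(cfg, file.path(out, "config.json"))

design <- simulate_library(cfg$screen)
counts <- simulate_screen_counts(design, cfg$screen)
write_screen_inputs(design, counts, out, params = cfg$screen)
cat(sprintf("library: %d constructs (%d targeting, %d NTC) across %d samples\n",
            nrow(design), sum(!design$is_ntc), sum(design$is_ntc),
            ncol(counts$counts)))

dep <- simulate_dependency_matrix(
  n_genes = cfg$screen$n_genes, n_lines = cfg$dependency$n_lines,
  planted_fractions = cfg$dependency$planted_fractions,
  seed = cfg$seed + 7L, gene_names = cfg$screen$gene_names)
write_tsv_table(dep, file.path(out, "dependency.tsv"), row_names = "gene")
cat(sprintf("dependency reference: %d genes x %d cell lines\n",
            nrow(dep), ncol(dep)))

cohort <- simulate_cohort(cfg$cohort)
# expose cohort rows under the screen's gene names: the planted candidate
# carries the co-expression/overexpression/survival signal
fpkm <- cohort$fpkm
bg <- grep("^BG", rownames(fpkm), value = TRUE)
other <- setdiff(cfg$screen$gene_names, cfg$candidate_gene)
rownames(fpkm)[match(c(cohort$candidate, bg[seq_along(other)]),
                     rownames(fpkm))] <- c(cfg$candidate_gene, other)
write_tsv_table(fpkm, file.path(out, "fpkm.tsv"), row_names = "gene")
write_tsv_table(data.frame(sample = names(cohort$classes),
                           class = unname(cohort$classes)),
                file.path(out, "sample_classes.tsv"))
write_tsv_table(cohort$clinical, file.path(out, "clinical.tsv"))
writeLines(cohort$gene_set, file.path(out, "activity_geneset.txt"))
cat(sprintf("cohort: %d tumours + %d normals, %d genes; candidate %s (planted r=%.2f, lfc=%.2f, HR=%.1f)\n",
            sum(cohort$classes == "tumour"), sum(cohort$classes == "normal"),
            nrow(fpkm), cfg$candidate_gene, cfg$cohort$planted_r,
            cfg$cohort$tumour_overexpression_lfc,
            cfg$cohort$survival_hazard_ratio))

occ <- simulate_occupancy(cfg$occupancy)
write_tsv_table(occ$promoters, file.path(out, "occupancy_counts.tsv"))
write_tsv_table(occ$spike, file.path(out, "spike_counts.tsv"))
write_tsv_table(data.frame(gene = names(occ$regulation),
                           log2FC = unname(occ$regulation)),
                file.path(out, "regulation.tsv"))
cat(sprintf("occupancy: %d promoters, planted global depletion %.2f, spike fraction %.2f\n",
            cfg$occupancy$n_promoters, cfg$occupancy$global_depletion,
            cfg$occupancy$spike_fraction))
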