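#!/usr/bin/env Rscript

# Stage 5: spike-in-normalized occupancy. Computes spike scaling factors,
# the normalized treated/vehicle promoter signals and the implied global
# binding change, the regulation-vs-occupancy bin plot (8 equal-width
# bins) and the rank bin plot (15 equal-count bins).
# Reads results/data/, writes results/occupancy/.

suppressPackageStartupMessages(library(screentriage))

dat <- "results/data"
out <- "results/occupancy"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- load_config(file.path(dat, "config.json"))

prom <- read_tsv_table(file.path(dat, "occupancy_counts.tsv"))
spike <- spike_scaling(read_tsv_table(file.path(dat, "spike_counts.tsv")))
reg_df <- read_tsv_table(file.path(dat, "regulation.tsv"))
regulation <- stats::setNames(reg_df$log2FC, reg_df$gene)
write_tsv_table(spike, file.path(out, "spike_scaling.tsv"))

f <- stats::setNames(spike$f, spike$sample)
norm <- data.frame(gene = prom$gene,
                   vehicle = prom$vehicle * f["vehicle"],
                   treated = prom$treated * f["treated"])
norm$delta_log2FC <- log2((norm$treated + 1) / (norm$vehicle + 1))
write_tsv_table(norm, file.path(out, "normalized_signal.tsv"))
depletion <- sum(norm$treated) / sum(norm$vehicle)
cat(sprintf("spike factors: %s; global treated/vehicle signal ratio %.3f (planted %.2f)\n",
            paste(sprintf("%s=%.3f", spike$sample, spike$f), collapse = ", "),
            depletion, cfg$occupancy$global_depletion))

bp <- regulation_occupancy_binplot(regulation[norm$gene], norm$vehicle,
                                   n_bins = 8L)
write_tsv_table(bp$bins, file.path(out, "regulation_binplot.tsv"))
cat(sprintf("regulation vs occupancy (8 equal-width bins): r=%.3f, p=%.2g\n",
            bp$cor$r, bp$cor$p))

rb <- rank_binplot(norm$delta_log2FC, norm$vehicle, n_bins = 15L)
write_tsv_table(rb, file.path(out, "rank_binplot.tsv"))
cat(sprintf("rank bin plot: %d bins of %d-%d promoters; covariate means %.1f -> %.1f\n",
            nrow(rb), min(rb$n), max(rb$n),
            rb$covariate_mean[1], rb$covariate_mean[nrow(rb)]))

cor_vt <- promoter_correlation(norm$vehicle, norm$treated)
cat(sprintf("vehicle vs treated promoter correlation: r=%.3f (n=%d)\n",
            cor_vt$r, cor_vt$n))
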