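# screentriage

Analysis workflow for triaging candidate cancer dependencies from pooled
shRNA dropout screens. It is written for the common study design in which
a library of inducible shRNAs (five per gene plus non-targeting controls)
is screened in parallel in cultured tumour cells, engrafted tumours and
untransformed fibroblasts, and the screen hits are then filtered against
a dependency-portal reference, a patient expression cohort and
spike-in-normalized chromatin occupancy.

A gene survives triage when it

1. drops out in the in vivo screen (gene median log2FC < −1, with at
   least two individually significant shRNAs),
2. is more important for tumour cells than fibroblasts
   (Δlog2FC = in vivo − fibroblast < 0),
3. co-expresses with a transcriptional-activity score in patients
   (Pearson r > 0.5, activity = mean per-gene z-scored expression over a
   gene set), and
4. is overexpressed in tumours versus healthy tissue (log2FC > 0.3).

The statistical core is a fully specified negative-binomial
differential-abundance test (median-of-ratios size factors, moment
dispersion with trend shrinkage, delta-method Wald test), gene-level
median-of-guides aggregation with NTC pseudo-gene nulls (5/5/4/4 binning
of 18 controls), an essentiality score (percentage of reference cell
lines depending on a gene; ≥ 50% = common essential), Kaplan–Meier /
log-rank survival stratification on top/bottom-third score strata, and
spike-in scaling (`f = median(n_spike)/n_spike`) for promoter occupancy
(TSS ± 3 kb, strand-aware). A synthetic-data generator reproduces the
statistical structure of every input with planted effects, so the whole
chain runs and is tested without any external download.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
study (92 genes × 5 shRNAs + 18 NTCs; three screen contexts; a
159-patient cohort; a 1086-line dependency reference; 5000 promoters with
an 80% planted global binding loss):

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_screen_stats.R
Rscript analysis/03_expression_survival.R
Rscript analysis/04_triage.R
Rscript analysis/05_occupancy.R
```

which prints, stage by stage:

```
library: 478 constructs (460 targeting, 18 NTC) across 22 samples
Library representation: 478 constructs detected; 100.0% within 10-fold of median; uniform: TRUE
invitro: 30/96 genes essential (median log2FC < -1, >= 2 sig constructs); NTC medians 0.37, 0.29, 0.38, 0.35
invivo: 20/96 genes essential (median log2FC < -1, >= 2 sig constructs); NTC medians 0.44, 0.17, 0.14, -0.03
co-expressed with activity score (r > 0.5): 1/92 genes
overexpressed in tumours (log2FC > 0.3): 2/92 genes
survival: high (n=40) vs low (n=40) double-third strata, log-rank chi2=12.94, p=0.00032
genes passing all four filters: 1
top candidate: GENE001 (in vivo -1.59, delta vs fibroblast -1.76, r=0.79, tumour lfc=1.00, essentiality 55.0%)
spike factors: vehicle=1.003, treated=0.997; global treated/vehicle signal ratio 0.200 (planted 0.20)
regulation vs occupancy (8 equal-width bins): r=-1.000, p=1.1e-11
```

Reading the output: the 478-construct library passes the detection and
10-fold uniformity QC; per context, genes are called essential from the
median shRNA log2 fold change while the four NTC pseudo-genes stay near
zero; exactly one gene — the planted candidate `GENE001` — passes all
four triage filters and ranks first; patients in the top third of both
the candidate and the activity score die faster (log-rank p ≈ 3e-4); and
spike-in normalization recovers the planted 80% global occupancy loss
(ratio 0.200) that raw counts would hide. Stage tables land under
`results/`.

The same run is available as one call from R:

```r
library(screentriage)
run <- run_pipeline(default_config(seed = 1), out_dir = "results/run")
run$candidates[run$candidates$pass_all, c("gene", "rank", "r_coexpr")]
make_report(run)   # waterfall / volcano / scatter / bin-plot tables
```

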