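---
title: "Methods: pooled dropout screen analysis and candidate triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled dropout screen analysis and candidate triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screentriage)
```

# The analysis

`screentriage` implements the computational arm of a target-triage study
design for cancer dependencies: a pooled, inducible shRNA dropout screen
run in parallel in cultured tumour cells, engrafted tumours and
untransformed fibroblasts, combined with a dependency-portal reference, a
patient expression cohort and spike-in-normalized chromatin occupancy.
A gene becomes a candidate when it (1) drops out in the in vivo screen,
(2) is more important for tumour cells than fibroblasts, (3) co-expresses
with a transcriptional-activity score in patients, and (4) is
overexpressed in tumours versus healthy tissue.

Every stage operates on plain tables and is exercised end to end on
synthetic data with planted effects, so the whole chain is testable
without any external download.

# Screen statistics

**Counting.** Guide reads are matched exactly (no mismatches) against the
library's guide sequences, first at the fixed library offset and, failing
that, at any substring position. Reads matching no guide are tallied, so
`matched + unmatched = total` always holds. Library representation is
declared uniform when every construct is detected and more than 80% of
constructs lie within 10-fold of the median non-zero abundance. The
10-fold rule needs an anchor; we use the median because an all-vs-all
pairwise reading is ill-defined, and the rule is then scale-invariant.

**Normalization.** Median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_i \, c_{ij} / (\prod_j c_{ij})^{1/m}$ over
constructs positive in all samples, rescaled to geometric mean 1 so
normalized counts keep the raw magnitude.

**Dispersion.** Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$. Per construct, $\hat\alpha$ is the method-of-moments
value $\max(0, (s^2 - \bar\mu)/\bar\mu^2)$ with within-group variances
pooled by degrees of freedom, then shrunk half-way toward the mean of
$\hat\alpha$ in its abundance bin (20 equal-count bins), floored at
$10^{-8}$. This is a deliberately simple, fully specified estimator —
not a replacement for the shrinkage machinery of mature differential
count frameworks.

**Construct test.** The log2 fold change is
$\log_2((m_T + c_0)/(m_C + c_0))$ on normalized group means with
pseudocount $c_0 = 0.5$; its delta-method standard error under the NB
model is
$\mathrm{SE}^2 = (1/\ln 2)^2 \sum_g (1/m_g + \alpha)/n_g$, and
$z = \mathrm{lfc}/\mathrm{SE}$ is referred to a two-sided normal tail,
with Benjamini–Hochberg adjustment reported alongside. Classification
uses the raw $p < 0.05$ to mirror the thresholds the analysis is defined
with.

A caveat the package itself quantifies (see the type-I entry written by
`scripts/acceptance.R`): with three replicates per arm the moment
dispersion estimate retains enough noise that the normal-referred Wald
statistic behaves approximately like a $t$ with ~16 effective degrees of
freedom, i.e. the realized type-I error at nominal 0.05 is around
0.06–0.07. Plugging the true dispersion in restores calibration, so this
is a property of the simplified estimator, not of the test machinery.
Gene-level calls are robust to it because they additionally require a
median log2FC below −1 and two corroborating constructs.

**Gene level.** Each gene's statistic is the median of its constructs'
log2 fold changes (five per gene in the default design), with the SEM
across constructs, and an essential call when the median is below −1 and
at least two constructs are individually depleted and significant (the
corroboration count is configurable; two is the conservative field
default). The 18 non-targeting controls are randomly binned into four
pseudo-genes of sizes 5/5/4/4 and carried through aggregation as an
empirical null.

# Triage

The essentiality score of a gene is the percentage of reference cancer
cell lines (binary dependency matrix, 1086 lines in the default
emulation) in which it is essential; 50% or more defines "common
essential". Cross-screen comparison classifies genes into the four
quadrants of the in vitro / in vivo plane at the −1 threshold per
context. The candidate filters are: in vivo median log2FC < −1;
Δlog2FC = in vivo − fibroblast < 0 (tumour selectivity, computed on
gene-level medians for consistency with the screen plots); Pearson
r > 0.5 against the activity score; tumour-vs-normal log2FC > 0.3.
Passing genes are ranked by descending r with ties broken by ascending
in vivo log2FC — the published analysis names its top candidate without
stating a formula, so this ranking key is this package's own choice, made
once: co-expression is the filter with the most graded information, and
the screen effect is the natural tiebreak. Common-essential status is
reported but deliberately not used as an exclusion filter, since broadly
essential complexes can still be the intended positives.

# Expression and survival

Expression (FPKM) is z-scaled per gene across tumour samples (sample
standard deviation, $n-1$; immaterial at $n = 159$ but fixed for
determinism). The activity score is the per-sample mean of member-gene
z-scores. Candidate co-expression uses Pearson r with the
$t = r\sqrt{(n-2)/(1-r^2)}$ two-sided p. Overexpression is the
pseudocounted ratio of class means on the log2 scale ($c_0 = 0.1$) with a
delta-method SE. Survival strata are the samples in the top third of
*both* scores (high) versus the bottom third of both (low); Kaplan–Meier
curves and the two-group log-rank test come from the survival package.
Two ambiguities are exposed as configuration rather than resolved
silently: whether normals enter the scaling cohort (default: no), and an
optional mode restricting the analysis to the half of the cohort with the
highest combined score (default: full cohort, to avoid conditioning on
outcome).

# Occupancy

Spike-in scaling factors are $f_j = \mathrm{median}_k(n^{spike}_k) /
n^{spike}_j$; any positive constant in the numerator gives identical
between-sample ratios, and the median keeps normalized counts near raw
magnitude. Promoter signal counts read starts in the strand-aware window
TSS ± 3 kb (0-based half-open internally; windows truncated at
coordinate 0 with a warning). Read-start counting was chosen over
per-base coverage averaging; the two differ only by a factor near the
read length for uniform reads. Feature classification assigns each
interval by its midpoint with precedence promoter (TSS ± 3 kb) >
gene body (promoter edge to TES) > downstream (TES + 2 kb) > intergenic,
so the classes partition any interval set exactly; a seeded generator of
random fixed-length intervals (default $10^5$ at desk scale, 300 bp)
provides the genomic background. Two bin summaries mirror the standard
displays: eight equal-width bins over the regulation range (Pearson r on
bin means), and fifteen equal-count bins after sorting promoters by their
occupancy change, any remainder spread over the leading bins.

# The synthetic-data generator

The generator reproduces the statistical structure each stage assumes,
with the study's stated design constants as defaults:

* **Screen** — 92 target genes × 5 shRNAs + 18 NTCs (478 constructs);
  contexts `invitro` (3 replicates), `invivo` (5), `fibroblast` (3);
  expected depth 1000 reads per construct, matching the representation
  floor of 1000 cells per construct; NB dispersion α = 0.05, a typical
  mid-depth pooled-screen value, constant across constructs (the simplest
  model that exercises the dispersion estimator); baseline abundances
  log-normal (σ = 0.25) so the 10-fold QC rule is non-trivial. In vivo
  samples first pass through an independent multinomial engraftment
  bottleneck of 1000 cells per construct per tumour — the stated floor —
  which conserves total cell count exactly.
* **Cohort** — 159 tumours + 4 normals; a latent per-patient activity
  factor drives 25 gene-set members (per-gene noise sd 0.3) and a
  candidate gene at a planted correlation (default 0.8); normals carry
  the candidate at a planted log2 fold below tumours (default 1);
  exponential event times with hazard ratio (default 2) between the top
  and bottom latent thirds and the geometric-mean hazard in between,
  baseline median survival 600 days; censoring hits each patient with the
  nominal probability, uniformly over their follow-up, giving closed-form
  oracles.
* **Occupancy** — 5000 promoters with log-normal baselines; the treated
  experimental signal is multiplied by a planted global depletion
  (default 0.2); spike-in chromatin is constant across samples and sized
  to 6% of the reference sample's reads, matching the experimental
  admixture fraction; each sample gets an arbitrary sequencing scale so
  only spike normalization can recover the depletion; optional Poisson
  read resampling adds counting noise.

What the generator does **not** emulate: sequencing errors (reads either
match a guide exactly or not at all), PCR duplicates and UMI structure,
guide-specific efficacy differences, batch effects and covariates in the
cohort, tumour microenvironment composition, and peak-level ChIP
structure (the occupancy module consumes read placements or interval
counts; peak calling is out of scope). Green tests therefore demonstrate
correctness of the computations under the stated model, not robustness to
those real-data complications.

# Numerical choices and problem sizes

Determinism is end-to-end: every generator takes an explicit seed, and a
run manifest records seeds, parameters and a config hash; identical
configs produce identical outputs. Degenerate inputs have defined
behaviour: all-zero samples fail QC with fraction 0; constructs with zero
counts in both groups are flagged untestable (lfc 0, p 1); zero-variance
genes scale to all-zero rows with a warning; constant regulation values
make equal-width binning an error rather than a guess. Even-sized groups
use the mean of the two central values for medians; log-rank ties use the
standard tied-risk-set formulation.

The test suite and `scripts/acceptance.R` run at desk scale, chosen so
the whole suite completes in a few minutes on one core: $10^4$ null
construct-tests for type-I calibration, 50 null in vivo screens (the
five-vs-five design whose controls the NTC claim concerns) for the
pseudo-gene null band, 20 reseeded full-pipeline runs for
planted-candidate recovery, $10^3$–$10^5$ random intervals for the
feature background, and 5000-promoter occupancy sets. Oracle-equivalence
checks (size factors, log-rank, Pearson p, feature fractions, bin
summaries) run on ≤100-element instances against naive loop
implementations at $10^{-8}$ tolerance.

# Known limitations

* The construct-level Wald test is anti-conservative at three replicates
  (see above); interpret raw construct p-values accordingly and rely on
  the gene-level criteria.
* The cohort simulator links survival to the latent activity factor in
  three hazard steps rather than a continuous proportional-hazards model;
  it is built for stratified log-rank analyses, not for Cox-model
  benchmarking.
* The candidate ranking key is a package convention (see Triage); any
  downstream use should treat the full filter table, not just the rank,
  as the result.
* Promoter windows use the read's leftmost coordinate; for long reads on
  the minus strand this differs from the fragment 5' end by up to the
  read length.
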