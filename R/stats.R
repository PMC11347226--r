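# Differential-abundance statistics for screen counts: median-of-ratios
# normalization, moment dispersion estimation with trend shrinkage, a
# negative-binomial Wald test per construct, NTC pseudo-gene binning, and
# gene-level median-of-guides aggregation.

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over constructs (restricted to
#' rows positive in every sample) of `c_ij / geomean_i(c_i.)`; size factors
#' are then rescaled to geometric mean 1, so normalized counts stay on the
#' raw-count scale. If no row is positive in all samples, the geometric
#' mean of each row is taken over its positive entries instead (with a
#' warning).
#'
#' @param counts Non-negative count matrix, constructs x samples (>= 2
#'   samples), or a `count_table`.
#' @return Named positive numeric vector of size factors (geometric
#'   mean 1).
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  stop_if_not(is.matrix(counts) && ncol(counts) >= 2,
              "counts must be a matrix with >= 2 samples")
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    ref <- apply(counts[pos, , drop = FALSE], 1L, geo_mean)
    ratios <- counts[pos, , drop = FALSE] / ref
  } else {
    warning("no construct has positive counts in all samples; ",
            "using positive-subset geometric means")
    some <- rowSums(counts > 0) > 0
    stop_if_not(any(some), "all counts are zero")
    sub <- counts[some, , drop = FALSE]
    ref <- apply(sub, 1L, function(r) geo_mean(r[r > 0]))
    ratios <- sub / ref
    ratios[sub == 0] <- NA
  }
  s <- apply(ratios, 2L, stats::median, na.rm = TRUE)
  stop_if_not(all(is.finite(s) & s > 0), "degenerate size factors")
  s / geo_mean(s)
}

#' Per-construct dispersion by method of moments with trend shrinkage
#'
#' On normalized counts, each construct's raw dispersion is the
#' method-of-moments estimate `max(0, (s2 - mu) / mu^2)` pooled across
#' replicate groups (within-group variances pooled by degrees of freedom,
#' means averaged). Raw estimates are then shrunk half-way toward a
#' mean-trend: constructs are split into up to 20 equal-count abundance
#' bins and the trend is the mean raw estimate per bin. Constructs with no
#' replicated group take their dispersion entirely from the trend. A floor
#' of 1e-8 keeps downstream standard errors finite.
#'
#' @param counts Count matrix (constructs x samples) or `count_table`.
#' @param size_factors Size factors from [estimate_size_factors()].
#' @param groups Factor/character vector of replicate-group labels, one
#'   per sample; samples sharing a label are treated as replicates.
#' @param n_bins Number of abundance bins for the trend (default 20).
#' @param shrink_weight Weight on the raw per-construct estimate
#'   (default 0.5).
#' @return Named numeric vector of dispersions, one per construct.
#' @export
estimate_dispersion <- function(counts, size_factors, groups,
                                n_bins = 20L, shrink_weight = 0.5) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  stop_if_not(length(groups) == ncol(counts),
              "groups must label every sample")
  k <- sweep(counts, 2L, size_factors, "/")
  groups <- as.character(groups)
  glev <- unique(groups)
  n_per <- table(groups)[glev]
  rep_groups <- glev[n_per >= 2]
  stop_if_not(length(rep_groups) >= 1,
              "at least one group needs >= 2 replicates")
  ss <- matrix(0, nrow(k), length(rep_groups))
  df <- numeric(length(rep_groups))
  mu_g <- matrix(0, nrow(k), length(rep_groups))
  for (i in seq_along(rep_groups)) {
    kg <- k[, groups == rep_groups[i], drop = FALSE]
    mu_g[, i] <- rowMeans(kg)
    ss[, i] <- rowSums((kg - mu_g[, i])^2)
    df[i] <- ncol(kg) - 1
  }
  s2 <- rowSums(ss) / sum(df)
  mu <- rowMeans(mu_g)
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  # mean-dispersion trend over equal-count abundance bins
  nb <- max(1L, min(as.integer(n_bins), floor(nrow(k) / 2)))
  bin <- ceiling(rank(mu, ties.method = "first") / (nrow(k) / nb))
  bin <- pmin(pmax(bin, 1L), nb)
  trend_by_bin <- tapply(raw, bin, mean)
  trend <- as.numeric(trend_by_bin[as.character(bin)])

  disp <- shrink_weight * raw + (1 - shrink_weight) * trend
  pmax(disp, 1e-8, na.rm = TRUE)
}

#' Negative-binomial Wald test per construct
#'
#' For each construct, the log2 fold change is
#' `log2((m_T + c0) / (m_C + c0))` where `m_T`, `m_C` are normalized group
#' mean counts and `c0` is a pseudocount. The standard error follows the
#' delta method under the NB variance `mu + alpha * mu^2`:
#' `SE^2 = (1/ln 2)^2 * sum_g (1/m_g + alpha) / n_g` with `m_g` evaluated
#' at the (pseudocounted) group means. `z = log2FC / SE` is referred to a
#' standard normal two-sided tail; Benjamini-Hochberg adjusted p-values
#' are added over all constructs. Constructs with zero counts in both
#' groups are flagged untestable (log2FC 0, p 1).
#'
#' @param counts Count matrix (constructs x samples) or `count_table`.
#' @param size_factors Size factors from [estimate_size_factors()].
#' @param dispersion Per-construct dispersions (recycled if length 1).
#' @param treated,control Column names (or indices) of the treated and
#'   control samples.
#' @param pseudocount Pseudocount `c0` (default 0.5).
#' @return A data.frame with columns `construct_id`, `log2FC`, `SE`,
#'   `wald_z`, `p`, `padj`, `untestable`.
#' @export
test_constructs <- function(counts, size_factors, dispersion,
                            treated, control, pseudocount = 0.5) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  kt <- sweep(counts[, treated, drop = FALSE], 2L,
              size_factors[treated], "/")
  kc <- sweep(counts[, control, drop = FALSE], 2L,
              size_factors[control], "/")
  stop_if_not(ncol(kt) >= 1 && ncol(kc) >= 1,
              "both contrast groups must be present")
  alpha <- rep_len(dispersion, nrow(counts))
  m_t <- rowMeans(kt) + pseudocount
  m_c <- rowMeans(kc) + pseudocount
  lfc <- log2(m_t / m_c)
  se <- sqrt((1 / log(2))^2 *
               ((1 / m_t + alpha) / ncol(kt) + (1 / m_c + alpha) / ncol(kc)))
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  untestable <- rowSums(counts[, c(treated, control), drop = FALSE]) == 0
  lfc[untestable] <- 0
  z[untestable] <- 0
  p[untestable] <- 1
  data.frame(construct_id = rownames(counts),
             log2FC = lfc, SE = se, wald_z = z, p = p,
             padj = stats::p.adjust(p, method = "BH"),
             untestable = untestable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bin non-targeting controls into pseudo-genes
#'
#' Randomly partitions NTC construct ids into pseudo-genes sized like the
#' targeting-gene groups, so the controls can be carried through gene-level
#' aggregation as an empirical null. With the standard 18 controls the
#' sizes are two groups of five and two groups of four (`NTC1`/`NTC2`
#' five, `NTC3`/`NTC4` four); for other counts, explicit `sizes` summing
#' to `length(ntc_ids)` must be supplied.
#'
#' @param ntc_ids Character vector of NTC construct ids.
#' @param seed Integer seed for the partition.
#' @param sizes Optional integer vector of pseudo-gene sizes.
#' @return A list of class `ntc_binning`: `assignment` (named character
#'   vector id -> pseudo-gene), `sizes`, `seed`.
#' @export
bin_ntcs <- function(ntc_ids, seed = 1L, sizes = NULL) {
  n <- length(ntc_ids)
  stop_if_not(!anyDuplicated(ntc_ids), "ntc_ids must be unique")
  if (is.null(sizes)) {
    stop_if_not(n == 18L,
                "with ", n, " NTCs an explicit `sizes` partition is required ",
                "(default 5/5/4/4 applies to 18)")
    sizes <- c(5L, 5L, 4L, 4L)
  }
  stop_if_not(sum(sizes) == n, "sizes must sum to length(ntc_ids)")
  assignment <- with_seed(seed, {
    shuffled <- sample(ntc_ids)
    stats::setNames(rep(paste0("NTC", seq_along(sizes)), sizes), shuffled)
  })
  structure(list(assignment = assignment[ntc_ids], sizes = sizes,
                 seed = seed),
            class = "ntc_binning")
}

#' Aggregate construct statistics to gene level
#'
#' Per gene (including NTC pseudo-genes), takes the median of its
#' constructs' log2 fold changes (even-sized groups: mean of the two
#' central values), the SEM over those log2FCs, and the number of
#' constructs that are individually depleted and significant
#' (`log2FC < lfc_threshold` and `p < p_threshold`). A gene is called
#' essential when its median log2FC is below `lfc_threshold` and at least
#' `min_sig_constructs` of its constructs corroborate. Untestable
#' constructs are dropped; genes with no testable construct are excluded
#' with a warning.
#'
#' @param construct_stats Output of [test_constructs()].
#' @param gene_map Named character vector construct_id -> gene (NTC
#'   constructs already mapped to pseudo-genes, e.g. via [bin_ntcs()]).
#' @param lfc_threshold Depletion threshold on log2FC (default -1).
#' @param p_threshold Per-construct significance threshold (default 0.05,
#'   on the raw p-value).
#' @param min_sig_constructs Corroborating constructs required for the
#'   essential call (default 2).
#' @return A data.frame with columns `gene`, `median_log2FC`, `sem`,
#'   `n_constructs`, `n_sig_constructs`, `essential`.
#' @export
aggregate_genes <- function(construct_stats, gene_map,
                            lfc_threshold = -1, p_threshold = 0.05,
                            min_sig_constructs = 2L) {
  stop_if_not(all(construct_stats$construct_id %in% names(gene_map)),
              "every construct must map to a gene or pseudo-gene")
  st <- construct_stats
  st$gene <- unname(gene_map[st$construct_id])
  dropped <- unique(st$gene[tapply(st$untestable, st$gene, all)[st$gene]])
  if (length(dropped)) {
    warning("gene(s) with no testable construct excluded: ",
            paste(dropped, collapse = ", "))
  }
  st <- st[!st$untestable, , drop = FALSE]
  stop_if_not(nrow(st) > 0, "no testable constructs")
  agg <- function(d) {
    data.frame(gene = d$gene[1],
               median_log2FC = stats::median(d$log2FC),
               sem = if (nrow(d) > 1) stats::sd(d$log2FC) / sqrt(nrow(d)) else 0,
               n_constructs = nrow(d),
               n_sig_constructs = sum(d$log2FC < lfc_threshold &
                                        d$p < p_threshold),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(st, st$gene), agg))
  out$essential <- out$median_log2FC < lfc_threshold &
    out$n_sig_constructs >= min_sig_constructs
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Run the per-context screen analysis
#'
#' Convenience wrapper chaining size factors, dispersion estimation, the
#' construct-level Wald test and gene aggregation for one context's
#' treated-vs-control contrast.
#'
#' @param count_table A `count_table` (counts + sample metadata).
#' @param design Library design data.frame.
#' @param context Context label to analyse.
#' @param ntc_binning Optional [bin_ntcs()] result; defaults to a seeded
#'   5/5/4/4 binning of the design's NTCs when there are 18.
#' @param treated_label,control_label Treatment labels of the contrast
#'   (defaults `"treated"` vs `"vehicle"`).
#' @param ... Passed to [aggregate_genes()].
#' @return A list with `construct_stats` (with `gene` and `context`
#'   columns), `gene_stats`, `size_factors`, `dispersion`.
#' @export
analyze_screen_context <- function(count_table, design, context,
                                   ntc_binning = NULL,
                                   treated_label = "treated",
                                   control_label = "vehicle", ...) {
  meta <- count_table$meta
  sel <- meta$context == context &
    meta$treatment %in% c(treated_label, control_label)
  stop_if_not(any(sel), "no samples for context ", context)
  meta <- meta[sel, , drop = FALSE]
  counts <- count_table$counts[, meta$sample, drop = FALSE]
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, sf, groups = meta$treatment)
  st <- test_constructs(counts, sf, disp,
                        treated = meta$sample[meta$treatment == treated_label],
                        control = meta$sample[meta$treatment == control_label])
  ntc_ids <- design$construct_id[design$gene == "NTC"]
  gene_map <- stats::setNames(design$gene, design$construct_id)
  if (length(ntc_ids)) {
    if (is.null(ntc_binning) && length(ntc_ids) == 18L) {
      ntc_binning <- bin_ntcs(ntc_ids, seed = 1L)
    }
    if (!is.null(ntc_binning)) {
      gene_map[names(ntc_binning$assignment)] <- ntc_binning$assignment
    }
  }
  st$gene <- unname(gene_map[st$construct_id])
  st$context <- context
  gs <- aggregate_genes(st, gene_map, ...)
  list(construct_stats = st, gene_stats = gs,
       size_factors = sf, dispersion = disp)
}
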