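# Spike-in-normalized chromatin occupancy: scaling factors, strand-aware
# promoter-window signal, genomic feature classification, and the
# regulation/occupancy bin summaries.
#
# Coordinates are 0-based half-open internally (BED convention); tabular
# annotation is interpreted the same way.

#' Spike-in scaling factors
#'
#' Each sample's scaling factor is `f = median(n_spike) / n_spike`, so
#' multiplying counts by `f` equalizes spike-in totals across samples
#' exactly while keeping normalized counts near raw magnitude. The
#' normalization is idempotent: renormalizing already-normalized samples
#' yields `f = 1` everywhere.
#'
#' @param samples Data.frame with columns `sample`, `n_exp`, `n_spike`
#'   (all `n_spike` > 0).
#' @return The input with an `f` column appended.
#' @export
spike_scaling <- function(samples) {
  stop_if_not(all(c("sample", "n_exp", "n_spike") %in% names(samples)),
              "samples needs columns sample, n_exp, n_spike")
  stop_if_not(all(samples$n_spike > 0),
              "spike-in read count must be > 0 for every sample")
  samples$f <- stats::median(samples$n_spike) / samples$n_spike
  samples
}

as_annotation <- function(annotation) {
  req <- c("gene", "chrom", "strand", "tss", "tes")
  stop_if_not(all(req %in% names(annotation)),
              "annotation needs columns: ", paste(req, collapse = ", "))
  stop_if_not(all(annotation$strand %in% c("+", "-")),
              "strand must be '+' or '-'")
  plus <- annotation$strand == "+"
  stop_if_not(all(annotation$tes[plus] > annotation$tss[plus]),
              "TES must exceed TSS on the + strand")
  stop_if_not(all(annotation$tss[!plus] > annotation$tes[!plus]),
              "TSS must exceed TES on the - strand (5' coordinate)")
  stop_if_not(all(pmin(annotation$tss, annotation$tes) >= 0),
              "coordinates must be >= 0")
  annotation
}

reads_to_start_points <- function(reads) {
  if (inherits(reads, "GRanges")) {
    starts0 <- GenomicRanges::start(reads) - 1L
    chrom <- as.character(GenomicRanges::seqnames(reads))
  } else {
    stop_if_not(all(c("chrom", "start") %in% names(reads)),
                "reads need columns chrom, start (0-based)")
    starts0 <- reads$start
    chrom <- reads$chrom
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = starts0 + 1L,
                                                 width = 1L))
}

#' Spike-normalized promoter-window signal
#'
#' Counts reads whose start coordinate lies in the promoter window
#' `[TSS - half_width, TSS + half_width)` of each gene and multiplies by
#' the sample's spike scaling factor. The TSS is the strand-aware 5' end
#' (for minus-strand genes the window is still genomically symmetric
#' around the TSS coordinate). Windows that would extend below zero are
#' truncated at zero with a warning.
#'
#' @param reads BED-like data.frame (`chrom`, `start`, 0-based) or a
#'   `GRanges` of read placements; read start = leftmost coordinate.
#' @param annotation Data.frame with columns `gene`, `chrom`, `strand`,
#'   `tss`, `tes` (0-based).
#' @param f Spike scaling factor for this sample (default 1).
#' @param half_width Half window width in bp (default 3000).
#' @return Data.frame with columns `gene`, `count`, `signal`
#'   (`count * f`).
#' @export
promoter_signal <- function(reads, annotation, f = 1, half_width = 3000L) {
  annotation <- as_annotation(annotation)
  stop_if_not(is.numeric(f) && length(f) == 1 && f > 0, "f must be > 0")
  lo <- annotation$tss - half_width
  if (any(lo < 0)) {
    warning(sum(lo < 0), " promoter window(s) truncated at coordinate 0")
    lo <- pmax(lo, 0)
  }
  win <- GenomicRanges::GRanges(annotation$chrom,
                                IRanges::IRanges(start = lo + 1L,
                                                 end = annotation$tss +
                                                   half_width))
  pts <- reads_to_start_points(reads)
  n <- GenomicRanges::countOverlaps(win, pts)
  data.frame(gene = annotation$gene, count = n, signal = n * f,
             stringsAsFactors = FALSE)
}

feature_ranges <- function(annotation, promoter_halfwidth = 3000L,
                           downstream_width = 2000L) {
  annotation <- as_annotation(annotation)
  plus <- annotation$strand == "+"
  mk <- function(chrom, lo, hi) {
    keep <- hi > lo
    lo <- pmax(lo[keep], 0)
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(start = lo + 1L, end = hi[keep]))
  }
  prom <- mk(annotation$chrom,
             annotation$tss - promoter_halfwidth,
             annotation$tss + promoter_halfwidth)
  body_lo <- ifelse(plus, annotation$tss + promoter_halfwidth,
                    annotation$tes)
  body_hi <- ifelse(plus, annotation$tes,
                    annotation$tss - promoter_halfwidth)
  body <- mk(annotation$chrom, body_lo, body_hi)
  down_lo <- ifelse(plus, annotation$tes,
                    annotation$tes - downstream_width)
  down_hi <- ifelse(plus, annotation$tes + downstream_width,
                    annotation$tes)
  down <- mk(annotation$chrom, down_lo, down_hi)
  list(promoter = prom, gene_body = body, downstream = down)
}

#' Classify intervals into genomic feature classes
#'
#' Each interval is classified by its midpoint with precedence
#' promoter > gene body > downstream > intergenic across all (possibly
#' overlapping) genes: promoter = TSS +/- 3 kb, gene body = the
#' transcribed region beyond the promoter up to the TES, downstream = the
#' 2 kb past the TES, strand-aware. The per-class fractions always sum
#' to 1.
#'
#' @param intervals BED-like data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) or `GRanges`.
#' @param annotation Gene annotation (see [promoter_signal()]).
#' @param promoter_halfwidth,downstream_width Window sizes in bp.
#' @return A list with `fractions` (named numeric over the four classes),
#'   `counts` (same shape), `class` (per-interval factor), `n`.
#' @export
feature_distribution <- function(intervals, annotation,
                                 promoter_halfwidth = 3000L,
                                 downstream_width = 2000L) {
  if (inherits(intervals, "GRanges")) {
    starts0 <- GenomicRanges::start(intervals) - 1L
    ends0 <- GenomicRanges::end(intervals)
    chrom <- as.character(GenomicRanges::seqnames(intervals))
  } else {
    stop_if_not(all(c("chrom", "start", "end") %in% names(intervals)),
                "intervals need columns chrom, start, end")
    starts0 <- intervals$start
    ends0 <- intervals$end
    chrom <- intervals$chrom
  }
  stop_if_not(all(ends0 > starts0), "intervals must have end > start")
  stop_if_not(all(chrom %in% annotation$chrom),
              "interval(s) on chromosome(s) absent from the annotation")
  mid <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = floor((starts0 + ends0) / 2) + 1L,
                            width = 1L))
  feats <- feature_ranges(annotation, promoter_halfwidth, downstream_width)
  lvls <- c("promoter", "gene_body", "downstream", "intergenic")
  cls <- factor(rep("intergenic", length(mid)), levels = lvls)
  for (nm in c("downstream", "gene_body", "promoter")) {
    cls[IRanges::overlapsAny(mid, feats[[nm]])] <- nm
  }
  counts <- table(cls)
  list(fractions = stats::setNames(as.numeric(counts) / length(mid), lvls),
       counts = stats::setNames(as.integer(counts), lvls),
       class = cls, n = length(mid))
}

#' Seeded random fixed-length genomic intervals
#'
#' Draws `n` intervals of the given width uniformly over a genome
#' (chromosomes chosen proportionally to placeable length), the reference
#' background for [feature_distribution()].
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param n Number of intervals (desk-scale default 1e5).
#' @param width Interval width in bp (default 300).
#' @param seed Integer seed.
#' @return BED-like data.frame `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
random_intervals <- function(chrom_sizes, n = 1e5, width = 300L, seed = 1L) {
  stop_if_not(!is.null(names(chrom_sizes)) && all(chrom_sizes >= width),
              "chrom_sizes must be named and >= width")
  with_seed(seed, {
    place <- chrom_sizes - width + 1
    chrom <- sample(names(chrom_sizes), n, replace = TRUE,
                    prob = place / sum(place))
    start <- floor(stats::runif(n) * place[chrom])
    data.frame(chrom = chrom, start = unname(start),
               end = unname(start) + width, stringsAsFactors = FALSE)
  })
}

bin_summary <- function(bin, x, y, n_bins) {
  f <- factor(bin, levels = seq_len(n_bins))
  out <- data.frame(bin = seq_len(n_bins))
  out$n <- as.integer(tabulate(bin, nbins = n_bins))
  out$x_mean <- as.numeric(tapply(x, f, mean))
  out$y_mean <- as.numeric(tapply(y, f, mean))
  out$y_sem <- as.numeric(tapply(y, f, function(v) {
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  }))
  out
}

#' Regulation vs occupancy bin plot (equal-width bins)
#'
#' Bins genes into `n_bins` equal-width bins spanning the range of the
#' regulation values (log2FC), then summarizes mean regulation, mean
#' occupancy and the SEM of occupancy per bin. Pearson r and its t-test
#' p-value are computed on the non-empty bin means.
#'
#' @param regulation Numeric log2FC per gene.
#' @param occupancy Numeric occupancy per gene (same length/order), or a
#'   matrix with one column per signal.
#' @param n_bins Number of bins (default 8).
#' @return A list with `bins` (data.frame: signal, bin, n, x_mean,
#'   y_mean, y_sem) and `cor` (data.frame: signal, r, p, n_bins_used).
#' @export
regulation_occupancy_binplot <- function(regulation, occupancy,
                                         n_bins = 8L) {
  occ <- if (is.matrix(occupancy)) occupancy else
    matrix(occupancy, ncol = 1, dimnames = list(NULL, "occupancy"))
  stop_if_not(length(regulation) == nrow(occ),
              "regulation and occupancy must align")
  stop_if_not(length(regulation) >= n_bins, "need >= n_bins genes")
  stop_if_not(all(is.finite(regulation)) && all(is.finite(occ)),
              "values must be finite")
  rng <- range(regulation)
  stop_if_not(diff(rng) > 0,
              "all regulation values identical; equal-width binning undefined")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(regulation, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bins <- list(); cors <- list()
  for (s in colnames(occ)) {
    bs <- bin_summary(bin, regulation, occ[, s], n_bins)
    bs <- cbind(signal = s, bs)
    keep <- bs$n > 0
    ct <- stats::cor.test(bs$x_mean[keep], bs$y_mean[keep],
                          method = "pearson")
    bins[[s]] <- bs
    cors[[s]] <- data.frame(signal = s, r = unname(ct$estimate),
                            p = ct$p.value, n_bins_used = sum(keep),
                            stringsAsFactors = FALSE)
  }
  list(bins = do.call(rbind, c(bins, list(make.row.names = FALSE))),
       cor = do.call(rbind, c(cors, list(make.row.names = FALSE))))
}

#' Rank bin plot (equal-count bins)
#'
#' Sorts promoters by `delta` (ascending: strongest decrease first) and
#' splits them into `n_bins` bins of equal count (any remainder spread
#' over the leading bins), reporting the per-bin mean of the covariate
#' and of `delta` itself.
#'
#' @param delta Numeric per-promoter change (e.g. log2FC of occupancy).
#' @param covariate Numeric per-promoter covariate (e.g. another
#'   factor's binding), same length.
#' @param n_bins Number of equal-count bins (default 15).
#' @return Data.frame: `bin`, `n`, `delta_mean`, `covariate_mean`,
#'   `covariate_sem`.
#' @export
rank_binplot <- function(delta, covariate, n_bins = 15L) {
  n <- length(delta)
  stop_if_not(length(covariate) == n, "delta and covariate must align")
  stop_if_not(n >= n_bins, "need at least as many promoters as bins")
  ord <- order(delta)
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  bin_sorted <- rep(seq_len(n_bins), sizes)
  bs <- bin_summary(bin_sorted, delta[ord], covariate[ord], n_bins)
  data.frame(bin = bs$bin, n = bs$n, delta_mean = bs$x_mean,
             covariate_mean = bs$y_mean, covariate_sem = bs$y_sem)
}

#' Pearson correlation between two promoter signals
#'
#' @param signal_a,signal_b Numeric vectors over the same promoter
#'   universe (length >= 4, non-zero variance).
#' @return A list with `r`, `p`, `n`.
#' @export
promoter_correlation <- function(signal_a, signal_b) {
  correlate_candidate(signal_a, signal_b)
}
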