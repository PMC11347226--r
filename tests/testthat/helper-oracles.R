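# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, explicit formulas) so they cannot share a bug
# with the vectorized implementations they check.

brute_size_factors <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  ref <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  s <- vapply(seq_len(ncol(counts)), function(j) {
    stats::median(counts[keep, j] / ref)
  }, numeric(1))
  s / exp(mean(log(s)))
}

brute_logrank_chi2 <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

brute_pearson <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# midpoint feature classification, one interval at a time
brute_feature_class <- function(chrom, start, end, ann,
                                prom_hw = 3000, down_w = 2000) {
  mid <- floor((start + end) / 2)
  in_win <- function(lo, hi) mid >= max(lo, 0) && mid < hi
  for (cls in c("promoter", "gene_body", "downstream")) {
    for (i in seq_len(nrow(ann))) {
      if (ann$chrom[i] != chrom) next
      tss <- ann$tss[i]; tes <- ann$tes[i]; plus <- ann$strand[i] == "+"
      hit <- switch(cls,
        promoter = in_win(tss - prom_hw, tss + prom_hw),
        gene_body = if (plus) in_win(tss + prom_hw, tes)
                    else in_win(tes, tss - prom_hw),
        downstream = if (plus) in_win(tes, tes + down_w)
                     else in_win(tes - down_w, tes))
      if (isTRUE(hit)) return(cls)
    }
  }
  "intergenic"
}

brute_equal_width_bins <- function(x, y, n_bins) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  out <- data.frame(bin = seq_len(n_bins), n = 0, x_mean = NA_real_,
                    y_mean = NA_real_)
  for (b in seq_len(n_bins)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    inb <- if (b == n_bins) x >= lo & x <= hi else x >= lo & x < hi
    out$n[b] <- sum(inb)
    if (any(inb)) {
      out$x_mean[b] <- mean(x[inb])
      out$y_mean[b] <- mean(y[inb])
    }
  }
  out
}

toy_annotation <- function() {
  # two chromosomes; one minus-strand gene; coordinates 0-based half-open
  data.frame(
    gene = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(10000, 60000, 20000),
    tes = c(30000, 40000, 26000),
    stringsAsFactors = FALSE)
}

null_screen <- function(seed, contexts = "invitro", replicates = 3L,
                        n_genes = 92L, depth = 1000, dispersion = 0.05,
                        n_ntc = 18L, ...) {
  p <- screen_sim_params(n_genes = n_genes, guides_per_gene = 5L,
                         n_ntc = n_ntc, contexts = contexts,
                         replicates_per_context = replicates,
                         depth = depth, dispersion = dispersion,
                         seed = seed, ...)
  d <- simulate_library(p)
  list(params = p, design = d, counts = simulate_screen_counts(d, p))
}
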