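# Spike normalization, promoter windows, feature classification and the
# two bin-plot summaries.

test_that("spike scaling factors equalize spike totals and are idempotent", {
  eq <- spike_scaling(data.frame(sample = c("a", "b"),
                                 n_exp = c(1e6, 2e6),
                                 n_spike = c(5e4, 5e4)))
  expect_equal(eq$f, c(1, 1))

  two <- spike_scaling(data.frame(sample = c("a", "b"),
                                  n_exp = c(1e6, 1e6),
                                  n_spike = c(1e4, 2e4)))
  expect_equal(two$f, c(1.5, 0.75))
  expect_equal(two$n_spike[1] * two$f[1], two$n_spike[2] * two$f[2])

  renorm <- spike_scaling(data.frame(sample = two$sample,
                                     n_exp = two$n_exp * two$f,
                                     n_spike = two$n_spike * two$f))
  expect_equal(renorm$f, c(1, 1))
  expect_error(spike_scaling(data.frame(sample = "a", n_exp = 1,
                                        n_spike = 0)), "spike")
})

test_that("promoter windows count read starts strand-awarely", {
  ann <- toy_annotation()
  # gA: + strand, TSS 10000 -> window [7000, 13000)
  # gB: - strand, TSS 60000 -> window [57000, 63000)
  none <- promoter_signal(data.frame(chrom = "chr1", start = 50), ann)
  expect_equal(none$count, c(0L, 0L, 0L))

  inside <- data.frame(chrom = rep("chr1", 12),
                       start = seq(7000, 12999, length.out = 12))
  got <- promoter_signal(inside, ann, f = 0.5)
  expect_equal(got$signal[got$gene == "gA"], 6)

  # read 1 kb 5' of the minus-strand TSS = genomically right of it
  minus <- promoter_signal(data.frame(chrom = "chr1", start = 61000), ann)
  expect_equal(minus$count[minus$gene == "gB"], 1L)
  # boundary: half-open window excludes TSS + 3000
  edge <- promoter_signal(data.frame(chrom = "chr1",
                                     start = c(13000, 12999, 7000, 6999)),
                          ann)
  expect_equal(edge$count[edge$gene == "gA"], 2L)

  low <- data.frame(gene = "gLow", chrom = "chr3", strand = "+",
                    tss = 1000, tes = 9000, stringsAsFactors = FALSE)
  expect_warning(promoter_signal(data.frame(chrom = "chr3", start = 10), low),
                 "truncated")
})

test_that("feature classification matches the per-interval oracle and sums to 1", {
  ann <- toy_annotation()
  one <- feature_distribution(data.frame(chrom = "chr1", start = 10050,
                                         end = 10150), ann)
  expect_equal(unname(one$fractions["promoter"]), 1)
  far <- feature_distribution(data.frame(chrom = "chr2", start = 1.2e6,
                                         end = 1.2e6 + 300), ann)
  expect_equal(unname(far$fractions["intergenic"]), 1)

  rand <- random_intervals(c(chr1 = 2e5, chr2 = 1e5), n = 1000L,
                           width = 300L, seed = 9L)
  got <- feature_distribution(rand, ann)
  oracle <- vapply(seq_len(nrow(rand)), function(i)
    brute_feature_class(rand$chrom[i], rand$start[i], rand$end[i], ann),
    character(1))
  expect_equal(unname(got$counts),
               unname(table(factor(oracle, levels = names(got$counts)))),
               ignore_attr = TRUE)
  expect_equal(sum(got$fractions), 1, tolerance = 1e-15)

  shuf <- rand[sample(nrow(rand)), ]
  expect_equal(feature_distribution(shuf, ann)$fractions, got$fractions)
})

test_that("equal-width regulation bins partition genes and expose the trend", {
  set.seed(71)
  reg <- stats::rnorm(400)
  occ <- 3 * reg + 2
  bp <- regulation_occupancy_binplot(reg, occ, n_bins = 8L)
  expect_equal(sum(bp$bins$n), 400L)
  expect_equal(bp$cor$r, 1, tolerance = 1e-10)
  neg <- regulation_occupancy_binplot(reg, -2 * reg + stats::rnorm(400, 0, 0.2))
  expect_lt(neg$cor$r, 0)

  oracle <- brute_equal_width_bins(reg, occ, 8L)
  expect_equal(bp$bins$n, oracle$n)
  expect_equal(bp$bins$x_mean, oracle$x_mean, tolerance = 1e-12)
  expect_equal(bp$bins$y_mean, oracle$y_mean, tolerance = 1e-12)

  expect_error(regulation_occupancy_binplot(rep(1, 20), stats::rnorm(20)),
               "identical")
  expect_error(regulation_occupancy_binplot(stats::rnorm(5), stats::rnorm(5)),
               "n_bins")
})

test_that("rank bins hold equal counts and track a planted monotone relation", {
  flat <- rank_binplot(stats::rnorm(30), rep(2.5, 30), n_bins = 15L)
  expect_equal(flat$n, rep(2L, 15))
  expect_equal(flat$covariate_mean, rep(2.5, 15))

  spread <- rank_binplot(stats::rnorm(32), stats::rnorm(32), n_bins = 15L)
  expect_equal(sort(spread$n, decreasing = TRUE), c(3L, 3L, rep(2L, 13)))
  expect_equal(spread$n[1:2], c(3L, 3L))

  set.seed(72)
  cov <- stats::rnorm(300)
  delta <- -cov + stats::rnorm(300, 0, 0.2)  # strong covariate -> most negative delta
  rb <- rank_binplot(delta, cov, n_bins = 15L)
  expect_lt(stats::cor(rb$bin, rb$covariate_mean, method = "spearman"), 0)
  expect_error(rank_binplot(stats::rnorm(10), stats::rnorm(10), 15L), "bins")
})

test_that("promoter correlations behave at identity, null and latent co-binding", {
  set.seed(73)
  a <- stats::rnorm(5000)
  expect_equal(promoter_correlation(a, a)$r, 1)
  expect_lt(abs(promoter_correlation(a, stats::rnorm(5000))$r), 0.1)
  lat <- stats::rnorm(5000)
  x <- 0.95 * lat + sqrt(1 - 0.95^2) * stats::rnorm(5000)
  y <- 0.95 * lat + sqrt(1 - 0.95^2) * stats::rnorm(5000)
  expect_gt(promoter_correlation(x, y)$r, 0.85)
})

test_that("spike normalization recovers a planted global depletion", {
  os <- simulate_occupancy(occupancy_sim_params(n_promoters = 4000L,
                                                global_depletion = 0.2,
                                                spike_fraction = 0.06,
                                                resample_reads = TRUE,
                                                seed = 74L))
  sp <- spike_scaling(os$spike)
  f <- stats::setNames(sp$f, sp$sample)
  ratio <- sum(os$promoters$treated * f["treated"]) /
    sum(os$promoters$vehicle * f["vehicle"])
  expect_lt(abs(ratio - 0.2) / 0.2, 0.1)
  # without spike correction the depletion is hidden by sequencing scale
  raw_ratio <- sum(os$promoters$treated) / sum(os$promoters$vehicle)
  expect_gt(abs(raw_ratio - 0.2) / 0.2, abs(ratio - 0.2) / 0.2)
})
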