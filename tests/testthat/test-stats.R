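# Normalization, dispersion, the construct-level Wald test, NTC binning
# and gene aggregation.

test_that("size factors match the median-of-ratios definition and its oracle", {
  m <- matrix(c(10, 20, 10, 20, 40, 20, 5, 10, 5), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("s", 1:3)))
  expect_equal(unname(estimate_size_factors(cbind(m[, 1], m[, 1]))),
               c(1, 1))
  two <- cbind(A = m[, 1], B = 2 * m[, 1])
  sf <- estimate_size_factors(two)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  set.seed(17)
  big <- matrix(stats::rnbinom(400, mu = 200, size = 10), ncol = 4,
                dimnames = list(paste0("c", 1:100), paste0("s", 1:4)))
  expect_equal(unname(estimate_size_factors(big)),
               unname(brute_size_factors(big)), tolerance = 1e-12)

  # independent reference implementation agrees up to the geometric-mean
  # rescaling convention
  ds <- DESeq2::estimateSizeFactorsForMatrix(big)
  expect_equal(unname(estimate_size_factors(big)),
               unname(ds / exp(mean(log(ds)))), tolerance = 1e-3)
})

test_that("dispersion estimates recover truth and respect degenerate input", {
  # constant counts: variance 0 -> floor
  const <- matrix(100, nrow = 5, ncol = 6,
                  dimnames = list(paste0("c", 1:5), paste0("s", 1:6)))
  sf <- rep(1, 6)
  expect_true(all(estimate_dispersion(const, sf, rep(c("a", "b"), each = 3))
                  <= 1e-6))

  # NB truth alpha = 0.1, depth 1e3, 50 replicates: most estimates close
  set.seed(23)
  nb <- matrix(stats::rnbinom(200 * 50, mu = 1000, size = 10), ncol = 50)
  rownames(nb) <- paste0("c", 1:200); colnames(nb) <- paste0("s", 1:50)
  disp <- estimate_dispersion(nb, rep(1, 50), rep("g", 50))
  expect_gt(mean(disp >= 0.05 & disp <= 0.2), 0.9)

  # Poisson truth: estimates shrink toward zero with many replicates
  pois <- matrix(stats::rpois(200 * 50, 1000), ncol = 50)
  rownames(pois) <- paste0("c", 1:200); colnames(pois) <- paste0("s", 1:50)
  expect_lt(mean(estimate_dispersion(pois, rep(1, 50), rep("g", 50))), 0.005)
})

test_that("Wald test handles identity, zeros, and covers planted effects", {
  cts <- matrix(c(100, 200, 150, 100, 200, 150), nrow = 1,
                dimnames = list("c1", paste0("s", 1:6)))
  cts <- rbind(c1 = c(100, 200, 150, 100, 200, 150),
               c2 = c(0, 0, 0, 0, 0, 0),
               c3 = c(50, 60, 55, 52, 61, 57))
  colnames(cts) <- paste0("s", 1:6)
  st <- test_constructs(cts, rep(1, 6) |> stats::setNames(colnames(cts)),
                        0.05, treated = paste0("s", 1:3),
                        control = paste0("s", 4:6))
  expect_equal(st$log2FC[1], 0)
  expect_equal(st$p[1], 1)
  expect_true(st$untestable[2])
  expect_equal(st$log2FC[2], 0)
  expect_equal(st$p[2], 1)

  # BH monotonicity: padj ordering preserves p ordering
  set.seed(31)
  big <- matrix(stats::rnbinom(600, mu = 500, size = 20), ncol = 6)
  rownames(big) <- paste0("c", 1:100); colnames(big) <- paste0("s", 1:6)
  stb <- test_constructs(big, estimate_size_factors(big), 0.05,
                         paste0("s", 1:3), paste0("s", 4:6))
  ord <- order(stb$p)
  expect_true(all(diff(stb$padj[ord]) >= -1e-12))

  # coverage: planted 4-fold depletion (depth 1e4, alpha 0.05, 3v3)
  plant <- stats::setNames(lapply(1:50, function(i) list(invitro = -2)),
                           sprintf("GENE%03d", 1:50))
  p <- screen_sim_params(n_genes = 400L, n_ntc = 0L, contexts = "invitro",
                         replicates_per_context = 3L, depth = 1e4,
                         dispersion = 0.05, planted_effects = plant,
                         seed = 11L)
  d <- simulate_library(p)
  ct <- simulate_screen_counts(d, p)
  sfp <- estimate_size_factors(ct$counts)
  dispp <- estimate_dispersion(ct$counts, sfp, ct$meta$treatment)
  stp <- test_constructs(ct$counts, sfp, dispp,
                         treated = ct$meta$sample[ct$meta$treatment == "treated"],
                         control = ct$meta$sample[ct$meta$treatment == "vehicle"])
  planted <- stp$construct_id %in% d$construct_id[d$gene %in% names(plant)]
  expect_gt(mean(abs(stp$log2FC[planted] + 2) < 2 * stp$SE[planted]), 0.9)
})

test_that("Wald p-values track a label-permutation reference", {
  plant <- stats::setNames(lapply(1:8, function(i) list(invitro = -1.5)),
                           sprintf("GENE%03d", 1:8))
  p <- screen_sim_params(n_genes = 40L, n_ntc = 0L, contexts = "invitro",
                         replicates_per_context = 6L, depth = 1000,
                         dispersion = 0.05, planted_effects = plant,
                         seed = 12L)
  d <- simulate_library(p)
  ct <- simulate_screen_counts(d, p)
  sf <- estimate_size_factors(ct$counts)
  disp <- estimate_dispersion(ct$counts, sf, ct$meta$treatment)
  trt <- ct$meta$sample[ct$meta$treatment == "treated"]
  veh <- ct$meta$sample[ct$meta$treatment == "vehicle"]
  st <- test_constructs(ct$counts, sf, disp, trt, veh)
  k <- sweep(ct$counts, 2L, sf, "/")
  set.seed(1)
  perm_p <- vapply(seq_len(nrow(k)), function(i) {
    x <- k[i, c(trt, veh)]
    stat <- function(idx) abs(log2((mean(x[idx]) + 0.5) /
                                     (mean(x[-idx]) + 0.5)))
    obs <- stat(1:6)
    mean(replicate(2000, stat(sample(12, 6))) >= obs - 1e-12)
  }, numeric(1))
  # the two references agree in rank everywhere and in significance calls
  expect_gt(stats::cor(st$p, perm_p, method = "spearman"), 0.95)
  expect_gt(mean((st$p < 0.05) == (perm_p < 0.05)), 0.9)
})

test_that("NTC binning yields an exact seeded 5/5/4/4 partition", {
  ids <- sprintf("NTC_sh%02d", 1:18)
  b <- bin_ntcs(ids, seed = 7L)
  expect_equal(sort(as.integer(table(b$assignment)), decreasing = TRUE),
               c(5L, 5L, 4L, 4L))
  expect_setequal(names(b$assignment), ids)
  expect_setequal(unique(b$assignment), paste0("NTC", 1:4))
  expect_identical(bin_ntcs(ids, seed = 7L)$assignment, b$assignment)
  expect_false(identical(bin_ntcs(ids, seed = 8L)$assignment, b$assignment))
  expect_error(bin_ntcs(ids[1:10]), "sizes")
  expect_equal(sort(as.integer(table(bin_ntcs(ids[1:10],
                                              sizes = c(5L, 5L))$assignment))),
               c(5L, 5L))
})

test_that("gene aggregation takes medians, SEMs and the essential call", {
  mk <- function(gene, lfc, p) {
    data.frame(construct_id = paste0(gene, "_", seq_along(lfc)),
               log2FC = lfc, SE = 0.1, wald_z = 0, p = p,
               padj = p, untestable = FALSE, stringsAsFactors = FALSE)
  }
  st <- rbind(mk("gA", rep(-1.5, 5), rep(0.01, 5)),
              mk("gB", c(-2, -1, 0, 1, 2), rep(0.5, 5)),
              mk("gC", c(-1.6, -1.4, -1.3, 0.2, 0.1),
                 c(0.01, 0.02, 0.03, 0.9, 0.8)))
  map <- stats::setNames(sub("_[0-9]+$", "", st$construct_id),
                         st$construct_id)
  g <- aggregate_genes(st, map)
  expect_equal(g$median_log2FC[g$gene == "gA"], -1.5)
  expect_equal(g$sem[g$gene == "gA"], 0)
  expect_true(g$essential[g$gene == "gA"])
  expect_equal(g$median_log2FC[g$gene == "gB"], 0)
  expect_false(g$essential[g$gene == "gB"])
  expect_equal(g$median_log2FC[g$gene == "gC"], -1.3)
  expect_equal(g$n_sig_constructs[g$gene == "gC"], 3L)
  expect_true(g$essential[g$gene == "gC"])

  # even group size: mean of the two central values
  st4 <- mk("gD", c(-2, -1, 1, 4), rep(0.5, 4))
  g4 <- aggregate_genes(st4, stats::setNames(rep("gD", 4),
                                             st4$construct_id))
  expect_equal(g4$median_log2FC, 0)

  # order invariance and sign-flip equivariance
  shuf <- st[sample(nrow(st)), ]
  expect_equal(aggregate_genes(shuf, map), g)
  neg <- st; neg$log2FC <- -neg$log2FC
  gneg <- aggregate_genes(neg, map)
  expect_equal(gneg$median_log2FC, -g$median_log2FC)

  # untestable-only genes are excluded with a warning
  stu <- rbind(st, mk("gE", 0, 1))
  stu$untestable[stu$construct_id == "gE_1"] <- TRUE
  mapu <- c(map, gE_1 = "gE")
  expect_warning(gu <- aggregate_genes(stu, mapu), "gE")
  expect_false("gE" %in% gu$gene)
})

test_that("NTC pseudo-genes stay near zero in a null screen", {
  sc <- null_screen(404L, contexts = "invivo", replicates = 5L,
                    bottleneck_cells = 478000L)
  res <- analyze_screen_context(sc$counts, sc$design, "invivo",
                                ntc_binning = bin_ntcs(
                                  sc$design$construct_id[sc$design$is_ntc],
                                  seed = 404L))
  ntc <- res$gene_stats[grepl("^NTC", res$gene_stats$gene), ]
  expect_equal(nrow(ntc), 4L)
  expect_true(all(abs(ntc$median_log2FC) < 0.5))
  expect_true(all(!ntc$essential))
})
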