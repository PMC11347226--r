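# Synthetic-data generators: design arithmetic, determinism, and recovery
# of planted structure by independent oracles.

test_that("library construction follows the stated design arithmetic", {
  p <- screen_sim_params(n_genes = 92L, guides_per_gene = 5L, n_ntc = 18L)
  lib <- simulate_library(p)
  expect_equal(nrow(lib), 478L)
  expect_equal(sum(!lib$is_ntc), 460L)
  expect_equal(sum(lib$is_ntc), 18L)
  expect_false(anyDuplicated(lib$construct_id) > 0)
  expect_false(anyDuplicated(lib$guide_seq) > 0)
  expect_true(all(nchar(lib$guide_seq) == 22L))
  expect_true(all(grepl("^[ACGT]+$", lib$guide_seq)))

  tiny <- simulate_library(screen_sim_params(1L, 1L, 0L))
  expect_equal(nrow(tiny), 1L)

  expect_identical(simulate_library(p), simulate_library(p))
  expect_error(screen_sim_params(0L), "n_genes")
  expect_error(screen_sim_params(5L, depth = -1), "depth")
  expect_error(screen_sim_params(5L, dispersion = -0.1), "dispersion")
})

test_that("zero dispersion yields Poisson-scale counts at the right depth", {
  p <- screen_sim_params(n_genes = 200L, n_ntc = 0L, contexts = "invitro",
                         replicates_per_context = 3L, depth = 1000,
                         dispersion = 0, seed = 5L)
  d <- simulate_library(p)
  ct <- simulate_screen_counts(d, p)
  mu <- 1000 * ct$baseline
  z <- sweep(ct$counts, 1L, mu, "-") / sqrt(mu)
  expect_lt(abs(mean(ct$counts) - 1000), 3 * sqrt(1000 / length(ct$counts)) + 15)
  expect_lt(abs(stats::var(as.vector(z)) - 1), 0.1)
})

test_that("planted dropout is recovered by the direct count-ratio oracle", {
  plant <- stats::setNames(
    lapply(1:20, function(i) list(invitro = -2)), sprintf("GENE%03d", 1:20))
  p <- screen_sim_params(n_genes = 200L, n_ntc = 0L, contexts = "invitro",
                         replicates_per_context = 3L, depth = 1e4,
                         dispersion = 0.05, planted_effects = plant,
                         seed = 21L)
  d <- simulate_library(p)
  ct <- simulate_screen_counts(d, p)
  trt <- ct$meta$sample[ct$meta$treatment == "treated"]
  veh <- ct$meta$sample[ct$meta$treatment == "vehicle"]
  for (g in c("GENE001", "GENE010", "GENE020")) {
    idx <- d$construct_id[d$gene == g]
    oracle <- log2(mean(ct$counts[idx, trt]) / mean(ct$counts[idx, veh]))
    expect_lt(abs(oracle - (-2)), 0.2)
  }
  expect_error(
    simulate_screen_counts(
      d, screen_sim_params(n_genes = 200L, n_ntc = 0L, contexts = "invitro",
                           planted_effects = list(NOPE = list(invitro = -1)))),
    "unknown gene")
})

test_that("engraftment bottleneck conserves cells and drops rare constructs", {
  set.seed(99)
  ab <- exp(stats::rnorm(500, 0, 1))
  cells <- bottleneck_pool(ab, 5000L)
  expect_identical(sum(cells), 5000L)
  expect_identical(bottleneck_pool(ab, 1L * length(ab)) |> sum(), 500L)
  # low-abundance constructs are preferentially lost at 10 cells/construct
  cells10 <- bottleneck_pool(ab, 10L * 500L)
  expect_gt(sum(cells10 == 0), 0)
  expect_lt(mean(ab[cells10 == 0]), mean(ab))
})

test_that("dependency matrix rows carry the planted essential fractions", {
  dep <- simulate_dependency_matrix(3L, 1086L, c(0.5, 0, 1), seed = 3L)
  expect_equal(unname(rowSums(dep)), c(543, 0, 1086))
  expect_true(all(dep %in% c(0L, 1L)))
  expect_identical(dep, simulate_dependency_matrix(3L, 1086L, c(0.5, 0, 1),
                                                   seed = 3L))
  expect_error(simulate_dependency_matrix(2L, 10L, c(0.5, 1.2)), "fractions")
})

test_that("cohort simulator plants exact collinearity, overexpression and survival", {
  # exact collinearity: planted_r = 1 with no member noise
  p1 <- cohort_sim_params(n_patients = 40L, n_genes = 20L, geneset_size = 5L,
                          planted_r = 1, noise_sd = 0, seed = 8L)
  co <- simulate_cohort(p1)
  z <- scale_expression(co$fpkm[, co$classes == "tumour"])
  sc <- geneset_score(z, co$gene_set)
  expect_equal(correlate_candidate(z[co$candidate, ], sc)$r, 1,
               tolerance = 1e-10)

  # overexpression: ratio-of-means oracle within ±2 SE of the plant
  p2 <- cohort_sim_params(n_patients = 159L, tumour_overexpression_lfc = 1,
                          seed = 9L)
  co2 <- simulate_cohort(p2)
  est <- tumour_vs_normal_lfc(co2$fpkm, co2$classes, co2$candidate)
  expect_lt(abs(est$log2FC - 1), 3 * est$SE)

  # censoring fraction matches the nominal rate
  rates <- vapply(1:20, function(s) {
    cc <- simulate_cohort(cohort_sim_params(n_patients = 100L, n_genes = 10L,
                                            geneset_size = 3L,
                                            censoring_rate = 0.3, seed = s))
    mean(!cc$clinical$event)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.3), 0.03)
  expect_error(cohort_sim_params(geneset_size = 200L, n_genes = 100L),
               "geneset_size")
})

test_that("occupancy simulator honours degenerate depletion and noise settings", {
  base <- occupancy_sim_params(n_promoters = 300L, noise_sd = 0,
                               global_depletion = 1, seed = 4L)
  os <- simulate_occupancy(base)
  sp <- spike_scaling(os$spike)
  norm <- sweep(as.matrix(os$promoters[, c("vehicle", "treated")]), 2L,
                sp$f, "*")
  expect_equal(norm[, "vehicle"], norm[, "treated"], tolerance = 1e-10)

  gone <- simulate_occupancy(occupancy_sim_params(n_promoters = 300L,
                                                  noise_sd = 0,
                                                  global_depletion = 0,
                                                  seed = 4L))
  expect_true(all(gone$promoters$treated == 0))

  neg <- simulate_occupancy(occupancy_sim_params(n_promoters = 2000L,
                                                 regulation_slope = -0.5,
                                                 seed = 6L))
  spn <- spike_scaling(neg$spike)
  nv <- neg$promoters$vehicle * spn$f[spn$sample == "vehicle"]
  bp <- regulation_occupancy_binplot(neg$regulation, nv)
  expect_lt(bp$cor$r, 0)

  expect_identical(simulate_occupancy(base), simulate_occupancy(base))
  expect_error(occupancy_sim_params(spike_fraction = 1.5), "spike_fraction")
})

test_that("written synthetic inputs round-trip through the readers", {
  p <- screen_sim_params(n_genes = 5L, n_ntc = 3L, contexts = "invitro",
                         seed = 2L)
  d <- simulate_library(p)
  ct <- simulate_screen_counts(d, p)
  dir <- withr::local_tempdir()
  write_screen_inputs(d, ct, dir, params = p)
  lib2 <- read_library(file.path(dir, "library.tsv"))
  expect_equal(lib2$construct_id, d$construct_id)
  expect_equal(lib2$is_ntc, d$is_ntc)
  counts2 <- read_tsv_table(file.path(dir, "counts.tsv"))
  expect_equal(counts2$construct_id, rownames(ct$counts))
  expect_equal(as.matrix(counts2[, -1]), ct$counts,
               ignore_attr = TRUE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 2L)
})
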