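# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised on outputs of this module; the generators plant known effects so
# recovery can be checked against ground truth.

#' Parameters for the pooled shRNA screen simulator
#'
#' Describes a doxycycline-inducible dropout screen: a library of
#' `n_genes` target genes with `guides_per_gene` shRNAs each plus `n_ntc`
#' non-targeting controls, screened in one or more contexts (e.g. cultured
#' tumour cells, allografts, fibroblasts) with paired vehicle/treated
#' replicates. Counts are negative binomial with variance
#' `mu + dispersion * mu^2`; baseline construct abundances are log-normal
#' (sdlog 0.25) so the library-representation QC rule is non-trivial.
#'
#' @param n_genes Number of target genes.
#' @param guides_per_gene shRNAs per gene (default 5).
#' @param n_ntc Number of non-targeting control shRNAs (default 18).
#' @param contexts Character vector of screen context labels.
#' @param replicates_per_context Integer replicates per context (recycled),
#'   named by context or in `contexts` order.
#' @param depth Expected reads per construct (> 0).
#' @param dispersion NB dispersion alpha >= 0 (0 gives Poisson counts).
#' @param planted_effects Named list: gene -> named list context -> true
#'   log2 fold change applied to treated samples.
#' @param bottleneck_cells Optional total engrafted cell count; contexts in
#'   `bottleneck_contexts` pass the library through a multinomial
#'   bottleneck of this size per sample before the treatment effect.
#' @param bottleneck_contexts Contexts subject to the engraftment
#'   bottleneck (default: any context named `"invivo"`).
#' @param gene_names Optional explicit gene names (length `n_genes`).
#' @param seed Integer seed.
#' @return A validated list of class `screen_sim_params`.
#' @export
screen_sim_params <- function(n_genes,
                              guides_per_gene = 5L,
                              n_ntc = 18L,
                              contexts = c("invitro", "invivo", "fibroblast"),
                              replicates_per_context = 3L,
                              depth = 1000,
                              dispersion = 0.05,
                              planted_effects = list(),
                              bottleneck_cells = NULL,
                              bottleneck_contexts = intersect(contexts, "invivo"),
                              gene_names = NULL,
                              seed = 1L) {
  stop_if_not(is_count(n_genes), "n_genes must be a positive integer")
  stop_if_not(is_count(guides_per_gene), "guides_per_gene must be >= 1")
  stop_if_not(is_count(n_ntc, min = 0L), "n_ntc must be a non-negative integer")
  stop_if_not(length(contexts) >= 1L && !anyDuplicated(contexts),
              "contexts must be distinct labels")
  stop_if_not(is.numeric(depth) && all(depth > 0), "depth must be > 0")
  stop_if_not(is.numeric(dispersion) && dispersion >= 0,
              "dispersion must be >= 0")
  reps <- rep_len(as.integer(replicates_per_context), length(contexts))
  if (!is.null(names(replicates_per_context))) {
    reps <- as.integer(replicates_per_context[contexts])
  }
  stop_if_not(all(reps >= 1L), "replicates_per_context must be >= 1")
  if (!is.null(gene_names)) {
    stop_if_not(length(gene_names) == n_genes && !anyDuplicated(gene_names),
                "gene_names must be ", n_genes, " distinct names")
  }
  genes <- gene_names %||% sprintf("GENE%03d", seq_len(n_genes))
  if (length(planted_effects)) {
    stop_if_not(all(names(planted_effects) %in% genes),
                "planted_effects references unknown gene(s): ",
                paste(setdiff(names(planted_effects), genes), collapse = ", "))
    ok <- vapply(planted_effects, function(e) {
      all(names(e) %in% contexts) && all(is.finite(unlist(e)))
    }, logical(1))
    stop_if_not(all(ok), "planted_effects must map known contexts to finite log2FCs")
  }
  if (!is.null(bottleneck_cells)) {
    stop_if_not(is_count(bottleneck_cells), "bottleneck_cells must be a positive integer")
  }
  structure(list(n_genes = as.integer(n_genes),
                 guides_per_gene = as.integer(guides_per_gene),
                 n_ntc = as.integer(n_ntc),
                 contexts = contexts,
                 replicates_per_context = stats::setNames(reps, contexts),
                 depth = depth,
                 dispersion = dispersion,
                 planted_effects = planted_effects,
                 bottleneck_cells = bottleneck_cells,
                 bottleneck_contexts = bottleneck_contexts,
                 gene_names = genes,
                 seed = as.integer(seed)),
            class = "screen_sim_params")
}

#' Simulate an shRNA library design
#'
#' Builds the construct table for a pooled screen: `n_genes *
#' guides_per_gene` targeting shRNAs plus `n_ntc` non-targeting controls
#' (gene label `"NTC"`), each with a unique id and a unique random 22-nt
#' guide sequence. Deterministic given `params$seed`.
#'
#' @param params A [screen_sim_params()] object.
#' @return A data.frame with columns `construct_id`, `gene`, `guide_seq`,
#'   `is_ntc`.
#' @export
simulate_library <- function(params) {
  stop_if_not(inherits(params, "screen_sim_params"),
              "params must come from screen_sim_params()")
  genes <- params$gene_names
  n_t <- params$n_genes * params$guides_per_gene
  n <- n_t + params$n_ntc
  ids <- c(paste0(rep(genes, each = params$guides_per_gene), "_sh",
                  rep(seq_len(params$guides_per_gene), params$n_genes)),
           if (params$n_ntc > 0) sprintf("NTC_sh%02d", seq_len(params$n_ntc)))
  gene_col <- c(rep(genes, each = params$guides_per_gene),
                rep("NTC", params$n_ntc))
  guides <- with_seed(params$seed, {
    repeat {
      g <- apply(matrix(sample(c("A", "C", "G", "T"), 22L * n, replace = TRUE),
                        nrow = n), 1L, paste, collapse = "")
      if (!anyDuplicated(g)) break
    }
    g
  })
  data.frame(construct_id = ids, gene = gene_col, guide_seq = guides,
             is_ntc = gene_col == "NTC", stringsAsFactors = FALSE)
}

#' Pass a construct pool through an engraftment bottleneck
#'
#' Draws the number of cells carrying each construct after engrafting
#' `n_cells` cells from a pool with the given relative abundances. The
#' draw is multinomial, so the total cell count is conserved exactly.
#'
#' @param abundance Non-negative relative abundances, one per construct.
#' @param n_cells Total number of engrafted cells.
#' @return Integer vector of per-construct cell counts summing to `n_cells`.
#' @export
bottleneck_pool <- function(abundance, n_cells) {
  stop_if_not(all(abundance >= 0) && sum(abundance) > 0,
              "abundance must be non-negative with positive sum")
  stop_if_not(is_count(n_cells), "n_cells must be a positive integer")
  as.vector(stats::rmultinom(1L, size = n_cells, prob = abundance))
}

#' Simulate screen counts with planted dropout effects
#'
#' For each context and replicate, draws paired vehicle/treated construct
#' counts from a negative binomial with mean
#' `depth * baseline * 2^lfc` (lfc from `planted_effects` for treated
#' samples, 0 otherwise) and variance `mu + dispersion * mu^2`. Contexts
#' listed in `params$bottleneck_contexts` first pass the library through an
#' independent multinomial engraftment bottleneck per sample
#' (`bottleneck_cells` cells), emulating allograft screens.
#'
#' @param design Library design from [simulate_library()].
#' @param params A [screen_sim_params()] object consistent with `design`.
#' @return A list of class `count_table` with `counts` (integer matrix,
#'   constructs x samples), `meta` (data.frame: sample, context, treatment,
#'   replicate) and `baseline` (the true relative abundances).
#' @export
simulate_screen_counts <- function(design, params) {
  stop_if_not(inherits(params, "screen_sim_params"),
              "params must come from screen_sim_params()")
  stop_if_not(is.data.frame(design) &&
                all(c("construct_id", "gene") %in% names(design)),
              "design must be a library design data.frame")
  genes <- setdiff(unique(design$gene), "NTC")
  stop_if_not(all(names(params$planted_effects) %in% genes),
              "planted effect references gene absent from design")
  n <- nrow(design)
  with_seed(params$seed + 1L, {
    baseline <- exp(stats::rnorm(n, 0, 0.25))
    baseline <- baseline / mean(baseline)
    cols <- list(); meta <- list()
    for (ctx in params$contexts) {
      lfc <- vapply(design$gene, function(g) {
        e <- params$planted_effects[[g]]
        if (is.null(e)) 0 else (e[[ctx]] %||% 0)
      }, numeric(1), USE.NAMES = FALSE)
      bneck <- !is.null(params$bottleneck_cells) &&
        ctx %in% params$bottleneck_contexts
      for (r in seq_len(params$replicates_per_context[[ctx]])) {
        for (trt in c("vehicle", "treated")) {
          base_s <- baseline
          if (bneck) {
            cells <- bottleneck_pool(baseline, params$bottleneck_cells)
            base_s <- cells / sum(cells) * n
          }
          mu <- params$depth * base_s *
            if (trt == "treated") 2^lfc else 1
          counts <- if (params$dispersion == 0) {
            stats::rpois(n, mu)
          } else {
            stats::rnbinom(n, mu = mu, size = 1 / params$dispersion)
          }
          nm <- paste(ctx, trt, r, sep = "_")
          cols[[nm]] <- counts
          meta[[nm]] <- data.frame(sample = nm, context = ctx,
                                   treatment = trt, replicate = r,
                                   stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- design$construct_id
    structure(list(counts = counts,
                   meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                   baseline = stats::setNames(baseline, design$construct_id)),
              class = "count_table")
  })
}

#' Simulate a binary gene-by-cell-line dependency matrix
#'
#' Emulates a dependency-portal reference: each gene's row contains
#' `round(fraction * n_lines)` ones placed at seeded-random cell lines.
#'
#' @param n_genes Number of genes (ignored if `planted_fractions` is named
#'   with the full gene set).
#' @param n_lines Number of cell lines (columns).
#' @param planted_fractions Per-gene fraction of dependent lines in
#'   \[0, 1\]; recycled to `n_genes` if unnamed.
#' @param seed Integer seed.
#' @param gene_names Optional gene names.
#' @return Binary integer matrix, genes x cell lines.
#' @export
simulate_dependency_matrix <- function(n_genes, n_lines, planted_fractions,
                                       seed = 1L, gene_names = NULL) {
  stop_if_not(is_count(n_genes) && is_count(n_lines),
              "n_genes and n_lines must be positive integers")
  stop_if_not(all(planted_fractions >= 0 & planted_fractions <= 1),
              "planted_fractions must lie in [0, 1]")
  frac <- rep_len(planted_fractions, n_genes)
  genes <- gene_names %||% names(planted_fractions) %||%
    sprintf("GENE%03d", seq_len(n_genes))
  genes <- rep_len(genes, n_genes)
  with_seed(seed, {
    mat <- matrix(0L, nrow = n_genes, ncol = n_lines,
                  dimnames = list(genes, sprintf("LINE%04d", seq_len(n_lines))))
    for (i in seq_len(n_genes)) {
      k <- round(frac[i] * n_lines)
      if (k > 0) mat[i, sample.int(n_lines, k)] <- 1L
    }
    mat
  })
}

#' Parameters for the expression/survival pseudo-cohort simulator
#'
#' Describes a tumour cohort with a latent "activity" factor (a stand-in
#' for MYC pathway activity): a designated gene set whose members track the
#' factor (per-gene noise `noise_sd`), one designated candidate gene whose
#' scaled expression correlates with the factor at `planted_r`, a small
#' healthy-reference group in which the candidate is underexpressed by
#' `tumour_overexpression_lfc` (log2), and exponential survival times whose
#' hazard differs by `survival_hazard_ratio` between the top and bottom
#' thirds of the latent factor.
#'
#' @param n_patients Number of tumour samples (>= 4).
#' @param n_genes Total genes in the expression matrix.
#' @param geneset_size Size of the activity gene set (<= n_genes).
#' @param planted_r Target Pearson correlation (|r| <= 1) between the
#'   candidate and the activity score.
#' @param tumour_overexpression_lfc Tumour-vs-normal log2 fold change of
#'   the candidate.
#' @param survival_hazard_ratio Hazard ratio (> 0), top vs bottom
#'   activity-score third.
#' @param censoring_rate Fraction of patients censored, in \[0, 1\].
#' @param noise_sd Per-gene noise sd around the latent factor.
#' @param n_normal Number of healthy-reference samples.
#' @param baseline_hazard Event rate per day in the low stratum.
#' @param seed Integer seed.
#' @return A validated list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 159L,
                              n_genes = 120L,
                              geneset_size = 25L,
                              planted_r = 0.8,
                              tumour_overexpression_lfc = 1,
                              survival_hazard_ratio = 2,
                              censoring_rate = 0.3,
                              noise_sd = 0.3,
                              n_normal = 4L,
                              baseline_hazard = log(2) / 600,
                              seed = 1L) {
  stop_if_not(is_count(n_patients, 4L), "n_patients must be >= 4")
  stop_if_not(is_count(n_genes) && is_count(geneset_size),
              "n_genes and geneset_size must be positive integers")
  stop_if_not(geneset_size <= n_genes, "geneset_size exceeds n_genes")
  stop_if_not(abs(planted_r) <= 1, "|planted_r| must be <= 1")
  stop_if_not(survival_hazard_ratio > 0, "survival_hazard_ratio must be > 0")
  stop_if_not(censoring_rate >= 0 && censoring_rate <= 1,
              "censoring_rate must be in [0, 1]")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 geneset_size = as.integer(geneset_size),
                 planted_r = planted_r,
                 tumour_overexpression_lfc = tumour_overexpression_lfc,
                 survival_hazard_ratio = survival_hazard_ratio,
                 censoring_rate = censoring_rate,
                 noise_sd = noise_sd,
                 n_normal = as.integer(n_normal),
                 baseline_hazard = baseline_hazard,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

#' Simulate an expression cohort with planted correlation and survival
#'
#' Generates a non-negative FPKM matrix (genes x samples) for
#' `n_patients` tumours and `n_normal` healthy references. Gene-set member
#' FPKM is `base * 2^(0.5 * (A + noise))` around the per-patient latent
#' activity `A ~ N(0,1)`; the candidate gene uses
#' `planted_r * A + sqrt(1 - planted_r^2) * noise` in place of `A + noise`,
#' so its scaled expression correlates with the activity score at about
#' `planted_r` (exactly 1 when `planted_r = 1` and `noise_sd = 0`).
#' Survival times are exponential with hazard `baseline_hazard` in the
#' bottom latent-activity third, `baseline_hazard * HR` in the top and the
#' geometric mean in between; censoring is independent at
#' `censoring_rate`, uniform over each patient's follow-up.
#'
#' @param params A [cohort_sim_params()] object.
#' @return A list of class `expression_cohort`: `fpkm` (matrix), `classes`
#'   (`"tumour"`/`"normal"` per column), `clinical` (data.frame: sample,
#'   time, event; tumours only), `gene_set` (member gene names),
#'   `candidate` (candidate gene name), `latent` (true activity factor).
#' @export
simulate_cohort <- function(params) {
  stop_if_not(inherits(params, "cohort_sim_params"),
              "params must come from cohort_sim_params()")
  p <- params
  with_seed(p$seed, {
    A <- stats::rnorm(p$n_patients)
    set_genes <- sprintf("SET%03d", seq_len(p$geneset_size))
    candidate <- "CAND1"
    n_bg <- p$n_genes - p$geneset_size - 1L
    stop_if_not(n_bg >= 0, "n_genes too small for gene set plus candidate")
    bg_genes <- if (n_bg > 0) sprintf("BG%03d", seq_len(n_bg)) else character()
    genes <- c(candidate, set_genes, bg_genes)

    base <- exp(stats::rnorm(length(genes), log(20), 0.8))
    names(base) <- genes
    z <- matrix(stats::rnorm(length(genes) * p$n_patients),
                nrow = length(genes), dimnames = list(genes, NULL))
    for (g in set_genes) {
      z[g, ] <- A + stats::rnorm(p$n_patients, 0, p$noise_sd)
    }
    z[candidate, ] <- p$planted_r * A +
      sqrt(max(0, 1 - p$planted_r^2)) * stats::rnorm(p$n_patients, 0, 1)
    fpkm_t <- base * 2^(0.5 * z)

    # healthy reference: candidate mean scaled down by the planted log2FC,
    # all other genes drawn around their tumour mean
    tum_mean <- rowMeans(fpkm_t)
    sdlog <- 0.2
    fpkm_n <- matrix(stats::rlnorm(length(genes) * p$n_normal,
                                   meanlog = log(tum_mean) - sdlog^2 / 2,
                                   sdlog = sdlog),
                     nrow = length(genes), dimnames = list(genes, NULL))
    fpkm_n[candidate, ] <- fpkm_n[candidate, ] *
      2^(-p$tumour_overexpression_lfc)

    fpkm <- cbind(fpkm_t, fpkm_n)
    colnames(fpkm) <- c(sprintf("T%03d", seq_len(p$n_patients)),
                        sprintf("N%02d", seq_len(p$n_normal)))
    classes <- stats::setNames(rep(c("tumour", "normal"),
                                   c(p$n_patients, p$n_normal)),
                               colnames(fpkm))

    terts <- stats::quantile(A, c(1, 2) / 3)
    hr <- p$survival_hazard_ratio
    rate <- ifelse(A >= terts[2], p$baseline_hazard * hr,
                   ifelse(A <= terts[1], p$baseline_hazard,
                          p$baseline_hazard * sqrt(hr)))
    t_event <- stats::rexp(p$n_patients, rate)
    censored <- stats::runif(p$n_patients) < p$censoring_rate
    time <- ifelse(censored, stats::runif(p$n_patients) * t_event, t_event)
    clinical <- data.frame(sample = sprintf("T%03d", seq_len(p$n_patients)),
                           time = time, event = !censored,
                           stringsAsFactors = FALSE)

    structure(list(fpkm = fpkm, classes = classes, clinical = clinical,
                   gene_set = set_genes, candidate = candidate,
                   latent = stats::setNames(A, clinical$sample),
                   params = p),
              class = "expression_cohort")
  })
}

#' Parameters for the spike-in ChIP occupancy simulator
#'
#' Describes a two-sample (vehicle vs treated) spike-normalized ChIP
#' experiment over `n_promoters` promoters. The spike-in chromatin amount
#' is constant across samples; `spike_fraction` fixes it as the spike-in
#' read fraction of the vehicle sample. `global_depletion` multiplies the
#' treated experimental signal, emulating genome-wide loss of binding that
#' only spike-in normalization can reveal.
#'
#' @param n_promoters Number of promoters.
#' @param spike_fraction Spike-in read fraction of the vehicle sample,
#'   in (0, 1).
#' @param global_depletion Multiplier (>= 0) on treated experimental
#'   signal.
#' @param regulation_slope Slope linking standardized vehicle occupancy to
#'   simulated gene regulation (log2FC on depletion).
#' @param noise_sd Relative noise sd on per-promoter signal (and absolute
#'   noise sd on regulation values); >= 0.
#' @param resample_reads If `TRUE`, per-promoter and spike read counts are
#'   Poisson-resampled around their expectations (read-level realism); if
#'   `FALSE` expectations are returned directly.
#' @param seed Integer seed.
#' @return A validated list of class `occupancy_sim_params`.
#' @export
occupancy_sim_params <- function(n_promoters = 5000L,
                                 spike_fraction = 0.06,
                                 global_depletion = 0.2,
                                 regulation_slope = -0.5,
                                 noise_sd = 0.1,
                                 resample_reads = FALSE,
                                 seed = 1L) {
  stop_if_not(is_count(n_promoters), "n_promoters must be a positive integer")
  stop_if_not(spike_fraction > 0 && spike_fraction < 1,
              "spike_fraction must be in (0, 1)")
  stop_if_not(global_depletion >= 0, "global_depletion must be >= 0")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(n_promoters = as.integer(n_promoters),
                 spike_fraction = spike_fraction,
                 global_depletion = global_depletion,
                 regulation_slope = regulation_slope,
                 noise_sd = noise_sd,
                 resample_reads = isTRUE(resample_reads),
                 seed = as.integer(seed)),
            class = "occupancy_sim_params")
}

#' Simulate a spike-normalized two-sample occupancy data set
#'
#' Per-promoter vehicle signal is a log-normal baseline with relative
#' noise; treated signal is the same baseline (independent noise) scaled by
#' `global_depletion`. Each sample gets an arbitrary sequencing scale, so
#' raw read counts are not comparable until spike-normalized. Gene
#' regulation values are `regulation_slope` times the standardized vehicle
#' occupancy plus noise.
#'
#' @param params An [occupancy_sim_params()] object.
#' @return A list of class `occupancy_set`: `promoters` (data.frame: gene,
#'   vehicle, treated raw read counts), `spike` (data.frame: sample, n_exp,
#'   n_spike), `regulation` (named numeric), `truth` (list with the
#'   noise-free signals and sequencing scales).
#' @export
simulate_occupancy <- function(params) {
  stop_if_not(inherits(params, "occupancy_sim_params"),
              "params must come from occupancy_sim_params()")
  p <- params
  with_seed(p$seed, {
    genes <- sprintf("PROM%05d", seq_len(p$n_promoters))
    baseline <- exp(stats::rnorm(p$n_promoters, log(100), 1))
    sig_v <- pmax(baseline * (1 + stats::rnorm(p$n_promoters, 0, p$noise_sd)), 0)
    sig_t <- p$global_depletion *
      pmax(baseline * (1 + stats::rnorm(p$n_promoters, 0, p$noise_sd)), 0)

    # constant spike-in material; read fraction pinned on the vehicle sample
    S <- p$spike_fraction / (1 - p$spike_fraction) * sum(sig_v)
    q <- c(vehicle = 1, treated = stats::runif(1, 0.6, 1.6))
    exp_counts <- cbind(vehicle = q["vehicle"] * sig_v,
                        treated = q["treated"] * sig_t)
    spike_exp <- q * S
    if (p$resample_reads) {
      counts <- matrix(stats::rpois(length(exp_counts), exp_counts),
                       ncol = 2, dimnames = dimnames(exp_counts))
      n_spike <- stats::rpois(2L, spike_exp)
    } else {
      counts <- exp_counts
      n_spike <- spike_exp
    }

    occ_z <- as.vector(scale(sig_v))
    if (stats::sd(sig_v) == 0) occ_z <- rep(0, p$n_promoters)
    regulation <- p$regulation_slope * occ_z +
      stats::rnorm(p$n_promoters, 0, p$noise_sd)

    structure(list(promoters = data.frame(gene = genes,
                                          vehicle = counts[, "vehicle"],
                                          treated = counts[, "treated"],
                                          stringsAsFactors = FALSE),
                   spike = data.frame(sample = c("vehicle", "treated"),
                                      n_exp = colSums(counts),
                                      n_spike = n_spike,
                                      stringsAsFactors = FALSE),
                   regulation = stats::setNames(regulation, genes),
                   truth = list(signal_vehicle = sig_v,
                                signal_treated = sig_t,
                                seq_scale = q, spike_amount = S),
                   params = p),
              class = "occupancy_set")
  })
}

#' Write synthetic inputs and a run manifest to disk
#'
#' Serializes a simulated screen (library + counts + metadata) in the TSV
#' formats the pipeline reads, alongside a JSON manifest recording the
#' generator parameters and seed.
#'
#' @param design Library design data.frame.
#' @param count_table A `count_table` from [simulate_screen_counts()].
#' @param dir Output directory (created if missing).
#' @param params The generating [screen_sim_params()], recorded in the
#'   manifest.
#' @return `dir`, invisibly.
#' @export
write_screen_inputs <- function(design, count_table, dir, params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_table(design[, c("construct_id", "gene", "guide_seq")],
                  file.path(dir, "library.tsv"))
  write_tsv_table(count_table$counts, file.path(dir, "counts.tsv"),
                  row_names = "construct_id")
  write_tsv_table(count_table$meta, file.path(dir, "samples.tsv"))
  if (!is.null(params)) {
    jsonlite::write_json(unclass(params), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(dir)
}
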