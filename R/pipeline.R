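# End-to-end orchestration: a single config drives simulation, counting/QC,
# differential testing, gene aggregation, triage, expression/survival and
# occupancy, writing tables and a JSON run manifest.

#' Default run configuration
#'
#' Study-condition defaults: a 92-gene library with five shRNAs per gene
#' plus 18 NTCs (478 constructs), screened in cultured tumour cells (3
#' replicates), allografts (5, with an engraftment bottleneck of 1000
#' cells per construct) and fibroblasts (3) at 1000 reads per construct;
#' a 159-patient cohort with 4 healthy references; a 1086-line dependency
#' reference; and a 5000-promoter spike-in occupancy experiment with an
#' 80% planted global depletion. One gene (`GENE001`) is planted to pass
#' all four triage filters: depleted in vivo, tumour-selective vs
#' fibroblasts, co-expressed with the activity score (r 0.8) and
#' overexpressed in tumours (log2FC 1). Thresholds default to the
#' printed analysis values (essential log2FC -1, p 0.05, essentiality
#' score 50, co-expression r 0.5, overexpression log2FC 0.3).
#'
#' @param seed Integer master seed; stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  genes <- sprintf("GENE%03d", 1:92)
  plant <- list()
  plant[["GENE001"]] <- list(invitro = -2, invivo = -2, fibroblast = 0)
  for (g in genes[2:10]) {
    plant[[g]] <- list(invitro = -2.5, invivo = -2, fibroblast = -2)
  }
  for (g in genes[11:30]) {
    plant[[g]] <- list(invitro = -2, invivo = 0, fibroblast = 0)
  }
  for (g in genes[31:40]) {
    plant[[g]] <- list(invivo = -2, fibroblast = -2)
  }
  frac <- stats::setNames(rep(0.05, length(genes)), genes)
  frac[genes[2:10]] <- 0.8
  frac[genes[11:30]] <- 0.3
  frac["GENE001"] <- 0.55

  structure(list(
    seed = as.integer(seed),
    candidate_gene = "GENE001",
    screen = screen_sim_params(
      n_genes = 92L, guides_per_gene = 5L, n_ntc = 18L,
      contexts = c("invitro", "invivo", "fibroblast"),
      replicates_per_context = c(invitro = 3L, invivo = 5L, fibroblast = 3L),
      depth = 1000, dispersion = 0.05, planted_effects = plant,
      bottleneck_cells = 1000L * 478L, gene_names = genes,
      seed = as.integer(seed)),
    dependency = list(n_lines = 1086L, planted_fractions = frac),
    cohort = cohort_sim_params(seed = as.integer(seed) + 101L),
    occupancy = occupancy_sim_params(seed = as.integer(seed) + 202L,
                                     resample_reads = TRUE),
    thresholds = list(essential_lfc = -1, p = 0.05, essentiality = 50,
                      r = 0.5, overexpression = 0.3),
    modes = list(scale_include_normals = FALSE, survival_mode = "full",
                 min_sig_constructs = 2L)),
    class = "run_config")
}

validate_config <- function(config) {
  stop_if_not(inherits(config, "run_config") || is.list(config),
              "config must be a run_config list")
  thr <- config$thresholds
  stop_if_not(!is.null(thr) && all(vapply(thr, is.finite, logical(1))),
              "all thresholds must be finite")
  for (p in config$input_paths %||% list()) {
    stop_if_not(file.exists(p), "configured input path missing: ", p)
  }
  stop_if_not(inherits(config$screen, "screen_sim_params"),
              "config$screen must be screen_sim_params()")
  stop_if_not(inherits(config$cohort, "cohort_sim_params"),
              "config$cohort must be cohort_sim_params()")
  stop_if_not(inherits(config$occupancy, "occupancy_sim_params"),
              "config$occupancy must be occupancy_sim_params()")
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full triage pipeline on synthetic inputs
#'
#' Executes simulate -> count QC -> per-context differential test ->
#' gene aggregation -> cross-screen comparison -> essentiality scoring ->
#' expression/survival -> candidate ranking -> occupancy analyses, writing
#' stage tables and a JSON manifest (seeds, parameters, config hash) to
#' `out_dir`. Reruns with an identical config are identical.
#'
#' @param config A [default_config()]-style configuration.
#' @param out_dir Output directory (created; default: fresh temp dir).
#' @return A list of class `pipeline_run` with all stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds

  design <- run_stage("simulate_library", simulate_library(config$screen))
  counts <- run_stage("simulate_counts",
                      simulate_screen_counts(design, config$screen))
  qc <- run_stage("representation_qc",
                  representation_qc(counts$counts[, 1], design))

  ntc_ids <- design$construct_id[design$gene == "NTC"]
  binning <- if (length(ntc_ids) == 18L) {
    bin_ntcs(ntc_ids, seed = config$seed)
  }
  screens <- run_stage("screen_stats", {
    res <- lapply(config$screen$contexts, function(ctx) {
      analyze_screen_context(counts, design, ctx, ntc_binning = binning,
                             lfc_threshold = thr$essential_lfc,
                             p_threshold = thr$p,
                             min_sig_constructs = config$modes$min_sig_constructs)
    })
    names(res) <- config$screen$contexts
    res
  })
  gene_stats <- lapply(screens, `[[`, "gene_stats")
  comparison <- run_stage("compare_screens",
                          compare_screens(gene_stats,
                                          threshold = thr$essential_lfc))

  dep <- run_stage("dependency_matrix", simulate_dependency_matrix(
    n_genes = config$screen$n_genes, n_lines = config$dependency$n_lines,
    planted_fractions = config$dependency$planted_fractions,
    seed = config$seed + 7L, gene_names = config$screen$gene_names))
  scores <- run_stage("essentiality_score",
                      essentiality_score(dep, threshold = thr$essentiality))

  cohort <- run_stage("simulate_cohort", simulate_cohort(config$cohort))
  expr <- run_stage("expression_survival", {
    tum <- cohort$classes == "tumour"
    z <- if (isTRUE(config$modes$scale_include_normals)) {
      scale_expression(cohort$fpkm)[, tum, drop = FALSE]
    } else {
      scale_expression(cohort$fpkm[, tum, drop = FALSE])
    }
    score <- geneset_score(z, cohort$gene_set)
    # map screen genes onto cohort rows: the designated candidate carries
    # the planted signal, remaining screen genes take background rows
    bg <- grep("^BG", rownames(cohort$fpkm), value = TRUE)
    other <- setdiff(config$screen$gene_names, config$candidate_gene)
    stop_if_not(length(bg) >= length(other),
                "cohort has too few background genes for the screen universe")
    gene_rows <- stats::setNames(c(cohort$candidate, bg[seq_along(other)]),
                                 c(config$candidate_gene, other))
    coexpr <- data.frame(
      gene = names(gene_rows),
      r = vapply(gene_rows, function(rw)
        correlate_candidate(z[rw, ], score)$r, numeric(1)),
      stringsAsFactors = FALSE)
    overexpr <- data.frame(
      gene = names(gene_rows),
      log2FC = vapply(gene_rows, function(rw)
        tumour_vs_normal_lfc(cohort$fpkm, cohort$classes, rw)$log2FC,
        numeric(1)),
      stringsAsFactors = FALSE)
    surv <- stratify_and_logrank(z[cohort$candidate, ], score,
                                 cohort$clinical,
                                 mode = config$modes$survival_mode)
    list(z = z, score = score, coexpression = coexpr,
         overexpression = overexpr, survival = surv,
         gene_rows = gene_rows)
  })

  candidates <- run_stage("rank_candidates", rank_candidates(
    comparison, expr$coexpression, expr$overexpression, scores,
    lfc_threshold = thr$essential_lfc, r_threshold = thr$r,
    overexpr_threshold = thr$overexpression))

  occ <- run_stage("occupancy", {
    oset <- simulate_occupancy(config$occupancy)
    spike <- spike_scaling(oset$spike)
    f <- stats::setNames(spike$f, spike$sample)
    norm_v <- oset$promoters$vehicle * f["vehicle"]
    norm_t <- oset$promoters$treated * f["treated"]
    depletion <- sum(norm_t) / sum(norm_v)
    binplot <- regulation_occupancy_binplot(oset$regulation,
                                            cbind(occupancy = norm_v))
    delta <- log2((norm_t + 1) / (norm_v + 1))
    rankplot <- rank_binplot(delta, norm_v)
    list(set = oset, spike = spike, normalized = data.frame(
      gene = oset$promoters$gene, vehicle = norm_v, treated = norm_t,
      delta_log2FC = delta, stringsAsFactors = FALSE),
      depletion_estimate = depletion, binplot = binplot,
      rankplot = rankplot)
  })

  run_stage("write_outputs", {
    write_screen_inputs(design, counts, file.path(out_dir, "inputs"),
                        params = config$screen)
    for (ctx in names(screens)) {
      write_tsv_table(screens[[ctx]]$construct_stats,
                      file.path(out_dir, paste0("constructs_", ctx, ".tsv")))
      write_tsv_table(gene_stats[[ctx]],
                      file.path(out_dir, paste0("genes_", ctx, ".tsv")))
    }
    write_tsv_table(comparison, file.path(out_dir, "comparison.tsv"))
    write_tsv_table(scores, file.path(out_dir, "essentiality.tsv"))
    write_tsv_table(expr$coexpression, file.path(out_dir, "coexpression.tsv"))
    write_tsv_table(expr$overexpression,
                    file.path(out_dir, "overexpression.tsv"))
    write_tsv_table(expr$survival$km, file.path(out_dir, "km_curves.tsv"))
    write_tsv_table(candidates, file.path(out_dir, "candidates.tsv"))
    write_tsv_table(occ$normalized, file.path(out_dir, "occupancy.tsv"))
    write_tsv_table(occ$binplot$bins, file.path(out_dir, "binplot.tsv"))
    write_tsv_table(occ$rankplot, file.path(out_dir, "rankplot.tsv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("screentriage")),
      seed = config$seed,
      config_hash = rlang::hash(config),
      qc = unclass(qc),
      logrank = list(chi2 = expr$survival$logrank_chi2,
                     p = expr$survival$p),
      depletion_estimate = occ$depletion_estimate,
      top_candidate = if (any(candidates$pass_all))
        candidates$gene[which(candidates$rank == 1)] else NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })

  structure(list(config = config, design = design, counts = counts,
                 qc = qc, ntc_binning = binning, screens = screens,
                 gene_stats = gene_stats, comparison = comparison,
                 dependency = dep, scores = scores, cohort = cohort,
                 expression = expr, candidates = candidates,
                 occupancy = occ, out_dir = out_dir),
            class = "pipeline_run")
}

#' Build plot-ready report tables from a completed run
#'
#' Emits the figure-style tables: a waterfall table (genes sorted by
#' ascending median log2FC, with SEM) per context, a volcano table
#' (per-construct log2FC and -log10 p, NTCs flagged) per context, the in
#' vitro vs in vivo scatter with quadrant classes, and the
#' regulation/occupancy bin-plot table.
#'
#' @param run A `pipeline_run` from [run_pipeline()], or its `out_dir`.
#' @return Named list of data.frames (also written under
#'   `<out_dir>/report/` when a run directory is available).
#' @export
make_report <- function(run) {
  if (is.character(run)) {
    dir <- run
    need <- c("comparison.tsv", "binplot.tsv")
    ctx_files <- list.files(dir, pattern = "^genes_.*\\.tsv$")
    missing <- c(need[!file.exists(file.path(dir, need))],
                 if (length(ctx_files) == 0) "genes_<context>.tsv")
    stop_if_not(length(missing) == 0,
                "incomplete run; missing stage output(s): ",
                paste(missing, collapse = ", "))
    contexts <- sub("^genes_(.*)\\.tsv$", "\\1", ctx_files)
    gene_stats <- lapply(stats::setNames(contexts, contexts), function(ctx)
      read_tsv_table(file.path(dir, paste0("genes_", ctx, ".tsv"))))
    construct_stats <- lapply(stats::setNames(contexts, contexts),
                              function(ctx)
      read_tsv_table(file.path(dir, paste0("constructs_", ctx, ".tsv"))))
    comparison <- read_tsv_table(file.path(dir, "comparison.tsv"))
    binplot <- read_tsv_table(file.path(dir, "binplot.tsv"))
  } else {
    stop_if_not(inherits(run, "pipeline_run"), "not a pipeline run")
    dir <- run$out_dir
    gene_stats <- run$gene_stats
    construct_stats <- lapply(run$screens, `[[`, "construct_stats")
    comparison <- run$comparison
    binplot <- run$occupancy$binplot$bins
  }
  report <- list()
  for (ctx in names(gene_stats)) {
    g <- gene_stats[[ctx]]
    report[[paste0("waterfall_", ctx)]] <-
      g[order(g$median_log2FC), c("gene", "median_log2FC", "sem")]
    cs <- construct_stats[[ctx]]
    report[[paste0("volcano_", ctx)]] <-
      data.frame(construct_id = cs$construct_id, gene = cs$gene,
                 log2FC = cs$log2FC, neg_log10_p = -log10(pmax(cs$p, 1e-300)),
                 is_ntc = grepl("^NTC", cs$gene), stringsAsFactors = FALSE)
  }
  report$scatter <- comparison
  report$binplot <- binplot
  rep_dir <- file.path(dir, "report")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report)) {
    write_tsv_table(report[[nm]], file.path(rep_dir, paste0(nm, ".tsv")))
  }
  invisible(report)
}

#' Save / load a run configuration
#'
#' JSON round-trip for [default_config()]-style objects; parameter blocks
#' are re-validated through their constructors on load, so
#' `load_config(save_config(cfg, p))` reproduces `cfg`.
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   a `run_config`.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  payload <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  # named atomic vectors must travel as JSON objects to keep their names
  payload$screen$replicates_per_context <-
    as.list(config$screen$replicates_per_context)
  payload$dependency$planted_fractions <-
    as.list(config$dependency$planted_fractions)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  relist_effects <- function(pe) lapply(pe, as.list)
  screen <- raw$screen
  cfg <- list(
    seed = as.integer(raw$seed),
    candidate_gene = raw$candidate_gene,
    screen = screen_sim_params(
      n_genes = screen$n_genes, guides_per_gene = screen$guides_per_gene,
      n_ntc = screen$n_ntc, contexts = screen$contexts,
      replicates_per_context = unlist(screen$replicates_per_context),
      depth = screen$depth, dispersion = screen$dispersion,
      planted_effects = relist_effects(screen$planted_effects),
      bottleneck_cells = screen$bottleneck_cells,
      bottleneck_contexts = screen$bottleneck_contexts,
      gene_names = screen$gene_names, seed = screen$seed),
    dependency = list(
      n_lines = as.integer(raw$dependency$n_lines),
      planted_fractions = unlist(raw$dependency$planted_fractions)),
    cohort = do.call(cohort_sim_params, raw$cohort),
    occupancy = do.call(occupancy_sim_params, raw$occupancy),
    thresholds = raw$thresholds,
    modes = raw$modes)
  cfg$modes$min_sig_constructs <- as.integer(cfg$modes$min_sig_constructs)
  structure(cfg, class = "run_config")
}
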