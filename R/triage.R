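# Candidate triage: dependency-reference essentiality scores, cross-screen
# comparison, and the multi-filter candidate ranking.

#' Essentiality score against a dependency reference
#'
#' The essentiality score of a gene is the percentage of reference cancer
#' cell lines in which it is classified essential (row mean of a binary
#' gene x cell-line dependency matrix, times 100). Genes scoring at least
#' 50 are classified common essential.
#'
#' @param dep Binary matrix genes x cell lines (entries 0/1), rownames =
#'   genes.
#' @param genes Genes to score (default: all rows).
#' @param threshold Common-essential threshold on the percentage
#'   (default 50).
#' @return A data.frame with columns `gene`, `score`, `common_essential`.
#' @export
essentiality_score <- function(dep, genes = rownames(dep), threshold = 50) {
  stop_if_not(is.matrix(dep) && ncol(dep) > 0, "dep must be a non-empty matrix")
  stop_if_not(all(dep %in% c(0, 1)), "dep entries must be 0/1")
  missing <- setdiff(genes, rownames(dep))
  stop_if_not(length(missing) == 0,
              "gene(s) absent from dependency matrix: ",
              paste(missing, collapse = ", "))
  score <- 100 * rowSums(dep[genes, , drop = FALSE]) / ncol(dep)
  data.frame(gene = genes, score = unname(score),
             common_essential = unname(score >= threshold),
             stringsAsFactors = FALSE)
}

#' Compare gene-level dropout across screen contexts
#'
#' Joins per-context gene median log2 fold changes and classifies each
#' gene into the four quadrant classes of an in vitro vs in vivo scatter:
#' dispensable in both, essential in vitro only, essential in vivo only,
#' or essential in both, using `median_log2FC < threshold` per context.
#' Genes missing either context are labelled `"incomplete"` and excluded
#' from the quadrants.
#'
#' @param gene_stats Named list of [aggregate_genes()] data.frames, one
#'   per context.
#' @param invitro,invivo Names of the two compared contexts (default
#'   `"invitro"`, `"invivo"`).
#' @param threshold Essentiality threshold on the median log2FC
#'   (default -1).
#' @return A data.frame with one row per gene: `gene`, one
#'   `median_log2FC.<context>` column per supplied context, and `class`.
#' @export
compare_screens <- function(gene_stats, invitro = "invitro",
                            invivo = "invivo", threshold = -1) {
  stop_if_not(is.list(gene_stats) && !is.null(names(gene_stats)),
              "gene_stats must be a named list of per-context tables")
  stop_if_not(all(c(invitro, invivo) %in% names(gene_stats)),
              "gene_stats must contain the two compared contexts")
  genes <- sort(unique(unlist(lapply(gene_stats, `[[`, "gene"))))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (ctx in names(gene_stats)) {
    g <- gene_stats[[ctx]]
    out[[paste0("median_log2FC.", ctx)]] <-
      g$median_log2FC[match(genes, g$gene)]
  }
  vitro <- out[[paste0("median_log2FC.", invitro)]]
  vivo <- out[[paste0("median_log2FC.", invivo)]]
  ess_vitro <- vitro < threshold
  ess_vivo <- vivo < threshold
  cls <- ifelse(is.na(vitro) | is.na(vivo), "incomplete",
         ifelse(ess_vitro & ess_vivo, "essential both",
         ifelse(ess_vitro & !ess_vivo, "essential in vitro only",
         ifelse(!ess_vitro & ess_vivo, "essential in vivo only",
                "dispensable both"))))
  out$class <- cls
  out
}

#' Rank triage candidates through the four filters
#'
#' Applies the candidate filters to each gene: (1) essential in vivo
#' (median log2FC < `lfc_threshold`), (2) tumour-selective (in vivo minus
#' fibroblast median log2FC < `delta_threshold`), (3) co-expressed with
#' the activity score (Pearson r > `r_threshold`), and (4) overexpressed
#' in tumours vs normal tissue (log2FC > `overexpr_threshold`). Genes
#' passing all four are ranked by descending r, ties broken by ascending
#' in vivo log2FC.
#'
#' @param comparison Output of [compare_screens()] (must include the in
#'   vivo and fibroblast contexts).
#' @param coexpression Data.frame `gene`, `r` (candidate-vs-activity
#'   Pearson correlations).
#' @param overexpression Data.frame `gene`, `log2FC` (tumour vs normal).
#' @param scores Optional [essentiality_score()] table, joined for
#'   reporting (not used as a filter).
#' @param invivo,fibroblast Context column suffixes in `comparison`.
#' @param lfc_threshold,delta_threshold,r_threshold,overexpr_threshold
#'   Filter thresholds (defaults -1, 0, 0.5, 0.3).
#' @return A data.frame, one row per gene, with per-context log2FCs,
#'   `delta_log2FC`, `r_coexpr`, `lfc_tumour_vs_normal`, four
#'   `pass_*` flags, `pass_all`, and `rank` (NA for non-passing genes;
#'   passing genes first). When no gene passes, the attribute
#'   `"filter_diagnostics"` reports per-filter pass counts.
#' @export
rank_candidates <- function(comparison, coexpression, overexpression,
                            scores = NULL,
                            invivo = "invivo", fibroblast = "fibroblast",
                            lfc_threshold = -1, delta_threshold = 0,
                            r_threshold = 0.5, overexpr_threshold = 0.3) {
  out <- comparison
  vivo_col <- paste0("median_log2FC.", invivo)
  fib_col <- paste0("median_log2FC.", fibroblast)
  stop_if_not(all(c(vivo_col, fib_col) %in% names(out)),
              "comparison must include the in vivo and fibroblast contexts")
  out$delta_log2FC <- out[[vivo_col]] - out[[fib_col]]
  out$r_coexpr <- coexpression$r[match(out$gene, coexpression$gene)]
  out$lfc_tumour_vs_normal <-
    overexpression$log2FC[match(out$gene, overexpression$gene)]
  if (!is.null(scores)) {
    out$essentiality_score <- scores$score[match(out$gene, scores$gene)]
    out$common_essential <-
      scores$common_essential[match(out$gene, scores$gene)]
  }
  pass <- function(x) !is.na(x) & x
  out$pass_invivo <- pass(out[[vivo_col]] < lfc_threshold)
  out$pass_tumour_selective <- pass(out$delta_log2FC < delta_threshold)
  out$pass_coexpression <- pass(out$r_coexpr > r_threshold)
  out$pass_overexpression <-
    pass(out$lfc_tumour_vs_normal > overexpr_threshold)
  out$pass_all <- out$pass_invivo & out$pass_tumour_selective &
    out$pass_coexpression & out$pass_overexpression
  ord <- order(!out$pass_all, -out$r_coexpr, out[[vivo_col]])
  out <- out[ord, , drop = FALSE]
  out$rank <- NA_integer_
  out$rank[out$pass_all] <- seq_len(sum(out$pass_all))
  rownames(out) <- NULL
  if (!any(out$pass_all)) {
    attr(out, "filter_diagnostics") <-
      c(pass_invivo = sum(out$pass_invivo),
        pass_tumour_selective = sum(out$pass_tumour_selective),
        pass_coexpression = sum(out$pass_coexpression),
        pass_overexpression = sum(out$pass_overexpression))
  }
  out
}
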