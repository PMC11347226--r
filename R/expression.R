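# Cohort expression analyses: per-gene scaling, gene-set activity scores,
# candidate co-expression, tumour-vs-normal overexpression, and
# Kaplan-Meier / log-rank survival stratification.

#' Scale expression per gene across samples
#'
#' Centres each gene at its mean and divides by its sample standard
#' deviation (n - 1). Zero-variance genes are set to all-zero with a
#' warning rather than dropped, so matrix dimensions are preserved.
#'
#' @param fpkm Numeric matrix genes x samples (>= 2 samples).
#' @return Matrix of z-scores with the same dimensions.
#' @export
scale_expression <- function(fpkm) {
  stop_if_not(is.matrix(fpkm) && ncol(fpkm) >= 2,
              "fpkm must be a matrix with >= 2 samples")
  mu <- rowMeans(fpkm)
  sdev <- apply(fpkm, 1L, stats::sd)
  flat <- sdev == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) set to all-zero")
    sdev[flat] <- 1
  }
  z <- (fpkm - mu) / sdev
  z[flat, ] <- 0
  z
}

#' Gene-set activity score per sample
#'
#' The per-sample mean of the z-scored expression of the set's member
#' genes — a simple proxy for the activity of the programme the set
#' represents (e.g. MYC target genes). Membership is resolved against the
#' matrix; missing members are reported via attributes.
#'
#' @param z Z-score matrix from [scale_expression()].
#' @param gene_set Character vector of member gene names.
#' @return Named numeric vector of per-sample scores, with attributes
#'   `genes_found` and `genes_missing`.
#' @export
geneset_score <- function(z, gene_set) {
  found <- intersect(gene_set, rownames(z))
  stop_if_not(length(found) > 0,
              "no gene-set member present in the expression matrix")
  score <- colMeans(z[found, , drop = FALSE])
  attr(score, "genes_found") <- found
  attr(score, "genes_missing") <- setdiff(gene_set, found)
  score
}

#' Pearson correlation of a candidate with an activity score
#'
#' Pearson r with the two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param candidate Numeric vector (e.g. the candidate gene's z-score
#'   row).
#' @param score Numeric vector of the same length (>= 4).
#' @return A list with `r`, `p`, `n`.
#' @export
correlate_candidate <- function(candidate, score) {
  stop_if_not(length(candidate) == length(score) && length(score) >= 4,
              "candidate and score must have equal length >= 4")
  stop_if_not(stats::sd(candidate) > 0 && stats::sd(score) > 0,
              "correlation undefined for zero-variance input")
  ct <- stats::cor.test(candidate, score, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(score))
}

#' Tumour-vs-normal log2 fold change of one gene
#'
#' Ratio estimator `log2((mean tumour + c0) / (mean normal + c0))` with a
#' delta-method standard error on the log2 scale:
#' `SE^2 = (1/ln 2)^2 * (var_T / (n_T * m_T^2) + var_N / (n_N * m_N^2))`
#' with pseudocounted means `m`.
#'
#' @param fpkm Expression matrix genes x samples.
#' @param classes Character vector per sample, `"tumour"` or `"normal"`.
#' @param gene Gene name.
#' @param pseudocount Pseudocount `c0` (default 0.1).
#' @return A list with `log2FC`, `SE`, `n_tumour`, `n_normal`.
#' @export
tumour_vs_normal_lfc <- function(fpkm, classes, gene, pseudocount = 0.1) {
  stop_if_not(gene %in% rownames(fpkm), "gene not found: ", gene)
  stop_if_not(length(classes) == ncol(fpkm),
              "classes must label every sample")
  xt <- fpkm[gene, classes == "tumour"]
  xn <- fpkm[gene, classes == "normal"]
  stop_if_not(length(xt) > 0 && length(xn) > 0,
              "both tumour and normal samples are required")
  m_t <- mean(xt) + pseudocount
  m_n <- mean(xn) + pseudocount
  v_t <- if (length(xt) > 1) stats::var(xt) else 0
  v_n <- if (length(xn) > 1) stats::var(xn) else 0
  se <- sqrt((1 / log(2))^2 *
               (v_t / (length(xt) * m_t^2) + v_n / (length(xn) * m_n^2)))
  list(log2FC = log2(m_t / m_n), SE = se,
       n_tumour = length(xt), n_normal = length(xn))
}

#' Stratify a cohort on two scores and run a log-rank test
#'
#' Splits tumour samples into thirds on each score; the high group is the
#' samples in the top third of both scores, the low group the bottom third
#' of both. Kaplan-Meier curves (with Greenwood standard errors) and the
#' two-group log-rank test come from the survival package. With
#' `mode = "aggressive50"`, the analysis is first restricted to the 50% of
#' patients with the highest combined (summed) score.
#'
#' @param score_a,score_b Named numeric scores (names = sample ids), e.g.
#'   a candidate z-row and a gene-set activity score.
#' @param clinical Data.frame with columns `sample`, `time`, `event`.
#' @param mode `"full"` (default) or `"aggressive50"`.
#' @return A list of class `survival_result`: `groups` (named
#'   `"high"`/`"low"` per stratified sample), `km` (data.frame: group,
#'   time, n_risk, surv, se), `logrank_chi2`, `p`, `n_high`, `n_low`.
#' @export
stratify_and_logrank <- function(score_a, score_b, clinical,
                                 mode = c("full", "aggressive50")) {
  mode <- match.arg(mode)
  stop_if_not(all(c("sample", "time", "event") %in% names(clinical)),
              "clinical needs columns sample, time, event")
  ids <- intersect(clinical$sample, intersect(names(score_a), names(score_b)))
  stop_if_not(length(ids) >= 6, "too few samples with both scores and clinical data")
  a <- score_a[ids]; b <- score_b[ids]
  cl <- clinical[match(ids, clinical$sample), , drop = FALSE]
  if (mode == "aggressive50") {
    keep <- rank(a + b, ties.method = "first") > length(ids) / 2
    a <- a[keep]; b <- b[keep]; cl <- cl[keep, , drop = FALSE]
  }
  third <- function(x) {
    q <- stats::quantile(x, c(1, 2) / 3, names = FALSE, type = 7)
    ifelse(x >= q[2], "high", ifelse(x <= q[1], "low", "mid"))
  }
  ta <- third(a); tb <- third(b)
  grp <- ifelse(ta == "high" & tb == "high", "high",
                ifelse(ta == "low" & tb == "low", "low", NA))
  for (g in c("high", "low")) {
    stop_if_not(sum(grp == g, na.rm = TRUE) > 0, "empty stratum: ", g)
  }
  sel <- !is.na(grp)
  cl <- cl[sel, , drop = FALSE]
  grp <- grp[sel]
  stop_if_not(sum(cl$event) >= 2, "need >= 2 events across strata")
  surv <- survival::Surv(cl$time, cl$event)
  sd <- survival::survdiff(surv ~ grp)
  chi2 <- sd$chisq
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(surv ~ grp)
  km <- data.frame(group = rep(sub("^grp=", "", names(fit$strata)),
                               fit$strata),
                   time = fit$time, n_risk = fit$n.risk,
                   surv = fit$surv, se = fit$std.err * fit$surv,
                   stringsAsFactors = FALSE)
  structure(list(groups = stats::setNames(grp, cl$sample), km = km,
                 logrank_chi2 = unname(chi2), p = unname(p),
                 n_high = sum(grp == "high"), n_low = sum(grp == "low")),
            class = "survival_result")
}

#' Read a gene set from a plain list or GMT file
#'
#' Plain format: one gene symbol per line. GMT: tab-separated set name,
#' description, then member genes; `set_name` selects the set (default:
#' first).
#'
#' @param path File path.
#' @param set_name Optional GMT set name.
#' @return Character vector of gene names.
#' @export
read_gene_set <- function(path, set_name = NULL) {
  stop_if_not(file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  stop_if_not(length(lines) > 0, "empty gene-set file: ", path)
  if (any(grepl("\t", lines))) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    names(parts) <- vapply(parts, `[[`, character(1), 1L)
    sel <- set_name %||% names(parts)[1]
    stop_if_not(sel %in% names(parts), "gene set not found: ", sel)
    genes <- parts[[sel]][-(1:2)]
  } else {
    genes <- trimws(lines)
  }
  unique(genes[nzchar(genes)])
}
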