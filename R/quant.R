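# Guide quantification: library parsing, exact-match read counting, and the
# library-representation QC rule.

#' Read and validate an shRNA library design table
#'
#' Expects a TSV with header columns `construct_id`, `gene`, `guide_seq`.
#' Construct ids and guide sequences must be unique; guides must be ACGT
#' strings of a single common length.
#'
#' @param path Path to the library TSV.
#' @return A data.frame with columns `construct_id`, `gene`, `guide_seq`,
#'   `is_ntc` (gene label `"NTC"`).
#' @export
read_library <- function(path) {
  lib <- read_tsv_table(path)
  required <- c("construct_id", "gene", "guide_seq")
  stop_if_not(all(required %in% names(lib)),
              "library TSV must have columns: ",
              paste(required, collapse = ", "))
  stop_if_not(nrow(lib) > 0, "library file is empty: ", path)
  validate_library(lib[, required])
}

validate_library <- function(lib) {
  dup <- lib$construct_id[duplicated(lib$construct_id)]
  stop_if_not(length(dup) == 0,
              "duplicated construct_id(s): ", paste(unique(dup), collapse = ", "))
  dupg <- lib$guide_seq[duplicated(lib$guide_seq)]
  stop_if_not(length(dupg) == 0,
              "duplicated guide sequence(s): ",
              paste(unique(dupg), collapse = ", "))
  bad <- which(!grepl("^[ACGT]+$", lib$guide_seq))
  stop_if_not(length(bad) == 0,
              "guide_seq not an ACGT string at row(s): ",
              paste(bad, collapse = ", "))
  stop_if_not(length(unique(nchar(lib$guide_seq))) == 1L,
              "guide sequences must share a single length")
  lib$is_ntc <- lib$gene == "NTC"
  lib
}

#' Read sequences from a FASTQ file
#'
#' Thin wrapper returning plain character reads (plain or gzip FASTQ).
#'
#' @param path FASTQ path.
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  stop_if_not(file.exists(path), "file not found: ", path)
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Count reads per construct by exact guide matching
#'
#' A read increments exactly one construct's count iff its guide-region
#' substring equals that construct's guide with no mismatches. The guide
#' region is first taken at the fixed library offset `guide_start`; a read
#' that does not match there is rescued by searching the guide at any
#' substring position (robust to trimming differences), first hit wins.
#' Guides are unique by library validation, so at most one construct can
#' match; reads matching none are tallied as unmatched. Reads shorter than
#' the guide length are unmatched. Count conservation holds on every
#' input: `matched + unmatched = total`.
#'
#' @param reads Character vector of read sequences (see [read_fastq()]).
#' @param design Library design (see [read_library()]).
#' @param guide_start 1-based offset of the guide region within the read.
#' @param reverse_complement If `TRUE`, reads are reverse-complemented
#'   before matching (amplicon protocols normally fix orientation, so the
#'   default is `FALSE`).
#' @return A list of class `guide_counts`: `counts` (named integer vector
#'   per construct), `n_matched`, `n_unmatched`, `n_total`.
#' @export
count_reads <- function(reads, design, guide_start = 1L,
                        reverse_complement = FALSE) {
  design <- validate_library(design[, c("construct_id", "gene", "guide_seq")])
  stop_if_not(nrow(design) > 0, "design must be non-empty")
  reads <- as.character(reads)
  if (isTRUE(reverse_complement) && length(reads)) {
    reads <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads)))
  }
  glen <- nchar(design$guide_seq[1])
  counts <- stats::setNames(integer(nrow(design)), design$construct_id)
  n_total <- length(reads)
  if (n_total == 0) {
    return(structure(list(counts = counts, n_matched = 0L,
                          n_unmatched = 0L, n_total = 0L),
                     class = "guide_counts"))
  }
  # fixed-offset pass
  sub <- substr(reads, guide_start, guide_start + glen - 1L)
  hit <- match(sub, design$guide_seq)
  miss <- which(is.na(hit) | nchar(sub) < glen)
  hit[miss] <- NA_integer_
  # rescue pass: search anywhere in the read, first matching guide wins
  if (length(miss)) {
    pending <- miss[nchar(reads[miss]) >= glen]
    for (i in seq_len(nrow(design))) {
      if (!length(pending)) break
      found <- grepl(design$guide_seq[i], reads[pending], fixed = TRUE)
      hit[pending[found]] <- i
      pending <- pending[!found]
    }
  }
  tab <- tabulate(hit, nbins = nrow(design))
  counts[] <- tab
  n_matched <- sum(tab)
  structure(list(counts = counts,
                 n_matched = n_matched,
                 n_unmatched = n_total - n_matched,
                 n_total = n_total),
            class = "guide_counts")
}

#' Library-representation quality control
#'
#' Checks the two-part uniformity rule for a sequenced library: (1) every
#' construct is detected, and (2) more than 80\% of all constructs have an
#' abundance within 10-fold of the library's typical abundance. The fold
#' comparison is anchored at the median non-zero count `m`; a construct
#' with count `c` is within 10-fold when `max(c/m, m/c) < 10` (zero counts
#' always fail). The rule is scale-invariant.
#'
#' @param counts Named numeric vector of per-construct counts for one
#'   sample (names matched against `design$construct_id`), or a
#'   `guide_counts` object.
#' @param design Library design data.frame.
#' @param fold Fold-change bound (default 10).
#' @param min_fraction Required fraction within `fold` (strict >;
#'   default 0.8).
#' @return A list of class `representation_report`: `n_detected`,
#'   `fraction_within_10fold`, `uniform`.
#' @export
representation_qc <- function(counts, design, fold = 10, min_fraction = 0.8) {
  if (inherits(counts, "guide_counts")) counts <- counts$counts
  stop_if_not(!is.null(names(counts)), "counts must be named by construct")
  stop_if_not(setequal(names(counts), design$construct_id),
              "counts do not align with the library design")
  counts <- counts[design$construct_id]
  n <- length(counts)
  n_detected <- sum(counts > 0)
  if (n_detected == 0) {
    frac <- 0
  } else {
    m <- stats::median(counts[counts > 0])
    ratio <- pmax(counts / m, m / counts) # 0 -> Inf, fails the bound
    frac <- mean(ratio < fold)
  }
  structure(list(n_detected = n_detected,
                 fraction_within_10fold = frac,
                 uniform = n_detected == n && frac > min_fraction),
            class = "representation_report")
}

#' @export
print.representation_report <- function(x, ...) {
  cat(sprintf("Library representation: %d constructs detected; %.1f%% within 10-fold of median; uniform: %s\n",
              x$n_detected, 100 * x$fraction_within_10fold, x$uniform))
  invisible(x)
}
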