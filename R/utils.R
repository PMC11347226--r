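# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded generators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else {
      suppressWarnings(rm(".Random.seed", envir = env))
    }
  })
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

#' Read / write the pipeline's TSV tables
#'
#' Plain tab-separated files with a header row; the de facto interchange
#' format for screen count matrices and annotation tables.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @param row_names Name for a column storing row names (`NULL` to drop).
#' @return `read_tsv_table` returns a data.frame; `write_tsv_table` is
#'   called for its side effect and returns `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  stop_if_not(file.exists(path), "file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path, row_names = NULL) {
  if (!is.null(row_names)) {
    x <- cbind(stats::setNames(data.frame(rownames(x),
                                          stringsAsFactors = FALSE),
                               row_names),
               as.data.frame(x, check.names = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

geo_mean <- function(x) exp(mean(log(x)))
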