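`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as tab-separated text
#'
#' Plain TSV writer used for all tabular artifacts (no quoting, no row names).
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path input path.
#' @return data frame with character columns left as-is.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# seeded evaluation that restores the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
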