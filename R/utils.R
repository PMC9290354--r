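# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-separated table
#'
#' TSV dialect used throughout the package: tab separator, `.` decimal,
#' no quoting, `#`-prefixed comment lines ignored.
#'
#' @param path file path.
#' @param ... passed to [utils::read.delim()].
#' @return a data.frame.
#' @export
read_tsv_table <- function(path, ...) {
  read.delim(path, sep = "\t", quote = "", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a tab-separated table
#'
#' @param x data.frame.
#' @param path output file path.
#' @param row_names write row names as a leading column? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, row_names = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  invisible(path)
}

# stop()/warning() wrappers with sprintf-style formatting
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# checked scalar accessors
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_number(x, name, lower = lower)
  if (x != as.integer(x)) stopf("'%s' must be an integer", name)
  invisible(as.integer(x))
}
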