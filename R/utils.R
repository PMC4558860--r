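#' @useDynLib retroscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom utils head tail packageVersion
#' @import methods
NULL

BASES <- c("A", "C", "G", "T")

# random DNA as a single string
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

reverse_complement <- function(x) cpp_revcomp(x)

# 0-based half-open interval overlap length
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a non-missing scalar", name), call. = FALSE)
}

# commented header written at the top of every table/format this package emits
writer_header <- function(comment_char = "#", extra = NULL) {
  h <- sprintf("%s retroscape %s", comment_char,
               as.character(utils::packageVersion("retroscape")))
  if (!is.null(extra)) h <- c(h, paste(comment_char, extra))
  h
}

write_tsv_with_header <- function(df, path, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header(extra = extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
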