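# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a typed error
#'
#' All user-facing failures in the package raise a condition inheriting from
#' `scregulon_error`, so callers can catch package errors distinctly from
#' programming errors.
#' @noRd
abort <- function(msg, class = "scregulon_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "scregulon_error", "error"),
                      call = NULL))
}

format_error <- function(msg) abort(msg, "scregulon_format_error")
parse_error  <- function(msg) abort(msg, "scregulon_parse_error")
domain_error <- function(msg) abort(msg, "scregulon_domain_error")
io_error     <- function(msg) abort(msg, "scregulon_io_error")

is_gzipped <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

# Open a read connection, transparently decompressing *.gz.
open_text <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  if (is_gzipped(path)) gzfile(path, open = "rt", encoding = "UTF-8")
  else file(path, open = "rt", encoding = "UTF-8")
}

read_text_lines <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Jaccard index of two character sets.
jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# Guess a field delimiter from a header line (comma vs tab vs whitespace).
guess_delimiter <- function(line) {
  n_tab <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
  n_com <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else if (n_com > 0L) "," else ""
}

split_fields <- function(line, delimiter) {
  if (identical(delimiter, "")) strsplit(trimws(line), "[ \t]+")[[1L]]
  else strsplit(line, delimiter, fixed = TRUE)[[1L]]
}
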