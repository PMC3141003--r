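## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return The geometric mean of `x`.
#' @examples
#' geometric_mean(c(1, 4, 16))  # 4
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop_arg("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

## Derive a component sub-seed from the global seed. Offsets are fixed
## per call site; result kept well below 2^31.
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 599999L) * 3571L + as.integer(offset)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Polynomial content hash over a character vector; used for run-manifest
## change detection so the pipeline has no dependency on a digest package.
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

hash_file <- function(path) content_hash(readLines(path, warn = FALSE))

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == round(x)

check_counts <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (!is_count(vals[[nm]]))
      stop_arg("'", nm, "' must be a single non-negative integer")
  invisible(TRUE)
}
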