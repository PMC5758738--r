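#' @importFrom stats lm coef cor fitted phyper p.adjust sd setNames
#' @importFrom utils write.table read.table head combn packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a fixed RNG seed, restoring the RNG state afterwards
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# population standard deviation (denominator n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# 31-bit polynomial rolling hash of a character scalar, as 8 hex digits;
# fingerprints configs in run logs without an external digest dependency
config_fingerprint <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# deterministic TSV writer: no quoting, no row names, LF endings
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
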