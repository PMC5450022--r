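#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom setNames aggregate quantile
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed; independent
#' stages draw their own seeds through this splitting scheme (a fixed LCG
#' step, kept below 2^31 so it is always a valid R integer seed).
#'
#' @param seed master integer seed.
#' @param k stream index (non-negative integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 48271) %% m + (as.numeric(k) * 2654435761) %% m) %% m)
}

## FNV-1a hash of a serialized R object; used to stamp output files so a
## re-run with an identical config is recognisably identical.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## TSV writers with a reproducibility header ("# key: value" comment lines).
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    for (nm in names(header)) {
      writeLines(sprintf("# %s: %s", nm, header[[nm]]), con)
    }
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) all(is.numeric(x)) && all(is.finite(x)) &&
  all(x >= 0) && all(x <= 1)
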