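# internal helpers shared across modules

#' @keywords internal
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All exported stochastic operations funnel through this so that a given
# (arguments, seed) pair is bit-reproducible and never perturbs the session.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    .stopf("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a string; used to derive per-gene-set RNG
# substreams from a master seed so identical inputs always see identical
# permutation streams regardless of iteration order.
#' @keywords internal
name_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' @keywords internal
derive_seed <- function(master, label) {
  as.integer((as.numeric(master) + name_hash(label)) %% 2147483647)
}

#' @keywords internal
.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#", ...)
}

#' @keywords internal
.write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
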