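#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation among the DEGs relative to
#' the expressed-gene universe with the hypergeometric upper tail,
#' `P(X >= overlap)`, and adjusts across the collection with
#' Benjamini-Hochberg.
#'
#' @param degs Character vector of DEG identifiers (must be a subset of
#'   `universe`).
#' @param universe Character vector of all tested gene identifiers.
#' @param collection Named list of gene sets.
#' @return Data frame of class `ora_result`: `set`, `overlap`, `set_size`
#'   (within the universe), `deg_size`, `universe_size`, `pval`, `padj`.
#' @export
ora_test <- function(degs, universe, collection) {
  universe <- unique(universe)
  degs <- unique(degs)
  missing <- setdiff(degs, universe)
  if (length(missing))
    .stopf("DEGs absent from the universe: %s%s",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5)
             sprintf(" (and %d more)", length(missing) - 5) else "")
  if (length(collection) == 0L) .stopf("empty gene-set collection")
  U <- length(universe)
  D <- length(degs)
  rows <- lapply(names(collection), function(nm) {
    s <- length(intersect(collection[[nm]], universe))
    ov <- length(intersect(collection[[nm]], degs))
    p <- if (s == 0L) 1 else
      stats::phyper(ov - 1, s, U - s, D, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = s, deg_size = D,
               universe_size = U, pval = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pval, method = "BH")
  structure(out, class = c("ora_result", "data.frame"))
}
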