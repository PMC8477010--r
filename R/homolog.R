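# Mouse-to-human homolog mapping, applied before matching mouse genes
# against human-derived gene-set collections.

#' Read a mouse-to-human homolog map
#'
#' @param path TSV with columns `mouse_symbol`, `human_symbol`.
#' @return Data frame of class `homolog_map`.
#' @export
read_homolog_map <- function(path) {
  map <- .read_tsv(path)
  if (!all(c("mouse_symbol", "human_symbol") %in% names(map)))
    .stopf("homolog map needs columns mouse_symbol, human_symbol")
  structure(map, class = c("homolog_map", "data.frame"))
}

#' Map gene identifiers through a homolog table
#'
#' One-to-one entries are translated; genes absent from the map are
#' dropped and reported; a mouse gene with several human homologs is
#' resolved to the alphabetically first one, and the event is recorded.
#'
#' @param genes Character vector of (mouse) identifiers.
#' @param map A [read_homolog_map()] table (or equivalent data frame).
#' @return List: `genes` (mapped identifiers, input order, unmapped
#'   dropped), `unmapped` (input identifiers without a homolog),
#'   `multi` (data frame of one-to-many resolutions).
#' @export
apply_homolog_map <- function(genes, map) {
  if (is.null(map) || nrow(map) == 0L)
    .stopf("homolog map is empty; load a mouse_symbol/human_symbol table")
  # resolve one-to-many deterministically: first human symbol by sort order
  map <- map[order(map$mouse_symbol, map$human_symbol), ]
  dup <- duplicated(map$mouse_symbol)
  multi_mice <- unique(map$mouse_symbol[dup])
  resolved <- map[!dup, ]
  idx <- match(genes, resolved$mouse_symbol)
  unmapped <- genes[is.na(idx)]
  mapped <- resolved$human_symbol[idx[!is.na(idx)]]
  multi <- resolved[resolved$mouse_symbol %in% intersect(multi_mice, genes),
                    c("mouse_symbol", "human_symbol")]
  names(multi) <- c("mouse_symbol", "kept_human_symbol")
  rownames(multi) <- NULL
  list(genes = mapped, unmapped = unmapped, multi = multi)
}

#' Map a ranked list to human symbols
#'
#' Convenience wrapper: translates the gene identifiers of a
#' `ranked_list`, drops unmapped genes, and keeps the first (highest
#' |score|) occurrence when two mouse genes collapse onto one human
#' symbol.
#'
#' @param ranked A `ranked_list`.
#' @param map A homolog map.
#' @return A `ranked_list` over human symbols, plus attributes
#'   `unmapped` and `collapsed`.
#' @export
map_ranked_list <- function(ranked, map) {
  ranked <- as_ranked(ranked)
  res <- apply_homolog_map(ranked$gene_id, map)
  keep <- !(ranked$gene_id %in% res$unmapped)
  out <- ranked[keep, ]
  out$gene_id <- res$genes
  dupped <- duplicated(out$gene_id)
  collapsed <- unique(out$gene_id[dupped])
  out <- out[!dupped, ]
  rownames(out) <- NULL
  structure(out, class = c("ranked_list", "data.frame"),
            unmapped = res$unmapped, collapsed = collapsed)
}
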