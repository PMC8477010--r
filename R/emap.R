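# Enrichment-map style similarity graph over significant gene sets.

#' @keywords internal
set_similarity <- function(a, b, metric) {
  inter <- length(intersect(a, b))
  switch(metric,
         jaccard = inter / length(union(a, b)),
         overlap = inter / min(length(a), length(b)))
}

#' Similarity graph of significantly enriched gene sets
#'
#' Builds the integration graph behind enrichment-map figures: nodes are
#' the significant gene sets (carrying size, NES and enrichment sign),
#' and an undirected edge connects two sets whose membership similarity
#' reaches the cutoff.
#'
#' @param gsea A `gsea_result`.
#' @param collection The gene-set collection the result was computed on.
#' @param metric `"jaccard"` (default) or `"overlap"` coefficient.
#' @param cutoff Minimum similarity for an edge (default 0.25).
#' @param significant_only Restrict nodes to `significant` records
#'   (default `TRUE`).
#' @return List of class `similarity_graph`: `nodes` (data frame `set`,
#'   `size`, `nes`, `sign`), `edges` (data frame `from`, `to`,
#'   `similarity`), `metric`, `cutoff`.
#' @export
similarity_graph <- function(gsea, collection,
                             metric = c("jaccard", "overlap"),
                             cutoff = 0.25, significant_only = TRUE) {
  metric <- match.arg(metric)
  recs <- as.data.frame(gsea)
  if (significant_only) recs <- recs[recs$significant %in% TRUE, ]
  if (nrow(recs) == 0L) .stopf("no significant gene sets to graph")
  missing <- setdiff(recs$set, names(collection))
  if (length(missing))
    .stopf("sets absent from the collection: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  nodes <- data.frame(set = recs$set, size = recs$size, nes = recs$nes,
                      sign = sign(recs$nes), stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(nodes) > 1L) {
    pairs <- utils::combn(nodes$set, 2)
    sim <- apply(pairs, 2, function(p)
      set_similarity(collection[[p[1]]], collection[[p[2]]], metric))
    keep <- sim >= cutoff
    edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                        similarity = sim[keep], stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, metric = metric,
                 cutoff = cutoff),
            class = "similarity_graph")
}

#' Export a similarity graph
#'
#' Writes the edge list as TSV and, optionally, the full graph as GraphML
#' for downstream layout tools.
#'
#' @param graph A [similarity_graph()].
#' @param edges_file Path for the edge-list TSV (`NULL` to skip).
#' @param graphml_file Path for the GraphML export (`NULL` to skip).
#' @export
write_similarity_graph <- function(graph, edges_file = NULL,
                                   graphml_file = NULL) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (!is.null(edges_file)) .write_tsv(graph$edges, edges_file)
  if (!is.null(graphml_file)) {
    g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                       vertices = graph$nodes)
    igraph::write_graph(g, graphml_file, format = "graphml")
  }
  invisible(graph)
}
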