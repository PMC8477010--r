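# Preranked GSEA with the classic (unweighted) scoring scheme and a
# gene-set permutation null, following the original two-tailed NES / FDR
# methodology: ES is the signed extremum of a hit/miss running sum, NES
# divides ES by the mean same-sign null ES, and the FDR q compares the
# tails of the pooled null and observed NES distributions.

#' Build the ranking statistic from a differential-expression result
#'
#' Every expressed (tested) gene is scored by its fold change weighted by
#' the inverse p-value, `score = log2fc / max(p, p_floor)`, and the list
#' is ordered from the highest to the lowest score. The sign of the score
#' is the sign of the fold change; smaller p-values push genes toward the
#' extremes. Ties are broken lexicographically by gene identifier so the
#' ordering is deterministic.
#'
#' @param de A `de_result` data frame (needs `gene_id`, `log2fc`,
#'   `pvalue`).
#' @param p_floor Smallest p-value used in the denominator
#'   (default 1e-300).
#' @return Object of class `ranked_list`: data frame `gene_id`, `score`,
#'   ordered high to low.
#' @export
rank_metric <- function(de, p_floor = 1e-300) {
  if (p_floor <= 0) .stopf("p_floor must be > 0")
  score <- de$log2fc / pmax(de$pvalue, p_floor)
  ord <- order(-score, de$gene_id)
  structure(data.frame(gene_id = de$gene_id[ord], score = score[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' @keywords internal
as_ranked <- function(ranked) {
  if (inherits(ranked, "ranked_list")) return(ranked)
  if (is.data.frame(ranked) && all(c("gene_id", "score") %in% names(ranked)))
    return(ranked)
  .stopf("ranked must be a ranked_list (gene_id, score)")
}

# ES from sorted hit positions: the running sum gains 1/k at each of the
# k hits and loses 1/(N-k) at each miss; candidate extrema sit at (just
# after) each hit and just before each hit.
#' @keywords internal
es_from_positions <- function(pos, N) {
  k <- length(pos)
  pos <- sort(pos)
  i <- seq_len(k)
  at_hit <- i / k - (pos - i) / (N - k)
  before_hit <- (i - 1) / k - (pos - i) / (N - k)
  es_pos <- max(at_hit, 0)
  es_neg <- min(before_hit, 0)
  # resolve exact ties (and their floating-point shadows) to the positive
  # extremum, consistently with enrichment_score()
  if (es_pos >= -es_neg - 1e-12) es_pos else es_neg
}

#' Classic enrichment score with running sum and leading edge
#'
#' Computes the unweighted Kolmogorov-Smirnov-style running sum of a gene
#' set along a ranked list: each hit increments by `1/Nh`, each miss
#' decrements by `1/(N - Nh)`. The enrichment score is the signed maximum
#' deviation from zero; the leading edge contains the hit genes at or
#' before the extremum (positive ES) or after it (negative ES).
#'
#' @param ranked A `ranked_list`.
#' @param set Character vector of gene identifiers.
#' @return List: `es`, `running_sum` (length-N vector), `leading_edge`,
#'   `size` (hits in the ranked list), `hit_positions`.
#' @export
enrichment_score <- function(ranked, set) {
  ranked <- as_ranked(ranked)
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% set
  k <- sum(hit)
  if (k == 0L) .stopf("gene set has no member in the ranked list")
  if (k == N) .stopf("gene set covers the whole ranked list")
  rs <- cumsum(ifelse(hit, 1 / k, -1 / (N - k)))
  imax <- which.max(rs); imin <- which.min(rs)
  es <- if (rs[imax] >= -rs[imin] - 1e-12) max(rs[imax], 0) else rs[imin]
  pos <- which(hit)
  le <- if (es >= 0) ranked$gene_id[pos[pos <= imax]]
        else ranked$gene_id[pos[pos > imin]]
  list(es = es, running_sum = rs, leading_edge = le, size = k,
       hit_positions = pos)
}

#' Gene-set permutation null for the enrichment score
#'
#' Draws `n_perm` random gene sets of the given size from the ranked list
#' (gene-set permutation, not phenotype permutation) and returns their
#' enrichment scores.
#'
#' @param ranked A `ranked_list`.
#' @param set_size Size of the permuted sets (1 <= size < N).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; same seed gives the identical null sample.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000, seed = 1) {
  ranked <- as_ranked(ranked)
  N <- nrow(ranked)
  set_size <- as.integer(set_size)
  if (n_perm < 1) .stopf("n_perm must be >= 1")
  if (set_size < 1L || set_size >= N)
    .stopf("set_size must satisfy 1 <= size < N")
  with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) es_from_positions(sample.int(N, set_size), N),
           numeric(1))
  })
}

#' Normalized enrichment score and nominal p from a null sample
#'
#' NES is the observed ES divided by the mean magnitude of the same-sign
#' null scores; the nominal p-value is the same-sign tail fraction with
#' the add-one rule, so p is never below `1/(n_same_sign + 1)`.
#'
#' @param es Observed enrichment score.
#' @param null Null ES sample from [permutation_null()].
#' @return List `nes`, `pval`. An ES of 0 maps to NES 0, p 1; if the null
#'   contains no same-sign value the record is flagged (`nes = NA`).
#' @export
nes_from_null <- function(es, null) {
  if (length(null) == 0L) .stopf("empty null sample")
  if (es == 0) return(list(nes = 0, pval = 1))
  same <- if (es > 0) null[null > 0] else null[null < 0]
  if (length(same) == 0L) return(list(nes = NA_real_, pval = NA_real_))
  nes <- es / mean(abs(same))
  tail <- if (es > 0) sum(same >= es) else sum(same <= es)
  list(nes = nes, pval = (1 + tail) / (1 + length(same)))
}

#' Tail-ratio FDR for normalized enrichment scores
#'
#' For each observed NES, q is the ratio of the same-sign tail fraction in
#' the pooled null NES distribution to the same-sign tail fraction in the
#' observed NES distribution, clipped to \[0, 1\] and made monotone within
#' each sign stratum (a set can never have a larger q than a less extreme
#' set of the same sign).
#'
#' @param nes Observed NES values (one per tested set).
#' @param null_nes Pooled null NES values (all sets' normalized null
#'   scores).
#' @return Numeric vector of q-values aligned with `nes`.
#' @export
fdr_q <- function(nes, null_nes) {
  if (length(nes) == 0L) return(numeric(0))
  if (length(null_nes) == 0L) .stopf("empty null NES pool")
  q <- rep(NA_real_, length(nes))
  for (sgn in c(1, -1)) {
    obs_idx <- which(!is.na(nes) & sign(nes) == sgn)
    if (!length(obs_idx)) next
    null_s <- null_nes[!is.na(null_nes) & sign(null_nes) == sgn]
    obs_s <- nes[obs_idx]
    raw <- vapply(obs_s, function(v) {
      null_tail <- if (length(null_s))
        mean(abs(null_s) >= abs(v)) else 0
      obs_tail <- mean(abs(obs_s) >= abs(v))
      if (obs_tail == 0) return(0)
      min(max(null_tail / obs_tail, 0), 1)
    }, numeric(1))
    # monotone enforcement (step-up style): each set takes the smallest
    # raw q among sets no more extreme than itself, so q never decreases
    # as |NES| decreases
    ord <- order(-abs(obs_s))
    raw_sorted <- raw[ord]
    enforced <- rev(cummin(rev(raw_sorted)))
    q[obs_idx[ord]] <- enforced
  }
  q[!is.na(nes) & nes == 0] <- 1
  q
}

#' Preranked GSEA over a gene-set collection
#'
#' Runs the classic-scheme preranked analysis for every set in the
#' collection: sets are restricted to the ranked genes, sets outside the
#' size bounds are skipped (and logged), each surviving set gets an ES, a
#' gene-set permutation null, an NES and nominal p, and finally a pooled
#' tail-ratio FDR q. Per-set permutation streams are derived from the
#' master seed and a hash of the set name, so results do not depend on
#' collection order and identical sets always receive identical nulls.
#'
#' @param ranked A `ranked_list`.
#' @param collection Named list of gene-id vectors (see [read_gmt()]).
#' @param n_perm Permutations per set (default 1000).
#' @param min_size,max_size Set-size bounds after restriction to the
#'   ranked genes (defaults 15 and 500).
#' @param seed Master seed.
#' @param q_cut Significance threshold on the FDR q (default 0.05).
#' @return Object of class `gsea_result`: data frame with `set`, `size`,
#'   `es`, `nes`, `pval`, `fdr_q`, `significant`, `leading_edge`
#'   (list column). Attribute `skipped` records sets left out and why.
#' @export
gsea_collection <- function(ranked, collection, n_perm = 1000,
                            min_size = 15, max_size = 500, seed = 1,
                            q_cut = 0.05) {
  ranked <- as_ranked(ranked)
  if (length(collection) == 0L) .stopf("empty gene-set collection")
  if (is.null(names(collection))) .stopf("collection sets must be named")
  N <- nrow(ranked)
  skipped <- data.frame(set = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  rows <- list()
  null_nes_pool <- list()
  for (nm in names(collection)) {
    members <- intersect(collection[[nm]], ranked$gene_id)
    k <- length(members)
    if (k < max(min_size, 1L) || k > min(max_size, N - 1L)) {
      reason <- if (k == 0L) "no overlap with ranked list"
        else if (k >= N) "covers whole ranked list"
        else sprintf("size %d outside [%d, %d]", k, min_size, max_size)
      skipped <- rbind(skipped, data.frame(set = nm, reason = reason,
                                           stringsAsFactors = FALSE))
      next
    }
    esr <- enrichment_score(ranked, members)
    null <- permutation_null(ranked, k, n_perm, derive_seed(seed, nm))
    np <- nes_from_null(esr$es, null)
    # normalize the null by its own same-sign means -> pooled null NES
    mpos <- mean(null[null > 0]); mneg <- mean(abs(null[null < 0]))
    nn <- ifelse(null > 0, null / mpos, ifelse(null < 0, null / mneg, 0))
    null_nes_pool[[nm]] <- nn[is.finite(nn)]
    rows[[nm]] <- data.frame(set = nm, size = k, es = esr$es,
                             nes = np$nes, pval = np$pval,
                             stringsAsFactors = FALSE)
    rows[[nm]]$leading_edge <- list(esr$leading_edge)
  }
  if (!length(rows)) {
    .warnf("all %d sets were skipped; empty GSEA result",
           length(collection))
    out <- data.frame(set = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), pval = numeric(0),
                      fdr_q = numeric(0), significant = logical(0))
    out$leading_edge <- list()
    return(structure(out, class = c("gsea_result", "data.frame"),
                     skipped = skipped, n_perm = n_perm, seed = seed))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr_q <- fdr_q(out$nes, unlist(null_nes_pool, use.names = FALSE))
  out$significant <- !is.na(out$fdr_q) & out$fdr_q < q_cut
  out <- out[, c("set", "size", "es", "nes", "pval", "fdr_q",
                 "significant", "leading_edge")]
  structure(out, class = c("gsea_result", "data.frame"),
            skipped = skipped, n_perm = n_perm, seed = seed)
}

#' Write a GSEA result table to TSV
#'
#' The leading edge is collapsed to a comma-separated field.
#'
#' @param gsea A `gsea_result`.
#' @param path Output path.
#' @param header_lines Optional provenance comment lines.
#' @export
write_gsea_table <- function(gsea, path, header_lines = NULL) {
  tab <- as.data.frame(gsea)
  tab$leading_edge <- vapply(tab$leading_edge, paste, "", collapse = ",")
  .write_tsv(tab, path, header_lines)
}
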