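# Directional disease panels and reverse-ASD pattern classification.
#
# A panel assigns each gene set an expected direction in ASD cortex
# (up_in_ASD for ASD-upregulated signatures, down_in_ASD for
# ASD-downregulated signatures and for ASD-risk sets, whose members tend
# to be downregulated in ASD). A transcript group whose significant
# enrichments run *against* those directions — ASD-up sets enriched
# downward, ASD-risk sets enriched upward — shows a reverse-ASD pattern.

#' Construct a panel specification
#'
#' @param set_name Character vector of gene-set names.
#' @param expected_direction One of `"up_in_ASD"`, `"down_in_ASD"` per
#'   set.
#' @return Data frame of class `panel_spec`.
#' @export
panel_spec <- function(set_name, expected_direction) {
  if (length(set_name) != length(expected_direction))
    .stopf("set_name and expected_direction lengths differ")
  if (anyDuplicated(set_name)) .stopf("duplicate panel set names")
  if (!all(expected_direction %in% c("up_in_ASD", "down_in_ASD")))
    .stopf("expected_direction must be 'up_in_ASD' or 'down_in_ASD'")
  structure(data.frame(set_name = set_name,
                       expected_direction = expected_direction,
                       stringsAsFactors = FALSE),
            class = c("panel_spec", "data.frame"))
}

#' @rdname panel_spec
#' @param path Two-column TSV (`set_name`, `expected_direction`).
#' @export
read_panel_spec <- function(path) {
  tab <- .read_tsv(path)
  panel_spec(tab$set_name, tab$expected_direction)
}

#' @rdname panel_spec
#' @param panel A `panel_spec`.
#' @export
write_panel_spec <- function(panel, path) {
  .write_tsv(as.data.frame(panel), path)
}

#' Classify a transcript group's enrichment profile against a panel
#'
#' For each panel set present in the GSEA result, a significant
#' enrichment is scored as `reverse` when its sign opposes the set's
#' expected ASD direction (an `up_in_ASD` set with negative NES, or a
#' `down_in_ASD` set with positive NES) and as `like` when it matches;
#' non-significant or missing sets count as `null`. The group label is
#' `reverse-ASD` when reverse calls outnumber like calls, `ASD-like` for
#' the converse, and `indeterminate` on a tie or when nothing is
#' significant. The strength score sums `|NES|` over significant sets,
#' weighted +1 for reverse and -1 for like, so stronger and more numerous
#' concordant enrichments yield larger magnitudes.
#'
#' @param gsea A `gsea_result` covering at least one panel set.
#' @param panel A [panel_spec()].
#' @param q_cut FDR threshold defining significance (default 0.05).
#' @param group Optional transcript-group (contrast) name for reporting.
#' @return Object of class `pattern_call`: `group`, `sets` (per-set NES,
#'   q, significance and concordance), `n_reverse`, `n_like`, `label`,
#'   `strength`.
#' @export
classify_pattern <- function(gsea, panel, q_cut = 0.05, group = NULL) {
  stopifnot(inherits(panel, "panel_spec"))
  recs <- as.data.frame(gsea)
  if (!any(panel$set_name %in% recs$set))
    .stopf("no panel set appears in the GSEA result")
  miss <- setdiff(panel$set_name, recs$set)
  if (length(miss))
    .warnf("panel set(s) missing from GSEA records (counted as null): %s",
           paste(miss, collapse = ", "))
  idx <- match(panel$set_name, recs$set)
  nes <- recs$nes[idx]
  q <- recs$fdr_q[idx]
  sig <- !is.na(q) & q < q_cut & !is.na(nes) & nes != 0
  expected_sign <- ifelse(panel$expected_direction == "up_in_ASD", 1, -1)
  concord <- rep("null", nrow(panel))
  concord[sig & sign(nes) == -expected_sign] <- "reverse"
  concord[sig & sign(nes) == expected_sign] <- "like"
  n_rev <- sum(concord == "reverse")
  n_like <- sum(concord == "like")
  label <- if (n_rev > n_like) "reverse-ASD"
           else if (n_like > n_rev) "ASD-like" else "indeterminate"
  strength <- sum(abs(nes[concord == "reverse"])) -
    sum(abs(nes[concord == "like"]))
  sets <- data.frame(set_name = panel$set_name,
                     expected_direction = panel$expected_direction,
                     nes = nes, fdr_q = q, significant = sig,
                     concordance = concord, stringsAsFactors = FALSE)
  structure(list(group = group, sets = sets, n_reverse = n_rev,
                 n_like = n_like, label = label, strength = strength,
                 q_cut = q_cut),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("%s: %s (reverse %d, like %d, strength %.2f)\n",
              x$group %||% "pattern", x$label, x$n_reverse, x$n_like,
              x$strength))
  invisible(x)
}

#' Compare two pattern calls on the same panel
#'
#' Judged on the number of significant sets concordant with the reference
#' call's dominant category and on the strength score: `weakened` when
#' the second call has strictly fewer such sets *and* lower strength,
#' `strengthened` for the reverse, `unchanged` otherwise. Per-set NES and
#' q deltas are reported alongside.
#'
#' @param a Reference [classify_pattern()] call.
#' @param b Comparison call, computed against the same panel.
#' @return List of class `pattern_comparison`: `verdict`, counts and
#'   strengths of both calls, and `deltas` (per-set `d_nes`, `d_fdr_q`).
#' @export
compare_patterns <- function(a, b) {
  stopifnot(inherits(a, "pattern_call"), inherits(b, "pattern_call"))
  if (!identical(a$sets[c("set_name", "expected_direction")],
                 b$sets[c("set_name", "expected_direction")]))
    .stopf("pattern calls were computed against different panels")
  # count sets concordant with the reference call's dominant category
  cat_ref <- switch(a$label, "reverse-ASD" = "reverse",
                    "ASD-like" = "like", "reverse")
  n_a <- sum(a$sets$concordance == cat_ref)
  n_b <- sum(b$sets$concordance == cat_ref)
  # compare strength in the reference direction
  s_a <- if (cat_ref == "reverse") a$strength else -a$strength
  s_b <- if (cat_ref == "reverse") b$strength else -b$strength
  verdict <- if (n_b < n_a && s_b < s_a) "weakened"
             else if (n_b > n_a && s_b > s_a) "strengthened"
             else "unchanged"
  deltas <- data.frame(set_name = a$sets$set_name,
                       d_nes = b$sets$nes - a$sets$nes,
                       d_fdr_q = b$sets$fdr_q - a$sets$fdr_q,
                       stringsAsFactors = FALSE)
  structure(list(verdict = verdict, reference_label = a$label,
                 n_concordant_a = n_a, n_concordant_b = n_b,
                 strength_a = a$strength, strength_b = b$strength,
                 deltas = deltas),
            class = "pattern_comparison")
}

#' Write a pattern call as JSON
#'
#' @param call A `pattern_call`.
#' @param path Output path.
#' @export
write_pattern_call <- function(call, path) {
  stopifnot(inherits(call, "pattern_call"))
  jsonlite::write_json(
    list(group = call$group, label = call$label,
         n_reverse = call$n_reverse, n_like = call$n_like,
         strength = call$strength, q_cut = call$q_cut, sets = call$sets),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
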