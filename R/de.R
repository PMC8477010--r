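# NB Wald test, BH adjustment, DEG calling, overlap summaries, PCA.

# Fit the NB log-link group mean (eta = log of the normalized mean) by
# Newton iteration with fixed dispersion, vectorized over genes.
# Groups whose counts are all zero get the floored mean 0.5 / sum(sf).
#' @keywords internal
fit_group_eta <- function(Y, sf, idx, alpha, n_iter = 10L) {
  Yg <- Y[, idx, drop = FALSE]
  sfg <- sf[idx]
  tot <- rowSums(Yg)
  sft <- sum(sfg)
  zero <- tot == 0
  eta <- log(pmax(tot / sft, 0.5 / sft * 1e-2))
  for (it in seq_len(n_iter)) {
    mu <- exp(eta) %o% sfg
    U <- rowSums((Yg - mu) / (1 + alpha * mu))
    I <- rowSums(mu / (1 + alpha * mu))
    step <- pmin(pmax(U / pmax(I, 1e-12), -3), 3)
    eta <- eta + ifelse(zero, 0, step)
  }
  eta[zero] <- log(0.5 / sft)
  mu <- exp(eta) %o% sfg
  list(eta = eta, info = pmax(rowSums(mu / (1 + alpha * mu)), 1e-12))
}

# Two-group NB Wald test on raw index sets; shared by wald_test() and the
# resimulation engine of the power module.
#' @keywords internal
nb_wald_core <- function(Y, sf, alpha, idxA, idxB) {
  fa <- fit_group_eta(Y, sf, idxA, alpha)
  fb <- fit_group_eta(Y, sf, idxB, alpha)
  delta <- fa$eta - fb$eta
  se <- sqrt(1 / fa$info + 1 / fb$info)
  stat <- delta / se
  list(log2fc = delta / log(2), se = se / log(2), stat = stat,
       pvalue = pmax(2 * stats::pnorm(-abs(stat)), .Machine$double.xmin))
}

#' Negative-binomial Wald test for one contrast
#'
#' Per-gene NB log-link regression with fixed (estimated) dispersion:
#' group means are fitted by maximum likelihood, and the log2 fold change
#' (numerator over denominator) is tested with the Wald statistic
#' `beta / SE(beta)` against a two-sided normal reference. Genes with zero
#' counts across both contrast groups are excluded and reported in the
#' `skipped` attribute.
#'
#' @param cm A [count_matrix()].
#' @param factors Size factors ([size_factors()]; computed if `NULL`).
#' @param dispersions A [estimate_dispersion()] fit (computed if `NULL`).
#' @param contrast Contrast name (see [study_contrasts()]) or a contrast
#'   list.
#' @return Object of class `de_result`: data frame with `gene_id`,
#'   `base_mean` (mean normalized count over the contrast samples),
#'   `log2fc`, `se`, `stat`, `pvalue`. Attributes `contrast`, `skipped`.
#' @export
wald_test <- function(cm, factors = NULL, dispersions = NULL, contrast) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(factors)) factors <- size_factors(cm)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(cm, factors)
  ct <- resolve_contrast(contrast, cm$samples)
  idxA <- match(ct$numerator, colnames(cm$counts))
  idxB <- match(ct$denominator, colnames(cm$counts))

  genes <- intersect(rownames(cm$counts), dispersions$gene_id)
  Y <- cm$counts[genes, , drop = FALSE]
  both_zero <- rowSums(Y[, c(idxA, idxB), drop = FALSE]) == 0
  skipped <- c(attr(dispersions, "excluded"), genes[both_zero])
  Y <- Y[!both_zero, , drop = FALSE]
  alpha <- dispersions$dispersion[match(rownames(Y), dispersions$gene_id)]

  w <- nb_wald_core(Y, factors, alpha, idxA, idxB)
  base_mean <- rowMeans(sweep(Y[, c(idxA, idxB), drop = FALSE], 2,
                              factors[c(idxA, idxB)], "/"))
  out <- data.frame(gene_id = rownames(Y), base_mean = base_mean,
                    log2fc = w$log2fc, se = w$se, stat = w$stat,
                    pvalue = w$pvalue, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("de_result", "data.frame"),
            contrast = ct$name, skipped = skipped)
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`): output order matches input order and
#' values are capped at 1.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) .stopf("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    .stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Full differential-expression analysis for one contrast
#'
#' Composes [wald_test()] with [bh_adjust()] and the DEG rule
#' (adjusted p below `alpha`; fold change is never a criterion).
#'
#' @inheritParams wald_test
#' @param alpha DEG threshold on the adjusted p-value (default 0.05).
#' @return A `de_result` data frame with added `padj` and `is_deg`.
#' @export
de_analysis <- function(cm, contrast, factors = NULL, dispersions = NULL,
                        alpha = 0.05) {
  de <- wald_test(cm, factors, dispersions, contrast)
  de$padj <- bh_adjust(de$pvalue)
  de$is_deg <- de$padj < alpha
  de
}

#' Call differentially expressed genes
#'
#' Flags genes with BH-adjusted p below `alpha` as DEGs — adjusted
#' p-values only, no fold-change cutoff — and tallies up- and
#' downregulated calls.
#'
#' @param de A `de_result` (adjusted p-values are computed if absent).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List of class `deg_table`: `table` (DEG rows with `gene_id`,
#'   `log2fc`, `padj`, `direction`), `n_deg`, `n_up`, `n_down`,
#'   `contrast`.
#' @export
call_degs <- function(de, alpha = 0.05) {
  if (is.null(de$padj)) de$padj <- if (nrow(de)) bh_adjust(de$pvalue)
    else numeric(0)
  hit <- de$padj < alpha
  tab <- data.frame(gene_id = de$gene_id[hit], log2fc = de$log2fc[hit],
                    padj = de$padj[hit],
                    direction = ifelse(de$log2fc[hit] > 0, "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n_deg = nrow(tab),
                 n_up = sum(tab$direction == "up"),
                 n_down = sum(tab$direction == "down"),
                 contrast = attr(de, "contrast"), alpha = alpha),
            class = "deg_table")
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("DEGs (%s, adj p < %g): %d (%d up, %d down)\n",
              x$contrast %||% "?", x$alpha, x$n_deg, x$n_up, x$n_down))
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlap and direction concordance of two DEG tables
#'
#' Counts shared and unique DEGs (Venn-style) and, among the shared genes,
#' the fraction whose fold-change signs agree. With no shared genes the
#' concordance is reported as not applicable (`NA`).
#'
#' @param a,b Outputs of [call_degs()] (or their `$table` data frames).
#' @return List of class `overlap_summary`: `n_shared`, `n_only_a`,
#'   `n_only_b`, `concordance` (fraction in \[0, 1\] or `NA`),
#'   `concordance_pct`, and the `shared` gene table with both signs.
#' @export
deg_overlap <- function(a, b) {
  ta <- if (inherits(a, "deg_table")) a$table else a
  tb <- if (inherits(b, "deg_table")) b$table else b
  shared_ids <- intersect(ta$gene_id, tb$gene_id)
  sa <- sign(ta$log2fc[match(shared_ids, ta$gene_id)])
  sb <- sign(tb$log2fc[match(shared_ids, tb$gene_id)])
  conc <- if (length(shared_ids)) mean(sa == sb) else NA_real_
  structure(list(
    n_shared = length(shared_ids),
    n_only_a = nrow(ta) - length(shared_ids),
    n_only_b = nrow(tb) - length(shared_ids),
    concordance = conc,
    concordance_pct = if (is.na(conc)) NA_real_ else 100 * conc,
    shared = data.frame(gene_id = shared_ids, sign_a = sa, sign_b = sb,
                        stringsAsFactors = FALSE)),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("shared %d | only A %d | only B %d | concordance %s\n",
              x$n_shared, x$n_only_a, x$n_only_b,
              if (is.na(x$concordance_pct)) "n/a"
              else sprintf("%.1f%%", x$concordance_pct)))
  invisible(x)
}

#' Principal component projection of the samples
#'
#' PCA of the samples on `log2(normalized count + 1)` values (a simple
#' variance-stabilizing transform; the projection is a diagnostic of
#' sample grouping, not an inferential stage). Components are ordered by
#' nonincreasing explained variance.
#'
#' @param cm A [count_matrix()].
#' @param factors Size factors (computed if `NULL`).
#' @param n_components Number of components to return (default all).
#' @return List with `coordinates` (data frame: `sample_id`, `group`,
#'   `PC1`, ...) and `explained` (variance fractions, summing to 1 over
#'   the full rank).
#' @export
pca_projection <- function(cm, factors = NULL, n_components = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2L) .stopf("PCA needs >= 2 samples")
  x <- log2(normalized_counts(cm, factors) + 1)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components %||% ncol(pc$x), ncol(pc$x))
  coords <- data.frame(sample_id = rownames(pc$x),
                       group = cm$samples$group[match(rownames(pc$x),
                                                      cm$samples$sample_id)],
                       pc$x[, seq_len(k), drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
  list(coordinates = coords, explained = frac)
}
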