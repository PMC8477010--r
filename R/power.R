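# Replicate-number power study by NB resimulation.
#
# A fitted comparison model freezes, from a pilot analysis, the per-gene
# normalized group means, the dispersions, and the set of genes to treat
# as truly DE (the pilot's called DEGs, with their estimated effects).
# Power at a given replicate number is the average recall of that
# true-DEG set, TP / (TP + FN), over full reruns of the DE pipeline on
# resimulated counts.

#' Fit per-gene NB models for one comparison from a pilot analysis
#'
#' Group means are the normalized group means of the pilot (floored at
#' 0.5 to avoid degenerate NB means), dispersions come from the pilot's
#' dispersion fit, and the true-DEG set is the pilot's called DEGs (BH
#' adjusted p below `alpha`) with their estimated fold-change signs.
#' Genes not in the true-DEG set are modelled with a common mean across
#' the two groups, so the simulated truth matches the TP/FN accounting.
#'
#' @param cm The pilot [count_matrix()].
#' @param factors Pilot size factors (computed if `NULL`).
#' @param dispersions Pilot [estimate_dispersion()] fit (computed if
#'   `NULL`).
#' @param contrast Contrast name or list.
#' @param de The pilot `de_result` for this contrast (recomputed if
#'   `NULL`); must carry `padj` or it will be BH-adjusted here.
#' @param alpha DEG threshold (default 0.05).
#' @param mean_floor Floor on normalized group means (default 0.5).
#' @return Object of class `nb_comparison_model`: data frame `gene_id`,
#'   `mean_num`, `mean_den`, `dispersion`, `is_true_de`, `sign`;
#'   attribute `contrast`.
#' @export
fit_nb_models <- function(cm, factors = NULL, dispersions = NULL, contrast,
                          de = NULL, alpha = 0.05, mean_floor = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(factors)) factors <- size_factors(cm)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(cm, factors)
  ct <- resolve_contrast(contrast, cm$samples)
  if (is.null(de)) de <- wald_test(cm, factors, dispersions, ct)
  if (!identical(attr(de, "contrast"), ct$name))
    .stopf("DE result is for contrast '%s', not '%s'",
           attr(de, "contrast") %||% "<none>", ct$name)
  if (is.null(de$padj)) de$padj <- bh_adjust(de$pvalue)

  idxA <- match(ct$numerator, colnames(cm$counts))
  idxB <- match(ct$denominator, colnames(cm$counts))
  Yn <- normalized_counts(cm, factors)[de$gene_id, , drop = FALSE]
  mA <- pmax(rowMeans(Yn[, idxA, drop = FALSE]), mean_floor)
  mB <- pmax(rowMeans(Yn[, idxB, drop = FALSE]), mean_floor)
  mC <- pmax(rowMeans(Yn[, c(idxA, idxB), drop = FALSE]), mean_floor)
  is_de <- de$padj < alpha
  out <- data.frame(
    gene_id = de$gene_id,
    mean_num = ifelse(is_de, mA, mC),
    mean_den = ifelse(is_de, mB, mC),
    dispersion = dispersions$dispersion[match(de$gene_id,
                                              dispersions$gene_id)],
    is_true_de = is_de,
    sign = ifelse(is_de, sign(de$log2fc), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("nb_comparison_model", "data.frame"),
            contrast = ct$name)
}

#' Simulated statistical power at a given replicate number
#'
#' Each replicate draws NB counts from the fitted model at `n_per_group`
#' samples per group (unit library sizes), then reruns the full analysis
#' — size factors, dispersion estimation, Wald test, BH adjustment, DEG
#' calling — and counts how many true DEGs are recalled (TP) or missed
#' (FN). Power is TP / (TP + FN), averaged over replicates; false
#' positives among the truly non-DE genes are recorded as an empirical
#' FDR diagnostic but never enter the power formula.
#'
#' @param model A [fit_nb_models()] object with a nonempty true-DEG set.
#' @param n_per_group Samples per group in the resimulation (>= 2).
#' @param n_reps Number of replicates (default 100).
#' @param alpha DEG threshold in the reanalysis (default 0.05).
#' @param seed Integer seed.
#' @param adjust Call DEGs on BH-adjusted p-values (default `TRUE`, the
#'   study procedure); `FALSE` thresholds the raw p-values instead, a
#'   diagnostic mode for calibration checks.
#' @return Object of class `power_result`: `contrast`, `n_per_group`,
#'   `n_reps`, `n_true_de`, `power` (mean), `power_sd`, per-replicate
#'   `tp`, `fn`, `power_reps`, `fp`.
#' @export
simulate_power <- function(model, n_per_group, n_reps = 100, alpha = 0.05,
                           seed = 1, adjust = TRUE) {
  stopifnot(inherits(model, "nb_comparison_model"))
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) .stopf("n_per_group must be >= 2")
  n_true <- sum(model$is_true_de)
  if (n_true == 0L)
    .stopf(paste0("power undefined: the pilot called no DEGs for ",
                  "contrast '%s'"), attr(model, "contrast"))
  G <- nrow(model)
  n <- n_per_group
  mu <- c(rep(model$mean_num, n), rep(model$mean_den, n))
  size <- rep(1 / pmax(model$dispersion, 1e-12), 2 * n)
  groups <- rep(c("num", "den"), each = n)
  true_ids <- model$gene_id[model$is_true_de]
  res <- with_seed(seed, {
    tp <- fn <- fp <- integer(n_reps)
    for (r in seq_len(n_reps)) {
      Y <- matrix(stats::rnbinom(G * 2 * n, mu = mu, size = size),
                  nrow = G)
      rownames(Y) <- model$gene_id
      keep <- rowSums(Y) > 0
      Ys <- Y[keep, , drop = FALSE]
      sf <- size_factors(Ys)
      disp <- estimate_dispersion(Ys, sf, groups)
      genes <- disp$gene_id
      w <- nb_wald_core(Ys[genes, , drop = FALSE], sf,
                        disp$dispersion, seq_len(n), n + seq_len(n))
      padj <- if (adjust) bh_adjust(w$pvalue) else w$pvalue
      called <- genes[padj < alpha]
      tp[r] <- length(intersect(called, true_ids))
      fn[r] <- n_true - tp[r]
      fp[r] <- length(setdiff(called, true_ids))
    }
    list(tp = tp, fn = fn, fp = fp)
  })
  power_reps <- res$tp / (res$tp + res$fn)
  structure(list(contrast = attr(model, "contrast"),
                 n_per_group = n_per_group, n_reps = n_reps,
                 n_true_de = n_true, power = mean(power_reps),
                 power_sd = stats::sd(power_reps), tp = res$tp,
                 fn = res$fn, fp = res$fp, power_reps = power_reps),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("%s, n=%d/group: power %.3f (sd %.3f) over %d reps, %d true DEGs\n",
              x$contrast, x$n_per_group, x$power, x$power_sd, x$n_reps,
              x$n_true_de))
  invisible(x)
}

#' Power curve across comparisons and replicate numbers
#'
#' Runs [simulate_power()] for every fitted comparison model at each
#' requested replicate number and summarizes the across-comparison
#' minimum power per replicate number. Comparisons whose pilot called no
#' DEGs have undefined power; they are excluded and listed.
#'
#' @param models List of [fit_nb_models()] objects (named or not).
#' @param ns Replicate numbers to evaluate (default `c(3, 6, 9)`).
#' @param n_reps Replicates per configuration (default 100).
#' @param alpha DEG threshold (default 0.05).
#' @param seed Master seed; each (comparison, n) gets a derived
#'   substream, so adding configurations never reshuffles others.
#' @return List of class `power_curve`: `table` (contrast, n_per_group,
#'   n_reps, n_true_de, tp/fn means, power, power_sd), `summary`
#'   (`n_per_group`, `min_power`, `at_contrast`), `undefined` (excluded
#'   contrast names).
#' @export
power_curve <- function(models, ns = c(3, 6, 9), n_reps = 100,
                        alpha = 0.05, seed = 1) {
  if (inherits(models, "nb_comparison_model")) models <- list(models)
  if (!length(models)) .stopf("no models given")
  defined <- vapply(models, function(m) sum(m$is_true_de) > 0, logical(1))
  undefined <- vapply(models[!defined], attr, "", "contrast")
  models <- models[defined]
  if (!length(models))
    .stopf("power undefined for every comparison (no pilot DEGs)")
  rows <- list()
  for (m in models) {
    ct <- attr(m, "contrast")
    for (n in ns) {
      pr <- simulate_power(m, n, n_reps, alpha,
                           derive_seed(seed, paste(ct, n)))
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = ct, n_per_group = n, n_reps = n_reps,
        n_true_de = pr$n_true_de, mean_tp = mean(pr$tp),
        mean_fn = mean(pr$fn), power = pr$power, power_sd = pr$power_sd,
        mean_fp = mean(pr$fp), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(ns, function(n) {
    sub <- tab[tab$n_per_group == n, ]
    i <- which.min(sub$power)
    data.frame(n_per_group = n, min_power = sub$power[i],
               at_contrast = sub$contrast[i], stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, summary = summ,
                 undefined = unname(undefined)),
            class = "power_curve")
}

#' Serialize a fitted comparison model to TSV
#'
#' @param model A [fit_nb_models()] object.
#' @param path Output path.
#' @export
write_nb_model <- function(model, path) {
  .write_tsv(as.data.frame(model), path,
             header_lines = sprintf("contrast: %s",
                                    attr(model, "contrast")))
}
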