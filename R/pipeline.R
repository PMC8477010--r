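# End-to-end orchestration of the six-comparison study.

#' Build a pipeline run configuration
#'
#' Exactly one input mode is active: `synthetic` (a named list of
#' generator settings) or `input` (paths to counts/sample-sheet files,
#' with optional GMT collections, a panel spec and a homolog map).
#'
#' @param synthetic `NULL`, or a list with any of `n_genes`, `profile`,
#'   `n_per_group`, `sf_jitter` (defaults: 2000, "study-like", 3, 0).
#' @param input `NULL`, or a list with `counts`, `samples` and optionally
#'   `gmt`, `panel`, `homolog_map` paths.
#' @param adj_p DEG threshold (default 0.05).
#' @param fdr GSEA significance threshold (default 0.05).
#' @param n_perm GSEA permutations (default 1000).
#' @param min_size,max_size GSEA set-size bounds (defaults 15, 500).
#' @param power_ns Replicate numbers for the power study
#'   (default `c(3, 6, 9)`).
#' @param power_reps Power replicates per configuration (default 100).
#' @param run_power,run_gsea,run_ora Stage switches (all default `TRUE`).
#' @param seed Master seed; every stochastic stage derives its substream
#'   from it.
#' @param out_dir Output directory, or `NULL` to keep results in memory
#'   only.
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = list(), input = NULL, adj_p = 0.05,
                       fdr = 0.05, n_perm = 1000, min_size = 15,
                       max_size = 500, power_ns = c(3, 6, 9),
                       power_reps = 100, run_power = TRUE, run_gsea = TRUE,
                       run_ora = TRUE, seed = 1, out_dir = NULL) {
  if (!is.null(synthetic) && !is.null(input))
    .stopf("exactly one of synthetic or input may be set, not both")
  if (is.null(synthetic) && is.null(input))
    .stopf("one of synthetic or input must be set")
  if (!is.null(synthetic)) {
    defaults <- list(n_genes = 2000, profile = "study-like",
                     n_per_group = 3, sf_jitter = 0)
    synthetic <- utils::modifyList(defaults, synthetic)
  }
  structure(list(synthetic = synthetic, input = input, adj_p = adj_p,
                 fdr = fdr, n_perm = n_perm, min_size = min_size,
                 max_size = max_size, power_ns = power_ns,
                 power_reps = power_reps, run_power = run_power,
                 run_gsea = run_gsea, run_ora = run_ora,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Configuration file; the keys mirror the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @keywords internal
config_hash <- function(config) {
  name_hash(paste(deparse(unclass(config)), collapse = ""))
}

#' Run the six-comparison study end to end
#'
#' Executes the full analysis: input (or synthetic generation), size
#' factors, dispersion estimation, the six DE contrasts, DEG calling,
#' the two Venn/concordance overlaps (the two genotype contrasts, and
#' the two treatment contrasts), ranking, GSEA against the panel
#' collection, ORA of each contrast's DEGs, pattern classification and
#' comparison against the baseline genotype contrast, and the NB
#' resimulation power study. Reruns with the same configuration are
#' bit-identical. When `out_dir` is set every stage's table is written
#' with a provenance header (seed and configuration hash).
#'
#' @param config A [run_config()].
#' @return A result bundle (list of class `run_bundle`) with elements
#'   `config`, `config_hash`, `counts`, `factors`, `dispersions`, `pca`,
#'   `de` (per contrast, with `padj`/`is_deg`), `degs`, `overlaps`,
#'   `ranked`, `gsea`, `ora`, `patterns`, `pattern_comparisons`, `power`,
#'   `truth` (synthetic mode), `panels`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  log <- character(0)
  say <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- input ---------------------------------------------------------
  panels <- NULL
  truth <- NULL
  homolog <- NULL
  collection <- NULL
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    stage("synthetic input", {
      params <- sample_gene_params(sc$n_genes, sc$profile,
                                   derive_seed(seed, "params"))
      design <- study_design(sc$n_per_group, sf_jitter = sc$sf_jitter,
                             seed = derive_seed(seed, "design"))
      sim <- simulate_counts(params, design, derive_seed(seed, "counts"))
      cm <- sim$counts
      truth <- sim$truth
      say("synthetic input: %d genes, %d samples, profile '%s'",
          nrow(cm$counts), ncol(cm$counts), sc$profile)
      if (config$run_gsea) {
        # panel size bounded by the available truly-DE pool per direction
        tt <- truth[truth$contrast == "Veh-K/W", ]
        avail <- min(sum(tt$sign > 0), sum(tt$sign < 0))
        set_size <- min(50, floor(avail / 0.7))
        if (set_size >= config$min_size) {
          panels <- make_directional_panels(truth, set_size = set_size,
                                            seed = derive_seed(seed,
                                                               "panels"))
          say("panels: 10 synthetic sets of size %d", set_size)
        } else {
          say("panels skipped: only %d truly-DE genes per direction", avail)
        }
      }
      cm
    }) -> cm
    if (!is.null(panels)) collection <- panels$sets
  } else {
    inp <- config$input
    cm <- stage("read input", read_count_matrix(inp$counts, inp$samples))
    if (!is.null(inp$gmt))
      collection <- stage("read gene sets", read_gmt(inp$gmt))
    if (!is.null(inp$panel))
      panels <- list(sets = collection,
                     panel = stage("read panel", read_panel_spec(inp$panel)))
    if (!is.null(inp$homolog_map))
      homolog <- stage("read homolog map",
                       read_homolog_map(inp$homolog_map))
    say("input: %d genes, %d samples from %s", nrow(cm$counts),
        ncol(cm$counts), inp$counts)
  }

  # --- DE core -------------------------------------------------------
  factors <- stage("size factors", size_factors(cm))
  dispersions <- stage("dispersion", estimate_dispersion(cm, factors))
  say("dispersion: %d genes tested, %d all-zero genes excluded",
      nrow(dispersions), length(attr(dispersions, "excluded")))
  pca <- stage("pca", pca_projection(cm, factors))

  plan <- study_contrasts()
  de <- list(); degs <- list(); ranked <- list()
  for (cn in names(plan)) {
    de[[cn]] <- stage(paste("de", cn),
                      de_analysis(cm, cn, factors, dispersions,
                                  alpha = config$adj_p))
    degs[[cn]] <- call_degs(de[[cn]], config$adj_p)
    ranked[[cn]] <- rank_metric(de[[cn]])
    say("%s: %d genes tested, %d DEGs (%d up, %d down)", cn,
        nrow(de[[cn]]), degs[[cn]]$n_deg, degs[[cn]]$n_up,
        degs[[cn]]$n_down)
  }
  overlaps <- list(
    "Veh-K/W_vs_Mem-K/W" = deg_overlap(degs[["Veh-K/W"]],
                                       degs[["Mem-K/W"]]),
    "WT-M/V_vs_KO-M/V" = deg_overlap(degs[["WT-M/V"]], degs[["KO-M/V"]]))

  # --- enrichment ----------------------------------------------------
  gsea <- list(); ora <- list(); patterns <- list()
  pattern_comparisons <- list()
  if (config$run_gsea && !is.null(collection)) {
    for (cn in names(plan)) {
      rl <- ranked[[cn]]
      if (!is.null(homolog)) rl <- map_ranked_list(rl, homolog)
      gsea[[cn]] <- stage(paste("gsea", cn),
        gsea_collection(rl, collection, n_perm = config$n_perm,
                        min_size = config$min_size,
                        max_size = config$max_size,
                        seed = derive_seed(seed, paste("gsea", cn)),
                        q_cut = config$fdr))
      say("gsea %s: %d sets tested, %d significant, %d skipped", cn,
          nrow(gsea[[cn]]), sum(gsea[[cn]]$significant),
          nrow(attr(gsea[[cn]], "skipped")))
      if (!is.null(panels) && !is.null(panels$panel) &&
          nrow(gsea[[cn]]) > 0)
        patterns[[cn]] <- classify_pattern(gsea[[cn]], panels$panel,
                                           config$fdr, group = cn)
    }
    base <- patterns[["Veh-K/W"]]
    if (!is.null(base)) {
      for (cn in intersect(c("Mem-K/W", "KO-M/V", "WT-M/V"),
                           names(patterns)))
        pattern_comparisons[[paste0("Veh-K/W_vs_", cn)]] <-
          compare_patterns(base, patterns[[cn]])
    }
  }
  if (config$run_ora && !is.null(collection)) {
    for (cn in names(plan)) {
      universe <- de[[cn]]$gene_id
      dg <- degs[[cn]]$table$gene_id
      if (length(dg))
        ora[[cn]] <- stage(paste("ora", cn),
                           ora_test(dg, universe, collection))
    }
  }

  # --- power ---------------------------------------------------------
  power <- NULL
  if (config$run_power) {
    models <- lapply(names(plan), function(cn)
      fit_nb_models(cm, factors, dispersions, cn, de[[cn]],
                    alpha = config$adj_p))
    power <- stage("power",
                   power_curve(models, ns = config$power_ns,
                               n_reps = config$power_reps,
                               alpha = config$adj_p,
                               seed = derive_seed(seed, "power")))
    if (length(power$undefined))
      say("power: undefined for %s (no pilot DEGs)",
          paste(power$undefined, collapse = ", "))
  }

  bundle <- structure(
    list(config = config, config_hash = config_hash(config),
         counts = cm, factors = factors, dispersions = dispersions,
         pca = pca, de = de, degs = degs, overlaps = overlaps,
         ranked = ranked, gsea = gsea, ora = ora, patterns = patterns,
         pattern_comparisons = pattern_comparisons, power = power,
         truth = truth, panels = panels, log = log),
    class = "run_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @keywords internal
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(sprintf("seed: %d", bundle$config$seed),
            sprintf("config_hash: %d", bundle$config_hash))
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  for (cn in names(bundle$de))
    .write_tsv(as.data.frame(bundle$de[[cn]]),
               file.path(dir, sprintf("de_%s.tsv", safe(cn))), prov)
  for (cn in names(bundle$gsea))
    write_gsea_table(bundle$gsea[[cn]],
                     file.path(dir, sprintf("gsea_%s.tsv", safe(cn))),
                     prov)
  for (cn in names(bundle$ora))
    .write_tsv(as.data.frame(bundle$ora[[cn]]),
               file.path(dir, sprintf("ora_%s.tsv", safe(cn))), prov)
  for (cn in names(bundle$patterns))
    write_pattern_call(bundle$patterns[[cn]],
                       file.path(dir, sprintf("pattern_%s.json", safe(cn))))
  if (!is.null(bundle$power))
    .write_tsv(bundle$power$table, file.path(dir, "power.tsv"), prov)
  ov <- lapply(bundle$overlaps, function(o)
    o[c("n_shared", "n_only_a", "n_only_b", "concordance_pct")])
  jsonlite::write_json(ov, file.path(dir, "overlaps.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(c(paste0("# ", prov), bundle$log),
             file.path(dir, "pipeline.log"))
  write_report(bundle, file.path(dir, "report.md"))
  invisible(dir)
}

#' Render a human-readable study report
#'
#' Markdown summary of a pipeline run: per-comparison DEG tallies, the
#' overlap/concordance summaries, the top five positively and negatively
#' enriched gene sets per comparison, pattern labels with their
#' comparisons, and the power summary.
#'
#' @param bundle A [run_pipeline()] result.
#' @param path Optional output path; when `NULL` the lines are returned
#'   invisibly only.
#' @return Character vector of report lines, invisibly.
#' @export
write_report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "run_bundle"))
  ln <- c("# Six-comparison study report", "",
          sprintf("seed %d, config hash %d", bundle$config$seed,
                  bundle$config_hash), "", "## Differential expression", "")
  for (cn in names(bundle$degs)) {
    d <- bundle$degs[[cn]]
    ln <- c(ln, sprintf("- %s: %d DEGs (%d up, %d down) of %d genes",
                        cn, d$n_deg, d$n_up, d$n_down,
                        nrow(bundle$de[[cn]])))
  }
  ln <- c(ln, "", "## DEG overlaps", "")
  for (on in names(bundle$overlaps)) {
    o <- bundle$overlaps[[on]]
    ln <- c(ln, sprintf("- %s: %d shared, %d / %d unique; concordance %s",
                        on, o$n_shared, o$n_only_a, o$n_only_b,
                        if (is.na(o$concordance_pct)) "not applicable"
                        else sprintf("%.1f%%", o$concordance_pct)))
  }
  if (length(bundle$gsea)) {
    ln <- c(ln, "", "## Top enriched gene sets", "")
    for (cn in names(bundle$gsea)) {
      g <- as.data.frame(bundle$gsea[[cn]])
      g <- g[order(-g$nes), ]
      top <- function(df) if (nrow(df)) sprintf("%s (NES %.2f, q %.3f)",
                                                df$set, df$nes, df$fdr_q)
                          else "none"
      gneg <- g[g$nes < 0, ]
      gneg <- gneg[order(gneg$nes), ]
      ln <- c(ln, sprintf("### %s", cn),
              "positive:", paste0("  - ", top(utils::head(g[g$nes > 0, ], 5))),
              "negative:", paste0("  - ", top(utils::head(gneg, 5))),
              "")
    }
  }
  if (length(bundle$patterns)) {
    ln <- c(ln, "## Pattern calls", "")
    for (cn in names(bundle$patterns)) {
      p <- bundle$patterns[[cn]]
      ln <- c(ln, sprintf("- %s: %s (reverse %d, like %d, strength %.2f)",
                          cn, p$label, p$n_reverse, p$n_like, p$strength))
    }
    for (on in names(bundle$pattern_comparisons)) {
      pc <- bundle$pattern_comparisons[[on]]
      ln <- c(ln, sprintf("- %s: %s", on, pc$verdict))
    }
  }
  if (!is.null(bundle$power)) {
    ln <- c(ln, "", "## Power summary", "")
    s <- bundle$power$summary
    for (i in seq_len(nrow(s)))
      ln <- c(ln, sprintf("- n = %d per group: minimum power %.3f (%s)",
                          s$n_per_group[i], s$min_power[i],
                          s$at_contrast[i]))
  }
  if (!is.null(path)) writeLines(ln, path)
  invisible(ln)
}
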