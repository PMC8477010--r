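#' Named calibration profiles for the synthetic-count generator
#'
#' A calibration profile fixes the distributions from which per-gene
#' negative-binomial parameters are drawn. Profiles are documented
#' constants, not fitted quantities; they emulate the broad features of a
#' bulk forebrain RNA-seq pilot with three animals per design cell.
#'
#' Shipped profiles:
#' \describe{
#'   \item{`study-like`}{Log-normal baseline means (median 100 normalized
#'     counts, sdlog 1); dispersions in \[0.01, 0.5\], skewed toward the
#'     low values typical of inbred-mouse bulk brain tissue; a dense
#'     genotype effect (5\% of genes, |log2FC| uniform in \[0.5, 2\]) and
#'     sparse, strong treatment effects within each genotype arm (1\% of
#'     genes each, |log2FC| uniform in \[1, 2\]).}
#'   \item{`shared-genotype`}{As `study-like` but with no treatment
#'     effects, so the genotype effect is identical in the vehicle and
#'     memantine arms. Used to study direction concordance of DEGs shared
#'     between the two genotype contrasts.}
#'   \item{`null`}{No effects at all; every gene is truly non-DE.}
#' }
#'
#' @param name Profile name.
#' @return A list of documented constants consumed by
#'   [sample_gene_params()].
#' @export
calibration_profile <- function(name = c("study-like", "shared-genotype",
                                         "null")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("study-like", "shared-genotype", "null"))
    .stopf("unknown calibration profile '%s'", as.character(name)[1])
  base <- list(
    name = name,
    mu_meanlog = log(100), mu_sdlog = 1,
    # dispersion = exp(log(lo) + B * log(hi/lo)), B ~ Beta(1, 2.5):
    # support [0.01, 0.5], median ~0.03
    disp_lo = 0.01, disp_hi = 0.5, disp_beta = c(1, 2.5),
    frac_genotype = 0.05,  lfc_genotype = c(0.5, 2),
    frac_treatment = 0.01, lfc_treatment = c(1, 2))
  if (name == "shared-genotype") base$frac_treatment <- 0
  if (name == "null") {
    base$frac_genotype <- 0
    base$frac_treatment <- 0
  }
  base
}

#' Draw per-gene negative-binomial parameters
#'
#' Samples, for each gene, a baseline mean, a dispersion, and three signed
#' log2 fold-change effects: a genotype effect (applied to both KO cells)
#' and one treatment effect per genotype arm. A gene is truly
#' differentially expressed for a contrast exactly when the corresponding
#' combination of effects is nonzero.
#'
#' @param n_genes Number of genes (>= 1).
#' @param profile A profile name or the list returned by
#'   [calibration_profile()].
#' @param seed Integer seed; identical seed and arguments give identical
#'   parameters.
#' @return Data frame with columns `gene_id`, `mu_base`, `dispersion`,
#'   `log2fc_genotype`, `log2fc_treatment_wt`, `log2fc_treatment_ko`.
#' @export
sample_gene_params <- function(n_genes, profile = "study-like", seed = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    .stopf("n_genes must be a positive integer")
  n_genes <- as.integer(n_genes)
  if (is.character(profile)) profile <- calibration_profile(profile)
  with_seed(seed, {
    spike <- function(frac, range) {
      hit <- stats::rbinom(n_genes, 1L, frac) == 1L
      ifelse(hit,
             sample(c(-1, 1), n_genes, replace = TRUE) *
               stats::runif(n_genes, range[1], range[2]),
             0)
    }
    data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      mu_base = stats::rlnorm(n_genes, profile$mu_meanlog, profile$mu_sdlog),
      dispersion = exp(log(profile$disp_lo) +
                         stats::rbeta(n_genes, profile$disp_beta[1],
                                      profile$disp_beta[2]) *
                         log(profile$disp_hi / profile$disp_lo)),
      log2fc_genotype = spike(profile$frac_genotype, profile$lfc_genotype),
      log2fc_treatment_wt = spike(profile$frac_treatment,
                                  profile$lfc_treatment),
      log2fc_treatment_ko = spike(profile$frac_treatment,
                                  profile$lfc_treatment),
      stringsAsFactors = FALSE)
  })
}

#' Define the 2x2 study layout for simulation
#'
#' @param n_per_group Samples per design cell (default 3, as in the study).
#' @param library_size_factors Optional per-sample positive scaling of
#'   library depth (length `4 * n_per_group`); defaults to all 1.
#' @param sf_jitter If > 0 and no explicit factors are given, library size
#'   factors are drawn uniformly from `[1 - sf_jitter, 1 + sf_jitter]`
#'   (e.g. 0.3 for +/-30\%) to exercise normalization.
#' @param seed Seed used only for the jitter draw.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_per_group = 3, library_size_factors = NULL,
                         sf_jitter = 0, seed = 1) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 1L) .stopf("n_per_group must be >= 1")
  cells <- c("WT.Veh", "WT.Mem", "KO.Veh", "KO.Mem")
  groups <- rep(cells, each = n_per_group)
  n <- length(groups)
  if (is.null(library_size_factors)) {
    library_size_factors <- if (sf_jitter > 0)
      with_seed(seed, stats::runif(n, 1 - sf_jitter, 1 + sf_jitter))
    else rep(1, n)
  }
  if (length(library_size_factors) != n || any(library_size_factors <= 0))
    .stopf("library_size_factors must be %d positive values", n)
  sheet <- data.frame(
    sample_id = paste0(groups, "_", sequence(rep(n_per_group, 4))),
    genotype = sub("\\..*", "", groups),
    treatment = sub(".*\\.", "", groups),
    stringsAsFactors = FALSE)
  structure(list(samples = sheet, groups = groups,
                 library_size_factors = library_size_factors,
                 n_per_group = n_per_group),
            class = "study_design")
}

# True log2 fold change of every gene for each of the six contrasts,
# as the difference of the cell-level effect sums (numerator - denominator).
#' @keywords internal
cell_log2fc <- function(params) {
  cbind("WT.Veh" = 0,
        "WT.Mem" = params$log2fc_treatment_wt,
        "KO.Veh" = params$log2fc_genotype,
        "KO.Mem" = params$log2fc_genotype + params$log2fc_treatment_ko)
}

#' Ground-truth differential-expression table for a parameter set
#'
#' Recomputes, directly from the generator parameters, the true log2 fold
#' change of every gene under each of the six study contrasts, along with
#' the true-DE flag and sign (sign is 0 exactly when the gene is not DE
#' for that contrast).
#'
#' @param params Output of [sample_gene_params()].
#' @return Long data frame: `gene_id`, `contrast`, `true_log2fc`, `is_de`,
#'   `sign`.
#' @export
truth_table <- function(params) {
  cl <- cell_log2fc(params)
  plan <- study_contrasts()
  do.call(rbind, lapply(plan, function(ct) {
    lfc <- cl[, ct$numerator] - cl[, ct$denominator]
    data.frame(gene_id = params$gene_id, contrast = ct$name,
               true_log2fc = lfc, is_de = lfc != 0, sign = sign(lfc),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Simulate negative-binomial counts for a 2x2 study
#'
#' Generates gene-independent NB counts. The expected count of gene g in
#' sample j is `sf_j * mu_base_g * 2^(sum of the effects active in j's
#' design cell)`, with NB variance `mu + dispersion * mu^2`
#' (dispersion 0 is the Poisson limit).
#'
#' @param params Output of [sample_gene_params()].
#' @param design A [study_design()].
#' @param seed Integer seed; output is bit-identical for identical inputs.
#' @return List with `counts` (a [count_matrix()]) and `truth`
#'   (the [truth_table()] of `params`).
#' @export
simulate_counts <- function(params, design, seed = 1) {
  if (nrow(params) == 0L) .stopf("params is empty")
  stopifnot(inherits(design, "study_design"))
  if (any(params$mu_base <= 0)) .stopf("mu_base must be > 0")
  if (any(params$dispersion < 0)) .stopf("dispersion must be >= 0")
  G <- nrow(params)
  cl <- cell_log2fc(params)
  mu <- params$mu_base * 2^cl[, design$groups, drop = FALSE]
  mu <- sweep(mu, 2, design$library_size_factors, "*")
  counts <- with_seed(seed, {
    y <- matrix(0L, G, ncol(mu))
    for (j in seq_len(ncol(mu))) {
      a <- params$dispersion
      pois <- a < 1e-12
      col <- numeric(G)
      if (any(pois)) col[pois] <- stats::rpois(sum(pois), mu[pois, j])
      if (any(!pois)) col[!pois] <- stats::rnbinom(sum(!pois),
                                                   mu = mu[!pois, j],
                                                   size = 1 / a[!pois])
      y[, j] <- as.integer(col)
    }
    y
  })
  dimnames(counts) <- list(params$gene_id, design$samples$sample_id)
  list(counts = count_matrix(counts, design$samples),
       truth = truth_table(params))
}

#' Build directional gene-set panels from a simulation truth table
#'
#' Constructs synthetic stand-ins for ASD-related and ASD-risk gene-set
#' panels: each set carries an expected direction in ASD (`up_in_ASD` or
#' `down_in_ASD`) and is enriched by construction for genes whose true
#' fold-change sign in the chosen contrast realizes the requested pattern,
#' diluted with a stated fraction of random genes.
#'
#' Under `pattern = "reverse"` (the default), `up_in_ASD` sets draw their
#' core from genes truly *down* in the contrast and `down_in_ASD` sets
#' from genes truly *up*, so that a correct analysis recovers a
#' reverse-ASD enrichment profile; `pattern = "like"` swaps the mapping.
#'
#' @param truth A [truth_table()].
#' @param contrast Contrast name whose true signs drive the construction.
#' @param set_size Target panel size (members per set).
#' @param dilution Fraction of each set filled with random genes.
#' @param pattern `"reverse"` or `"like"`.
#' @param seed Integer seed.
#' @return List with `sets` (named list of gene-id vectors: four
#'   ASD-related sets, six ASD-risk sets, all suffixed `_synthetic`) and
#'   `panel` (a [panel_spec()] giving each set's expected ASD direction).
#' @export
make_directional_panels <- function(truth, contrast = "Veh-K/W",
                                    set_size = 50, dilution = 0.3,
                                    pattern = c("reverse", "like"),
                                    seed = 1) {
  pattern <- match.arg(pattern)
  tt <- truth[truth$contrast == contrast, ]
  if (nrow(tt) == 0L) .stopf("contrast '%s' absent from truth", contrast)
  if (dilution < 0 || dilution >= 1) .stopf("dilution must be in [0, 1)")
  up_pool <- tt$gene_id[tt$sign > 0]
  down_pool <- tt$gene_id[tt$sign < 0]
  null_pool <- tt$gene_id[tt$sign == 0]
  n_core <- max(1L, round(set_size * (1 - dilution)))
  n_fill <- set_size - n_core
  # reverse pattern: what is up in ASD is down in this contrast
  pool_for <- function(direction) {
    want_up <- (direction == "up_in_ASD") == (pattern == "like")
    if (want_up) up_pool else down_pool
  }
  sets_def <- c(
    DEG_Up_synthetic = "up_in_ASD", CoExp_Up_M16_synthetic = "up_in_ASD",
    DEG_Down_synthetic = "down_in_ASD",
    CoExp_Down_M12_synthetic = "down_in_ASD",
    Risk_SFARI_all_synthetic = "down_in_ASD",
    Risk_SFARI_high_synthetic = "down_in_ASD",
    Risk_FMRP_targets_synthetic = "down_in_ASD",
    Risk_DeNovo_missense_synthetic = "down_in_ASD",
    Risk_DeNovo_variants_synthetic = "down_in_ASD",
    Risk_AutismKB_synthetic = "down_in_ASD")
  for (d in c("up_in_ASD", "down_in_ASD")) {
    pool <- pool_for(d)
    if (length(pool) < n_core)
      .stopf(paste0("insufficient truly %s genes in contrast '%s' to build ",
                    "'%s' panels (%d available, %d needed)"),
             if (xor(d == "up_in_ASD", pattern == "like")) "downregulated"
             else "upregulated",
             contrast, d, length(pool), n_core)
  }
  sets <- with_seed(seed, {
    lapply(sets_def, function(d) {
      core <- sample(pool_for(d), n_core)
      fill <- if (n_fill > 0)
        sample(setdiff(null_pool, core), min(n_fill, length(null_pool)))
      else character(0)
      sort(c(core, fill))
    })
  })
  list(sets = sets,
       panel = panel_spec(names(sets_def), unname(sets_def)))
}

#' Write a simulated study to plain-text files
#'
#' Counts and sample sheet as TSV, panels as GMT, panel directions and
#' truth table as TSV — the on-disk interface consumed by the pipeline.
#'
#' @param sim Output of [simulate_counts()].
#' @param panels Output of [make_directional_panels()] (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(sim, panels = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"),
                     file.path(dir, "samples.tsv"))
  .write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  if (!is.null(panels)) {
    write_gmt(panels$sets, file.path(dir, "panels_synthetic.gmt"))
    write_panel_spec(panels$panel, file.path(dir, "panel_directions.tsv"))
  }
  invisible(dir)
}
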