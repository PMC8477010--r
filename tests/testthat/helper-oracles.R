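# Independent oracles and small fixture builders used across the suite.

# Brute-force Benjamini-Hochberg step-up: for each p_i, the minimum over
# all j with rank >= rank(i) of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force enrichment score: walk the ranked list position by
# position, build the full running sum, and take the signed maximum
# deviation (ties resolved toward the positive extremum).
es_oracle <- function(ranked_ids, set_ids) {
  N <- length(ranked_ids)
  hit <- ranked_ids %in% set_ids
  k <- sum(hit)
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) 1 / k else -1 / (N - k)
    rs[i] <- cur
  }
  hi <- max(rs)
  lo <- min(rs)
  if (hi >= -lo - 1e-12) max(hi, 0) else lo
}

# A small simulated 2x2 study used by several files.
make_study <- function(n_genes = 400, profile = "study-like", seed = 11,
                       n_per_group = 3, sf_jitter = 0) {
  params <- sample_gene_params(n_genes, profile, seed = seed)
  design <- study_design(n_per_group, sf_jitter = sf_jitter,
                         seed = seed + 1)
  sim <- simulate_counts(params, design, seed = seed + 2)
  list(params = params, design = design, counts = sim$counts,
       truth = sim$truth)
}

# Bare two-group NB count matrix for estimator checks.
two_group_counts <- function(n_genes, n_per_group, mu, alpha, lfc = 0,
                             seed = 1) {
  withr::with_seed(seed, {
    muA <- mu * 2^lfc
    Y <- cbind(
      matrix(rnbinom(n_genes * n_per_group, mu = rep(muA, n_per_group),
                     size = 1 / pmax(alpha, 1e-12)), n_genes),
      matrix(rnbinom(n_genes * n_per_group, mu = rep(mu, n_per_group),
                     size = 1 / pmax(alpha, 1e-12)), n_genes))
    rownames(Y) <- sprintf("g%04d", seq_len(n_genes))
    colnames(Y) <- sprintf("s%02d", seq_len(2 * n_per_group))
    Y
  })
}

two_groups <- function(n_per_group) rep(c("A", "B"), each = n_per_group)

# Minimal ranked list from explicit scores.
ranked_from_scores <- function(scores) {
  stopifnot(!is.null(names(scores)))
  de <- data.frame(gene_id = names(scores), log2fc = scores,
                   pvalue = rep(0.5, length(scores)))
  ord <- order(-scores, names(scores))
  structure(data.frame(gene_id = names(scores)[ord],
                       score = unname(scores[ord]),
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# Hand-built comparison model: explicit group means and dispersions.
toy_model <- function(n_null = 40, n_de = 10, lfc = 8, disp = 0.01,
                      base = 200) {
  g <- sprintf("g%03d", seq_len(n_null + n_de))
  de <- c(rep(TRUE, n_de), rep(FALSE, n_null))
  structure(data.frame(
    gene_id = g,
    mean_num = ifelse(de, base * 2^lfc, base),
    mean_den = base,
    dispersion = disp,
    is_true_de = de,
    sign = ifelse(de, 1, 0), stringsAsFactors = FALSE),
    class = c("nb_comparison_model", "data.frame"), contrast = "toy")
}
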