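# Per-gene NB dispersion estimation.
#
# The gene-wise estimate maximizes a Cox-Reid-adjusted profile likelihood
# on a log-spaced grid (with parabolic refinement); group means are
# profiled out once from the normalized counts rather than re-fit at every
# grid point. With few replicates these gene-wise estimates are noisy, so
# by default they are moderated toward a parametric mean-dispersion trend
# (alpha(mu) = a0 + a1/mu) with an empirical-Bayes log-normal prior whose
# width is read off the spread of the gene-wise estimates — the standard
# sharing-of-information device for 3-samples-per-group designs.

ALPHA_LO <- 1e-8
ALPHA_HI <- 10

# Cox-Reid-adjusted profile log-likelihood of alpha for all genes at once.
#' @keywords internal
apl_grid <- function(Y, sf, groups, ngrid = 37L) {
  G <- nrow(Y)
  Yn <- sweep(Y, 2, sf, "/")
  glev <- unique(groups)
  MU <- matrix(0, G, ncol(Y))
  for (g in glev) {
    idx <- groups == g
    MU[, idx] <- pmax(rowMeans(Yn[, idx, drop = FALSE]), 1e-8)
  }
  MU <- sweep(MU, 2, sf, "*")
  lalph <- seq(log(ALPHA_LO), log(ALPHA_HI), length.out = ngrid)
  LL <- matrix(-Inf, G, ngrid)
  for (i in seq_len(ngrid)) {
    a <- exp(lalph[i])
    ll <- rowSums(stats::dnbinom(Y, size = 1 / a, mu = MU, log = TRUE))
    W <- MU / (1 + a * MU)
    pen <- 0
    for (g in glev)
      pen <- pen +
        0.5 * log(pmax(rowSums(W[, groups == g, drop = FALSE]), 1e-12))
    LL[, i] <- ll - pen
  }
  list(LL = LL, lalph = lalph, basemean = rowMeans(Yn))
}

# Grid argmax with one parabolic refinement step in log alpha.
#' @keywords internal
argmax_refine <- function(LL, lalph) {
  ngrid <- length(lalph)
  best <- max.col(LL, ties.method = "first")
  la <- lalph[best]
  ii <- which(best > 1L & best < ngrid)
  if (length(ii)) {
    b <- best[ii]
    y1 <- LL[cbind(ii, b - 1L)]
    y2 <- LL[cbind(ii, b)]
    y3 <- LL[cbind(ii, b + 1L)]
    h <- lalph[2] - lalph[1]
    den <- y1 - 2 * y2 + y3
    shift <- ifelse(is.finite(den) & den < 0, 0.5 * h * (y1 - y3) / den, 0)
    la[ii] <- lalph[b] + pmin(pmax(shift, -h), h)
  }
  la
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Gene-wise dispersions are estimated by Cox-Reid-adjusted profile maximum
#' likelihood, clamped to `[1e-8, 10]`. When `moderate = TRUE` (default)
#' the gene-wise estimates are additionally shrunk toward a fitted
#' mean-dispersion trend under an empirical-Bayes log-normal prior, which
#' stabilizes the small-sample behaviour of the downstream Wald test.
#' Genes with all-zero counts are excluded and reported.
#'
#' @param cm A [count_matrix()] or counts matrix.
#' @param factors Size factors; computed via [size_factors()] if `NULL`.
#' @param groups Per-sample group labels; defaults to the design cells of
#'   the sample sheet. At least one group must have >= 2 samples.
#' @param moderate Apply empirical-Bayes moderation (default `TRUE`).
#' @return Object of class `dispersion_fit`: data frame with `gene_id`,
#'   `base_mean`, `dispersion_mle` (gene-wise estimate) and `dispersion`
#'   (moderated value used downstream; equals the gene-wise estimate when
#'   `moderate = FALSE`). Attributes: `excluded` (all-zero genes),
#'   `trend` (a0, a1), `prior_var`, `groups`.
#' @export
estimate_dispersion <- function(cm, factors = NULL, groups = NULL,
                                moderate = TRUE) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.null(groups)) {
    if (!inherits(cm, "count_matrix"))
      .stopf("groups must be given when cm is a bare matrix")
    groups <- cm$samples$group
  }
  if (length(groups) != ncol(counts))
    .stopf("groups length must match sample count")
  if (max(table(groups)) < 2L)
    .stopf("dispersion estimation needs >= 2 samples in some group")
  if (is.null(factors)) factors <- size_factors(counts)

  excluded <- rownames(counts)[rowSums(counts) == 0]
  keep <- rowSums(counts) > 0
  Y <- counts[keep, , drop = FALSE]

  grid <- apl_grid(Y, factors, groups)
  la_mle <- argmax_refine(grid$LL, grid$lalph)
  a_mle <- pmin(pmax(exp(la_mle), ALPHA_LO), ALPHA_HI)

  a_map <- a_mle
  trend <- c(a0 = NA_real_, a1 = NA_real_)
  prior_var <- NA_real_
  if (moderate && nrow(Y) >= 10L) {
    bm <- grid$basemean
    use <- a_mle > 1e-6 & a_mle < ALPHA_HI * 0.9
    if (sum(use) >= 10L) {
      # iterative trimmed fit of alpha(mu) = a0 + a1/mu
      a0 <- stats::median(a_mle[use]); a1 <- 0
      for (it in 1:5) {
        pred <- pmax(a0 + a1 / bm, 1e-6)
        r <- a_mle / pred
        sel <- use & r > 1e-2 & r < 15
        fit <- tryCatch(stats::lm(a_mle[sel] ~ I(1 / bm[sel]),
                                  weights = 1 / pred[sel]^2),
                        error = function(e) NULL)
        if (is.null(fit)) break
        a0n <- max(stats::coef(fit)[1], 1e-4)
        a1n <- max(stats::coef(fit)[2], 0)
        conv <- abs(a0n - a0) < 1e-6 && abs(a1n - a1) < 1e-6
        a0 <- a0n; a1 <- a1n
        if (conv) break
      }
      trend <- c(a0 = unname(a0), a1 = unname(a1))
      ltrend <- log(pmax(a0 + a1 / bm, 1e-6))
      # expected sampling variance of a log-dispersion estimate
      svar <- trigamma((ncol(Y) - length(unique(groups))) / 2)
      prior_var <- max(mean((la_mle[use] - ltrend[use])^2) - svar, 0.25)
      LLmap <- grid$LL -
        outer(ltrend, grid$lalph, function(m, l) (l - m)^2 / (2 * prior_var))
      a_map <- pmin(pmax(exp(argmax_refine(LLmap, grid$lalph)), ALPHA_LO),
                    ALPHA_HI)
    }
  }

  out <- data.frame(gene_id = rownames(Y), base_mean = grid$basemean,
                    dispersion_mle = a_mle, dispersion = a_map,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("dispersion_fit", "data.frame"),
            excluded = excluded, trend = trend, prior_var = prior_var,
            groups = groups)
}
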