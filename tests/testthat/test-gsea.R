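test_that("rank metric applies the fold-change-over-p rule", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(1, 0, -2, 0.5),
                   pvalue = c(0.01, 1e-9, 0.5, 0.1))
  rl <- rank_metric(de)
  expect_equal(rl$score[rl$gene_id == "a"], 100)
  expect_equal(rl$score[rl$gene_id == "b"], 0)
  expect_equal(rl$score[rl$gene_id == "c"], -4)
  expect_identical(rl$gene_id, c("a", "d", "b", "c"))
  # the floor caps the inverse-p weight
  tiny <- data.frame(gene_id = "a", log2fc = 1, pvalue = 1e-320)
  expect_equal(rank_metric(tiny, p_floor = 1e-300)$score, 1e300)
  # ties break lexicographically so the ordering is reproducible
  tie <- data.frame(gene_id = c("z", "y"), log2fc = c(0, 0),
                    pvalue = c(0.5, 0.5))
  expect_identical(rank_metric(tie)$gene_id, c("y", "z"))
})

test_that("rank metric never lowers |score| for stronger evidence", {
  de <- withr::with_seed(91, data.frame(
    gene_id = sprintf("g%03d", 1:200),
    log2fc = rnorm(200), pvalue = runif(200)))
  rl <- rank_metric(de)
  s <- rl$score[match(de$gene_id, rl$gene_id)]
  de2 <- de
  de2$log2fc <- de$log2fc * 2
  s2 <- rank_metric(de2)$score[match(de$gene_id,
                                     rank_metric(de2)$gene_id)]
  expect_true(all(abs(s2) >= abs(s)))
  de3 <- de
  de3$pvalue <- de$pvalue / 2
  rl3 <- rank_metric(de3)
  s3 <- rl3$score[match(de$gene_id, rl3$gene_id)]
  expect_true(all(abs(s3) >= abs(s)))
  expect_true(all(sign(s3) == sign(s)))
})

test_that("enrichment score matches the worked running-sum example", {
  rl <- ranked_from_scores(c(a = 5, b = 4, c = 3, d = 2, e = 1))
  top <- enrichment_score(rl, c("a", "b"))
  expect_equal(top$running_sum, c(0.5, 1, 2 / 3, 1 / 3, 0))
  expect_equal(top$es, 1)
  expect_setequal(top$leading_edge, c("a", "b"))

  bottom <- enrichment_score(rl, c("d", "e"))
  expect_equal(bottom$es, -1)
  expect_setequal(bottom$leading_edge, c("d", "e"))

  # reversing the list flips the sign
  rev_rl <- ranked_from_scores(c(a = 1, b = 2, c = 3, d = 4, e = 5))
  expect_equal(enrichment_score(rev_rl, c("a", "b"))$es, -top$es)

  expect_error(enrichment_score(rl, "zz"), "no member")
  expect_error(enrichment_score(rl, letters[1:5]), "whole")
})

test_that("incremental ES agrees with brute force and fgsea", {
  has_fgsea <- requireNamespace("fgsea", quietly = TRUE)
  withr::with_seed(92, {
    for (trial in 1:150) {
      N <- sample(10:50, 1)
      ids <- sprintf("g%02d", 1:N)
      scores <- setNames(rnorm(N), ids)
      k <- sample(1:(N - 1), 1)
      set <- sample(ids, k)
      rl <- ranked_from_scores(scores)
      es <- enrichment_score(rl, set)$es
      expect_equal(es, es_oracle(rl$gene_id, set))
      # the positions-formula fast path used for permutations
      expect_equal(es, revasd:::es_from_positions(which(rl$gene_id %in% set),
                                                  N))
      hit <- rl$gene_id %in% set
      rs <- cumsum(ifelse(hit, 1 / k, -1 / (N - k)))
      tied <- abs(max(rs) + min(rs)) < 1e-9
      if (has_fgsea && trial <= 40 && !tied) {
        # fgsea resolves exact positive/negative ties differently;
        # agreement is checked on the (generic) untied instances
        stats <- setNames(rl$score, rl$gene_id)
        expect_equal(es, fgsea::calcGseaStat(stats, which(hit),
                                             gseaParam = 0),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("the permutation null is reproducible and bounded", {
  rl <- ranked_from_scores(setNames(50:1, sprintf("g%02d", 1:50)))
  n1 <- permutation_null(rl, 10, n_perm = 200, seed = 5)
  n2 <- permutation_null(rl, 10, n_perm = 200, seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1, permutation_null(rl, 10, 200, seed = 6)))
  expect_true(all(abs(n1) <= 1))
  # near-full sets: deviation bounded by the single-miss extreme
  nb <- permutation_null(rl, 49, n_perm = 100, seed = 7)
  expect_true(all(abs(nb) <= 1))
  expect_error(permutation_null(rl, 50, 10), "set_size")
})

test_that("NES and nominal p follow the same-sign tail definition", {
  null <- c(0.2, 0.4, -0.3, 0.6, -0.1)
  r <- nes_from_null(0.4, null)
  expect_equal(r$nes, 0.4 / mean(c(0.2, 0.4, 0.6)))
  expect_equal(r$pval, (1 + 2) / (1 + 3))
  expect_equal(nes_from_null(mean(c(0.2, 0.4, 0.6)), null)$nes, 1)
  expect_identical(nes_from_null(0, null), list(nes = 0, pval = 1))
  # ES above every null value with 999 same-sign permutations -> p = 1/1000
  big <- nes_from_null(0.99, seq(0.001, 0.9, length.out = 999))
  expect_equal(big$pval, 1 / 1000)
  # no same-sign null values -> flagged record
  expect_true(is.na(nes_from_null(0.5, c(-0.2, -0.4))$nes))
})

test_that("tail-ratio FDR is clipped, monotone, and self-calibrating", {
  # a single set beyond every null value
  expect_equal(fdr_q(3, c(0.5, 1, -0.7, 2)), 0)
  # observed identical to null: q ~ 1 everywhere
  obs <- c(0.5, 1, 1.5, -0.5, -1, -1.5)
  expect_true(all(fdr_q(obs, rep(obs, 50)) >= 0.99))
  # monotone within each sign stratum
  nes <- withr::with_seed(93, c(runif(20, 0.1, 3), -runif(20, 0.1, 3)))
  null <- withr::with_seed(94, c(rnorm(2000)))
  q <- fdr_q(nes, null)
  for (sgn in c(1, -1)) {
    idx <- which(sign(nes) == sgn)
    ordmag <- idx[order(-abs(nes[idx]))]
    expect_true(all(diff(q[ordmag]) >= -1e-12))
  }
  expect_true(all(q >= 0 & q <= 1))
})

test_that("collection-level GSEA finds planted structure and skips bad sets", {
  ids <- sprintf("g%03d", 1:300)
  scores <- setNames(seq(3, -3, length.out = 300), ids)
  rl <- ranked_from_scores(scores)
  coll <- list(top = ids[1:30],
               shuffled = withr::with_seed(95, sample(ids, 30)),
               tiny = ids[1:5], huge = ids,
               top_copy = ids[1:30])
  res <- gsea_collection(rl, coll, n_perm = 500, min_size = 15,
                         max_size = 250, seed = 3)
  expect_setequal(attr(res, "skipped")$set, c("tiny", "huge"))
  top <- res[res$set == "top", ]
  expect_gt(top$nes, 0)
  expect_lt(top$fdr_q, 0.05)
  # identical membership under two names: identical ES (the null stream is
  # tied to the set name, so NES may differ within permutation noise)
  expect_equal(res$es[res$set == "top_copy"], top$es)
  # reproducible end to end
  res2 <- gsea_collection(rl, coll, n_perm = 500, min_size = 15,
                          max_size = 250, seed = 3)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  expect_warning(gsea_collection(rl, list(tiny = ids[1:3]), n_perm = 10),
                 "skipped")
})
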