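test_that("equal group means give a null Wald statistic", {
  Y <- rbind(g1 = c(7L, 7L, 7L, 7L, 7L, 7L),
             g2 = c(10L, 20L, 30L, 30L, 20L, 10L))
  colnames(Y) <- paste0("s", 1:6)
  cm <- count_matrix(Y, data.frame(sample_id = paste0("s", 1:6),
                                   genotype = rep(c("KO", "WT"), each = 3),
                                   treatment = "Veh"))
  de <- wald_test(cm, factors = NULL, dispersions = NULL, "Veh-K/W")
  expect_equal(de$log2fc, c(0, 0), tolerance = 1e-8)
  expect_equal(de$stat, c(0, 0), tolerance = 1e-6)
  expect_equal(de$pvalue, c(1, 1), tolerance = 1e-6)
})

test_that("genes unobserved in both contrast groups are skipped", {
  Y <- rbind(g1 = c(0L, 0L, 0L, 0L, 0L, 0L, 5L, 6L, 4L, 5L, 6L, 4L),
             g2 = c(9L, 8L, 10L, 9L, 11L, 10L, 9L, 8L, 10L, 9L, 11L, 10L))
  colnames(Y) <- paste0("s", 1:12)
  sheet <- data.frame(sample_id = paste0("s", 1:12),
                      genotype = rep(c("KO", "WT", "KO", "WT"), each = 3),
                      treatment = rep(c("Veh", "Veh", "Mem", "Mem"),
                                      each = 3))
  cm <- count_matrix(Y, sheet)
  de <- wald_test(cm, contrast = "Veh-K/W")
  expect_false("g1" %in% de$gene_id)
  expect_true("g1" %in% attr(de, "skipped"))
  # same gene is testable in the treated contrast
  de2 <- wald_test(cm, contrast = "Mem-K/W")
  expect_true("g1" %in% de2$gene_id)
})

test_that("fold-change estimates recover a known spiked effect", {
  mu <- withr::with_seed(71, exp(rnorm(300, log(100), 1)))
  Y <- two_group_counts(300, 100, mu = mu, alpha = 0.05, lfc = 1,
                        seed = 72)
  sheet <- data.frame(sample_id = colnames(Y),
                      genotype = rep(c("KO", "WT"), each = 100),
                      treatment = "Veh")
  cm <- count_matrix(Y, sheet)
  # unit factors: with every gene spiked, estimated size factors would
  # absorb the shared fold change by design
  de <- wald_test(cm, factors = rep(1, 200), contrast = "Veh-K/W")
  expect_gt(mean(de$log2fc), 0.9)
  expect_lt(mean(de$log2fc), 1.1)
  # essentially every spiked gene is sign-correct at this depth
  expect_gt(mean(de$log2fc > 0), 0.99)
})

test_that("bh_adjust equals the base step-up and validates input", {
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.7), 0.7)
  p <- withr::with_seed(73, runif(50)^2)
  expect_equal(bh_adjust(p), bh_oracle(p))
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DEG calling applies the adjusted-p rule only", {
  de <- structure(data.frame(
    gene_id = paste0("g", 1:5),
    log2fc = c(2, -3, 0.1, 4, -0.2),
    padj = c(0.01, 0.2, 0.03, 0.9, 0.04)),
    class = c("de_result", "data.frame"), contrast = "toy")
  dg <- call_degs(de)
  expect_equal(dg$n_deg, 3)
  expect_equal(dg$n_up, 2)
  expect_equal(dg$n_down, 1)
  expect_setequal(dg$table$gene_id, c("g1", "g3", "g5"))

  # threshold is strict: 0.049 in, 0.051 out; magnitude is irrelevant
  de2 <- de
  de2$padj <- c(0.049, 0.051, 0.5, 0.5, 0.5)
  de2$log2fc <- c(0.01, 8, 0, 0, 0)
  dg2 <- call_degs(de2)
  expect_identical(dg2$table$gene_id, "g1")

  empty <- de[0, ]
  expect_equal(call_degs(empty)$n_deg, 0)
})

test_that("DEG overlap reports shared counts and sign concordance", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"), log2fc = c(1, -2, 3))
  b <- data.frame(gene_id = c("g1", "g2", "g4"), log2fc = c(2, -1, 5))
  ov <- deg_overlap(a, b)
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$n_only_a, 1)
  expect_equal(ov$n_only_b, 1)
  expect_equal(ov$concordance_pct, 100)

  flip <- deg_overlap(data.frame(gene_id = "g1", log2fc = 1),
                      data.frame(gene_id = "g1", log2fc = -1))
  expect_equal(flip$concordance_pct, 0)

  disjoint <- deg_overlap(a, data.frame(gene_id = "g9", log2fc = 1))
  expect_equal(disjoint$n_shared, 0)
  expect_true(is.na(disjoint$concordance))

  # symmetric in the shared count
  expect_equal(deg_overlap(b, a)$n_shared, ov$n_shared)
})

test_that("PCA projection orders components and respects duplicates", {
  st <- make_study(200, seed = 81)
  cm <- st$counts
  cm$counts[, 2] <- cm$counts[, 1]  # duplicate a sample
  pc <- pca_projection(cm)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_equal(sum(pc$explained), 1, tolerance = 1e-8)
  expect_equal(unlist(pc$coordinates[1, -(1:2)]),
               unlist(pc$coordinates[2, -(1:2)]), tolerance = 1e-8)

  # two identical samples and one distinct: PC1 isolates the outlier
  Y <- cbind(a = c(10L, 50L, 200L), b = c(10L, 50L, 200L),
             c = c(200L, 50L, 10L))
  rownames(Y) <- paste0("g", 1:3)
  cm3 <- count_matrix(Y, data.frame(sample_id = c("a", "b", "c"),
                                    genotype = c("WT", "WT", "KO"),
                                    treatment = "Veh"))
  pc3 <- pca_projection(cm3)
  x <- pc3$coordinates$PC1
  expect_equal(x[1], x[2], tolerance = 1e-8)
  expect_gt(abs(x[3] - x[1]), 1)
})
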