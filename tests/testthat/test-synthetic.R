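test_that("parameter sampling is deterministic and honours the profile", {
  a <- sample_gene_params(500, "study-like", seed = 3)
  b <- sample_gene_params(500, "study-like", seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, sample_gene_params(500, "study-like", seed = 4)))

  nullp <- sample_gene_params(1000, "null", seed = 1)
  expect_true(all(nullp$log2fc_genotype == 0))
  expect_true(all(nullp$log2fc_treatment_wt == 0))
  expect_true(all(nullp$log2fc_treatment_ko == 0))

  expect_true(all(a$mu_base > 0))
  expect_true(all(a$dispersion >= 0.01 & a$dispersion <= 0.5))

  # spiked genotype fraction within 3 binomial SDs of the profile value
  p <- sample_gene_params(10000, "study-like", seed = 7)
  frac <- mean(p$log2fc_genotype != 0)
  band <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_gt(frac, 0.05 - band)
  expect_lt(frac, 0.05 + band)
  spiked <- abs(p$log2fc_genotype[p$log2fc_genotype != 0])
  expect_true(all(spiked >= 0.5 & spiked <= 2))
  spiked_t <- abs(p$log2fc_treatment_wt[p$log2fc_treatment_wt != 0])
  expect_true(all(spiked_t >= 1 & spiked_t <= 2))

  expect_error(sample_gene_params(0), "positive")
  expect_error(sample_gene_params(10, "no-such-profile"), "profile")
})

test_that("simulated counts follow the NB mean-variance law", {
  # alpha = 0.1 at mu = 100: variance mu + alpha mu^2 = 1100
  params <- data.frame(gene_id = sprintf("g%03d", 1:500), mu_base = 100,
                       dispersion = 0.1, log2fc_genotype = 0,
                       log2fc_treatment_wt = 0, log2fc_treatment_ko = 0)
  sim <- simulate_counts(params, study_design(50), seed = 2)
  y <- sim$counts$counts
  expect_true(all(y >= 0))
  expect_identical(storage.mode(y), "integer")
  vars <- apply(y, 1, var)
  expect_gt(mean(vars), 1050)
  expect_lt(mean(vars), 1150)

  # Poisson limit: dispersion 0 gives variance ~ mean
  params$dispersion <- 0
  sim0 <- simulate_counts(params[1:300, ], study_design(25), seed = 3)
  ratio <- apply(sim0$counts$counts, 1, var) /
    rowMeans(sim0$counts$counts)
  expect_gt(mean(ratio), 0.9)
  expect_lt(mean(ratio), 1.1)
})

test_that("group means track size factors and active effects", {
  params <- data.frame(gene_id = c("up", "flat"), mu_base = c(200, 200),
                       dispersion = c(0.01, 0.01),
                       log2fc_genotype = c(1, 0),
                       log2fc_treatment_wt = 0, log2fc_treatment_ko = 0)
  design <- study_design(200, library_size_factors = rep(c(1, 2), 400))
  sim <- simulate_counts(params, design, seed = 9)
  yn <- sweep(sim$counts$counts, 2, design$library_size_factors, "/")
  ko <- sim$counts$samples$genotype == "KO"
  expect_equal(mean(yn["up", ko]), 400, tolerance = 0.05)
  expect_equal(mean(yn["up", !ko]), 200, tolerance = 0.05)
  expect_equal(mean(yn["flat", ]), 200, tolerance = 0.05)
})

test_that("truth table is consistent with the generator parameters", {
  st <- make_study(300, seed = 21)
  tt <- truth_table(st$params)
  expect_identical(st$truth, tt)
  expect_true(all((tt$sign == 0) == (!tt$is_de)))
  expect_setequal(unique(tt$contrast), names(study_contrasts()))
  # the genotype contrast truth equals the genotype effect
  veh <- tt[tt$contrast == "Veh-K/W", ]
  expect_equal(veh$true_log2fc[match(st$params$gene_id, veh$gene_id)],
               st$params$log2fc_genotype)
  # the treated genotype contrast combines all three effects
  mem <- tt[tt$contrast == "Mem-K/W", ]
  expect_equal(mem$true_log2fc[match(st$params$gene_id, mem$gene_id)],
               st$params$log2fc_genotype + st$params$log2fc_treatment_ko -
                 st$params$log2fc_treatment_wt)

  sim2 <- simulate_counts(st$params, st$design, seed = 23)
  sim3 <- simulate_counts(st$params, st$design, seed = 23)
  expect_identical(sim2$counts$counts, sim3$counts$counts)
})

test_that("directional panels realize the requested pattern", {
  st <- make_study(2000, seed = 31)
  pan <- make_directional_panels(st$truth, set_size = 30, dilution = 0,
                                 seed = 5)
  expect_length(pan$sets, 10)
  expect_s3_class(pan$panel, "panel_spec")
  tt <- st$truth[st$truth$contrast == "Veh-K/W", ]
  sgn <- tt$sign[match(unlist(pan$sets), tt$gene_id)]
  dir <- rep(pan$panel$expected_direction, lengths(pan$sets))
  # reverse construction, no dilution: up_in_ASD members are truly down
  expect_true(all(sgn[dir == "up_in_ASD"] < 0))
  expect_true(all(sgn[dir == "down_in_ASD"] > 0))

  # swapped labels reverse the membership signs
  like <- make_directional_panels(st$truth, set_size = 30, dilution = 0,
                                  pattern = "like", seed = 5)
  sgn_l <- tt$sign[match(unlist(like$sets), tt$gene_id)]
  expect_true(all(sgn_l[dir == "up_in_ASD"] > 0))

  # diluted panels keep the stated core fraction
  dil <- make_directional_panels(st$truth, set_size = 40, dilution = 0.3,
                                 seed = 5)
  sgn_d <- tt$sign[match(dil$sets$DEG_Up_synthetic, tt$gene_id)]
  expect_equal(sum(sgn_d < 0), 28)
  expect_equal(sum(sgn_d == 0), 12)

  expect_error(
    make_directional_panels(truth_table(sample_gene_params(100, "null")),
                            set_size = 40),
    "insufficient")
})

test_that("a synthetic study round-trips through the plain-text interface", {
  st <- make_study(120, seed = 41)
  dir <- withr::local_tempdir()
  write_synthetic_study(list(counts = st$counts, truth = st$truth),
                        dir = dir)
  back <- read_count_matrix(file.path(dir, "counts.tsv"),
                            file.path(dir, "samples.tsv"))
  expect_equal(back$counts, st$counts$counts)
  expect_equal(back$samples$group, st$counts$samples$group)
})
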