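test_that("genotype simulation respects allele frequencies and determinism", {
  cfg <- sim_config(n_samples = 10000, n_regulators = 1,
                    targets_per_regulator = c(2, 2), n_passenger_genes = 0,
                    n_null_variants = 0, maf_range = c(0.5, 0.5),
                    ld_block_size = 1, n_eqtl = 0, n_aqtl_cis = 0,
                    n_aqtl_trans = 0, n_true_mrs = 0)
  g <- simulate_genotypes(cfg, seed = 3)
  expect_true(all(g$dosages %in% 0:2))
  expect_equal(mean(g$dosages[1, ]), 1.0, tolerance = 0.05)
  g2 <- simulate_genotypes(cfg, seed = 3)
  expect_identical(g$dosages, g2$dosages)
  expect_error(sim_config(n_samples = 1))
})

test_that("zero LD gives uncorrelated variants; positive LD gives correlated blocks", {
  cfg0 <- sim_config(n_samples = 1000, n_regulators = 2,
                     targets_per_regulator = c(2, 2), n_passenger_genes = 0,
                     n_null_variants = 0, ld_block_size = 5, rho_ld = 0,
                     n_eqtl = 0, n_aqtl_cis = 0, n_aqtl_trans = 0,
                     n_true_mrs = 0)
  g0 <- simulate_genotypes(cfg0, seed = 4)
  cc <- cor(t(g0$dosages[1:5, ]))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.1)

  cfg1 <- sim_config(n_samples = 1000, n_regulators = 2,
                     targets_per_regulator = c(2, 2), n_passenger_genes = 0,
                     n_null_variants = 0, ld_block_size = 5, rho_ld = 0.9,
                     n_eqtl = 0, n_aqtl_cis = 0, n_aqtl_trans = 0,
                     n_true_mrs = 0)
  g1 <- simulate_genotypes(cfg1, seed = 4)
  cc1 <- cor(t(g1$dosages[1:5, ]))
  expect_gt(mean(cc1[cbind(1:4, 2:5)]), 0.5)  # adjacent-variant r
  expect_gt(min(g1$maf), 0)
})

test_that("null configuration leaves expression independent of genotype", {
  cfg <- sim_config(n_samples = 500, n_regulators = 4,
                    targets_per_regulator = c(5, 5), n_passenger_genes = 0,
                    n_null_variants = 0, n_eqtl = 0, n_aqtl_cis = 0,
                    n_aqtl_trans = 0, n_true_mrs = 2)
  g <- simulate_genotypes(cfg, seed = 6)
  sim <- simulate_truth_and_expression(g, cfg, seed = 7)
  lay <- attr(g, "layout")
  pvals <- vapply(1:4, function(r) {
    gv <- g$dosages[lay$cis_variant[r], ]
    cor.test(gv, sim$expression$values[lay$reg_ids[r], ])$p.value
  }, numeric(1))
  expect_gt(min(pvals) * 4, 0.001)   # Bonferroni-consistent with the null
})

test_that("activity-only channel moves targets without moving the transcript", {
  cfg <- sim_config(n_samples = 500, n_regulators = 1,
                    targets_per_regulator = c(50, 50), n_passenger_genes = 0,
                    n_null_variants = 0, n_eqtl = 0, n_aqtl_cis = 1,
                    n_aqtl_trans = 0, n_true_mrs = 1, beta_aqtl = 0.8,
                    mode_magnitude = c(1, 1))
  g <- simulate_genotypes(cfg, seed = 8)
  sim <- simulate_truth_and_expression(g, cfg, seed = 9)
  v <- sim$truth$effects$variant_id[1]
  gv <- g$dosages[v, ]
  # transcript-genotype correlation at null level
  expect_gt(cor.test(gv, sim$expression$values["R001", ])$p.value, 0.001)
  # signed target-genotype correlations propagate through the activity
  net <- sim$truth$network
  tc <- vapply(seq_len(nrow(net)), function(i)
    cor(gv, sim$expression$values[net$target[i], ]) * sign(net$mode[i]),
    numeric(1))
  expect_gt(mean(tc), 0.1)
})

test_that("target variance matches the closed-form decomposition", {
  cfg <- sim_config(n_samples = 2000, n_regulators = 2,
                    targets_per_regulator = c(20, 20), n_passenger_genes = 0,
                    n_null_variants = 0, n_eqtl = 0, n_aqtl_cis = 0,
                    n_aqtl_trans = 0, n_true_mrs = 1, sd_target_noise = 0.5)
  g <- simulate_genotypes(cfg, seed = 10)
  sim <- simulate_truth_and_expression(g, cfg, seed = 11)
  net <- sim$truth$network
  v_theory <- (net$mode * net$likelihood)^2 + cfg$sd_target_noise^2
  v_emp <- apply(sim$expression$values[net$target, ], 1, var)
  expect_equal(unname(v_emp), v_theory, tolerance = 0.1)
})

test_that("phenotype heritability is realized and generation is deterministic", {
  cfg <- sim_config(n_samples = 2000, n_regulators = 6,
                    targets_per_regulator = c(5, 5), n_passenger_genes = 0,
                    n_null_variants = 0, n_eqtl = 2, n_aqtl_cis = 1,
                    n_aqtl_trans = 1, n_true_mrs = 4, mr_h2 = 0.5)
  g <- simulate_genotypes(cfg, seed = 12)
  sim <- simulate_truth_and_expression(g, cfg, seed = 13)
  ph <- simulate_phenotypes(sim$truth, cfg, seed = 14)
  S <- as.numeric(crossprod(sim$truth$activities[sim$truth$mr_set, ],
                            sim$truth$mr_weights))
  r2 <- summary(lm(ph$BMI ~ S))$r.squared
  expect_gt(r2, 0.42); expect_lt(r2, 0.58)
  ph2 <- simulate_phenotypes(sim$truth, cfg, seed = 14)
  expect_identical(ph, ph2)
  # vanishing noise: phenotype converges to the MR signal
  cfg2 <- cfg; cfg2$mr_h2 <- 0.999
  ph3 <- simulate_phenotypes(sim$truth, cfg2, seed = 15)
  expect_gt(cor(ph3$BMI, S), 0.99)
})

test_that("GWAS summary statistics are calibrated under the null and match OLS", {
  cfg <- sim_config(n_samples = 300, n_regulators = 4,
                    targets_per_regulator = c(3, 3), n_passenger_genes = 0,
                    n_null_variants = 200, ld_block_size = 1,
                    n_eqtl = 0, n_aqtl_cis = 0, n_aqtl_trans = 0,
                    n_true_mrs = 0)
  g <- simulate_genotypes(cfg, seed = 16)
  set.seed(17)
  ph <- data.frame(sample_id = colnames(g$dosages),
                   BMI = rnorm(300), age = 50)
  gw <- simulate_gwas_summary(g, ph)
  expect_gt(ks.test(gw$p, "punif")$p.value, 0.01)
  # monotone |z| <-> p
  ord <- order(abs(gw$beta / gw$se))
  expect_true(all(diff(gw$p[ord]) <= 1e-12))
  # single-variant closed-form OLS
  i <- 5
  sm <- summary(lm(ph$BMI ~ g$dosages[i, ]))$coefficients
  expect_equal(gw$beta[i], sm[2, 1], tolerance = 1e-10)
  expect_equal(gw$se[i], sm[2, 2], tolerance = 1e-10)
  expect_equal(gw$p[i], sm[2, 4], tolerance = 1e-10)
})

test_that("fixture directory is complete, re-readable and regenerable", {
  skip_if_not_installed("vcfR")
  dir <- tempfile("fx")
  cfg <- sim_config(n_samples = 40, n_regulators = 3,
                    targets_per_regulator = c(4, 6), n_passenger_genes = 5,
                    n_null_variants = 5, n_eqtl = 1, n_aqtl_cis = 1,
                    n_aqtl_trans = 0, n_true_mrs = 2, rng_seed = 18)
  fx <- write_fixture(dir, cfg)
  expect_true(all(file.exists(unlist(fx$files))))
  ex <- read_matrix_tsv(fx$files$expression)
  expect_equal(ex, fx$expression$values, tolerance = 1e-8)
  regs <- read_regulator_list(fx$files$regulators)
  expect_identical(regs, rownames(fx$truth$activities))
  cj <- jsonlite::read_json(fx$files$config)
  expect_identical(cj$schema_version, "1.0")
  expect_equal(cj$config$n_samples, 40)
  # exact regeneration from the recorded seed
  fx2 <- write_fixture(tempfile("fx2"), cfg, seed = cj$seed)
  expect_identical(fx2$genotypes$dosages, fx$genotypes$dosages)
  expect_equal(fx2$expression$values, fx$expression$values)
})
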