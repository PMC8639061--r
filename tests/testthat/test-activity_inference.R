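test_that("interactome modes and likelihoods match per-pair recomputation", {
  set.seed(1)
  n <- 60
  r <- rnorm(n)
  t1 <- 0.9 * r + 0.3 * rnorm(n)
  t2 <- -r            # perfectly anti-correlated
  t3 <- rnorm(n)
  vals <- rbind(R = r, T1 = t1, T2 = t2, T3 = t3)
  colnames(vals) <- sprintf("s%02d", 1:n)
  e <- expression_matrix(vals, "log2tpm")
  ed <- data.frame(regulator = "R", target = c("T1", "T2", "T3"),
                   mi = c(0.5, 0.8, 0.1))
  inter <- network_to_interactome(ed, e)
  reg <- inter$R
  expect_equal(reg$mode[reg$target == "T2"], -1)
  expect_equal(reg$likelihood[reg$target == "T2"], 1)   # top-MI target
  for (i in seq_len(nrow(reg))) {
    expect_equal(reg$mode[i],
                 cor(r, vals[reg$target[i], ], method = "spearman"))
    expect_equal(reg$likelihood[i], ed$mi[match(reg$target[i], ed$target)] / 0.8)
  }
  # targets absent from expression are dropped
  ed2 <- rbind(ed, data.frame(regulator = "R", target = "MISSING", mi = 0.9))
  inter2 <- suppressMessages(network_to_interactome(ed2, e))
  expect_setequal(inter2$R$target, c("T1", "T2", "T3"))
})

test_that("z-scaling gives per-gene mean 0 / sd 1 with n-1 denominator", {
  e <- make_expr(matrix(c(1, 2, 3), 1, 3), unit = "log2tpm")
  z <- zscale(e)
  expect_equal(unname(z$values[1, ]), (c(1, 2, 3) - 2) / sd(c(1, 2, 3)))
  e2 <- random_expr(10, 20, seed = 2)
  z2 <- zscale(e2)
  expect_equal(unname(rowMeans(z2$values)), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(z2$values, 1, sd)), rep(1, 10), tolerance = 1e-10)
  manual <- (e2$values - rowMeans(e2$values)) / apply(e2$values, 1, sd)
  expect_equal(z2$values, manual)
  e3 <- make_expr(rbind(rep(5, 4), 1:4), unit = "log2tpm")
  expect_warning(z3 <- zscale(e3), "constant")
  expect_equal(unname(z3$values[1, ]), rep(0, 4))
})

test_that("the 25-expressed-target rule is an exact boundary", {
  z <- random_expr(300, 30, seed = 3, unit = "zscore")
  regs <- random_regulons(rownames(z$values), c(24, 25), seed = 4)
  act <- activity_scores(z, regs, min_targets = 25)
  expect_false("REG01" %in% rownames(act))
  expect_true("REG02" %in% rownames(act))
  # a target missing from expression is dropped before the count
  regs2 <- random_regulons(rownames(z$values), c(25, 30), seed = 5)
  regs2$REG01$target[1] <- "NOT_A_GENE"
  act2 <- activity_scores(z, regs2, min_targets = 25)
  expect_false("REG01" %in% rownames(act2))
  expect_true("REG02" %in% rownames(act2))
  expect_error(activity_scores(z, structure(list(), class = "interactome")),
               "empty regulon")
})

test_that("NES is antisymmetric in modes and invariant to likelihood scale", {
  z <- random_expr(400, 50, seed = 5, unit = "zscore")
  regs <- random_regulons(rownames(z$values), c(40), seed = 6)
  a1 <- activity_scores(z, regs, min_targets = 25)
  flip <- regs
  flip$REG01$mode <- -flip$REG01$mode
  a2 <- activity_scores(z, flip, min_targets = 25)
  expect_equal(unclass(a2), -unclass(a1))
  half <- regs
  half$REG01$likelihood <- regs$REG01$likelihood / 2
  a3 <- activity_scores(z, half, min_targets = 25)
  expect_equal(unclass(a3), unclass(a1))
})

test_that("NES is null-calibrated: mean ~0, sd ~1 per regulator", {
  z <- random_expr(2000, 1000, seed = 7, unit = "zscore")
  regs <- random_regulons(rownames(z$values), c(25, 50, 100, 200), seed = 8)
  act <- activity_scores(z, regs, min_targets = 25)
  mu <- rowMeans(act)
  sds <- apply(act, 1, sd)
  expect_true(all(mu > -0.05 & mu < 0.05))
  expect_true(all(sds > 0.9 & sds < 1.1))
})

test_that("NES is invariant under monotone per-sample transforms", {
  z <- random_expr(200, 20, seed = 9, unit = "zscore")
  regs <- random_regulons(rownames(z$values), c(30), seed = 10)
  a1 <- activity_scores(z, regs, min_targets = 25)
  warped <- expression_matrix(exp(z$values / 2), "zscore")
  a2 <- activity_scores(warped, regs, min_targets = 25)
  expect_equal(unclass(a1), unclass(a2))
})

test_that("activities recover the planted truth on strong regulons", {
  cfg <- sim_config(n_samples = 500, n_regulators = 5,
                    targets_per_regulator = c(50, 60),
                    n_passenger_genes = 100, n_eqtl = 0, n_aqtl_cis = 0,
                    n_aqtl_trans = 0, n_true_mrs = 1,
                    mode_magnitude = c(0.5, 1), rng_seed = 2)
  g <- simulate_genotypes(cfg)
  sim <- simulate_truth_and_expression(g, cfg)
  inter <- network_to_interactome(truth_edges(sim$truth), sim$expression)
  act <- infer_activities(sim$expression, inter, min_targets = 25)
  for (r in rownames(act))
    expect_gte(cor(act[r, ], sim$truth$activities[r, ]), 0.7)
})

test_that("pleiotropy correction is identity for disjoint regulons or alpha=1", {
  z <- random_expr(300, 40, seed = 11, unit = "zscore")
  regs <- random_regulons(rownames(z$values)[1:100], c(30), seed = 12)
  regs$REG02 <- data.frame(target = rownames(z$values)[101:130],
                           mode = 1, likelihood = 1)
  class(regs) <- "interactome"
  act <- activity_scores(z, regs, min_targets = 25)
  corrected <- pleiotropy_correction(act, regs, z, min_common = 25)
  expect_equal(corrected, act)
  expect_error(pleiotropy_correction(act, regs, z, alpha = 1.5), "alpha")

  # nested regulons: alpha = 1 identity; alpha < 1 shrinks the weaker one
  regs2 <- list(
    A = data.frame(target = rownames(z$values)[1:60], mode = 1, likelihood = 1),
    B = data.frame(target = rownames(z$values)[1:30], mode = 1, likelihood = 1))
  class(regs2) <- "interactome"
  act2 <- activity_scores(z, regs2, min_targets = 25)
  same <- pleiotropy_correction(act2, regs2, z, min_common = 25, alpha = 1)
  expect_equal(same, act2)
  corr2 <- pleiotropy_correction(act2, regs2, z, min_common = 25, alpha = 0.5)
  dominated <- abs(act2["A", ]) > abs(act2["B", ])
  # B's shared-target contribution is removed where A is stronger; B is a
  # strict subset of A, so its unique-target score is 0 and |NES_B| halves
  expect_true(all(abs(corr2["B", dominated]) <=
                    abs(act2["B", dominated]) + 1e-12))
  expect_equal(corr2["B", dominated], act2["B", dominated] / 2)
  # A is untouched on samples where it dominates
  expect_equal(corr2["A", dominated], act2["A", dominated])
})

test_that("regulon TSV round-trips through the interactome container", {
  regs <- random_regulons(sprintf("g%03d", 1:50), c(5, 6), seed = 13)
  path <- tempfile(fileext = ".tsv")
  write_regulon_tsv(regs, path)
  back <- read_regulon_tsv(path)
  for (r in names(regs)) {
    a <- regs[[r]][order(regs[[r]]$target), ]
    b <- back[[r]][order(back[[r]]$target), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})
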