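test_that("genotype PCs are orthonormal with a fixed sign convention", {
  cfg <- sim_config(n_samples = 100, n_regulators = 4,
                    targets_per_regulator = c(2, 2), n_passenger_genes = 0,
                    n_null_variants = 20, n_eqtl = 0, n_aqtl_cis = 0,
                    n_aqtl_trans = 0, n_true_mrs = 0, rng_seed = 1)
  g <- simulate_genotypes(cfg)
  pcs <- genotype_pcs(g, n_pcs = 5)
  expect_identical(dim(pcs), c(100L, 5L))
  cp <- crossprod(pcs)
  expect_true(all(abs(cp[upper.tri(cp)]) < 1e-8))
  # variance explained matches the eigenvalues of the correlation matrix
  Gs <- scale(t(g$dosages))
  ev <- eigen(crossprod(Gs) / (nrow(Gs) - 1), symmetric = TRUE)$values
  expect_equal(unname(apply(pcs, 2, var)), ev[1:5], tolerance = 1e-8)
})

test_that("GWAS variant selection is an exact p-value filter", {
  gw <- data.frame(variant_id = paste0("v", 1:5), chr = "1", pos = 1:5,
                   beta = 0, se = 1, p = c(1e-9, 5e-8, 6e-8, 0.5, 1))
  sel <- select_gwas_variants(gw, 5e-8)
  expect_identical(sel$variant_id, c("v1", "v2"))
  expect_identical(nrow(select_gwas_variants(gw, cutoff = 1)), 5L)
  expect_identical(nrow(select_gwas_variants(transform(gw, p = 1), 5e-8)), 0L)
})

test_that("cis window is 1-based inclusive; trans excludes cis pairs", {
  variants <- data.frame(variant_id = c("v1", "v2", "v3"),
                         chr = c("1", "1", "2"),
                         pos = c(2e6, 2e6 + 1e6, 5e5))
  genes <- data.frame(gene_id = c("gA", "gB"), chr = c("1", "2"),
                      tss = c(1e6, 5e6))
  cp <- cis_pairs(variants, genes, window = 1e6)
  # v1 at distance 1e6 exactly -> included; v2 at 2e6 -> excluded;
  # v3 on another chromosome than gA, 4.5e6 from gB -> excluded
  expect_identical(paste(cp$variant_id, cp$gene_id), "v1 gA")
  tp <- trans_pairs(variants, genes, window = 1e6)
  expect_identical(nrow(tp), 5L)
  expect_false("v1 gA" %in% paste(tp$variant_id, tp$gene_id))
  # brute-force distance scan on a random fixture
  set.seed(2)
  v2 <- data.frame(variant_id = paste0("x", 1:50),
                   chr = sample(c("1", "2"), 50, TRUE),
                   pos = sample.int(4e6, 50))
  g2 <- data.frame(gene_id = paste0("y", 1:10),
                   chr = sample(c("1", "2"), 10, TRUE),
                   tss = sample.int(4e6, 10))
  got <- cis_pairs(v2, g2, window = 7e5)
  brute <- subset(merge(v2, g2), chr == chr & abs(pos - tss) <= 7e5)
  expect_identical(nrow(got), nrow(brute))
})

test_that("fit_qtl equals closed-form OLS and handles edge cases", {
  set.seed(3)
  n <- 6
  g <- c(0, 1, 2, 0, 1, 2)
  cov <- cbind(age = c(41, 52, 38, 47, 55, 60))
  y <- 0.7 * g + 0.01 * cov[, 1] + rnorm(n, sd = 0.2)
  f <- fit_qtl(g, y, cov)
  sm <- summary(lm(y ~ g + cov))$coefficients
  expect_equal(f$beta, sm[2, 1], tolerance = 1e-10)
  expect_equal(f$se, sm[2, 2], tolerance = 1e-10)
  expect_equal(f$t, sm[2, 3], tolerance = 1e-10)
  expect_equal(f$p, sm[2, 4], tolerance = 1e-10)
  # exact linear trait: beta recovered, p underflows toward zero
  f2 <- fit_qtl(g, 2 * g + c(1e-8, 0, -1e-8, 0, 0, 0))
  expect_equal(f2$beta, 2, tolerance = 1e-6)
  expect_lt(f2$p, 1e-10)
  expect_message(f3 <- fit_qtl(rep(1, n), y), "constant")
  expect_identical(f3$p, 1)
  # missing data dropped pairwise
  y_na <- y; y_na[2] <- NA
  f4 <- fit_qtl(g, y_na, cov)
  expect_identical(f4$n, 5L + 0L)
})

test_that("fit_qtl p-values are uniform under the null", {
  set.seed(4)
  n <- 200
  p <- vapply(1:1000, function(i)
    fit_qtl(rbinom(n, 2, 0.3), rnorm(n))$p, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("qtl_scan matches fit_qtl pair by pair", {
  cfg <- sim_config(n_samples = 80, n_regulators = 3,
                    targets_per_regulator = c(2, 2), n_passenger_genes = 0,
                    n_null_variants = 5, n_eqtl = 1, n_aqtl_cis = 1,
                    n_aqtl_trans = 0, n_true_mrs = 1, rng_seed = 5)
  g <- simulate_genotypes(cfg)
  sim <- simulate_truth_and_expression(g, cfg)
  traits <- sim$expression$values[c("R001", "R002"), ]
  set.seed(6)
  cov <- cbind(age = runif(80, 30, 70), pc1 = rnorm(80))
  rownames(cov) <- colnames(traits)
  pairs <- expand.grid(variant_id = rownames(g$dosages)[1:6],
                       gene_id = c("R001", "R002"),
                       stringsAsFactors = FALSE)
  scan <- qtl_scan(g, traits, pairs, cov)
  for (i in seq_len(nrow(scan))) {
    f <- fit_qtl(g$dosages[scan$variant_id[i], ], traits[scan$gene_id[i], ],
                 cov)
    expect_equal(scan$beta[i], f$beta, tolerance = 1e-10)
    expect_equal(scan$se[i], f$se, tolerance = 1e-10)
    expect_equal(scan$p[i], f$p, tolerance = 1e-10)
  }
})

test_that("gene-wise min-p uses positional tie-breaking", {
  a <- data.frame(variant_id = c("v1", "v2"), p = c(0.3, 0.01), pos = c(5, 9))
  expect_identical(genewise_minp(a)$lead_variant, "v2")
  expect_identical(genewise_minp(a)$min_p, 0.01)
  ties <- data.frame(variant_id = c("v1", "v2"), p = c(0.01, 0.01),
                     pos = c(9, 5))
  expect_identical(genewise_minp(ties)$lead_variant, "v2")
  one <- data.frame(variant_id = "v9", p = 0.42, pos = 1)
  expect_identical(genewise_minp(one)$min_p, 0.42)
})

test_that("empirical gene-wise p: floor, single-variant identity, Sidak", {
  set.seed(7)
  n <- 400
  # floor: an overwhelming association beats every permutation
  g1 <- matrix(rbinom(n, 2, 0.4), ncol = 1, dimnames = list(NULL, "v1"))
  y_strong <- g1[, 1] + rnorm(n, sd = 0.1)
  e <- empirical_genewise_p(g1, y_strong, n_sim = 500, seed = 8)
  expect_equal(e$q, 1 / 501)
  expect_error(empirical_genewise_p(g1, y_strong, n_sim = 50), "n_sim")
  # single variant, null trait: q ~ p
  y0 <- rnorm(n)
  e0 <- empirical_genewise_p(g1, y0, n_sim = 2000, seed = 9)
  expect_lt(abs(e0$q - e0$min_p), 0.05)
  # 10 perfectly correlated variants: effective tests = 1
  g10 <- matrix(rep(g1, 10), ncol = 10,
                dimnames = list(NULL, paste0("d", 1:10)))
  eld <- empirical_genewise_p(g10, y0, n_sim = 2000, seed = 10)
  expect_lt(abs(eld$q - eld$min_p), 0.05)
  # 10 independent variants: q ~ Sidak 1-(1-p)^10
  gi <- matrix(rbinom(n * 10, 2, 0.4), ncol = 10,
               dimnames = list(NULL, paste0("i", 1:10)))
  ei <- empirical_genewise_p(gi, y0, n_sim = 4000, seed = 11)
  sidak <- 1 - (1 - ei$min_p)^10
  expect_lt(abs(ei$q - sidak), 0.08)
})

test_that("joint permutation preserves the block LD structure exactly", {
  set.seed(12)
  G <- matrix(rbinom(600, 2, 0.3), 200, 3)
  G[, 2] <- pmin(2, G[, 1] + rbinom(200, 1, 0.1))
  perm <- sample.int(200)
  expect_identical(cor(G[perm, ]), cor(G))
})

test_that("BH adjustment matches brute-force step-up enumeration", {
  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(13)
  for (i in 1:25) {
    p <- runif(40)^sample(c(1, 3), 1)
    expect_equal(bh_fdr(p)$adjusted, brute_bh(p))
  }
  res <- bh_fdr(rep(0.001, 10))
  expect_true(all(res$significant))
  expect_true(bh_fdr(0.04)$significant)
})

test_that("trans threshold inverts the null CDF at the passing boundary", {
  gw <- data.frame(gene_id = c("g1", "g2"), q = c(0.001, 0.9),
                   significant = c(TRUE, FALSE))
  null_minp <- seq(0.001, 1, length.out = 1000)
  thr <- trans_threshold(null_minp, gw)
  # brute-force inversion: the largest null value whose ecdf <= q*
  expect_equal(thr, sort(null_minp)[floor(0.001 * 1000)])
  gw_none <- transform(gw, significant = FALSE)
  thr2 <- trans_threshold(null_minp, gw_none)
  expect_true(is.nan(thr2))
  expect_true(attr(thr2, "no_gene_passes"))
  gw_all <- transform(gw, significant = TRUE)
  expect_equal(trans_threshold(null_minp, gw_all),
               sort(null_minp)[floor(0.9 * 1000)])
})

test_that("QTL strength comparison reproduces the pooled two-proportion z-test", {
  mk <- function(n, frac_stronger, mode) {
    data.frame(variant_id = paste0(mode, seq_len(n)), gene_id = "g",
               p_e = 0.5,
               p_a = c(rep(0.1, round(frac_stronger * n)),
                       rep(0.9, n - round(frac_stronger * n))),
               mode = mode)
  }
  d <- rbind(mk(100, 0.2, "cis"), mk(100, 0.72, "trans"))
  eq <- data.frame(variant_id = d$variant_id, gene_id = d$gene_id,
                   p = d$p_e, mode = d$mode)
  aq <- data.frame(variant_id = d$variant_id, gene_id = d$gene_id,
                   p = d$p_a, mode = d$mode)
  res <- compare_qtl_strength(eq, aq)
  expect_equal(unname(res$prop[["cis"]]), 0.2)
  expect_equal(unname(res$prop[["trans"]]), 0.72)
  pbar <- (20 + 72) / 200
  z_hand <- (0.2 - 0.72) / sqrt(pbar * (1 - pbar) * (1 / 100 + 1 / 100))
  expect_equal(res$z, z_hand)
  # identical p-vectors: strict comparison gives proportion 0
  res0 <- compare_qtl_strength(eq, transform(aq, p = eq$p))
  expect_true(all(res0$prop == 0))
  # swapping the inputs flips the z sign
  res_sw <- compare_qtl_strength(aq, eq)
  expect_equal(res_sw$z, -z_hand)
})

test_that("gene-wise q-values are calibrated on a null fixture", {
  set.seed(14)
  n <- 300; n_genes <- 60
  dos <- matrix(rbinom(n * 10 * n_genes, 2, 0.3), nrow = 10 * n_genes)
  rownames(dos) <- sprintf("v%04d", seq_len(nrow(dos)))
  colnames(dos) <- sprintf("s%03d", seq_len(n))
  geno <- genotype_matrix(dos, chr = rep("1", nrow(dos)),
                          pos = seq_len(nrow(dos)))
  traits <- matrix(rnorm(n_genes * n), n_genes, n,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   colnames(dos)))
  pairs <- data.frame(variant_id = rownames(dos),
                      gene_id = rep(rownames(traits), each = 10))
  gw <- genewise_scan(geno, traits, pairs, n_sim = 500, seed = 15)
  # q-values are discrete at resolution 1/(n_sim+1); tie warnings are expected
  expect_gt(suppressWarnings(ks.test(gw$q, "punif")$p.value), 0.01)
  expect_lt(mean(gw$significant), 0.05)
})
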