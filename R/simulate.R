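#' Simulation configuration
#'
#' Defines the generative model for the synthetic cohort used to exercise
#' every stage of the workflow. The model is linear-Gaussian with
#' standardized regulator transcripts and activities:
#' \deqn{X_r = \beta_e g_v + \epsilon_x}
#' \deqn{A_r = \lambda X_r + \beta_a g_a + \epsilon_a}
#' \deqn{X_t = m w A_r + \epsilon_t}
#' where `g` is a standardized dosage. The `beta_aqtl` channel alters a
#' regulator's efficacy on its targets without altering its own transcript,
#' producing activity-only QTLs; it may act through a variant in cis to the
#' regulator or through a trans-acting variant on a separate chromosome.
#' Phenotypes are weighted sums of master-regulator activities plus noise at
#' a configured heritability.
#'
#' @param n_samples number of individuals.
#' @param n_regulators number of regulator genes.
#' @param targets_per_regulator length-2 range of targets per regulator
#'   (sampled uniformly; targets are exclusive to one regulator).
#' @param n_passenger_genes unregulated genes with iid N(0,1) expression.
#' @param n_null_variants extra variants with no planted effect.
#' @param maf_range allele-frequency range for simulated variants.
#' @param ld_block_size variants per LD block.
#' @param rho_ld within-block latent haplotype correlation in \[0, 1).
#' @param beta_eqtl variant -> regulator transcript effect (sd units).
#' @param beta_aqtl variant -> regulator activity effect (sd units),
#'   independent of the transcript.
#' @param lambda transcript -> activity coupling.
#' @param sd_expr_noise,sd_activity_noise,sd_target_noise,mode_magnitude
#'   noise standard deviations and the range of |m| for regulator -> target
#'   modes.
#' @param n_eqtl,n_aqtl_cis,n_aqtl_trans number of regulators planted with
#'   each effect type (the remainder carry no genetic effect).
#' @param n_true_mrs number of regulators driving the phenotype.
#' @param mr_weights optional phenotype weights (default equal).
#' @param mr_h2 phenotype variance fraction explained by MR activities.
#' @param age_confounding coefficient of standardized age in the phenotype
#'   (default 0: age is an inert covariate).
#' @param pheno_name phenotype column name.
#' @param rng_seed default seed for all generator calls.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500L,
                       n_regulators = 12L,
                       targets_per_regulator = c(45L, 65L),
                       n_passenger_genes = 60L,
                       n_null_variants = 40L,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 5L,
                       rho_ld = 0.6,
                       beta_eqtl = 0.8,
                       beta_aqtl = 0.8,
                       lambda = 0.7,
                       sd_expr_noise = 0.6,
                       sd_activity_noise = 0.6,
                       sd_target_noise = 0.5,
                       mode_magnitude = c(0.5, 1),
                       n_eqtl = 4L,
                       n_aqtl_cis = 2L,
                       n_aqtl_trans = 2L,
                       n_true_mrs = 5L,
                       mr_weights = NULL,
                       mr_h2 = 0.5,
                       age_confounding = 0,
                       pheno_name = "BMI",
                       rng_seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_regulators = as.integer(n_regulators),
              targets_per_regulator = as.integer(targets_per_regulator),
              n_passenger_genes = as.integer(n_passenger_genes),
              n_null_variants = as.integer(n_null_variants),
              maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
              rho_ld = rho_ld, beta_eqtl = beta_eqtl, beta_aqtl = beta_aqtl,
              lambda = lambda, sd_expr_noise = sd_expr_noise,
              sd_activity_noise = sd_activity_noise,
              sd_target_noise = sd_target_noise,
              mode_magnitude = mode_magnitude,
              n_eqtl = as.integer(n_eqtl),
              n_aqtl_cis = as.integer(n_aqtl_cis),
              n_aqtl_trans = as.integer(n_aqtl_trans),
              n_true_mrs = as.integer(n_true_mrs),
              mr_weights = mr_weights, mr_h2 = mr_h2,
              age_confounding = age_confounding,
              pheno_name = pheno_name, rng_seed = as.integer(rng_seed))
  stopifnot(cfg$n_samples >= 2, cfg$n_regulators >= 1,
            all(cfg$targets_per_regulator >= 1),
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$rho_ld >= 0, cfg$rho_ld < 1,
            cfg$n_true_mrs <= cfg$n_regulators,
            cfg$n_eqtl + cfg$n_aqtl_cis + cfg$n_aqtl_trans <= cfg$n_regulators,
            cfg$mr_h2 > 0, cfg$mr_h2 < 1)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic genome layout: regulators are spaced 3 Mb apart, four per
# chromosome, each with an LD block of variants near its TSS; trans-acting
# variants live on chromosome "T", unlinked null variants on chromosome "N";
# target and passenger genes on chromosome "U" away from all variants.
sim_layout <- function(cfg) {
  R <- cfg$n_regulators
  b <- cfg$ld_block_size
  reg_ids <- sprintf("R%03d", seq_len(R))
  reg_chr <- as.character((seq_len(R) - 1) %/% 4 + 1)
  reg_tss <- as.integer(((seq_len(R) - 1) %% 4) * 3e6 + 1e6)

  v_id <- character(0); v_chr <- character(0); v_pos <- integer(0)
  v_block <- integer(0)
  blk <- 0L
  cis_variant <- character(R)
  for (r in seq_len(R)) {
    blk <- blk + 1L
    ids <- sprintf("v_%s_%d", reg_ids[r], seq_len(b))
    v_id <- c(v_id, ids)
    v_chr <- c(v_chr, rep(reg_chr[r], b))
    v_pos <- c(v_pos, reg_tss[r] + 1000L + (seq_len(b) - 1L) * 200L)
    v_block <- c(v_block, rep(blk, b))
    cis_variant[r] <- ids[1]
  }
  # effect type per regulator
  type <- rep("null", R)
  if (cfg$n_eqtl > 0) type[seq_len(cfg$n_eqtl)] <- "eqtl"
  if (cfg$n_aqtl_cis > 0)
    type[cfg$n_eqtl + seq_len(cfg$n_aqtl_cis)] <- "aqtl_cis"
  if (cfg$n_aqtl_trans > 0)
    type[cfg$n_eqtl + cfg$n_aqtl_cis + seq_len(cfg$n_aqtl_trans)] <- "aqtl_trans"

  trans_variant <- rep(NA_character_, R)
  ti <- 0L
  for (r in which(type == "aqtl_trans")) {
    blk <- blk + 1L; ti <- ti + 1L
    ids <- sprintf("v_trans%d_%d", ti, seq_len(b))
    v_id <- c(v_id, ids)
    v_chr <- c(v_chr, rep("T", b))
    v_pos <- c(v_pos, as.integer(1e6 + (ti - 1L) * 3e6) + (seq_len(b) - 1L) * 200L)
    v_block <- c(v_block, rep(blk, b))
    trans_variant[r] <- ids[1]
  }
  if (cfg$n_null_variants > 0) {
    nb <- ceiling(cfg$n_null_variants / b)
    for (k in seq_len(nb)) {
      blk <- blk + 1L
      m <- min(b, cfg$n_null_variants - (k - 1L) * b)
      ids <- sprintf("v_null%d_%d", k, seq_len(m))
      v_id <- c(v_id, ids)
      v_chr <- c(v_chr, rep("N", m))
      v_pos <- c(v_pos, as.integer(1e6 + (k - 1L) * 3e6) + (seq_len(m) - 1L) * 200L)
      v_block <- c(v_block, rep(blk, m))
    }
  }
  list(reg_ids = reg_ids, reg_chr = reg_chr, reg_tss = reg_tss,
       variant = data.frame(variant_id = v_id, chr = v_chr, pos = v_pos,
                            block = v_block, stringsAsFactors = FALSE),
       type = type, cis_variant = cis_variant, trans_variant = trans_variant)
}

#' Simulate genotypes with LD blocks
#'
#' Dosages are Binomial(2, p) with p drawn uniformly from `maf_range`.
#' Within an LD block the two haplotypes follow a latent AR(1) Gaussian
#' process with correlation `rho_ld`, thresholded at the allele frequency,
#' which gives a tunable r-squared decay along the block.
#'
#' @param config a [sim_config].
#' @param seed RNG seed (default `config$rng_seed`).
#' @return a [genotype_matrix]; attribute `layout` records the genome
#'   layout shared with [simulate_truth_and_expression()].
#' @export
simulate_genotypes <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 2) stop("n_samples must be at least 2")
  lay <- sim_layout(config)
  vt <- lay$variant
  n <- config$n_samples
  with_seed(seed, {
    dos <- matrix(0L, nrow(vt), n,
                  dimnames = list(vt$variant_id,
                                  sprintf("S%04d", seq_len(n))))
    for (bk in unique(vt$block)) {
      rows <- which(vt$block == bk)
      m <- length(rows)
      p <- runif(m, config$maf_range[1], config$maf_range[2])
      d <- matrix(0L, m, n)
      for (hap in 1:2) {
        z <- matrix(rnorm(m * n), m, n)
        if (m > 1 && config$rho_ld > 0) {
          for (j in 2:m)
            z[j, ] <- config$rho_ld * z[j - 1, ] +
              sqrt(1 - config$rho_ld^2) * z[j, ]
        }
        d <- d + (z < qnorm(p))
      }
      # guard against monomorphic draws so realized MAF > 0
      mono <- rowSums(d) == 0 | rowSums(d) == 2L * n
      for (j in which(mono)) {
        s <- sample.int(n, 1)
        d[j, s] <- if (d[j, s] == 0L) 1L else 1L
      }
      dos[rows, ] <- d
    }
    g <- genotype_matrix(dos, vt$chr, vt$pos)
    attr(g, "layout") <- lay
    g
  })
}

#' Simulate ground-truth network, activities and expression
#'
#' Builds the planted regulator -> target network (signed modes, likelihood
#' weights), latent regulator activities and the expression matrix for
#' regulators, targets and passenger genes, following the generative model
#' documented in [sim_config()]. Regulator transcripts and activities are
#' standardized; target expression is the weighted activity signal plus
#' noise, so its variance is `(m * w)^2 + sd_target_noise^2`.
#'
#' @param genotypes [genotype_matrix] from [simulate_genotypes()].
#' @param config the same [sim_config].
#' @param seed RNG seed.
#' @return list with `expression` (an [expression_matrix], log2TPM-like
#'   scale) and `truth` (network, activities, planted effect map, MR set).
#' @export
simulate_truth_and_expression <- function(genotypes, config,
                                          seed = config$rng_seed + 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  lay <- attr(genotypes, "layout")
  if (is.null(lay)) lay <- sim_layout(config)
  R <- config$n_regulators
  n <- config$n_samples
  samples <- colnames(genotypes$dosages)
  std <- function(g) {
    s <- sd(g)
    if (s == 0) stop("monomorphic causal variant")
    (g - mean(g)) / s
  }
  with_seed(seed, {
    tr <- config$targets_per_regulator
    n_targ <- if (tr[1] == tr[2]) rep(tr[1], R) else
      sample(seq(tr[1], tr[2]), R, replace = TRUE)
    if (any(n_targ == 0)) stop("regulator with zero targets")
    total_t <- sum(n_targ)
    targ_ids <- sprintf("T%04d", seq_len(total_t))
    pass_ids <- if (config$n_passenger_genes > 0)
      sprintf("P%03d", seq_len(config$n_passenger_genes)) else character(0)

    X_reg <- matrix(0, R, n, dimnames = list(lay$reg_ids, samples))
    A <- matrix(0, R, n, dimnames = list(lay$reg_ids, samples))
    effects <- list()
    for (r in seq_len(R)) {
      type <- lay$type[r]
      be <- if (type == "eqtl") config$beta_eqtl else 0
      ba <- if (type %in% c("aqtl_cis", "aqtl_trans")) config$beta_aqtl else 0
      g_e <- std(genotypes$dosages[lay$cis_variant[r], ])
      g_a <- if (type == "aqtl_trans")
        std(genotypes$dosages[lay$trans_variant[r], ]) else g_e
      x <- be * g_e + rnorm(n, sd = config$sd_expr_noise)
      x <- x / sqrt(be^2 + config$sd_expr_noise^2)
      a <- config$lambda * x + ba * g_a + rnorm(n, sd = config$sd_activity_noise)
      a <- a / sqrt(config$lambda^2 + ba^2 + config$sd_activity_noise^2)
      X_reg[r, ] <- x
      A[r, ] <- a
      if (be != 0)
        effects[[length(effects) + 1]] <- data.frame(
          variant_id = lay$cis_variant[r], regulator = lay$reg_ids[r],
          type = "eqtl", beta = be, stringsAsFactors = FALSE)
      if (ba != 0)
        effects[[length(effects) + 1]] <- data.frame(
          variant_id = if (type == "aqtl_trans") lay$trans_variant[r]
                       else lay$cis_variant[r],
          regulator = lay$reg_ids[r], type = type, beta = ba,
          stringsAsFactors = FALSE)
    }
    effects <- if (length(effects)) do.call(rbind, effects) else
      data.frame(variant_id = character(0), regulator = character(0),
                 type = character(0), beta = numeric(0))

    parent <- rep(seq_len(R), n_targ)
    mode <- sample(c(-1, 1), total_t, replace = TRUE) *
      runif(total_t, config$mode_magnitude[1], config$mode_magnitude[2])
    lik <- runif(total_t, 0.5, 1)
    X_targ <- (mode * lik) * A[parent, , drop = FALSE] +
      matrix(rnorm(total_t * n, sd = config$sd_target_noise), total_t, n)
    rownames(X_targ) <- targ_ids

    X_pass <- matrix(rnorm(length(pass_ids) * n), length(pass_ids), n,
                     dimnames = list(pass_ids, samples))
    vals <- rbind(X_reg, X_targ, X_pass)
    colnames(vals) <- samples

    gene_ids <- rownames(vals)
    other <- setdiff(gene_ids, lay$reg_ids)
    coords <- data.frame(
      gene_id = c(lay$reg_ids, other),
      chr = c(lay$reg_chr, rep("U", length(other))),
      tss = c(lay$reg_tss, as.integer(1e6 + seq_along(other) * 1e5)),
      stringsAsFactors = FALSE)
    expr <- expression_matrix(vals, "log2tpm", coords)

    # MR set: prefer regulators with activity-only effects, then eQTL ones
    pref <- order(match(lay$type, c("aqtl_cis", "aqtl_trans", "eqtl", "null")))
    mr_set <- lay$reg_ids[pref[seq_len(config$n_true_mrs)]]
    w <- config$mr_weights
    if (is.null(w)) w <- rep(1, config$n_true_mrs)
    if (config$n_true_mrs > 0 && sum(w) == 0)
      stop("MR weights sum to zero")

    truth <- list(
      network = data.frame(regulator = lay$reg_ids[parent],
                           target = targ_ids, mode = mode,
                           likelihood = lik, stringsAsFactors = FALSE),
      activities = A,
      effects = effects,
      mr_set = mr_set, mr_weights = w,
      effect_type = stats::setNames(lay$type, lay$reg_ids),
      seed = seed)
    list(expression = expr, truth = truth)
  })
}

#' Simulate phenotypes from master-regulator activities
#'
#' `Y = sum_r c_r A_r + eps`, with the noise variance set so that the MR
#' activities explain `mr_h2` of the phenotypic variance. An `age` column is
#' simulated independently of the phenotype unless `age_confounding` is
#' nonzero.
#'
#' @param truth ground truth from [simulate_truth_and_expression()].
#' @param config the [sim_config].
#' @param seed RNG seed.
#' @return data.frame with `sample_id`, the phenotype column and `age`.
#' @export
simulate_phenotypes <- function(truth, config, seed = config$rng_seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  A <- truth$activities
  samples <- colnames(A)
  n <- length(samples)
  with_seed(seed, {
    if (config$n_true_mrs > 0) {
      w <- truth$mr_weights
      if (sum(w) == 0) stop("MR weights sum to zero")
      S <- as.numeric(crossprod(A[truth$mr_set, , drop = FALSE], w))
    } else {
      S <- rep(0, n)
    }
    age <- round(runif(n, 30, 70))
    sd_s <- sd(S)
    if (sd_s == 0) sd_s <- 1
    noise_sd <- sd_s * sqrt((1 - config$mr_h2) / config$mr_h2)
    y <- S + config$age_confounding * as.numeric(scale(age)) * sd_s +
      rnorm(n, sd = noise_sd)
    out <- data.frame(sample_id = samples, y = y, age = age,
                      stringsAsFactors = FALSE)
    names(out)[2] <- config$pheno_name
    out
  })
}

#' Simulate GWAS summary statistics
#'
#' Per-variant simple (marginal) OLS of the phenotype on dosage, yielding
#' beta, se and a two-sided t-test p-value — the summary-statistic input
#' expected by the QTL and colocalization stages.
#'
#' @param genotypes a [genotype_matrix].
#' @param pheno phenotype table from [simulate_phenotypes()].
#' @param trait phenotype column name (default: first non-id, non-age
#'   column).
#' @return a `gwas_summary` data.frame.
#' @export
simulate_gwas_summary <- function(genotypes, pheno, trait = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(trait))
    trait <- setdiff(names(pheno), c("sample_id", "age"))[1]
  samples <- intersect(colnames(genotypes$dosages), pheno$sample_id)
  y <- pheno[[trait]][match(samples, pheno$sample_id)]
  G <- genotypes$dosages[, samples, drop = FALSE]
  n <- length(y)
  yc <- y - mean(y)
  gm <- rowMeans(G)
  Gc <- G - gm
  sxx <- rowSums(Gc^2)
  sxy <- as.numeric(Gc %*% yc)
  beta <- sxy / sxx
  syy <- sum(yc^2)
  rss <- syy - beta * sxy
  df <- n - 2
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  out <- data.frame(variant_id = rownames(G), chr = genotypes$chr,
                    pos = genotypes$pos, beta = beta, se = se,
                    p = pmin(pmax(p, .Machine$double.xmin), 1),
                    trait = trait, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Write a complete synthetic fixture to disk
#'
#' Generates genotypes, expression, phenotypes and GWAS summary statistics
#' under one config and writes them in the plain-text formats read by the
#' package's own readers: a VCF v4.2, TSV matrices, a regulator list, a GWAS
#' TSV and a versioned truth/config JSON for exact regeneration.
#'
#' @param dir output directory (created if missing).
#' @param config a [sim_config].
#' @param seed base RNG seed (default `config$rng_seed`).
#' @return invisibly, a list with `files` (named file paths) and the
#'   in-memory `genotypes`, `expression`, `truth`, `phenotypes`, `gwas`.
#' @export
write_fixture <- function(dir, config, seed = config$rng_seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- simulate_genotypes(config, seed = seed)
  sim <- simulate_truth_and_expression(geno, config, seed = child_seed(seed, 1))
  pheno <- simulate_phenotypes(sim$truth, config, seed = child_seed(seed, 2))
  gwas <- simulate_gwas_summary(geno, pheno)

  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    expression = file.path(dir, "expression.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    regulators = file.path(dir, "regulators.txt"),
    gene_coords = file.path(dir, "gene_coords.tsv"),
    gwas = file.path(dir, "gwas.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json"))

  write_vcf(geno, paths$vcf)
  write_matrix_tsv(sim$expression$values, paths$expression)
  write.table(pheno, paths$phenotypes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(rownames(sim$truth$activities), paths$regulators)
  write.table(sim$expression$gene_coords, paths$gene_coords, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(gwas), paths$gwas, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_json <- sim$truth
  truth_json$activities <- NULL
  jsonlite::write_json(
    list(schema_version = "1.0", seed = seed, truth = truth_json),
    paths$truth, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(schema_version = "1.0", seed = seed,
         config = unclass(config)),
    paths$config, auto_unbox = TRUE, digits = NA)

  invisible(list(files = paths, genotypes = geno,
                 expression = sim$expression, truth = sim$truth,
                 phenotypes = pheno, gwas = gwas))
}

# Minimal VCF v4.2 writer for integer dosages (GT field). Rows are sorted
# by chromosome and position.
write_vcf <- function(genotypes, path) {
  dos <- genotypes$dosages
  if (any(abs(dos - round(dos)) > 1e-9))
    stop("VCF writer supports integer dosages only")
  ord <- order(genotypes$chr, genotypes$pos)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dos)), collapse = "\t")), con)
  for (i in ord) {
    gts <- gt_code[as.character(round(dos[i, ]))]
    writeLines(paste(c(genotypes$chr[i], genotypes$pos[i],
                       rownames(dos)[i], "A", "C", ".", "PASS", ".", "GT",
                       gts), collapse = "\t"), con)
  }
  invisible(path)
}
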