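# Shared fixture builders; all randomness is seeded by the caller.

make_expr <- function(values, unit = "log2tpm", coords = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  expression_matrix(values, unit, coords)
}

random_expr <- function(n_genes, n_samples, seed, unit = "log2tpm") {
  set.seed(seed)
  make_expr(matrix(rnorm(n_genes * n_samples), n_genes, n_samples),
            unit = unit)
}

# A regulon list with unit-magnitude modes of random sign: under the NES
# null (independent expression), Var(sum w m u / sqrt(sum w^2)) = 1.
random_regulons <- function(gene_ids, sizes, seed, likelihood_range = c(0.5, 1)) {
  set.seed(seed)
  out <- list()
  for (i in seq_along(sizes)) {
    t <- sample(gene_ids, sizes[i])
    out[[sprintf("REG%02d", i)]] <- data.frame(
      target = t,
      mode = sample(c(-1, 1), sizes[i], replace = TRUE),
      likelihood = runif(sizes[i], likelihood_range[1], likelihood_range[2]),
      stringsAsFactors = FALSE)
  }
  class(out) <- "interactome"
  out
}

# Truth network as an edge table usable by network_to_interactome (|mode|
# stands in for MI so likelihood ranks match true edge strength).
truth_edges <- function(truth) {
  net <- truth$network
  net$mi <- abs(net$mode)
  net
}

small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_samples = 200, n_regulators = 4,
                    targets_per_regulator = c(10, 15),
                    n_passenger_genes = 15, n_null_variants = 10,
                    n_eqtl = 1, n_aqtl_cis = 1, n_aqtl_trans = 1,
                    n_true_mrs = 3, rng_seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_truth_and_expression(geno, cfg)
  list(cfg = cfg, geno = geno, expr = sim$expression, truth = sim$truth)
}
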