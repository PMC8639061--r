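#' Genotype principal components
#'
#' PCA of the standardized dosage matrix (samples x variants). Scores are
#' orthogonal; each component's sign is fixed so that its largest-|loading|
#' element is positive, which makes results reproducible across platforms.
#'
#' @param genotypes a [genotype_matrix].
#' @param n_pcs number of components to return (default 5).
#' @return samples x PCs score matrix (rownames = sample ids).
#' @export
genotype_pcs <- function(genotypes, n_pcs = 5) {
  G <- t(genotypes$dosages)          # samples x variants
  s <- apply(G, 2, sd)
  G <- G[, s > 0, drop = FALSE]
  n_pcs <- min(n_pcs, ncol(G), nrow(G) - 1)
  pc <- prcomp(G, center = TRUE, scale. = TRUE)
  rot <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  sgn <- vapply(seq_len(n_pcs), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2, sgn, "*")
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  scores
}

#' Select genome-wide significant GWAS variants
#'
#' @param gwas a `gwas_summary` data.frame.
#' @param cutoff p-value cutoff (default 5e-8).
#' @return `gwas` rows with `p <= cutoff` (variant set A).
#' @export
select_gwas_variants <- function(gwas, cutoff = 5e-8) {
  gwas[gwas$p <= cutoff, , drop = FALSE]
}

#' Candidate cis variant-gene pairs
#'
#' A pair is cis when variant and gene TSS share a chromosome and
#' `|pos - tss| <= window` (1-based, inclusive at the boundary).
#'
#' @param variants data.frame with `variant_id`, `chr`, `pos`.
#' @param genes data.frame with `gene_id`, `chr`, `tss`.
#' @param window cis window in bp (default 1e6).
#' @return data.frame `(variant_id, gene_id, distance)`.
#' @export
cis_pairs <- function(variants, genes, window = 1e6) {
  stopifnot(window > 0)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    sel <- variants$chr == genes$chr[i] &
      abs(variants$pos - genes$tss[i]) <= window
    if (any(sel))
      out[[length(out) + 1]] <- data.frame(
        variant_id = variants$variant_id[sel], gene_id = genes$gene_id[i],
        distance = abs(variants$pos[sel] - genes$tss[i]),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(variant_id = character(0), gene_id = character(0),
                      distance = numeric(0)))
  do.call(rbind, out)
}

#' Candidate trans variant-gene pairs
#'
#' The full cross-product of the variant set with the master-regulator gene
#' list, excluding pairs that satisfy the cis criterion.
#'
#' @param variants data.frame with `variant_id`, `chr`, `pos`.
#' @param mr_genes data.frame with `gene_id`, `chr`, `tss` (the MR set).
#' @param window cis window used for the exclusion (default 1e6).
#' @return data.frame `(variant_id, gene_id)`.
#' @export
trans_pairs <- function(variants, mr_genes, window = 1e6) {
  all_pairs <- expand.grid(variant_id = variants$variant_id,
                           gene_id = mr_genes$gene_id,
                           stringsAsFactors = FALSE)
  cis <- cis_pairs(variants, mr_genes, window)
  key <- paste(all_pairs$variant_id, all_pairs$gene_id)
  cis_key <- paste(cis$variant_id, cis$gene_id)
  all_pairs[!(key %in% cis_key), , drop = FALSE]
}

#' Single variant-trait linear association
#'
#' OLS of the trait on dosage, covariates and an intercept. The reported t
#' statistic is `beta / se` with `n - (k + 2)` degrees of freedom (k
#' covariates, plus dosage and intercept). Rows with a missing value in any
#' input are dropped pairwise; a dosage that is constant after dropping
#' yields `p = 1` with a message.
#'
#' @param dosage numeric vector.
#' @param trait numeric vector (an expression row for eQTLs, an activity
#'   row for aQTLs).
#' @param covariates optional samples x k matrix.
#' @return one-row data.frame `(beta, se, t, p, n)`.
#' @export
fit_qtl <- function(dosage, trait, covariates = NULL) {
  n0 <- length(dosage)
  stopifnot(length(trait) == n0,
            is.null(covariates) || nrow(covariates) == n0)
  ok <- !is.na(dosage) & !is.na(trait)
  if (!is.null(covariates)) ok <- ok & !apply(is.na(covariates), 1, any)
  g <- dosage[ok]; y <- trait[ok]
  C <- if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE]
  n <- length(g)
  if (sd(g) == 0) {
    message("constant dosage after sample drop; p set to 1")
    return(data.frame(beta = 0, se = NA_real_, t = 0, p = 1, n = n))
  }
  X <- cbind(1, g, C)
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * XtX_inv[2, 2])
  beta <- unname(fit$coefficients[2])
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  data.frame(beta = beta, se = se, t = tval, p = max(p, .Machine$double.xmin),
             n = n)
}

# Residualize columns of M against covariates (with intercept) via the QR
# orthonormal basis; returns centered residual columns.
resid_covariates <- function(M, covariates) {
  n <- nrow(M)
  X <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, covariates)
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  M - Q %*% crossprod(Q, M)
}

#' Association scan over variant-gene pairs
#'
#' Vectorized OLS scan equivalent to [fit_qtl()] for complete data (by the
#' Frisch-Waugh theorem: trait and dosages are residualized against the
#' covariates once, then simple regressions are exact).
#'
#' @param genotypes a [genotype_matrix].
#' @param traits trait matrix (genes/regulators x samples).
#' @param pairs data.frame `(variant_id, gene_id)`.
#' @param covariates optional samples x k covariate matrix aligned to the
#'   shared samples.
#' @return data.frame `(variant_id, gene_id, beta, se, t, p, n)`.
#' @export
qtl_scan <- function(genotypes, traits, pairs, covariates = NULL) {
  samples <- intersect(colnames(genotypes$dosages), colnames(traits))
  if (!is.null(covariates)) {
    samples <- intersect(samples, rownames(covariates))
    covariates <- covariates[samples, , drop = FALSE]
  }
  n <- length(samples)
  G <- t(genotypes$dosages[, samples, drop = FALSE])   # samples x variants
  Tm <- t(traits[, samples, drop = FALSE])             # samples x genes
  k <- if (is.null(covariates)) 0 else ncol(covariates)
  Gr <- resid_covariates(G, covariates)
  Tr <- resid_covariates(Tm, covariates)
  df <- n - (k + 2)
  out <- pairs
  vi <- match(pairs$variant_id, colnames(Gr))
  gi <- match(pairs$gene_id, colnames(Tr))
  if (any(is.na(vi)) || any(is.na(gi)))
    stop("pairs reference variants or genes absent from the inputs")
  beta <- se <- tval <- p <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- Gr[, vi[i]]; y <- Tr[, gi[i]]
    sxx <- sum(g^2)
    if (sxx < 1e-12) { beta[i] <- 0; se[i] <- NA; tval[i] <- 0; p[i] <- 1; next }
    b <- sum(g * y) / sxx
    rss <- sum(y^2) - b^2 * sxx
    s <- sqrt(rss / df / sxx)
    beta[i] <- b; se[i] <- s; tval[i] <- b / s
    p[i] <- max(2 * pt(-abs(b / s), df), .Machine$double.xmin)
  }
  out$beta <- beta; out$se <- se; out$t <- tval; out$p <- p; out$n <- n
  out
}

#' Gene-wise minimum p-value
#'
#' @param assocs association data.frame for one gene (columns `variant_id`,
#'   `p`, optionally `pos` for the tie-break).
#' @return list `(min_p, lead_variant, n)`; p-value ties are broken by the
#'   smallest variant position (then variant id).
#' @export
genewise_minp <- function(assocs) {
  stopifnot(nrow(assocs) >= 1)
  ord <- if ("pos" %in% names(assocs))
    order(assocs$p, assocs$pos, assocs$variant_id) else
      order(assocs$p, assocs$variant_id)
  list(min_p = assocs$p[ord[1]], lead_variant = assocs$variant_id[ord[1]],
       n = nrow(assocs))
}

#' Empirical gene-wise p-value by block permutation
#'
#' Builds the null distribution of the gene-wise minimum p-value by jointly
#' permuting the sample indices of the gene's genotype block `n_sim` times
#' (which preserves the LD structure among the variants exactly while
#' breaking the genotype-trait association), recomputing the minimum
#' p-value each time. The gene-wise p is
#' `q_k = (1 + #\{sims with min-p <= observed\}) / (1 + n_sim)`, never zero.
#' Min-p comparisons are performed on the equivalent |correlation| scale.
#'
#' @param genotype_block samples x variants dosage matrix for the gene's
#'   tested variants.
#' @param trait numeric trait vector.
#' @param covariates optional samples x k matrix.
#' @param n_sim number of permutations (default 2000; 100000 at published
#'   scale; minimum 100).
#' @param seed RNG seed.
#' @param variant_pos optional positions for the lead-variant tie-break.
#' @return list `(q, min_p, lead_variant, n_variants, null_min_p)`.
#' @export
empirical_genewise_p <- function(genotype_block, trait, covariates = NULL,
                                 n_sim = 2000, seed = 1L,
                                 variant_pos = NULL) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  G <- as.matrix(genotype_block)
  n <- nrow(G); m <- ncol(G)
  stopifnot(length(trait) == n)
  Gr <- resid_covariates(G, covariates)
  yr <- resid_covariates(matrix(trait, ncol = 1), covariates)[, 1]
  gnorm <- sqrt(colSums(Gr^2))
  ok <- gnorm > 1e-12
  ynorm <- sqrt(sum(yr^2))
  r_obs <- rep(0, m)
  r_obs[ok] <- as.numeric(crossprod(Gr[, ok, drop = FALSE], yr)) /
    (gnorm[ok] * ynorm)
  k <- if (is.null(covariates)) 0 else ncol(covariates)
  df <- n - (k + 2)
  r2p <- function(r) {
    r <- pmin(abs(r), 1 - 1e-15)
    tv <- r * sqrt(df) / sqrt(1 - r^2)
    pmax(2 * pt(-tv, df), .Machine$double.xmin)
  }
  p_obs <- r2p(r_obs)
  ord <- if (!is.null(variant_pos)) order(p_obs, variant_pos) else order(p_obs)
  lead <- colnames(G)[ord[1]]
  r_max_obs <- max(abs(r_obs))
  null_rmax <- with_seed(seed, {
    Pi <- replicate(n_sim, sample.int(n))     # n x n_sim
    Yp <- matrix(yr[Pi], n, n_sim)            # permuted residual trait
    R <- crossprod(Yp, Gr[, ok, drop = FALSE]) /
      outer(rep(ynorm, n_sim), gnorm[ok])
    apply(abs(R), 1, max)
  })
  q <- (1 + sum(null_rmax >= r_max_obs)) / (1 + n_sim)
  list(q = q, min_p = p_obs[ord[1]], lead_variant = lead, n_variants = m,
       null_min_p = r2p(null_rmax))
}

#' Gene-wise QTL scan with empirical multiple-testing correction
#'
#' For every gene in `pairs`, runs [empirical_genewise_p()] over its tested
#' variants, then applies Benjamini-Hochberg across genes at `fdr`.
#'
#' @param genotypes a [genotype_matrix].
#' @param traits trait matrix (genes x samples).
#' @param pairs data.frame `(variant_id, gene_id)`.
#' @param covariates optional covariate matrix (samples x k).
#' @param n_sim permutations per gene.
#' @param fdr FDR level (default 0.05).
#' @param seed base seed; gene i uses a derived child seed.
#' @return data.frame `(gene_id, n_variants, min_p, lead_variant, q, q_bh,
#'   significant)` with the pooled null min-p distribution in attribute
#'   `null_min_p`.
#' @export
genewise_scan <- function(genotypes, traits, pairs, covariates = NULL,
                          n_sim = 2000, fdr = 0.05, seed = 1L) {
  samples <- intersect(colnames(genotypes$dosages), colnames(traits))
  if (!is.null(covariates)) {
    samples <- intersect(samples, rownames(covariates))
    covariates <- covariates[samples, , drop = FALSE]
  }
  genes <- unique(pairs$gene_id)
  res <- vector("list", length(genes))
  nulls <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    vids <- pairs$variant_id[pairs$gene_id == g]
    blk <- t(genotypes$dosages[vids, samples, drop = FALSE])
    pos <- genotypes$pos[match(vids, rownames(genotypes$dosages))]
    y <- traits[g, samples]
    e <- empirical_genewise_p(blk, y, covariates, n_sim = n_sim,
                              seed = child_seed(seed, i), variant_pos = pos)
    res[[i]] <- data.frame(gene_id = g, n_variants = e$n_variants,
                           min_p = e$min_p, lead_variant = e$lead_variant,
                           q = e$q, stringsAsFactors = FALSE)
    nulls[[i]] <- e$null_min_p
  }
  out <- do.call(rbind, res)
  bh <- bh_fdr(out$q, fdr)
  out$q_bh <- bh$adjusted
  out$significant <- bh$significant
  attr(out, "null_min_p") <- unlist(nulls)
  out
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up procedure on the gene-wise p-values.
#'
#' @param q numeric p-values.
#' @param fdr target FDR (default 0.05).
#' @return list `(adjusted, significant)`.
#' @export
bh_fdr <- function(q, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  adj <- p.adjust(q, method = "BH")
  list(adjusted = adj, significant = adj <= fdr)
}

#' Nominal trans-QTL significance threshold
#'
#' Inverts the empirical null min-p CDF at the largest gene-wise p among
#' BH-significant genes: the returned value is the nominal association p
#' whose gene-wise (empirical) p corresponds to the FDR-adjusted bound.
#' `NaN` (with attribute `no_gene_passes = TRUE`) when no gene is
#' significant.
#'
#' @param null_min_p pooled null min-p distribution (e.g. the attribute of
#'   [genewise_scan()]'s result).
#' @param genewise result data.frame from [genewise_scan()].
#' @param fdr FDR level used in the scan.
#' @return nominal p-value threshold.
#' @export
trans_threshold <- function(null_min_p, genewise, fdr = 0.05) {
  pass <- genewise$significant
  if (!any(pass)) {
    out <- NaN
    attr(out, "no_gene_passes") <- TRUE
    return(out)
  }
  q_star <- max(genewise$q[pass])
  s <- sort(null_min_p)
  k <- floor(q_star * length(s))
  if (k < 1) return(s[1] / 2)
  s[k]
}

#' Compare eQTL and aQTL signal strength
#'
#' For matched variant-gene pairs, computes the proportion of pairs where
#' the aQTL p-value is strictly smaller than the eQTL p-value, separately
#' for cis and trans, and tests the difference in proportions with the
#' pooled two-proportion z-test.
#'
#' @param eqtl,aqtl association data.frames with `variant_id`, `gene_id`,
#'   `p` and a `mode` column (`"cis"` or `"trans"`), or supply `mode` via
#'   the `mode` argument.
#' @param mode optional single mode label when the inputs carry none.
#' @return list `(prop, n, z, p_value)` where `prop`/`n` are named by mode.
#' @export
compare_qtl_strength <- function(eqtl, aqtl, mode = NULL) {
  key <- function(d) paste(d$variant_id, d$gene_id)
  merged <- merge(eqtl, aqtl, by = c("variant_id", "gene_id"),
                  suffixes = c("_e", "_a"))
  if (!is.null(mode)) merged$mode <- mode
  else if ("mode_e" %in% names(merged)) merged$mode <- merged$mode_e
  stopifnot("mode" %in% names(merged))
  stronger <- merged$p_a < merged$p_e
  prop <- tapply(stronger, merged$mode, mean)
  nn <- tapply(stronger, merged$mode, length)
  z <- p_value <- NA_real_
  if (all(c("cis", "trans") %in% names(prop))) {
    x1 <- prop[["cis"]] * nn[["cis"]]; x2 <- prop[["trans"]] * nn[["trans"]]
    n1 <- nn[["cis"]]; n2 <- nn[["trans"]]
    pbar <- (x1 + x2) / (n1 + n2)
    z <- (x1 / n1 - x2 / n2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    p_value <- 2 * pnorm(-abs(z))
  }
  list(prop = prop, n = nn, z = unname(z), p_value = unname(p_value))
}

#' Dense locus scan for colocalization
#'
#' Retests all variants within a window centered on a reference variant
#' against the supplied traits, regardless of GWAS significance. These
#' dense results feed colocalization only and carry no multiple-testing
#' correction.
#'
#' @param genotypes a [genotype_matrix].
#' @param traits trait matrix (genes x samples).
#' @param center_variant variant id at the window center.
#' @param window half-width in bp (default 5e5, i.e. a 1 Mb window).
#' @param covariates optional covariate matrix.
#' @param gene_ids genes to test (default: all rows of `traits`).
#' @return association data.frame as from [qtl_scan()].
#' @export
dense_locus_scan <- function(genotypes, traits, center_variant,
                             window = 5e5, covariates = NULL,
                             gene_ids = rownames(traits)) {
  i <- match(center_variant, rownames(genotypes$dosages))
  if (is.na(i)) stop("center variant not found")
  sel <- genotypes$chr == genotypes$chr[i] &
    abs(genotypes$pos - genotypes$pos[i]) <= window
  pairs <- expand.grid(variant_id = rownames(genotypes$dosages)[sel],
                       gene_id = gene_ids, stringsAsFactors = FALSE)
  qtl_scan(genotypes, traits, pairs, covariates)
}
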