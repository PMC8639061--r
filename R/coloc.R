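#' Per-variant log approximate Bayes factor
#'
#' Wakefield's approximation for a normal effect prior with standard
#' deviation `W`:
#' `log ABF = 0.5 * log(se^2 / (se^2 + W^2)) + (z^2 / 2) * W^2 / (se^2 + W^2)`
#' with `z = beta / se`. With `beta = 0` only the shrinkage term remains
#' (negative); as `W -> 0` the log ABF tends to 0.
#'
#' @param beta,se effect estimates and standard errors (vectors).
#' @param W prior standard deviation of the true effect (default 0.15 per
#'   trait sd).
#' @return numeric vector of log ABFs.
#' @export
log_abf <- function(beta, se, W = 0.15) {
  stopifnot(all(se > 0))
  z <- beta / se
  r <- W^2 / (se^2 + W^2)
  0.5 * log(1 - r) + (z^2 / 2) * r
}

#' Pairwise colocalization of two association signals
#'
#' Enumerates the five hypotheses over a locus — H0 no association, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant — from per-variant approximate Bayes factors and
#' per-variant prior probabilities `p1`, `p2`, `p12`. The posterior of H4
#' (PP) is classified as `none` when PP <= 0.25, `weak` when
#' 0.25 < PP < 0.50 (a PP of exactly 0.50 is still `weak`), and `well` when
#' PP > 0.50.
#'
#' @param stats a data.frame (LocusStats) with columns `variant_id`,
#'   `beta1`, `se1`, `beta2`, `se2`, identical variant order for both
#'   traits.
#' @param p1,p2,p12 per-variant priors (defaults 1e-4, 1e-4, 1e-5).
#' @param W effect prior sd passed to [log_abf()].
#' @param traits optional length-2 character vector of trait labels.
#' @return list of class `coloc_result`: `pp` (named H0..H4, sums to 1),
#'   `PP` (= pp\["H4"\]), `class`, `variant_pp_h4`, `top_shared_variant`,
#'   `traits`.
#' @export
pairwise_coloc <- function(stats, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                           W = 0.15, traits = c("trait1", "trait2")) {
  req <- c("variant_id", "beta1", "se1", "beta2", "se2")
  stopifnot(all(req %in% names(stats)))
  if (nrow(stats) == 0) stop("empty variant intersection")
  l1 <- log_abf(stats$beta1, stats$se1, W)
  l2 <- log_abf(stats$beta2, stats$se2, W)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over ordered distinct pairs (i, j), i != j:
  # log(sum_i e^l1i * sum_j e^l2j - sum_i e^(l1i + l2i))
  both <- s1 + s2
  d <- both + log1p(-exp(pmin(s12 - both, 0)))
  if (!is.finite(d)) d <- -Inf                    # single-variant locus
  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + d,
          H4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  PP <- unname(pp["H4"])
  cls <- if (PP <= 0.25) "none" else if (PP <= 0.50) "weak" else "well"
  vpp <- exp((l1 + l2) - logsumexp(l1 + l2))
  res <- list(pp = pp, PP = PP, class = cls,
              variant_pp_h4 = stats::setNames(vpp, stats$variant_id),
              top_shared_variant = stats$variant_id[which.max(vpp)],
              traits = traits)
  class(res) <- "coloc_result"
  res
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc: %s vs %s  PP(H4) = %.3f [%s]\n",
              x$traits[1], x$traits[2], x$PP, x$class))
  print(round(x$pp, 4))
  invisible(x)
}

# Build LocusStats for two association tables on their shared variants.
locus_stats <- function(a, b) {
  m <- merge(a[, c("variant_id", "beta", "se")],
             b[, c("variant_id", "beta", "se")],
             by = "variant_id", suffixes = c("1", "2"))
  if (nrow(m) == 0) stop("empty variant intersection")
  names(m) <- c("variant_id", "beta1", "se1", "beta2", "se2")
  m
}

#' Colocalization over a set of signal pairs
#'
#' Runs [pairwise_coloc()] for every requested pair of association tables
#' (GWAS summary statistics and/or dense QTL scans), on the intersection of
#' their variants.
#'
#' @param signals named list of association data.frames, each with
#'   `variant_id`, `beta`, `se`.
#' @param pairs optional 2-column matrix/data.frame of signal-name pairs
#'   (default: all unordered pairs).
#' @param ... passed to [pairwise_coloc()].
#' @return data.frame `(trait_a, trait_b, PP_H0..PP_H4, PP, class,
#'   top_shared_variant)`.
#' @export
coloc_matrix <- function(signals, pairs = NULL, ...) {
  nm <- names(signals)
  if (is.null(pairs)) {
    idx <- utils::combn(nm, 2)
    pairs <- data.frame(a = idx[1, ], b = idx[2, ], stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    st <- locus_stats(signals[[a]], signals[[b]])
    r <- pairwise_coloc(st, traits = c(a, b), ...)
    data.frame(trait_a = a, trait_b = b,
               PP_H0 = r$pp["H0"], PP_H1 = r$pp["H1"], PP_H2 = r$pp["H2"],
               PP_H3 = r$pp["H3"], PP_H4 = r$pp["H4"], PP = r$PP,
               class = r$class, top_shared_variant = r$top_shared_variant,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' LocusCompare-style table for two signals
#'
#' Per shared variant, the -log10 p of each signal (computed from beta/se
#' when no `p` column is present) and, when a genotype matrix is given, the
#' LD r-squared to a reference variant.
#'
#' @param stats_a,stats_b association data.frames with `variant_id`,
#'   `beta`, `se` and optionally `p`.
#' @param genotypes optional [genotype_matrix] for the r-squared column.
#' @param ref_variant reference variant id (default: the most significant
#'   variant of signal A).
#' @return data.frame `(variant_id, neglog10_p_a, neglog10_p_b, r2)`.
#' @export
locus_compare_table <- function(stats_a, stats_b, genotypes = NULL,
                                ref_variant = NULL) {
  getp <- function(d) {
    if ("p" %in% names(d)) d$p else 2 * pnorm(-abs(d$beta / d$se))
  }
  a <- data.frame(variant_id = stats_a$variant_id, pa = getp(stats_a))
  b <- data.frame(variant_id = stats_b$variant_id, pb = getp(stats_b))
  m <- merge(a, b, by = "variant_id")
  out <- data.frame(variant_id = m$variant_id,
                    neglog10_p_a = -log10(m$pa),
                    neglog10_p_b = -log10(m$pb))
  if (!is.null(genotypes)) {
    if (is.null(ref_variant))
      ref_variant <- m$variant_id[which.min(m$pa)]
    have <- intersect(out$variant_id, rownames(genotypes$dosages))
    ref <- genotypes$dosages[ref_variant, ]
    r2 <- rep(NA_real_, nrow(out))
    idx <- match(have, out$variant_id)
    r2[idx] <- as.numeric(cor(ref, t(genotypes$dosages[have, , drop = FALSE])))^2
    out$r2 <- r2
    attr(out, "ref_variant") <- ref_variant
  }
  out
}
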