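#' Mutual information by adaptive partitioning
#'
#' Rank-transforms both vectors and recursively splits the rank plane into
#' quadrants at the midpoints of each cell's rank ranges while a chi-square
#' uniformity statistic over the four quadrant counts exceeds `crit`
#' (default: the df = 3, alpha = 0.05 critical value). The MI estimate, in
#' nats, is the sum over terminal cells of
#' `(n_c / N) * ln(n_c * N / (n_x * n_y))`. Being rank-based, the estimate
#' is invariant under strictly increasing transforms of either argument
#' (an order reversal reflects the rank plane and can shift the midpoint
#' partition by one rank, changing the estimate only marginally).
#'
#' @param x,y numeric vectors of equal length (at least 8).
#' @param crit chi-square splitting threshold (default 7.815).
#' @return mutual information in nats (nonnegative).
#' @export
mutual_information <- function(x, y, crit = 7.815) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 8) stop("need at least 8 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input vector; MI set to 0")
    return(0)
  }
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")
  mi_adaptive_cpp(as.integer(rx), as.integer(ry), crit)
}

#' Estimate the MI significance threshold
#'
#' Builds a null MI distribution from randomly chosen gene pairs with
#' independently permuted sample labels, then fits an extreme-value tail
#' `ln P(MI > t) = a + b * t` on the upper 5% of the null and extrapolates
#' to the MI value with tail probability `p_threshold`. Direct permutation
#' cannot reach tail probabilities like 1e-8, hence the extrapolation.
#'
#' @param expr an [expression_matrix] (any unit).
#' @param p_threshold target tail probability (default 1e-8).
#' @param n_null permuted null pairs per batch (default 10000; minimum
#'   100). Because most null MIs are exactly zero, up to ten batches are
#'   drawn until at least 50 are positive.
#' @param crit chi-square splitting threshold passed to the MI estimator.
#' @param tail_frac fraction of the null used for the tail fit.
#' @param seed RNG seed.
#' @return the MI threshold t* (nats), with the fitted tail as attributes.
#' @export
mi_threshold <- function(expr, p_threshold = 1e-8, n_null = 10000,
                         crit = 7.815, tail_frac = 0.05, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  vals <- expr$values
  if (nrow(vals) < 2) stop("need at least 2 genes")
  if (n_null < 100) stop("n_null too small to fit the tail (< 100)")
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must lie in (0, 1]")
  n <- ncol(vals)
  with_seed(seed, {
    ranks <- t(apply(vals, 1, rank, ties.method = "first"))
    storage.mode(ranks) <- "integer"
    # the null is heavily massed at exactly zero (a cell only splits when
    # its quadrant chi-square exceeds `crit`), so batches of permuted pairs
    # are drawn until the positive tail is large enough to fit
    null_mi <- numeric(0)
    batches <- 0L
    while (batches < 10L && sum(null_mi > 0) < 50L) {
      batches <- batches + 1L
      i1 <- sample.int(nrow(vals), n_null, replace = TRUE)
      i2 <- sample.int(nrow(vals), n_null, replace = TRUE)
      batch <- numeric(n_null)
      # permute one member of each pair: shuffle its sample labels
      for (k in seq_len(n_null)) {
        perm <- sample.int(n)
        batch[k] <- mi_adaptive_cpp(ranks[i1[k], ], ranks[i2[k], perm], crit)
      }
      null_mi <- c(null_mi, batch)
    }
    n_null <- length(null_mi)
    if (p_threshold >= 1) {
      t_star <- min(null_mi)
    } else {
      s <- sort(null_mi)
      # with few samples most null MIs are exactly zero (no partition
      # split); the exponential tail is fit on the positive upper tail only
      pos <- which(s > 0)
      if (length(pos) < 10)
        stop("null MI distribution is degenerate (too few positive values);",
             " increase n_null or the sample size")
      k0 <- max(min(pos), floor((1 - tail_frac) * n_null))
      idx <- k0:(n_null - 1)
      tail_t <- s[idx]
      surv <- (n_null - idx) / n_null
      keep <- surv > 0
      if (length(unique(tail_t[keep])) < 3)
        stop("tail fit failed: null MI tail has too few distinct values")
      fit <- lm(log(surv[keep]) ~ tail_t[keep])
      a <- coef(fit)[1]; b <- coef(fit)[2]
      if (!is.finite(b) || b >= 0)
        stop("tail fit failed: nonnegative slope")
      t_star <- as.numeric((log(p_threshold) - a) / b)
    }
    structure(t_star, tail_fit = if (p_threshold < 1) c(a = unname(a), b = unname(b)) else NULL,
              null_quantiles = quantile(null_mi, c(0.5, 0.95, 0.99)))
  })
}

# Canonical unordered pair key
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Data-processing-inequality pruning
#'
#' For every triangle of edges, the edge with the smallest MI is removed:
#' if genes a-b, b-c and a-c are all connected, the weakest dependence is
#' taken to be indirect. Ties on the minimum are broken by removing the
#' lexicographically last pair id, so pruning is deterministic. Edges are
#' treated as unordered pairs; both directed copies of a pruned pair are
#' dropped. The operation never adds edges and is idempotent.
#'
#' @param edges data.frame with columns `regulator`, `target`, `mi`.
#' @return pruned data.frame, a subset of the input rows.
#' @export
apply_dpi <- function(edges) {
  stopifnot(all(c("regulator", "target", "mi") %in% names(edges)))
  if (nrow(edges) == 0) return(edges)
  key <- pair_key(edges$regulator, edges$target)
  first <- !duplicated(key)
  pk <- key[first]
  pa <- ifelse(edges$regulator[first] < edges$target[first],
               edges$regulator[first], edges$target[first])
  pb <- ifelse(edges$regulator[first] < edges$target[first],
               edges$target[first], edges$regulator[first])
  pmi <- edges$mi[first]
  names(pmi) <- pk

  nodes <- unique(c(pa, pb))
  adj <- split(c(pb, pa), c(pa, pb))  # neighbor lists
  drop <- character(0)
  # enumerate each triangle once: for pair (a,b) with a<b, common neighbors
  # w with w > b
  for (i in seq_along(pk)) {
    a <- pa[i]; b <- pb[i]
    common <- intersect(adj[[a]], adj[[b]])
    common <- common[common > b]
    for (w in common) {
      k_ab <- pk[i]
      k_aw <- pair_key(a, w)
      k_bw <- pair_key(b, w)
      tri_k <- c(k_ab, k_aw, k_bw)
      tri_mi <- pmi[tri_k]
      mn <- min(tri_mi)
      cand <- tri_k[tri_mi == mn]
      drop <- c(drop, if (length(cand) == 1) cand else max(cand))
    }
  }
  keep <- !(key %in% drop)
  edges[keep, , drop = FALSE]
}

#' Bootstrap consensus co-expression network
#'
#' The three-step network inference: (1) estimate the MI significance
#' threshold from the expression profiles; (2) for each bootstrap, resample
#' samples with replacement, compute MI for all regulator-gene pairs, keep
#' pairs above the threshold and prune by DPI; (3) keep edges whose
#' bootstrap support is significant under a Poisson null whose rate is the
#' total number of edge occurrences spread uniformly over all candidate
#' pairs, Bonferroni-corrected at 0.05 across the candidates. Edge direction is regulator -> target,
#' assigned from the regulator list; pairs of two regulators yield both
#' directed edges.
#'
#' @param expr an [expression_matrix].
#' @param regulators character vector of regulator gene ids.
#' @param n_bootstraps bootstrap count (default 50; 900 reproduces the
#'   published-scale profile).
#' @param p_threshold MI-threshold tail probability (default 1e-8).
#' @param n_null permuted pairs for the threshold estimate.
#' @param crit chi-square splitting threshold.
#' @param threshold optional precomputed MI threshold (skips step 1).
#' @param seed RNG seed.
#' @return a list of class `coexpression_network` with `edges`
#'   (regulator, target, mi, support), `n_bootstraps`, `mi_threshold`,
#'   `p_threshold`.
#' @export
bootstrap_consensus <- function(expr, regulators, n_bootstraps = 50,
                                p_threshold = 1e-8, n_null = 10000,
                                crit = 7.815, threshold = NULL, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (n_bootstraps < 2) stop("n_bootstraps must be at least 2")
  vals <- expr$values
  genes <- rownames(vals)
  regulators <- intersect(regulators, genes)
  if (!length(regulators)) stop("no regulators present in the expression matrix")
  n <- ncol(vals)

  if (is.null(threshold))
    threshold <- as.numeric(mi_threshold(expr, p_threshold, n_null, crit,
                                         seed = child_seed(seed, 0)))

  ridx <- match(regulators, genes)
  # candidate unordered pairs: regulator x gene, deduplicated
  ia <- rep(ridx, each = length(genes))
  ib <- rep(seq_along(genes), times = length(ridx))
  ok <- ia != ib & !(ib %in% ridx & ib < ia)
  ia <- ia[ok]; ib <- ib[ok]

  support <- new.env(hash = TRUE, parent = emptyenv())
  for (bs in seq_len(n_bootstraps)) {
    with_seed(child_seed(seed, bs), {
      cols <- sample.int(n, n, replace = TRUE)
      ranks <- t(apply(vals[, cols, drop = FALSE], 1, rank,
                       ties.method = "first"))
      storage.mode(ranks) <- "integer"
      mi <- mi_pairs_cpp(ranks, ia, ib, crit)
      sel <- mi >= threshold
      if (any(sel)) {
        ed <- data.frame(regulator = genes[ia[sel]], target = genes[ib[sel]],
                         mi = mi[sel], stringsAsFactors = FALSE)
        ed <- apply_dpi(ed)
        keys <- pair_key(ed$regulator, ed$target)
        for (k in keys) {
          cur <- if (exists(k, envir = support, inherits = FALSE))
            get(k, envir = support) else 0L
          assign(k, cur + 1L, envir = support)
        }
      }
    })
  }

  keys <- ls(support)
  if (!length(keys)) {
    net <- list(edges = data.frame(regulator = character(0),
                                   target = character(0), mi = numeric(0),
                                   support = integer(0)),
                n_bootstraps = n_bootstraps, mi_threshold = threshold,
                p_threshold = p_threshold)
    class(net) <- "coexpression_network"
    return(net)
  }
  supp <- vapply(keys, function(k) get(k, envir = support), integer(1))
  # Poisson null: occurrences scattered uniformly over all candidate pairs
  n_candidates <- length(ia)
  lambda <- sum(supp) / n_candidates
  pval <- ppois(supp - 1, lambda, lower.tail = FALSE)
  keep <- pval < 0.05 / n_candidates
  keys <- keys[keep]; supp <- supp[keep]

  # full-data MI for retained pairs
  parts <- strsplit(keys, "|", fixed = TRUE)
  g1 <- vapply(parts, `[[`, character(1), 1)
  g2 <- vapply(parts, `[[`, character(1), 2)
  ranks_full <- t(apply(vals, 1, rank, ties.method = "first"))
  storage.mode(ranks_full) <- "integer"
  mi_full <- mi_pairs_cpp(ranks_full, match(g1, genes), match(g2, genes), crit)

  # orient: regulator -> target; two regulators -> both directions
  is_r1 <- g1 %in% regulators
  is_r2 <- g2 %in% regulators
  reg_col <- c(g1[is_r1], g2[is_r2 & !is_r1], g2[is_r1 & is_r2])
  tgt_col <- c(g2[is_r1], g1[is_r2 & !is_r1], g1[is_r1 & is_r2])
  mi_col <- c(mi_full[is_r1], mi_full[is_r2 & !is_r1], mi_full[is_r1 & is_r2])
  sup_col <- c(supp[is_r1], supp[is_r2 & !is_r1], supp[is_r1 & is_r2])

  edges <- data.frame(regulator = reg_col, target = tgt_col, mi = mi_col,
                      support = as.integer(sup_col), stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  net <- list(edges = edges, n_bootstraps = n_bootstraps,
              mi_threshold = threshold, p_threshold = p_threshold)
  class(net) <- "coexpression_network"
  net
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d edges, %d regulators, %d targets (%d bootstraps)\n",
              nrow(x$edges), length(unique(x$edges$regulator)),
              length(unique(x$edges$target)), x$n_bootstraps))
  invisible(x)
}

#' Read / write a network TSV (regulator, target, mi, support)
#' @param net a `coexpression_network` (or its `edges` data.frame).
#' @param path file path.
#' @return `read_network_tsv` returns a `coexpression_network`.
#' @export
write_network_tsv <- function(net, path) {
  edges <- if (inherits(net, "coexpression_network")) net$edges else net
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  edges <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  net <- list(edges = edges, n_bootstraps = NA_integer_,
              mi_threshold = NA_real_, p_threshold = NA_real_)
  class(net) <- "coexpression_network"
  net
}
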