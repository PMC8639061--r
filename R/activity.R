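#' Convert a co-expression network into an interactome of regulons
#'
#' For every network edge, the mode of action `m` is the signed Spearman
#' correlation between regulator and target expression, and the likelihood
#' `w` is the edge MI scaled by the maximum MI within the regulon (so the
#' top target of each regulon has `w = 1`). Targets absent from the
#' expression matrix are dropped; regulons left without targets are omitted
#' with a message.
#'
#' @param network a `coexpression_network` (or a data.frame of edges with
#'   columns `regulator`, `target`, `mi`).
#' @param expr an [expression_matrix] providing the profiles for the
#'   correlation.
#' @return a named list of class `interactome`; each element is a
#'   data.frame `(target, mode, likelihood)` for one regulator.
#' @export
network_to_interactome <- function(network, expr) {
  edges <- if (inherits(network, "coexpression_network")) network$edges else network
  stopifnot(all(c("regulator", "target", "mi") %in% names(edges)),
            inherits(expr, "expression_matrix"))
  genes <- rownames(expr$values)
  present <- edges$target %in% genes & edges$regulator %in% genes
  n_drop <- sum(!present)
  if (n_drop > 0)
    message(sprintf("dropping %d edge(s) with genes absent from expression",
                    n_drop))
  edges <- edges[present, , drop = FALSE]
  out <- list()
  for (r in unique(edges$regulator)) {
    e <- edges[edges$regulator == r, , drop = FALSE]
    m <- as.numeric(cor(expr$values[r, ], t(expr$values[e$target, , drop = FALSE]),
                        method = "spearman"))
    w <- e$mi / max(e$mi)
    out[[r]] <- data.frame(target = e$target, mode = m, likelihood = w,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) message("no regulons survive; empty interactome")
  class(out) <- "interactome"
  out
}

#' Z-scale expression per gene
#'
#' Centers and scales each gene's values across samples to mean 0 and
#' sample standard deviation 1 (denominator n - 1). Constant genes become
#' all-zero rows with a warning.
#'
#' @param expr an [expression_matrix] (typically log2TPM).
#' @return an [expression_matrix] with unit `"zscore"`.
#' @export
zscale <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  bad <- s == 0
  if (any(bad)) {
    warning(sprintf("%d constant gene(s) z-scaled to zero", sum(bad)))
    s[bad] <- 1
  }
  z <- (v - mu) / s
  expression_matrix(z, "zscore", expr$gene_coords)
}

# Per-sample normal scores: within each sample, genes are rank-transformed
# to quantiles (rank - 0.5) / G (average ranks on ties) and mapped through
# the standard-normal quantile function.
normal_scores <- function(z_values) {
  G <- nrow(z_values)
  apply(z_values, 2, function(col) qnorm((rank(col) - 0.5) / G))
}

#' Per-sample regulator activity scores
#'
#' For each sample, all genes' z-scores are rank-transformed within the
#' sample and mapped to normal scores `u`. The activity of regulator r is
#' the weighted enrichment
#' \deqn{NES_r(s) = \sum_i w_i m_i u_i(s) / \sqrt{\sum_i w_i^2}}
#' over its targets, which is standard normal under the null of no
#' coordinated target behavior (for unit-magnitude modes). Regulators with
#' fewer than `min_targets` expressed targets are excluded.
#'
#' @param z an [expression_matrix] with unit `"zscore"`.
#' @param regulons an `interactome`.
#' @param min_targets minimum expressed targets per regulon (default 25).
#' @return matrix of class `activity_matrix` (regulators x samples) with
#'   attribute `n_targets`.
#' @export
activity_scores <- function(z, regulons, min_targets = 25) {
  stopifnot(inherits(z, "expression_matrix"))
  if (z$unit != "zscore") stop("activity scoring expects z-scaled input")
  if (!length(regulons)) stop("empty regulon set")
  genes <- rownames(z$values)
  U <- normal_scores(z$values)
  rownames(U) <- genes
  keep_reg <- character(0)
  nes_rows <- list()
  n_targets <- integer(0)
  for (r in names(regulons)) {
    reg <- regulons[[r]]
    reg <- reg[reg$target %in% genes, , drop = FALSE]
    if (nrow(reg) < min_targets) next
    wm <- reg$likelihood * reg$mode
    nes <- as.numeric(crossprod(wm, U[reg$target, , drop = FALSE])) /
      sqrt(sum(reg$likelihood^2))
    keep_reg <- c(keep_reg, r)
    nes_rows[[r]] <- nes
    n_targets <- c(n_targets, nrow(reg))
  }
  if (!length(keep_reg))
    stop(sprintf("no regulator has at least %d expressed targets", min_targets))
  out <- do.call(rbind, nes_rows)
  rownames(out) <- keep_reg
  colnames(out) <- colnames(z$values)
  structure(out, n_targets = stats::setNames(n_targets, keep_reg),
            class = c("activity_matrix", "matrix", "array"))
}

#' Pleiotropy correction of activity scores
#'
#' Accounts for shared targets among overlapping regulons: for each
#' regulator r and sample s, partners r' sharing at least `min_common`
#' targets with a stronger signal (`|NES_r| < |NES_r'|` on s) are assumed
#' to drive the shared targets. The score of r is recomputed on the targets
#' unique to r (relative to all stronger partners on that sample) and
#' blended with the original: `alpha * original + (1 - alpha) * unique`.
#' Regulators with no qualifying partner are unchanged; `alpha = 1` is the
#' identity.
#'
#' @param activities an `activity_matrix` computed from `regulons`.
#' @param regulons the same `interactome`.
#' @param z the z-scaled [expression_matrix] used for scoring.
#' @param min_common minimum shared-target count to qualify (default 25).
#' @param alpha blending weight in \[0, 1\] (default 0.5).
#' @return corrected `activity_matrix`.
#' @export
pleiotropy_correction <- function(activities, regulons, z,
                                  min_common = 25, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  stopifnot(inherits(z, "expression_matrix"))
  regs <- rownames(activities)
  genes <- rownames(z$values)
  U <- normal_scores(z$values)
  rownames(U) <- genes
  tset <- lapply(regulons[regs], function(reg)
    reg$target[reg$target %in% genes])
  partners <- lapply(regs, function(r) {
    others <- setdiff(regs, r)
    others[vapply(others, function(o)
      length(intersect(tset[[r]], tset[[o]])) >= min_common, logical(1))]
  })
  names(partners) <- regs
  out <- activities
  score_subset <- function(r, targets) {
    reg <- regulons[[r]]
    reg <- reg[reg$target %in% targets, , drop = FALSE]
    if (nrow(reg) == 0) return(rep(0, ncol(activities)))
    as.numeric(crossprod(reg$likelihood * reg$mode,
                         U[reg$target, , drop = FALSE])) /
      sqrt(sum(regulons[[r]]$likelihood[regulons[[r]]$target %in%
                                          unlist(tset[r])]^2))
  }
  for (r in regs) {
    prt <- partners[[r]]
    if (!length(prt)) next
    stronger <- abs(activities[prt, , drop = FALSE]) >
      matrix(abs(activities[r, ]), length(prt), ncol(activities), byrow = TRUE)
    pattern <- apply(stronger, 2, function(col) paste(which(col), collapse = ","))
    for (pat in unique(pattern)) {
      if (pat == "") next
      cols <- which(pattern == pat)
      strong_set <- prt[as.integer(strsplit(pat, ",")[[1]])]
      uniq <- setdiff(tset[[r]], unlist(tset[strong_set]))
      sc <- score_subset(r, uniq)
      out[r, cols] <- alpha * activities[r, cols] + (1 - alpha) * sc[cols]
    }
  }
  out
}

#' Infer regulator activities for an expression dataset
#'
#' Full activity pipeline: z-scale the expression matrix, score each
#' regulon, and apply the pleiotropy correction. Because the interactome is
#' an argument, a network inferred on one cohort can be applied to another:
#' interactome genes absent from the new dataset are dropped per regulon
#' (with a message) before the `min_targets` check.
#'
#' @param expr an [expression_matrix] in log2TPM (or any per-gene monotone
#'   unit; the scoring is rank-based within samples).
#' @param interactome an `interactome` from [network_to_interactome()].
#' @param min_targets minimum expressed targets per regulon (default 25).
#' @param pleiotropy apply the pleiotropy correction (default TRUE).
#' @param min_common,alpha correction parameters, see
#'   [pleiotropy_correction()].
#' @return an `activity_matrix`.
#' @export
infer_activities <- function(expr, interactome, min_targets = 25,
                             pleiotropy = TRUE, min_common = 25,
                             alpha = 0.5) {
  z <- if (expr$unit == "zscore") expr else zscale(expr)
  genes <- rownames(z$values)
  n_missing <- sum(vapply(interactome, function(reg)
    sum(!(reg$target %in% genes)), integer(1)))
  if (n_missing > 0)
    message(sprintf("%d interactome target(s) absent from expression; dropped",
                    n_missing))
  act <- activity_scores(z, interactome, min_targets = min_targets)
  if (pleiotropy)
    act <- pleiotropy_correction(act, interactome, z,
                                 min_common = min_common, alpha = alpha)
  act
}

#' Read / write regulon and activity tables
#'
#' Regulon TSV columns: `regulator`, `target`, `mode`, `likelihood`.
#' Activities are written as a regulator x sample TSV matrix.
#'
#' @param interactome an `interactome`; `x` an `activity_matrix`.
#' @param path file path.
#' @return readers return the corresponding object.
#' @export
write_regulon_tsv <- function(interactome, path) {
  df <- do.call(rbind, lapply(names(interactome), function(r)
    cbind(regulator = r, interactome[[r]])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regulon_tsv
#' @export
read_regulon_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(split(df[c("target", "mode", "likelihood")], df$regulator),
                function(d) { rownames(d) <- NULL; d })
  class(out) <- "interactome"
  out
}
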