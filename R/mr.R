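#' Train/test split of samples
#'
#' @param sample_ids character vector.
#' @param ratio training fraction (default 0.7).
#' @param seed RNG seed.
#' @return list with `train` and `test` id vectors; disjoint and exhaustive,
#'   with `length(train) == round(ratio * n)`.
#' @export
split_samples <- function(sample_ids, ratio = 0.7, seed = 1L) {
  n <- length(sample_ids)
  n_train <- round(ratio * n)
  with_seed(seed, {
    idx <- sample.int(n, n_train)
    list(train = sample_ids[sort(idx)], test = sample_ids[-sort(idx)])
  })
}

# Align an activity matrix (regulators x samples) and a phenotype vector,
# dropping samples with a missing phenotype.
align_xy <- function(activities, pheno, phenotype) {
  stopifnot(phenotype %in% names(pheno))
  shared <- intersect(colnames(activities), pheno$sample_id)
  y <- pheno[[phenotype]][match(shared, pheno$sample_id)]
  ok <- !is.na(y)
  X <- t(activities[, shared[ok], drop = FALSE])
  list(X = as.data.frame(X), y = y[ok], samples = shared[ok])
}

#' Cross-validated error curve over predictor counts
#'
#' For each repeat (with its own seed), a random forest on all predictors
#' ranks them by permutation importance; models are then refit on the top-p
#' predictors with p reduced sequentially by `step`, recording k-fold
#' cross-validated MSE. The returned curve gives the mean and sd of the CV
#' error over repeats at each predictor count.
#'
#' @param activities regulator x sample matrix (or any predictor matrix with
#'   predictors in rows).
#' @param pheno phenotype table with `sample_id` and the phenotype column.
#' @param phenotype phenotype column name.
#' @param step predictor-count decrement (default 5).
#' @param n_repeats repeats with distinct seeds (default 12).
#' @param cv_folds folds (default 5).
#' @param ntree trees per forest (default 500).
#' @param seed base seed; repeat i uses seed + i.
#' @return data.frame of class `cv_curve`: `n_predictors`, `mean_error`,
#'   `sd_error`.
#' @export
cv_error_curve <- function(activities, pheno, phenotype, step = 5,
                           n_repeats = 12, cv_folds = 5, ntree = 500,
                           seed = 1L) {
  xy <- align_xy(activities, pheno, phenotype)
  n <- length(xy$y)
  if (n < cv_folds) stop("fewer samples than CV folds")
  P <- ncol(xy$X)
  p_seq <- seq(P, 1, by = -step)
  err <- matrix(NA_real_, n_repeats, length(p_seq))
  for (rep_i in seq_len(n_repeats)) {
    with_seed(child_seed(seed, rep_i), {
      fit <- randomForest::randomForest(xy$X, xy$y, ntree = ntree,
                                        importance = TRUE)
      imp <- rank_importance(fit)
      folds <- sample(rep(seq_len(cv_folds), length.out = n))
      for (j in seq_along(p_seq)) {
        top <- imp$predictor[seq_len(p_seq[j])]
        mse <- numeric(cv_folds)
        for (f in seq_len(cv_folds)) {
          tr <- folds != f
          m <- randomForest::randomForest(xy$X[tr, top, drop = FALSE],
                                          xy$y[tr], ntree = ntree)
          pred <- predict(m, xy$X[!tr, top, drop = FALSE])
          mse[f] <- mean((pred - xy$y[!tr])^2)
        }
        err[rep_i, j] <- mean(mse)
      }
    })
  }
  out <- data.frame(n_predictors = p_seq,
                    mean_error = colMeans(err),
                    sd_error = apply(err, 2, sd))
  class(out) <- c("cv_curve", "data.frame")
  out
}

#' Choose a parsimonious predictor count from a CV curve
#'
#' One-standard-error rule: the smallest predictor count whose mean CV
#' error is within one sd (at the minimizer) of the minimum mean error.
#' The curve should be inspected alongside the returned count; callers may
#' override.
#'
#' @param curve a `cv_curve` from [cv_error_curve()].
#' @return integer predictor count K.
#' @export
select_mr_count <- function(curve) {
  stopifnot(all(c("n_predictors", "mean_error", "sd_error") %in% names(curve)))
  i_min <- which.min(curve$mean_error)
  thresh <- curve$mean_error[i_min] + curve$sd_error[i_min]
  ok <- curve$mean_error <= thresh
  as.integer(min(curve$n_predictors[ok]))
}

#' Permutation importance table from a random forest
#'
#' Percent increase in out-of-bag MSE upon permutation of each predictor,
#' i.e. `100 * (MSE_perm - MSE_oob) / MSE_oob` using the forest's raw
#' (unscaled) permutation importance, sorted descending with ties broken by
#' predictor id.
#'
#' @param forest_fit a [randomForest::randomForest] regression fit trained
#'   with `importance = TRUE`.
#' @return data.frame `(predictor, pct_inc_mse, rank)`.
#' @export
rank_importance <- function(forest_fit) {
  imp <- randomForest::importance(forest_fit, type = 1, scale = FALSE)
  mse_oob <- forest_fit$mse[length(forest_fit$mse)]
  pct <- 100 * imp[, 1] / mse_oob
  ord <- order(-pct, names(pct))
  data.frame(predictor = names(pct)[ord], pct_inc_mse = unname(pct[ord]),
             rank = seq_along(pct), stringsAsFactors = FALSE)
}

#' Train the final master-regulator model
#'
#' Splits the samples 70:30, ranks regulators by permutation importance on
#' the training split, restricts to the top K, trains the final forest and
#' evaluates Pearson correlation between predicted and observed phenotype
#' on both splits.
#'
#' @param activities regulator x sample matrix.
#' @param pheno phenotype table.
#' @param phenotype phenotype column name.
#' @param K number of master regulators to retain.
#' @param seed RNG seed (split, forests).
#' @param ratio training fraction (default 0.7).
#' @param ntree trees per forest (default 500).
#' @return list of class `mr_result`: `phenotype`, `mrs`, `importance`,
#'   `split`, `model`, `metrics` (r and p on train/test), `predictions`,
#'   `train_means`.
#' @export
train_final_model <- function(activities, pheno, phenotype, K, seed = 1L,
                              ratio = 0.7, ntree = 500) {
  xy <- align_xy(activities, pheno, phenotype)
  if (K > ncol(xy$X)) stop("K exceeds the number of available regulators")
  sp <- split_samples(xy$samples, ratio = ratio, seed = seed)
  tr <- xy$samples %in% sp$train
  with_seed(child_seed(seed, 99), {
    fit_all <- randomForest::randomForest(xy$X[tr, , drop = FALSE], xy$y[tr],
                                          ntree = ntree, importance = TRUE)
    imp <- rank_importance(fit_all)
    mrs <- imp$predictor[seq_len(K)]
    model <- randomForest::randomForest(xy$X[tr, mrs, drop = FALSE], xy$y[tr],
                                        ntree = ntree, importance = TRUE)
    pred_tr <- predict(model)   # OOB predictions on the training split
    pred_te <- predict(model, xy$X[!tr, mrs, drop = FALSE])
    ct_tr <- cor.test(pred_tr, xy$y[tr])
    ct_te <- cor.test(pred_te, xy$y[!tr])
    res <- list(phenotype = phenotype, mrs = mrs,
                importance = imp[imp$predictor %in% mrs, , drop = FALSE],
                split = sp, model = model,
                metrics = data.frame(
                  set = c("train", "test"),
                  r = c(unname(ct_tr$estimate), unname(ct_te$estimate)),
                  p = c(ct_tr$p.value, ct_te$p.value),
                  n = c(sum(tr), sum(!tr))),
                predictions = list(train = pred_tr, test = pred_te),
                train_means = colMeans(xy$X[tr, mrs, drop = FALSE]))
    class(res) <- "mr_result"
    res
  })
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("mr_result: %s, K = %d MRs\n", x$phenotype, length(x$mrs)))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Evaluate a master-regulator model on external data
#'
#' Predicts the phenotype in a validation cohort using only the MR set.
#' Regulators missing from the validation activity matrix are imputed with
#' their training means (with a warning).
#'
#' @param mr_result an `mr_result`.
#' @param activities_val validation regulator x sample matrix.
#' @param pheno_val validation phenotype table.
#' @return list with `r`, `p`, `n`, `predictions`.
#' @export
evaluate_model <- function(mr_result, activities_val, pheno_val) {
  phe <- mr_result$phenotype
  shared <- intersect(colnames(activities_val), pheno_val$sample_id)
  y <- pheno_val[[phe]][match(shared, pheno_val$sample_id)]
  ok <- !is.na(y)
  shared <- shared[ok]; y <- y[ok]
  X <- matrix(NA_real_, length(shared), length(mr_result$mrs),
              dimnames = list(shared, mr_result$mrs))
  have <- mr_result$mrs %in% rownames(activities_val)
  X[, have] <- t(activities_val[mr_result$mrs[have], shared, drop = FALSE])
  if (any(!have)) {
    warning(sprintf("%d regulator(s) missing from validation; mean-imputed",
                    sum(!have)))
    for (m in mr_result$mrs[!have]) X[, m] <- mr_result$train_means[m]
  }
  pred <- predict(mr_result$model, as.data.frame(X))
  ct <- cor.test(pred, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(y),
       predictions = pred)
}

#' Master-regulator overlap across phenotypes
#'
#' Counts, per regulator, the number of phenotypes whose MR set contains
#' it (the pleiotropy count).
#'
#' @param ... `mr_result` objects or plain character vectors of MR ids.
#' @return named integer vector, sorted by decreasing count then id.
#' @export
mr_overlap <- function(...) {
  sets <- lapply(list(...), function(x)
    if (inherits(x, "mr_result")) x$mrs else as.character(x))
  tab <- table(unlist(sets))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

#' Phenotype-stability sample filter
#'
#' Retains samples whose value in one column changed by less than
#' `max_rel_change` relative to a reference column — e.g. keep subjects
#' whose BMI at biopsy differs by under 10% from BMI at the time the
#' phenotype was measured.
#'
#' @param pheno phenotype table.
#' @param col,ref_col column names to compare.
#' @param max_rel_change relative-change bound (default 0.1).
#' @return filtered phenotype table.
#' @export
phenotype_stability_filter <- function(pheno, col, ref_col,
                                       max_rel_change = 0.1) {
  stopifnot(col %in% names(pheno), ref_col %in% names(pheno))
  rel <- abs(pheno[[col]] - pheno[[ref_col]]) / abs(pheno[[ref_col]])
  keep <- !is.na(rel) & rel < max_rel_change
  pheno[keep, , drop = FALSE]
}
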