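#' Cross-validation scheme
#'
#' Internal-validation scheme for retention models: leave-one-out (one
#' fold per training observation) or leave-k-percent-out (a seeded random
#' partition of the training set into disjoint folds of size
#' `ceiling(percent/100 * n)`, every observation held out exactly once per
#' repeat).
#'
#' @param kind `"loo"` or `"leave_k_percent_out"`.
#' @param percent held-out percentage for `"leave_k_percent_out"`
#'   (default 10).
#' @param n_repeats number of independent fold partitions (default 1);
#'   out-of-fold predictions are averaged over repeats.
#' @param seed integer seed for the fold partition.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("loo", "leave_k_percent_out"), percent = 10,
                      n_repeats = 1, seed = 1) {
  kind <- match.arg(kind)
  if (percent <= 0 || percent >= 100) stop("percent must be in (0, 100)")
  structure(list(kind = kind, percent = percent,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_scheme")
}

cv_folds <- function(n, scheme, repeat_offset = 0L) {
  if (scheme$kind == "loo") return(as.list(seq_len(n)))
  size <- ceiling(scheme$percent / 100 * n)
  perm <- with_seed(scheme$seed + repeat_offset, sample.int(n))
  unname(split(perm, ceiling(seq_along(perm) / size)))
}

#' Squared Pearson correlation between observed and predicted
#'
#' The calibration/validation R-squared used throughout the package:
#' the square of the Pearson correlation coefficient between observed and
#' predicted values. Symmetric in its arguments and invariant to affine
#' rescaling of either.
#'
#' @param y_obs,y_hat numeric vectors, length >= 3, neither constant.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(y_obs, y_hat) {
  if (length(y_obs) < 3 || length(y_obs) != length(y_hat))
    stop("need two equal-length vectors of length >= 3")
  if (stats::sd(y_obs) == 0 || stats::sd(y_hat) == 0)
    stop("correlation undefined for constant input")
  stats::cor(y_obs, y_hat)^2
}

#' Adjusted R-squared
#'
#' Standard degrees-of-freedom adjustment
#' `1 - (1 - r2) (n - 1) / (n - p - 1)`.
#'
#' @param r2 unadjusted R-squared.
#' @param n observations.
#' @param p model descriptors (requires `n > p + 1`).
#' @return Adjusted R-squared.
#' @export
adjusted_r_squared <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R-squared requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Root mean square error
#'
#' `sqrt(mean((y_hat - y_obs)^2))`.
#'
#' @param y_obs,y_hat numeric vectors of equal nonzero length.
#' @return RMSE (>= 0), same units as the response.
#' @export
rmse <- function(y_obs, y_hat) {
  if (!length(y_obs) || length(y_obs) != length(y_hat))
    stop("need two equal-length nonempty vectors")
  sqrt(mean((y_hat - y_obs)^2))
}

#' Spearman rank correlation
#'
#' Pearson correlation of the rank vectors, ties receiving average ranks;
#' measures how faithfully a model reproduces the experimental elution
#' order. Invariant under strictly monotone transforms of either argument.
#'
#' @param y_obs,y_hat numeric vectors, length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(y_obs, y_hat) {
  if (length(y_obs) < 3 || length(y_obs) != length(y_hat))
    stop("need two equal-length vectors of length >= 3")
  stats::cor(rank(y_obs, ties.method = "average"),
             rank(y_hat, ties.method = "average"))
}

#' Cross-validated predictions for a descriptor mask
#'
#' For each fold of the scheme, refits the SVR on the remaining training
#' rows (re-standardizing within the fold) and predicts the held-out rows;
#' returns one out-of-fold prediction per training observation (averaged
#' over repeats when `n_repeats > 1`). Deterministic given the scheme
#' seed.
#'
#' @param dataset a [qsrr_dataset] with a nonempty training split.
#' @param mask logical vector over the dataset's descriptors (or integer
#'   column indices) selecting the model descriptors.
#' @param config an [svr_config].
#' @param scheme a [cv_scheme].
#' @return Numeric vector of out-of-fold predictions, aligned with and
#'   named by the training observations.
#' @export
cross_validate <- function(dataset, mask, config = svr_config(),
                           scheme = cv_scheme("loo")) {
  stopifnot(inherits(dataset, "qsrr_dataset"), inherits(scheme, "cv_scheme"))
  tr <- which(dataset$split == "train")
  if (!length(tr)) stop("dataset has no training split")
  cols <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (!length(cols)) stop("mask selects no descriptors")
  X <- dataset$X[tr, cols, drop = FALSE]
  y <- dataset$y[tr]
  n <- length(y)
  acc <- matrix(NA_real_, n, scheme$n_repeats)
  for (rep_i in seq_len(scheme$n_repeats)) {
    folds <- cv_folds(n, scheme, repeat_offset = (rep_i - 1L) * 1000L)
    for (fold in folds) {
      if (n - length(fold) < 2)
        stop("cross-validation fold leaves fewer than 2 training rows")
      fit <- fit_svr(X[-fold, , drop = FALSE], y[-fold], config)
      acc[fold, rep_i] <- predict(fit, X[fold, , drop = FALSE])
    }
  }
  stats::setNames(rowMeans(acc), dataset$ids[tr])
}

#' Performance metrics for a prediction table
#'
#' Computes the full metric suite of a retention model from a prediction
#' table: calibration, cross-validation and external-prediction
#' R-squared / RMSE / Spearman rho, plus adjusted calibration R-squared.
#' Each metric is present exactly when its prediction column is populated.
#' All definitions are correlation-based: `q2` is the squared Pearson
#' correlation between the observed training values and their out-of-fold
#' predictions.
#'
#' @param predictions a `qsrr_predictions` table (see
#'   [prediction_table()]).
#' @param p_descriptors number of model descriptors (for the adjusted
#'   R-squared); `NULL` to skip the adjustment.
#' @return An object of class `qsrr_metrics`: a list with elements
#'   `r2_cal`, `r2_adj`, `q2_cv`, `r2_pred`, `rmse_cal`, `rmse_cv`,
#'   `rmse_pred`, `rho_cal`, `rho_cv`, `rho_pred`, `n_train`, `n_test`,
#'   `p_descriptors` (absent metrics are `NA`). Values are kept at full
#'   precision; rounding to 3 decimals happens only when printing or
#'   exporting via [report_table5()].
#' @export
evaluate_model <- function(predictions, p_descriptors = NULL) {
  stopifnot(inherits(predictions, "qsrr_predictions") ||
              is.data.frame(predictions))
  tr <- predictions[predictions$set == "train", ]
  te <- predictions[predictions$set == "test", ]
  has_cal <- nrow(tr) > 0 && !all(is.na(tr$predicted))
  has_cv <- nrow(tr) > 0 && !all(is.na(tr$cv_predicted))
  has_pred <- nrow(te) > 0 && !all(is.na(te$predicted))
  if (!has_cal && !has_cv && !has_pred)
    stop("prediction table has no populated prediction column")
  m <- list(r2_cal = NA_real_, r2_adj = NA_real_, q2_cv = NA_real_,
            r2_pred = NA_real_, rmse_cal = NA_real_, rmse_cv = NA_real_,
            rmse_pred = NA_real_, rho_cal = NA_real_, rho_cv = NA_real_,
            rho_pred = NA_real_, n_train = nrow(tr), n_test = nrow(te),
            p_descriptors = p_descriptors %||% NA_integer_)
  if (has_cal) {
    m$r2_cal <- r_squared(tr$observed, tr$predicted)
    m$rmse_cal <- rmse(tr$observed, tr$predicted)
    m$rho_cal <- spearman_rho(tr$observed, tr$predicted)
    if (!is.null(p_descriptors) && nrow(tr) > p_descriptors + 1)
      m$r2_adj <- adjusted_r_squared(m$r2_cal, nrow(tr), p_descriptors)
  }
  if (has_cv) {
    m$q2_cv <- r_squared(tr$observed, tr$cv_predicted)
    m$rmse_cv <- rmse(tr$observed, tr$cv_predicted)
    m$rho_cv <- spearman_rho(tr$observed, tr$cv_predicted)
  }
  if (has_pred) {
    m$r2_pred <- r_squared(te$observed, te$predicted)
    m$rmse_pred <- rmse(te$observed, te$predicted)
    m$rho_pred <- spearman_rho(te$observed, te$predicted)
  }
  structure(m, class = "qsrr_metrics")
}

#' @export
print.qsrr_metrics <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "---", sprintf("%.3f", v))
  cat("QSRR model performance (n_train=", x$n_train, ", n_test=",
      x$n_test, ", p=", x$p_descriptors, ")\n", sep = "")
  cat("  calibration:  R2=", fmt(x$r2_cal), "  R2_adj=", fmt(x$r2_adj),
      "  RMSE=", fmt(x$rmse_cal), "  rho=", fmt(x$rho_cal), "\n", sep = "")
  cat("  cross-val:    q2=", fmt(x$q2_cv), "  RMSE=", fmt(x$rmse_cv),
      "  rho=", fmt(x$rho_cv), "\n", sep = "")
  cat("  external:     R2=", fmt(x$r2_pred), "  RMSE=", fmt(x$rmse_pred),
      "  rho=", fmt(x$rho_pred), "\n", sep = "")
  invisible(x)
}
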