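#' Scramble a response vector
#'
#' Uniform random permutation of `y` with the descriptor matrix left
#' untouched — the core move of Y-randomization. Uses the current RNG
#' stream unless a seed is given.
#'
#' @param y numeric vector, length >= 2.
#' @param seed optional integer seed.
#' @return Permuted copy of `y`.
#' @export
scramble_response <- function(y, seed = NULL) {
  if (length(y) < 2) stop("need at least 2 values to scramble")
  if (!is.null(seed)) with_seed(seed, y[sample.int(length(y))])
  else y[sample.int(length(y))]
}

#' cRp^2 chance-correlation statistic
#'
#' `cRp^2 = sqrt(R2_original) * sqrt(R2_original - R2_y_mean)`, comparing
#' the original model's squared correlation with the mean squared
#' correlation of response-scrambled models. Values above 0.5 indicate
#' the original model is unlikely to be a chance correlation. When the
#' original model is no better than the scrambled average
#' (`R2_original < R2_y_mean`) the statistic is undefined; `NA` is
#' returned with attribute `flagged = TRUE` rather than an error.
#'
#' @param r2_original squared correlation of the original model, in
#'   `[0, 1]`.
#' @param r2_y_mean mean squared correlation of the scrambled models, in
#'   `[0, 1]`.
#' @return The statistic, or flagged `NA` when the margin is negative.
#' @export
c_rp2 <- function(r2_original, r2_y_mean) {
  if (r2_original < 0 || r2_original > 1 || r2_y_mean < 0 || r2_y_mean > 1)
    stop("both arguments must lie in [0, 1]")
  if (r2_original < r2_y_mean)
    return(structure(NA_real_, flagged = TRUE))
  sqrt(r2_original) * sqrt(r2_original - r2_y_mean)
}

#' Y-randomization validation of an FFA-SVR model
#'
#' Rebuilds the model on response-scrambled training data `n_iterations`
#' times and compares the original model's statistics against the
#' scrambled distribution via [c_rp2()]. In `"full"` mode each iteration
#' reruns the complete protocol — firefly descriptor selection, SVR fit
#' and cross-validation — on the scrambled response; `"fixed_mask"` mode
#' reuses the original descriptor mask and skips re-selection (orders of
#' magnitude cheaper; the mode is recorded in the report). `"auto"`
#' selects `"full"` when `n_iterations <= 20` and `"fixed_mask"`
#' otherwise.
#'
#' @param dataset a filtered [qsrr_dataset] with a training split.
#' @param ffa_config a [firefly_config] (used for selection in `"full"`
#'   mode and for the original model when no `mask` is given).
#' @param svr_config an [svr_config].
#' @param cv_scheme a [cv_scheme].
#' @param n_iterations number of scrambles (default 100).
#' @param seed master seed; per-iteration seeds are derived by counter.
#' @param mode `"auto"`, `"full"` or `"fixed_mask"`.
#' @param mask optional logical mask of the original model's descriptors;
#'   computed by [select_descriptors()] when omitted.
#' @return An object of class `qsrr_yrand`: per-iteration scrambled
#'   statistics (`r2_y`, `q2_y`), their means, the original `r2` and
#'   `q2`, and `crp2_cal` / `crp2_cv` computed from calibration and
#'   cross-validation statistics respectively.
#' @export
run_y_randomization <- function(dataset, ffa_config = firefly_config(),
                                svr_config = fireflyQSRR::svr_config(),
                                cv_scheme = fireflyQSRR::cv_scheme("loo"),
                                n_iterations = 100, seed = 1,
                                mode = c("auto", "full", "fixed_mask"),
                                mask = NULL) {
  mode <- match.arg(mode)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (mode == "auto") mode <- if (n_iterations <= 20) "full" else "fixed_mask"
  tr <- dataset$split == "train"
  if (!any(tr)) stop("dataset has no training split")

  if (is.null(mask)) {
    sel <- select_descriptors(dataset, ffa_config, svr_config, cv_scheme)
    mask <- sel$mask
  }
  model_stats <- function(ds, m) {
    Xtr <- ds$X[ds$split == "train", which(m), drop = FALSE]
    ytr <- ds$y[ds$split == "train"]
    fit <- fit_svr(Xtr, ytr, svr_config)
    cvp <- cross_validate(ds, m, svr_config, cv_scheme)
    c(r2 = tryCatch(r_squared(ytr, predict(fit, Xtr)),
                    error = function(e) NA_real_),
      q2 = tryCatch(r_squared(ytr, cvp), error = function(e) NA_real_))
  }
  orig <- model_stats(dataset, mask)

  records <- matrix(NA_real_, n_iterations, 2,
                    dimnames = list(NULL, c("r2_y", "q2_y")))
  for (i in seq_len(n_iterations)) {
    seed_i <- seed + i
    ds_i <- dataset
    ds_i$y[tr] <- scramble_response(dataset$y[tr], seed = seed_i)
    mask_i <- if (mode == "full") {
      cfg_i <- ffa_config
      cfg_i$seed <- seed_i
      select_descriptors(ds_i, cfg_i, svr_config, cv_scheme)$mask
    } else mask
    records[i, ] <- model_stats(ds_i, mask_i)
  }
  r2y_mean <- mean(records[, "r2_y"], na.rm = TRUE)
  q2y_mean <- mean(records[, "q2_y"], na.rm = TRUE)
  structure(
    list(n_iterations = n_iterations, mode = mode,
         records = as.data.frame(records),
         r2_original = unname(orig["r2"]), q2_original = unname(orig["q2"]),
         r2_y_mean = r2y_mean, q2_y_mean = q2y_mean,
         crp2_cal = c_rp2(unname(orig["r2"]), max(r2y_mean, 0)),
         crp2_cv = if (is.na(orig["q2"]) || is.na(q2y_mean)) NA_real_
                   else c_rp2(unname(orig["q2"]), max(min(q2y_mean, 1), 0)),
         seed = seed),
    class = "qsrr_yrand")
}

#' @export
print.qsrr_yrand <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "flagged/NA" else sprintf("%.3f", v)
  cat("Y-randomization (", x$n_iterations, " iterations, ", x$mode,
      " mode)\n", sep = "")
  cat("  original R2 = ", fmt(x$r2_original), ", scrambled mean R2_y = ",
      fmt(x$r2_y_mean), "\n", sep = "")
  cat("  cRp2 (calibration) = ", fmt(x$crp2_cal),
      ", cRp2 (cross-validation) = ", fmt(x$crp2_cv), "\n", sep = "")
  invisible(x)
}
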