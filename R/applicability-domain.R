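#' Leverage of observations in descriptor space
#'
#' Hat-matrix leverage `h(x) = x~' (X~' X~)^-1 x~` on the
#' intercept-augmented, training-standardized design built from the
#' model's selected descriptors. Training leverages are the hat-matrix
#' diagonal: each lies in `[1/n, 1]` and they sum to `p + 1`.
#'
#' @param X_train numeric matrix of the training rows over the selected
#'   descriptors (`n_train > p + 1`).
#' @param X_query optional matrix of query rows (same columns); defaults
#'   to the training rows themselves.
#' @param standardize z-score using training statistics first (default
#'   `TRUE`); leverages of training points are invariant to affine
#'   column rescaling either way.
#' @return Numeric vector of leverages for the query rows.
#' @export
leverage <- function(X_train, X_query = NULL, standardize = TRUE) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train); p <- ncol(X_train)
  if (n <= p + 1) stop("leverage requires n_train > p + 1")
  center <- rep(0, p); scl <- rep(1, p)
  if (standardize) {
    center <- colMeans(X_train)
    scl <- apply(X_train, 2L, stats::sd)
    scl[!is.finite(scl) | scl <= .Machine$double.eps] <- 1
  }
  std <- function(M) cbind(1, sweep(sweep(as.matrix(M), 2L, center),
                                    2L, scl, "/"))
  Xt <- std(X_train)
  XtX <- crossprod(Xt)
  inv <- tryCatch(solve(XtX), error = function(e)
    stop("singular design: the selected descriptors are collinear; ",
         "drop redundant columns"))
  Q <- std(if (is.null(X_query)) X_train else X_query)
  rowSums((Q %*% inv) * Q)
}

#' Leverage warning threshold
#'
#' `h* = 3 (p + 1) / n_train`, the customary Williams-plot warning limit:
#' three times the average training leverage.
#'
#' @param n_train training observations (`> p + 1`).
#' @param p number of model descriptors.
#' @return The threshold `h*`.
#' @examples
#' leverage_threshold(16, 5)  # 1.125
#' leverage_threshold(30, 3)  # 0.4
#' @export
leverage_threshold <- function(n_train, p) {
  if (n_train <= p + 1) stop("requires n_train > p + 1")
  3 * (p + 1) / n_train
}

#' Standardized residuals
#'
#' Residuals divided by their sample standard deviation (n - 1
#' denominator); the Williams plot flags observations with
#' `|standardized residual| > 3`.
#'
#' @param residuals numeric vector, length >= 3, not all equal.
#' @return Scaled residuals.
#' @export
standardized_residuals <- function(residuals) {
  if (length(residuals) < 3) stop("need at least 3 residuals")
  s <- stats::sd(residuals)
  if (!is.finite(s) || s <= .Machine$double.eps)
    stop("residual standard deviation is zero")
  residuals / s
}

#' Williams-plot applicability-domain report
#'
#' Assembles the per-observation table behind a Williams plot: leverage
#' `h` against standardized residual, with the training set represented
#' by its cross-validation residuals and the test set by its external
#' prediction residuals. Residuals from both sets are pooled before
#' scaling so they share one standard-deviation unit. An observation is
#' in-domain iff `h <= h*` and `|standardized residual| <= 3`.
#'
#' @param X_train training rows over the selected descriptors.
#' @param resid_train training residuals (typically cross-validation
#'   residuals, `predicted - experimental`).
#' @param X_test,resid_test optional test rows and residuals.
#' @param ids optional observation ids (train then test).
#' @return An object of class `qsrr_ad`: a data frame with columns `id`,
#'   `set`, `h`, `r_std`, `in_domain`, plus attributes `h_star`, `n_train`
#'   and `p`.
#' @export
williams_data <- function(X_train, resid_train, X_test = NULL,
                          resid_test = NULL, ids = NULL) {
  X_train <- as.matrix(X_train)
  n_tr <- nrow(X_train); p <- ncol(X_train)
  if (length(resid_train) != n_tr) stop("resid_train length mismatch")
  h <- leverage(X_train)
  set <- rep("train", n_tr)
  resid <- resid_train
  if (!is.null(X_test)) {
    X_test <- as.matrix(X_test)
    if (length(resid_test) != nrow(X_test))
      stop("resid_test length mismatch")
    h <- c(h, leverage(X_train, X_test))
    set <- c(set, rep("test", nrow(X_test)))
    resid <- c(resid, resid_test)
  }
  r_std <- standardized_residuals(resid)
  h_star <- leverage_threshold(n_tr, p)
  out <- data.frame(
    id = ids %||% sprintf("obs%03d", seq_along(h)),
    set = set, h = h, r_std = r_std,
    in_domain = h <= h_star & abs(r_std) <= 3,
    stringsAsFactors = FALSE)
  structure(out, h_star = h_star, n_train = n_tr, p = p,
            class = c("qsrr_ad", "data.frame"))
}

#' Plot a Williams applicability-domain diagram
#'
#' Leverage against standardized residual with the `h*` and +/-3 warning
#' limits; circles are training (cross-validation) points, diamonds test
#' points.
#'
#' @param ad a `qsrr_ad` report from [williams_data()].
#' @param ... passed to [graphics::plot()].
#' @return `ad`, invisibly.
#' @export
plot_williams <- function(ad, ...) {
  stopifnot(inherits(ad, "qsrr_ad"))
  h_star <- attr(ad, "h_star")
  graphics::plot(ad$h, ad$r_std,
                 pch = ifelse(ad$set == "train", 1, 5),
                 xlab = "leverage h", ylab = "standardized residual",
                 xlim = c(0, max(ad$h, h_star) * 1.1),
                 ylim = range(c(ad$r_std, -3.5, 3.5)), ...)
  graphics::abline(h = c(-3, 3), lty = 2)
  graphics::abline(v = h_star, lty = 2)
  invisible(ad)
}

#' Hotelling T-squared applicability domain
#'
#' Multivariate distance of query points from the training centroid,
#' `T2(x) = (x - xbar)' S^-1 (x - xbar)` with training mean and
#' covariance, compared against the F-distribution critical value
#' `p (n - 1) / (n - p) * F(1 - alpha; p, n - p)`.
#'
#' @param X_train training rows over the selected descriptors
#'   (`n_train > p`).
#' @param X_query optional query rows; defaults to the training rows.
#' @param alpha significance level (default 0.05).
#' @return A list with `t2` (per query row), `critical` and `flagged`
#'   (`t2 > critical`).
#' @export
hotelling_t2 <- function(X_train, X_query = NULL, alpha = 0.05) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train); p <- ncol(X_train)
  if (n <= p) stop("Hotelling T2 requires n_train > p")
  S <- stats::cov(X_train)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular training covariance; drop collinear descriptors"))
  xbar <- colMeans(X_train)
  Q <- as.matrix(if (is.null(X_query)) X_train else X_query)
  D <- sweep(Q, 2L, xbar)
  t2 <- rowSums((D %*% Sinv) * D)
  crit <- p * (n - 1) / (n - p) * stats::qf(1 - alpha, p, n - p)
  list(t2 = t2, critical = crit, flagged = t2 > crit)
}
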