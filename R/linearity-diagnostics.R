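#' Augmented partial residuals for one descriptor
#'
#' Fits `y = b0 + X b + c x_j^2` by least squares and returns the
#' augmented partial residual `e_i + b_j x_ij + c x_ij^2` paired with the
#' descriptor value, sorted ascending by `x_j`. Plotting the series
#' against `x_j` (an APARP) exposes curvature in the relationship between
#' the response and descriptor `j` after adjusting for the other columns;
#' when the fitted quadratic coefficient is zero it reduces to the
#' ordinary partial residual.
#'
#' @param y response vector.
#' @param X descriptor matrix (`n > p + 2`).
#' @param j descriptor column index.
#' @return A data frame with columns `x` and `apr` (sorted by `x`), with
#'   attributes `b_j` (linear coefficient) and `c_quad` (quadratic
#'   coefficient).
#' @export
aparp <- function(y, X, j) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) stop("APARP requires n > p + 2")
  if (j < 1 || j > p) stop("descriptor index out of range")
  xj <- X[, j]
  design <- cbind(X, xj2 = xj^2)
  fit <- stats::lm.fit(cbind(1, design), y)
  if (any(is.na(fit$coefficients)))
    stop("singular design in APARP fit; drop collinear descriptors")
  b_j <- fit$coefficients[1 + j]
  c_quad <- fit$coefficients[length(fit$coefficients)]
  apr <- fit$residuals + b_j * xj + c_quad * xj^2
  ord <- order(xj)
  structure(data.frame(x = xj[ord], apr = apr[ord]),
            b_j = unname(b_j), c_quad = unname(c_quad))
}

#' Durbin-Watson statistic with a normal-approximation p-value
#'
#' `DW = sum_{i>=2} (e_i - e_{i-1})^2 / sum e_i^2` on a residual series in
#' a meaningful order (here: ordered by a descriptor value, so that
#' curvature shows up as positive serial correlation). The statistic is
#' bounded in `[0, 4]` and centers near 2 for exchangeable residuals. The
#' p-value for positive serial correlation uses the normal approximation
#' `DW ~ N(2 - 2/n, 4/n)` under the null; adequate at the sample sizes
#' this package targets, and both decision quantities are returned so the
#' caller can apply other thresholds.
#'
#' @param ordered_residuals residual series, length >= 6, not all zero.
#' @return A list with `statistic`, `p_value` (one-sided, positive serial
#'   correlation) and `n`.
#' @export
durbin_watson <- function(ordered_residuals) {
  e <- as.numeric(ordered_residuals)
  n <- length(e)
  if (n < 6) stop("Durbin-Watson needs at least 6 residuals")
  if (all(e == 0)) stop("all residuals are zero")
  dw <- sum(diff(e)^2) / sum(e^2)
  mu <- 2 - 2 / n
  sigma <- 2 / sqrt(n)
  list(statistic = dw, p_value = stats::pnorm((dw - mu) / sigma), n = n)
}

#' Linearity screen for a descriptor table
#'
#' Decides between linear and nonlinear modeling of a retention dataset.
#' For every (non-degenerate) descriptor the response is regressed on the
#' descriptor alone, the residuals are ordered by the descriptor value
#' and tested for positive serial correlation with [durbin_watson()] —
#' curvature that a straight line misses leaves runs of same-signed
#' residuals along the descriptor axis. (This is the augmented
#' partial-residual series of [aparp()] after removal of its own linear
#' trend.) Per-descriptor p-values are Bonferroni-adjusted; the verdict
#' is `"nonlinear"` iff the smallest adjusted p-value is below `alpha`.
#'
#' @param dataset a filtered [qsrr_dataset].
#' @param alpha significance level (default 0.05).
#' @return An object of class `qsrr_linearity`: `verdict`, `dw_statistic`
#'   and `p_value` (of the most significant descriptor, adjusted), and a
#'   `per_descriptor` data frame with raw and adjusted p-values.
#' @export
linearity_screen <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "qsrr_dataset"))
  X <- dataset$X; y <- dataset$y
  p <- ncol(X)
  if (p < 1) stop("dataset has no descriptors")
  res <- lapply(seq_len(p), function(j) {
    xj <- X[, j]
    if (stats::sd(xj) <= .Machine$double.eps) return(NULL)
    fit <- stats::lm.fit(cbind(1, xj), y)
    e <- fit$residuals[order(xj)]
    if (all(abs(e) < 1e-12)) return(NULL)   # exact fit: nothing to test
    dw <- durbin_watson(e)
    data.frame(descriptor = dataset$descriptor_names[j],
               dw = dw$statistic, p_raw = dw$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  if (is.null(tab) || !nrow(tab))
    stop("no testable descriptors (all constant or exact fits)")
  tab$p_adj <- pmin(tab$p_raw * nrow(tab), 1)
  best <- which.min(tab$p_adj)
  structure(
    list(verdict = if (tab$p_adj[best] < alpha) "nonlinear" else "linear",
         dw_statistic = tab$dw[best], p_value = tab$p_adj[best],
         alpha = alpha, per_descriptor = tab),
    class = "qsrr_linearity")
}

#' @export
print.qsrr_linearity <- function(x, ...) {
  cat("Linearity screen: verdict ", x$verdict,
      " (min adjusted p = ", format(x$p_value, digits = 3),
      ", DW = ", format(x$dw_statistic, digits = 4),
      ", alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}
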