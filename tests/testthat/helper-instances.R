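# Shared synthetic-instance builders used across test files.

# Planted-signal instance with the response rescaled to a retention-factor
# like range (center ~1.2, sd ~0.45) so the default SVR operating point
# (C = 1, epsilon = 0.01) sees realistic magnitudes.
retention_like_instance <- function(seed, n = 40, p = 12, k_informative = 2,
                                    noise_sd = 0.05, link = "rbf_mixture",
                                    test_fraction = 0.2) {
  spec <- synthetic_spec(n = n, p = p,
                         informative_idx = seq_len(k_informative),
                         link = link, noise_sd = noise_sd, seed = seed)
  ds <- synthesize_dataset(spec, test_fraction = test_fraction)
  y0 <- attr(ds, "y_noiseless")
  sc <- 0.45 / max(sd(y0), .Machine$double.eps)
  sh <- 1.2 - mean(y0) * sc
  ds$y <- pmax(ds$y * sc + sh, 0)
  attr(ds, "y_noiseless") <- y0 * sc + sh
  ds
}

# Pure-noise (null) instance: descriptors with no relationship to y.
null_instance <- function(seed, n = 24, p = 8) {
  spec <- synthetic_spec(n = n, p = p, informative_idx = 1,
                         link = "linear", beta = 0 * 1, noise_sd = 1,
                         seed = seed)
  X <- generate_descriptors(spec)
  set.seed(seed + 5000L)
  y <- rnorm(n, mean = 1, sd = 0.3)
  qsrr_dataset(X, y, sprintf("null%03d", seq_len(n)), split = "train")
}

# Independent quadratic-programming solution of the epsilon-SVR dual
# (RBF kernel, no standardization) via the interior-point solver in
# kernlab. Used as an oracle against the package's fit.
svr_qp_oracle <- function(X, y, C, eps, gamma) {
  X <- as.matrix(X)
  n <- length(y)
  K <- exp(-gamma * as.matrix(dist(X))^2)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  cvec <- c(eps - y, eps + y)
  A <- matrix(rep(c(1, -1), each = n), 1)
  sol <- kernlab::ipop(cvec, H, A, b = 0, l = rep(0, 2 * n),
                       u = rep(C, 2 * n), r = 0, sigf = 9, maxiter = 200)
  u <- kernlab::primal(sol)
  beta <- u[1:n] - u[(n + 1):(2 * n)]
  f0 <- drop(K %*% beta)
  free <- which(u[1:n] > 1e-6 * C & u[1:n] < C * (1 - 1e-6))
  freestar <- which(u[(n + 1):(2 * n)] > 1e-6 * C &
                      u[(n + 1):(2 * n)] < C * (1 - 1e-6))
  bs <- c(y[free] - eps - f0[free], y[freestar] + eps - f0[freestar])
  b <- if (length(bs)) stats::median(bs) else stats::median(y - f0)
  function(Xq) {
    Xq <- as.matrix(Xq)
    an <- rowSums(Xq^2); bn <- rowSums(X^2)
    d2 <- pmax(outer(an, bn, "+") - 2 * tcrossprod(Xq, X), 0)
    drop(exp(-gamma * d2) %*% beta) + b
  }
}
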