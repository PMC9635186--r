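#' Specification of a synthetic QSRR instance
#'
#' Describes a simulated descriptor matrix and response with the
#' statistical structure retention modeling has to cope with: many
#' collinear nuisance descriptors, a small planted set of informative
#' ones, a smooth (optionally nonlinear) link and additive Gaussian
#' noise. The generator stands in for proprietary descriptor funds whose
#' values are not published.
#'
#' @param n observations (`>= 4`).
#' @param p descriptors (`>= 2`).
#' @param informative_idx indices of the planted informative descriptors
#'   (at least 1, fewer than `p`).
#' @param block_correlation within-block descriptor correlation in
#'   `[0, 1)`; blocks are equicorrelated.
#' @param block_size descriptors per correlated block; default one block
#'   spanning all `p` columns.
#' @param link `"linear"` (`y = X beta + eps`, `beta` nonzero only on the
#'   informative columns) or `"rbf_mixture"` (a Gaussian-bump mixture over
#'   the informative sub-vector; smooth and nonlinear, matching the
#'   inductive bias of an RBF-kernel learner).
#' @param noise_sd response noise standard deviation (same units as `k`).
#' @param covariate_mode `"none"` or `"mobile_phase_percent"`: appends a
#'   three-level mobile-phase percentage column (levels 30/45/50, scaled
#'   to `[0, 1]` internally) with an additive monotone effect on the
#'   response, emulating an organic-modifier design.
#' @param beta linear-link coefficients for the informative columns
#'   (recycled; default 1).
#' @param n_centers number of Gaussian bumps for the `rbf_mixture` link.
#' @param seed integer seed; the whole module is deterministic given the
#'   spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, p, informative_idx,
                           block_correlation = 0, block_size = NULL,
                           link = c("rbf_mixture", "linear"),
                           noise_sd = 0.05,
                           covariate_mode = c("none", "mobile_phase_percent"),
                           beta = 1, n_centers = 3, seed = 1) {
  link <- match.arg(link)
  covariate_mode <- match.arg(covariate_mode)
  if (n < 4 || p < 2) stop("need n >= 4 and p >= 2")
  informative_idx <- as.integer(informative_idx)
  if (length(informative_idx) < 1L || length(informative_idx) >= p ||
      any(informative_idx < 1L | informative_idx > p))
    stop("informative_idx must name at least 1 and fewer than p columns")
  if (block_correlation < 0 || block_correlation >= 1)
    stop("block_correlation must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(n = as.integer(n), p = as.integer(p),
         informative_idx = informative_idx,
         block_correlation = block_correlation,
         block_size = as.integer(block_size %||% p),
         link = link, noise_sd = noise_sd,
         covariate_mode = covariate_mode,
         beta = beta, n_centers = as.integer(n_centers),
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Generate a synthetic descriptor matrix
#'
#' Draws standard-normal descriptors in equicorrelated blocks: within a
#' block of size `block_size` every pair of columns has correlation
#' `block_correlation`; columns in different blocks are independent.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec].
#' @return An `n x p` numeric matrix with columns `D001`, `D002`, ...
#' @export
generate_descriptors <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    rho <- spec$block_correlation
    blocks <- split(seq_len(spec$p),
                    ceiling(seq_len(spec$p) / spec$block_size))
    X <- matrix(NA_real_, spec$n, spec$p)
    for (idx in blocks) {
      z <- stats::rnorm(spec$n)            # shared block factor
      eps <- matrix(stats::rnorm(spec$n * length(idx)), spec$n)
      X[, idx] <- sqrt(rho) * z + sqrt(1 - rho) * eps
    }
    colnames(X) <- sprintf("D%03d", seq_len(spec$p))
    X
  })
}

#' Generate a synthetic response with ground truth
#'
#' Builds the response from the informative columns of `X` under the
#' spec's link, adds the optional monotone mobile-phase term and Gaussian
#' noise. For `link = "linear"`, `y = X beta + eps` with `beta` nonzero
#' only on the informative columns. For `link = "rbf_mixture"`,
#' `y = sum_m w_m exp(-||x_S - c_m||^2 / (2 l^2)) + eps` over the
#' informative sub-vector `x_S`, with centers `c_m` drawn from the data
#' rows and bandwidth `l` the median pairwise distance of the informative
#' sub-vectors.
#'
#' @param X descriptor matrix (as from [generate_descriptors()]; if a
#'   mobile-phase covariate is requested it must be the last column,
#'   scaled to `[0, 1]`).
#' @param spec a [synthetic_spec].
#' @return A list with `y`, `y_noiseless` and `ground_truth` (informative
#'   indices and link parameters).
#' @export
generate_response <- function(X, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  idx <- spec$informative_idx
  if (any(idx > ncol(X))) stop("informative_idx outside the columns of X")
  with_seed(spec$seed + 1L, {
    S <- X[, idx, drop = FALSE]
    if (spec$link == "linear") {
      beta <- rep_len(spec$beta, length(idx))
      signal <- drop(S %*% beta)
      params <- list(beta = beta)
    } else {
      centers <- S[sample.int(nrow(S), spec$n_centers, replace = TRUE), ,
                   drop = FALSE]
      ell <- stats::median(stats::dist(S))
      if (!is.finite(ell) || ell <= 0) ell <- 1
      weights <- stats::runif(spec$n_centers, 0.5, 1.5)
      K <- exp(-as.matrix(fields_dist2(S, centers)) / (2 * ell^2))
      signal <- drop(K %*% weights)
      params <- list(centers = centers, weights = weights, ell = ell)
    }
    if (spec$covariate_mode == "mobile_phase_percent") {
      mp <- X[, ncol(X)]
      # lower organic-modifier percentage retains analytes longer
      signal <- signal + 1.5 * (1 - mp)
      params$mobile_phase_coef <- 1.5
    }
    y_noiseless <- signal
    y <- y_noiseless + stats::rnorm(length(signal), 0, spec$noise_sd)
    list(y = y, y_noiseless = y_noiseless,
         ground_truth = c(list(informative_idx = idx, link = spec$link),
                          params))
  })
}

# squared euclidean distances between rows of A and rows of B
fields_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Generate a complete synthetic QSRR dataset
#'
#' Runs [generate_descriptors()] and [generate_response()], wraps the
#' result in a [qsrr_dataset] and assigns a train/test split stratified by
#' response quantile so both sets share the response distribution.
#'
#' @param spec a [synthetic_spec].
#' @param test_fraction fraction of observations held out as the external
#'   test set (default 0.2); 0 assigns everything to training.
#' @return A [qsrr_dataset] with attributes `ground_truth` (informative
#'   indices, link parameters) and `y_noiseless`.
#' @export
synthesize_dataset <- function(spec, test_fraction = 0.2) {
  X <- generate_descriptors(spec)
  if (spec$covariate_mode == "mobile_phase_percent") {
    mp_levels <- c(30, 45, 50)
    mp <- with_seed(spec$seed + 2L,
                    sample(mp_levels, spec$n, replace = TRUE))
    Xc <- cbind(X, mobile_phase = (mp - 30) / 20)   # scaled to [0, 1]
    resp <- generate_response(Xc, spec)
    X <- Xc
  } else {
    resp <- generate_response(X, spec)
  }
  ds <- qsrr_dataset(X, resp$y, sprintf("obs%03d", seq_len(nrow(X))))
  if (test_fraction > 0)
    ds <- stratified_split(ds, test_fraction, seed = spec$seed + 3L)
  else
    ds$split <- rep("train", length(ds$y))
  attr(ds, "ground_truth") <- resp$ground_truth
  attr(ds, "y_noiseless") <- resp$y_noiseless
  ds
}

#' Response-stratified train/test split
#'
#' Assigns a test set while maintaining the response-value distribution in
#' both sets: observations are binned by response quantile and the test
#' fraction is sampled within each bin.
#'
#' @param dataset a [qsrr_dataset].
#' @param test_fraction fraction held out (0 < f < 1).
#' @param n_bins number of response-quantile strata (default 4).
#' @param seed integer seed.
#' @return The dataset with its `split` field set.
#' @export
stratified_split <- function(dataset, test_fraction = 0.2, n_bins = 4,
                             seed = 1) {
  stopifnot(inherits(dataset, "qsrr_dataset"),
            test_fraction > 0, test_fraction < 1)
  n <- length(dataset$y)
  bins <- cut(rank(dataset$y, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  groups <- split(seq_len(n), bins)
  # largest-remainder allocation so the total test count is exact
  k_total <- round(n * test_fraction)
  ideal <- lengths(groups) * test_fraction
  k <- floor(ideal)
  short <- k_total - sum(k)
  if (short > 0) {
    extra <- order(ideal - k, decreasing = TRUE)[seq_len(short)]
    k[extra] <- k[extra] + 1L
  } else if (short < 0) {
    trim <- order(ideal - k)[seq_len(-short)]
    k[trim] <- pmax(k[trim] - 1L, 0L)
  }
  test_idx <- with_seed(seed, {
    unlist(mapply(function(ii, ki) if (ki == 0) integer(0)
                  else sample(ii, min(ki, length(ii))),
                  groups, k, SIMPLIFY = FALSE), use.names = FALSE)
  })
  assign_split(dataset, dataset$ids[test_idx])
}

#' Paper-scale synthetic instances
#'
#' Convenience generators sized like the two packaged chromatographic
#' studies. `"quinolone"`: 21 observations, 313 raw descriptors of which
#' 14 are constant and 6 all-zero (so variance filtering leaves 293), 5
#' informative, RBF-mixture link, 16/5 split. `"sulfonamide"`: 39
#' observations, 112 descriptors plus a three-level mobile-phase
#' percentage covariate (113 columns), 2 informative descriptors plus the
#' covariate, 30/9 split. The noiseless signal is shifted/scaled to a
#' retention-factor-like range before noise is added.
#'
#' @param which `"quinolone"` or `"sulfonamide"`.
#' @param seed integer seed.
#' @return A [qsrr_dataset] with `ground_truth` and `y_noiseless`
#'   attributes; descriptors unfiltered (apply [filter_descriptors()]).
#' @export
make_paper_like_instance <- function(which = c("quinolone", "sulfonamide"),
                                     seed = 1) {
  which <- match.arg(which)
  if (which == "quinolone") {
    spec <- synthetic_spec(n = 21, p = 313, informative_idx = 1:5,
                           block_correlation = 0.6, block_size = 10,
                           link = "rbf_mixture", noise_sd = 0.05,
                           seed = seed)
    ds <- synthesize_dataset(spec, test_fraction = 5 / 21)
    # plant the degenerate columns variance filtering must remove
    dead <- with_seed(seed + 4L, sample(setdiff(seq_len(313), 1:5), 20))
    ds$X[, dead[1:14]] <- rep(stats::runif(14, -2, 2),
                              each = nrow(ds$X))
    ds$X[, dead[15:20]] <- 0
    target <- c(center = 1.55, sd = 0.35)   # quinolone-like k range
  } else {
    spec <- synthetic_spec(n = 39, p = 112, informative_idx = 1:2,
                           block_correlation = 0.6, block_size = 8,
                           link = "rbf_mixture", noise_sd = 0.05,
                           covariate_mode = "mobile_phase_percent",
                           seed = seed)
    ds <- synthesize_dataset(spec, test_fraction = 9 / 39)
    target <- c(center = 0.65, sd = 0.45)   # sulfonamide-like k range
  }
  y0 <- attr(ds, "y_noiseless")
  sc <- target["sd"] / max(stats::sd(y0), .Machine$double.eps)
  shift <- target["center"] - mean(y0) * sc
  ds$y <- pmax(ds$y * sc + shift, 0)
  attr(ds, "y_noiseless") <- y0 * sc + shift
  ds
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring
# any pre-existing global state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
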