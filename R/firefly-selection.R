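#' Firefly-algorithm configuration
#'
#' Parameters of the firefly swarm used for wrapper descriptor selection.
#' The number of fireflies controls exploration and the number of
#' generations controls exploitation; `gamma_abs` is the light-absorption
#' coefficient shaping the distance decay of attractiveness, and `alpha`
#' weights the random perturbation that keeps the swarm out of local
#' optima. Two named profiles reproduce the operating points used for the
#' packaged retention models: `firefly_profile("quinolone")` = 10
#' fireflies, 100 generations, alpha 0.1, beta0 1, gamma 0.01;
#' `firefly_profile("sulfonamide")` = 20 fireflies, 100 generations,
#' alpha 0.15, beta0 1, gamma 0.01.
#'
#' @param n_fireflies swarm size (>= 1).
#' @param generations iterations (>= 1).
#' @param alpha randomization weight (>= 0).
#' @param beta0 attractiveness at zero distance.
#' @param gamma_abs light absorption coefficient (>= 0).
#' @param seed integer seed; the whole selection run is deterministic
#'   given it.
#' @param min_descriptors minimum mask size forced during decoding
#'   (default 1, preventing empty models).
#' @param max_descriptors optional cap on mask size; `NULL` for none.
#' @return An object of class `firefly_config`.
#' @export
firefly_config <- function(n_fireflies = 10, generations = 100,
                           alpha = 0.1, beta0 = 1, gamma_abs = 0.01,
                           seed = 1, min_descriptors = 1,
                           max_descriptors = NULL) {
  if (n_fireflies < 1 || generations < 1) stop("counts must be >= 1")
  if (alpha < 0 || gamma_abs < 0) stop("alpha and gamma_abs must be >= 0")
  if (min_descriptors < 1) stop("min_descriptors must be >= 1")
  structure(list(n_fireflies = as.integer(n_fireflies),
                 generations = as.integer(generations),
                 alpha = alpha, beta0 = beta0, gamma_abs = gamma_abs,
                 seed = as.integer(seed),
                 min_descriptors = as.integer(min_descriptors),
                 max_descriptors = max_descriptors),
            class = "firefly_config")
}

#' @rdname firefly_config
#' @param which profile name, `"quinolone"` or `"sulfonamide"`.
#' @param ... overrides passed on to [firefly_config()].
#' @export
firefly_profile <- function(which = c("quinolone", "sulfonamide"), ...) {
  which <- match.arg(which)
  base <- if (which == "quinolone")
    list(n_fireflies = 10, generations = 100, alpha = 0.1,
         beta0 = 1, gamma_abs = 0.01)
  else
    list(n_fireflies = 20, generations = 100, alpha = 0.15,
         beta0 = 1, gamma_abs = 0.01)
  do.call(firefly_config, utils::modifyList(base, list(...)))
}

#' Firefly attractiveness
#'
#' Distance-decaying attractiveness `beta0 * exp(-gamma_abs * r^2)`: full
#' brightness at zero distance, Gaussian decay with the light-absorption
#' coefficient.
#'
#' @param beta0 attractiveness at zero distance.
#' @param gamma_abs absorption coefficient (>= 0).
#' @param r Euclidean distance (>= 0).
#' @return Attractiveness value.
#' @export
attractiveness <- function(beta0, gamma_abs, r) {
  if (any(r < 0)) stop("distance must be >= 0")
  beta0 * exp(-gamma_abs * r^2)
}

#' Move a firefly toward a brighter one
#'
#' Canonical position update
#' `x_i' = x_i + beta(r_ij) (x_j - x_i) + alpha (u - 0.5)` with `u`
#' uniform per coordinate and `r_ij` the Euclidean distance between the
#' continuous positions; the result is clipped to `[0, 1]^p`. Consumes
#' the current RNG stream, so results are reproducible under a caller's
#' seed.
#'
#' @param x_i current position in `[0, 1]^p`.
#' @param x_j brighter position of the same length.
#' @param config a [firefly_config] (uses `alpha`, `beta0`, `gamma_abs`).
#' @return Updated position.
#' @export
move_firefly <- function(x_i, x_j, config) {
  if (length(x_i) != length(x_j)) stop("positions differ in length")
  beta <- attractiveness(config$beta0, config$gamma_abs,
                         sqrt(sum((x_j - x_i)^2)))
  x_new <- x_i + beta * (x_j - x_i) +
    config$alpha * (stats::runif(length(x_i)) - 0.5)
  pmin(pmax(x_new, 0), 1)
}

#' Decode a continuous position into a descriptor mask
#'
#' Deterministic threshold decoding: descriptor `d` is selected iff
#' `position_d > 0.5`. If fewer than `min_descriptors` bits are set the
#' top coordinates by value are forced on (ties broken toward the lower
#' index); if more than `max_descriptors` are set, only the top
#' `max_descriptors` coordinates are kept.
#'
#' @param position numeric vector with coordinates in `[0, 1]`.
#' @param min_descriptors minimum mask size (default 1).
#' @param max_descriptors optional maximum mask size.
#' @return Logical mask of the same length.
#' @export
decode_mask <- function(position, min_descriptors = 1,
                        max_descriptors = NULL) {
  if (any(position < 0 | position > 1)) stop("coordinates must be in [0,1]")
  mask <- position > 0.5
  ord <- order(position, decreasing = TRUE)   # stable: lower index wins ties
  if (sum(mask) < min_descriptors) {
    mask[] <- FALSE
    mask[ord[seq_len(min_descriptors)]] <- TRUE
  }
  if (!is.null(max_descriptors) && sum(mask) > max_descriptors) {
    keep <- ord[position[ord] > 0.5][seq_len(max_descriptors)]
    mask[] <- FALSE
    mask[keep] <- TRUE
  }
  mask
}

#' Selection fitness: cross-validated RMSE of a masked SVR model
#'
#' The wrapper fitness driving descriptor selection: the RMSE of
#' out-of-fold predictions from [cross_validate()] on the training split,
#' using only the masked descriptor columns. Degenerate masked data yield
#' an `Inf` sentinel so the firefly never becomes the best. Results are
#' cached by mask bit-pattern when a cache environment is supplied
#' (cross-validation of an SVR per mask is the cost center of the whole
#' wrapper).
#'
#' @param mask logical descriptor mask with at least one bit set.
#' @param dataset a [qsrr_dataset] with a training split.
#' @param config an [svr_config].
#' @param scheme a [cv_scheme].
#' @param cache optional environment used as a mask-keyed memo table.
#' @return RMSE_CV (or `Inf` on degenerate data).
#' @export
ffa_fitness <- function(mask, dataset, config = svr_config(),
                        scheme = cv_scheme("loo"), cache = NULL) {
  if (!any(mask)) stop("mask selects no descriptors")
  key <- paste(which(mask), collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) {
    cache$hits <- (cache$hits %||% 0L) + 1L
    return(cache[[key]])
  }
  tr <- dataset$split == "train"
  val <- tryCatch({
    pred <- cross_validate(dataset, mask, config, scheme)
    rmse(dataset$y[tr], pred)
  }, error = function(e) Inf)
  if (!is.finite(val)) val <- Inf
  if (!is.null(cache)) {
    cache[[key]] <- val
    cache$evals <- (cache$evals %||% 0L) + 1L
  }
  val
}

#' Firefly-wrapper descriptor selection
#'
#' Runs the binary firefly algorithm over descriptor masks with
#' cross-validated SVR RMSE as fitness. Positions start uniform on
#' `[0, 1]^p`; each generation every firefly moves toward every brighter
#' firefly (lower RMSE_CV = brighter, ties broken by lower index) via
#' [move_firefly()], while the current best firefly takes only its own
#' `alpha` randomization step. The best mask ever evaluated is retained
#' (elitism), so the reported best fitness is non-increasing over
#' generations.
#'
#' @param dataset a filtered [qsrr_dataset] with a training split.
#' @param ffa_config a [firefly_config].
#' @param svr_config an [svr_config].
#' @param cv_scheme a [cv_scheme].
#' @param verbose emit a log line per generation.
#' @return An object of class `qsrr_selection`: `selected` (descriptor
#'   names), `mask`, `fitness` (RMSE_CV of the best mask), `history`
#'   (best fitness per generation), `n_evaluations`, `cache_hits`,
#'   `config`, `seed`.
#' @export
select_descriptors <- function(dataset, ffa_config = firefly_config(),
                               svr_config = fireflyQSRR::svr_config(),
                               cv_scheme = fireflyQSRR::cv_scheme("loo"),
                               verbose = FALSE) {
  stopifnot(inherits(dataset, "qsrr_dataset"),
            inherits(ffa_config, "firefly_config"))
  p <- length(dataset$descriptor_names)
  if (p == 0L) stop("dataset has no descriptors")
  nf <- ffa_config$n_fireflies
  cache <- new.env(parent = emptyenv())
  decode <- function(pos) decode_mask(pos, ffa_config$min_descriptors,
                                      ffa_config$max_descriptors)
  evaluate <- function(pos) ffa_fitness(decode(pos), dataset, svr_config,
                                        cv_scheme, cache)
  with_seed(ffa_config$seed, {
    positions <- matrix(stats::runif(nf * p), nf, p)
    fitnesses <- apply(positions, 1L, evaluate)
    best_i <- which.min(fitnesses)
    best <- list(mask = decode(positions[best_i, ]),
                 fitness = fitnesses[best_i])
    history <- numeric(ffa_config$generations)
    for (g in seq_len(ffa_config$generations)) {
      brightest <- which.min(fitnesses)     # ties -> lower index
      rank_order <- order(fitnesses)        # fireflies processed bright-first
      for (i in rank_order) {
        if (i == brightest) {
          # best firefly: pure randomization step, elitism keeps its record
          positions[i, ] <- pmin(pmax(
            positions[i, ] +
              ffa_config$alpha * (stats::runif(p) - 0.5), 0), 1)
          next
        }
        for (j in rank_order) {
          if (fitnesses[j] < fitnesses[i])
            positions[i, ] <- move_firefly(positions[i, ], positions[j, ],
                                           ffa_config)
        }
      }
      fitnesses <- apply(positions, 1L, evaluate)
      gen_best <- which.min(fitnesses)
      if (fitnesses[gen_best] < best$fitness)
        best <- list(mask = decode(positions[gen_best, ]),
                     fitness = fitnesses[gen_best])
      history[g] <- best$fitness
      if (verbose)
        message(sprintf("generation %3d: best RMSE_CV %.5f (%d descriptors)",
                        g, best$fitness, sum(best$mask)))
    }
    structure(
      list(selected = dataset$descriptor_names[best$mask],
           mask = best$mask, fitness = best$fitness, history = history,
           n_evaluations = cache$evals %||% 0L,
           cache_hits = cache$hits %||% 0L,
           config = ffa_config, seed = ffa_config$seed),
      class = "qsrr_selection")
  })
}

#' @export
print.qsrr_selection <- function(x, ...) {
  cat("Firefly descriptor selection: ", length(x$selected),
      " descriptors, RMSE_CV = ", format(x$fitness, digits = 5), "\n",
      "  ", paste(x$selected, collapse = ", "), "\n",
      "  ", x$n_evaluations, " fitness evaluations (",
      x$cache_hits, " cache hits), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
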