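#' SVR configuration
#'
#' Settings for the epsilon-insensitive support vector regression used
#' throughout the package. The defaults (RBF kernel, `C = 1`,
#' `epsilon = 0.01`) are the operating point of the packaged retention
#' models; the kernel width defaults to `"auto"` = `1 / p` on the selected
#' descriptors so the scale stays sane as the firefly wrapper varies the
#' mask size.
#'
#' @param C penalty for deviations outside the epsilon tube (> 0).
#' @param epsilon half-width of the insensitive tube (>= 0); training
#'   residuals smaller than `epsilon` carry zero loss.
#' @param kernel `"rbf"` (default), `"polynomial"`, `"sigmoid"` or
#'   `"linear"`.
#' @param gamma kernel width (> 0) or `"auto"` for `1 / p_selected`.
#' @param degree polynomial-kernel degree.
#' @param coef0 polynomial/sigmoid kernel offset.
#' @param standardize z-score descriptors with training statistics before
#'   fitting (default `TRUE`); RBF distances are meaningless across raw
#'   descriptor scales.
#' @param tolerance solver stopping tolerance.
#' @return An object of class `svr_config`.
#' @export
svr_config <- function(C = 1, epsilon = 0.01,
                       kernel = c("rbf", "polynomial", "sigmoid", "linear"),
                       gamma = "auto", degree = 3, coef0 = 0,
                       standardize = TRUE, tolerance = 1e-6) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop("C must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (!identical(gamma, "auto") && (!is.numeric(gamma) || gamma <= 0))
    stop("gamma must be > 0 or \"auto\"")
  structure(list(C = C, epsilon = epsilon, kernel = kernel, gamma = gamma,
                 degree = degree, coef0 = coef0, standardize = standardize,
                 tolerance = tolerance),
            class = "svr_config")
}

#' Radial-basis-function kernel
#'
#' `exp(-gamma * ||u - v||^2)`: a Gaussian similarity in `(0, 1]`,
#' symmetric in its arguments and positive semi-definite as a kernel.
#'
#' @param u,v numeric vectors of equal length.
#' @param gamma kernel width (> 0).
#' @return Kernel value.
#' @export
rbf_kernel <- function(u, v, gamma) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  exp(-gamma * sum((u - v)^2))
}

#' Fit an epsilon-SVR model
#'
#' Solves the standard epsilon-insensitive SVR dual (via the libsvm solver
#' in \pkg{e1071}) on optionally standardized descriptors. Standardization
#' statistics come from the training data only and are reapplied at
#' prediction; zero-variance columns are passed through unscaled and
#' recorded in the model.
#'
#' @param X_train numeric matrix (n x p, `n >= 2`, `p >= 1`).
#' @param y_train numeric response.
#' @param config an [svr_config].
#' @return An object of class `qsrr_svr`: support vectors and dual
#'   coefficients on the standardized scale, the bias, standardization
#'   statistics and a config echo. Prediction is
#'   `f(x) = sum_i coef_i K(sv_i, x) + bias`.
#' @export
fit_svr <- function(X_train, y_train, config = svr_config()) {
  stopifnot(inherits(config, "svr_config"))
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 2) stop("need at least 2 training observations")
  if (ncol(X_train) < 1) stop("need at least 1 descriptor")
  if (length(y_train) != nrow(X_train)) stop("X_train/y_train mismatch")
  p <- ncol(X_train)
  center <- rep(0, p); scl <- rep(1, p)
  unscaled <- integer(0)
  if (config$standardize) {
    center <- colMeans(X_train)
    scl <- apply(X_train, 2L, stats::sd)
    unscaled <- which(!is.finite(scl) | scl <= .Machine$double.eps)
    if (length(unscaled)) {
      center[unscaled] <- 0; scl[unscaled] <- 1
    }
  }
  Xs <- sweep(sweep(X_train, 2L, center), 2L, scl, "/")
  gamma <- if (identical(config$gamma, "auto")) 1 / p else config$gamma
  # a response that fits entirely inside the epsilon tube has an empty
  # support set; the optimal function is then flat at the response center
  fit <- if (stats::sd(y_train) > .Machine$double.eps)
    tryCatch(e1071::svm(
      x = Xs, y = y_train, type = "eps-regression", scale = FALSE,
      kernel = switch(config$kernel, rbf = "radial",
                      polynomial = "polynomial",
                      sigmoid = "sigmoid", linear = "linear"),
      cost = config$C, epsilon = config$epsilon, gamma = gamma,
      degree = config$degree, coef0 = config$coef0,
      tolerance = config$tolerance),
      error = function(e) {
        if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
        else stop(e)
      })
  else NULL
  if (is.null(fit))
    fit <- list(SV = matrix(numeric(0), 0L, p), coefs = numeric(0),
                rho = -mean(y_train))
  structure(
    list(support_vectors = fit$SV, coefficients = drop(fit$coefs),
         bias = -fit$rho, gamma = gamma, center = center, scale = scl,
         unscaled_columns = unscaled, config = config,
         descriptor_names = colnames(X_train), n_train = nrow(X_train)),
    class = "qsrr_svr")
}

kernel_matrix <- function(model, Xs) {
  SV <- model$support_vectors
  cfg <- model$config
  switch(cfg$kernel,
    rbf = exp(-model$gamma * fields_dist2(Xs, SV)),
    linear = tcrossprod(Xs, SV),
    polynomial = (model$gamma * tcrossprod(Xs, SV) + cfg$coef0)^cfg$degree,
    sigmoid = tanh(model$gamma * tcrossprod(Xs, SV) + cfg$coef0))
}

#' Predict retention factors from a fitted SVR model
#'
#' Applies the training standardization to the query rows and evaluates
#' `f(x) = sum_i coef_i K(sv_i, x) + bias` from the stored support vectors
#' and dual coefficients; deterministic given the model.
#'
#' @param object a `qsrr_svr` model.
#' @param newdata numeric matrix with the training column count.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.qsrr_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stop("newdata has ", ncol(newdata), " columns; model was trained on ",
         length(object$center))
  Xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  drop(kernel_matrix(object, Xs) %*% object$coefficients) + object$bias
}

#' @export
print.qsrr_svr <- function(x, ...) {
  cat("epsilon-SVR (", x$config$kernel, " kernel): ",
      length(x$coefficients), " support vectors of ", x$n_train,
      " training rows; C=", x$config$C, ", epsilon=", x$config$epsilon,
      ", gamma=", format(x$gamma, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Serialize / restore an SVR model as JSON
#'
#' Writes the complete model state (config, standardization statistics,
#' support vectors, dual coefficients, bias) to JSON so a fit can be
#' reloaded exactly; `read_svr_json()` restores an object whose
#' predictions match the original to full precision.
#'
#' @param model a `qsrr_svr`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_svr_json()` returns the model.
#' @export
write_svr_json <- function(model, path) {
  stopifnot(inherits(model, "qsrr_svr"))
  payload <- list(
    config = unclass(model$config),
    support_vectors = model$support_vectors,
    coefficients = model$coefficients, bias = model$bias,
    gamma = model$gamma, center = model$center, scale = model$scale,
    unscaled_columns = model$unscaled_columns,
    descriptor_names = model$descriptor_names, n_train = model$n_train)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_svr_json
#' @export
read_svr_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(svr_config, p$config)
  structure(
    list(support_vectors = as.matrix(p$support_vectors),
         coefficients = as.numeric(p$coefficients), bias = p$bias,
         gamma = p$gamma, center = as.numeric(p$center),
         scale = as.numeric(p$scale),
         unscaled_columns = as.integer(p$unscaled_columns),
         config = cfg, descriptor_names = p$descriptor_names,
         n_train = p$n_train),
    class = "qsrr_svr")
}
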