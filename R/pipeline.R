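#' End-to-end QSRR modeling pipeline
#'
#' Orchestrates the full workflow on a dataset with a train/test split:
#' variance filtering, linearity screening, firefly descriptor selection,
#' SVR fitting, internal cross-validation and external prediction,
#' metric computation, Y-randomization and applicability-domain analysis.
#' Every stage draws its seed from the master seed by a fixed counter, so
#' a rerun with the same configuration and seed reproduces every report
#' exactly. When `out_dir` is given each report is additionally written
#' there as JSON/CSV (no timestamps, so reruns are byte-identical).
#'
#' @param dataset a [qsrr_dataset] with a `train`/`test` split and
#'   `p >= 1` descriptors.
#' @param ffa_config a [firefly_config]; its seed is overridden by the
#'   master seed.
#' @param svr_config an [svr_config].
#' @param cv_scheme a [cv_scheme]; its seed is overridden by the master
#'   seed.
#' @param yrand_iterations Y-randomization iterations (default 20).
#' @param yrand_mode Y-randomization mode (see [run_y_randomization()]).
#' @param seed master seed.
#' @param out_dir optional output directory for JSON/CSV reports.
#' @param verbose log stage progress and per-generation selection lines.
#' @return An object of class `qsrr_run`: a list with elements
#'   `filtered` (dataset), `removal_log`, `linearity`, `selection`,
#'   `model`, `predictions`, `metrics`, `yrand`, `ad`, `hotelling`,
#'   `seed`.
#' @export
run_pipeline <- function(dataset, ffa_config = firefly_config(),
                         svr_config = fireflyQSRR::svr_config(),
                         cv_scheme = fireflyQSRR::cv_scheme("loo"),
                         yrand_iterations = 20,
                         yrand_mode = "auto",
                         seed = 1, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "qsrr_dataset"))
  if (!any(dataset$split == "train"))
    stop("stage split: dataset has no training observations")
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  ffa_config$seed <- seed + 1L
  cv_scheme$seed <- seed + 2L

  say("stage filter: variance filtering")
  filtered <- stage("filter", filter_descriptors(dataset))
  removal_log <- attr(filtered, "removal_log")
  say("  removed ", nrow(removal_log), " degenerate descriptors; p = ",
      length(filtered$descriptor_names))

  say("stage linearity: APARP / Durbin-Watson screen")
  lin <- stage("linearity", linearity_screen(filtered))
  say("  verdict: ", lin$verdict)

  say("stage select: firefly descriptor selection")
  sel <- stage("select",
               select_descriptors(filtered, ffa_config, svr_config,
                                  cv_scheme, verbose = verbose))
  say("  ", length(sel$selected), " descriptors, RMSE_CV = ",
      format(sel$fitness, digits = 5))

  tr <- filtered$split == "train"
  te <- filtered$split == "test"
  cols <- which(sel$mask)
  say("stage fit: SVR on ", sum(tr), " training rows")
  model <- stage("fit", fit_svr(filtered$X[tr, cols, drop = FALSE],
                                filtered$y[tr], svr_config))

  say("stage validate: cross-validation and external prediction")
  cv_pred <- stage("validate",
                   cross_validate(filtered, sel$mask, svr_config, cv_scheme))
  cal_pred <- predict(model, filtered$X[tr, cols, drop = FALSE])
  test_pred <- if (any(te))
    predict(model, filtered$X[te, cols, drop = FALSE]) else numeric(0)
  predictions <- prediction_table(
    ids = c(filtered$ids[tr], filtered$ids[te]),
    set = c(rep("train", sum(tr)), rep("test", sum(te))),
    observed = c(filtered$y[tr], filtered$y[te]),
    predicted = c(cal_pred, test_pred),
    cv_predicted = c(cv_pred, rep(NA_real_, sum(te))))
  metrics <- stage("validate",
                   evaluate_model(predictions, length(sel$selected)))

  say("stage yrand: ", yrand_iterations, " response scrambles")
  yrand <- stage("yrand",
                 run_y_randomization(filtered, ffa_config, svr_config,
                                     cv_scheme, yrand_iterations,
                                     seed = seed + 3L, mode = yrand_mode,
                                     mask = sel$mask))

  say("stage ad: Williams plot and Hotelling T2")
  ad <- stage("ad", williams_data(
    filtered$X[tr, cols, drop = FALSE], cv_pred - filtered$y[tr],
    X_test = if (any(te)) filtered$X[te, cols, drop = FALSE],
    resid_test = if (any(te)) test_pred - filtered$y[te],
    ids = c(filtered$ids[tr], filtered$ids[te])))
  hotel <- stage("ad", hotelling_t2(
    filtered$X[tr, cols, drop = FALSE],
    rbind(filtered$X[tr, cols, drop = FALSE],
          if (any(te)) filtered$X[te, cols, drop = FALSE])))

  bundle <- structure(
    list(filtered = filtered, removal_log = removal_log, linearity = lin,
         selection = sel, model = model, predictions = predictions,
         metrics = metrics, yrand = yrand, ad = ad, hotelling = hotel,
         seed = seed),
    class = "qsrr_run")
  if (!is.null(out_dir)) write_run_bundle(bundle, out_dir)
  bundle
}

#' @export
print.qsrr_run <- function(x, ...) {
  cat("QSRR pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  linearity verdict: ", x$linearity$verdict, "\n", sep = "")
  cat("  selected descriptors: ",
      paste(x$selection$selected, collapse = ", "), "\n", sep = "")
  print(x$metrics)
  cat("  cRp2 (calibration): ",
      ifelse(is.na(x$yrand$crp2_cal), "flagged",
             sprintf("%.3f", x$yrand$crp2_cal)), "\n", sep = "")
  cat("  in applicability domain: ", sum(x$ad$in_domain), "/",
      nrow(x$ad), "\n", sep = "")
  invisible(x)
}

write_run_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  j <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), digits = NA, auto_unbox = TRUE,
    dataframe = "columns", force = TRUE)
  j(list(seed = bundle$seed,
         selected = bundle$selection$selected,
         fitness = bundle$selection$fitness,
         history = bundle$selection$history), "selection.json")
  j(unclass(bundle$metrics), "metrics.json")
  j(list(verdict = bundle$linearity$verdict,
         dw_statistic = bundle$linearity$dw_statistic,
         p_value = bundle$linearity$p_value), "linearity.json")
  j(list(n_iterations = bundle$yrand$n_iterations, mode = bundle$yrand$mode,
         r2_original = bundle$yrand$r2_original,
         r2_y_mean = bundle$yrand$r2_y_mean,
         crp2_cal = bundle$yrand$crp2_cal,
         crp2_cv = bundle$yrand$crp2_cv,
         records = bundle$yrand$records), "yrand.json")
  utils::write.csv(as.data.frame(bundle$ad),
                   file.path(out_dir, "williams.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$predictions),
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)
  write_svr_json(bundle$model, file.path(out_dir, "model.json"))
  invisible(out_dir)
}

#' Side-by-side performance table for one or more models
#'
#' Formats the metric suites of one or more models (from
#' [evaluate_model()] or `qsrr_run` bundles) into the customary
#' metric-by-model layout, rounded to 3 decimals, with `---` for metrics
#' a model does not carry.
#'
#' @param ... named `qsrr_metrics` or `qsrr_run` objects (names become
#'   column headers).
#' @param file optional path to also write the table as CSV.
#' @return A character data frame (rows = metrics, columns = models).
#' @examples
#' m <- evaluate_model(qsrr_fixture("quinolones", "predictions"), 5)
#' report_table5(quinolones = m)
#' @export
report_table5 <- function(..., file = NULL) {
  models <- list(...)
  if (!length(models)) stop("no models supplied")
  models <- lapply(models, function(m) {
    if (inherits(m, "qsrr_run")) m <- m$metrics
    if (!inherits(m, "qsrr_metrics")) stop("arguments must be qsrr_metrics ",
                                           "or qsrr_run objects")
    m
  })
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model", seq_along(models))
  rows <- c(r2_cal = "R2_cal", r2_adj = "R2_cal_adj", q2_cv = "q2_CV",
            r2_pred = "R2_pred", rmse_cal = "RMSE_cal", rmse_cv = "RMSE_CV",
            rmse_pred = "RMSE_pred", rho_cal = "rho_cal", rho_cv = "rho_CV",
            rho_pred = "rho_pred")
  out <- data.frame(
    parameter = unname(rows),
    lapply(models, function(m)
      vapply(names(rows), function(k)
        if (is.na(m[[k]])) "---" else sprintf("%.3f", m[[k]]),
        character(1))),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
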