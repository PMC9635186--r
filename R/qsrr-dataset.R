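#' QSRR dataset container
#'
#' Bundles a numeric molecular-descriptor matrix, a retention-factor
#' response and per-observation metadata into the container every modeling
#' stage of the package consumes. Observations are compound/condition
#' pairs (e.g. `"Norfloxacin@pH6.5"` or `"Sulfadiazine@ACN45"`); descriptor
#' values are unitless and the response `k` is the dimensionless retention
#' factor.
#'
#' @param X numeric matrix (n observations x p descriptors). `p = 0` is
#'   allowed for retention-only tables.
#' @param y numeric response vector of length n (retention factors).
#' @param ids character vector of unique observation identifiers.
#' @param descriptor_names optional character vector of length p; defaults
#'   to `colnames(X)`.
#' @param split per-observation assignment, one of `"train"`, `"test"`,
#'   `"unassigned"`; recycled if length 1.
#' @return An object of class `qsrr_dataset`: a list with elements `X`,
#'   `y`, `ids`, `descriptor_names`, `split`.
#' @examples
#' X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("d1", "d2")))
#' ds <- qsrr_dataset(X, y = rowSums(X^2), ids = paste0("obs", 1:10))
#' ds
#' @export
qsrr_dataset <- function(X, y, ids, descriptor_names = colnames(X),
                         split = "unassigned") {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  if (p > 0L && is.null(descriptor_names))
    descriptor_names <- paste0("X", seq_len(p))
  descriptor_names <- as.character(descriptor_names %||% character(0))
  if (length(descriptor_names) != p)
    stop("descriptor_names must have one entry per descriptor column")
  if (anyDuplicated(descriptor_names))
    stop("descriptor names must be unique")
  colnames(X) <- descriptor_names
  if (length(y) != n || length(ids) != n)
    stop("rows(X), length(y) and length(ids) must agree")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate observation ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyNA(X) || anyNA(y))
    stop("missing values are not allowed in a qsrr_dataset")
  split <- rep_len(match.arg(split, c("train", "test", "unassigned"),
                             several.ok = TRUE), n)
  structure(
    list(X = X, y = as.numeric(y), ids = ids,
         descriptor_names = descriptor_names, split = split),
    class = "qsrr_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qsrr_dataset <- function(x, ...) {
  cat("QSRR dataset: ", length(x$y), " observations, ",
      length(x$descriptor_names), " descriptors\n", sep = "")
  cat("  split: ", sum(x$split == "train"), " train / ",
      sum(x$split == "test"), " test / ",
      sum(x$split == "unassigned"), " unassigned\n", sep = "")
  cat("  k range: [", format(min(x$y), digits = 4), ", ",
      format(max(x$y), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.qsrr_dataset <- function(x) c(length(x$y), length(x$descriptor_names))

#' Retention factor from retention and dead time
#'
#' Computes the dimensionless retention factor `k = (tR - t0) / t0`, the
#' standard chromatographic normalization of a retention time `tR` by the
#' column dead time `t0` (elution time of an unretained analyte).
#'
#' @param t_retention retention time(s), minutes.
#' @param t_dead column dead time, minutes (scalar, > 0). 2.9 min for the
#'   packaged quinolone system, 2.0 min for the sulfonamide system.
#' @return Retention factor(s) `k >= 0`.
#' @examples
#' compute_retention_factor(7.482, 2.9)  # ~1.58
#' @export
compute_retention_factor <- function(t_retention, t_dead) {
  if (length(t_dead) != 1L || !is.finite(t_dead) || t_dead <= 0)
    stop("t_dead must be a single positive time")
  if (any(!is.finite(t_retention)))
    stop("t_retention must be finite")
  if (any(t_retention < t_dead))
    stop("t_retention < t_dead: analyte elutes before an unretained ",
         "marker; check the dead time")
  (t_retention - t_dead) / t_dead
}

#' Load a QSRR dataset from a delimited text file
#'
#' Reads a CSV/TSV descriptor table (header row, `.` decimal separator,
#' optional `#` comment header) with one row per observation. All columns
#' other than the id columns and the response are taken as numeric
#' descriptors in file order. Missing or non-numeric cells are hard errors
#' naming the offending row and column; values are never imputed.
#'
#' @param path file path.
#' @param response_column name of the retention-factor column (default
#'   `"k"`). Response values must be `>= 0`.
#' @param id_columns character vector of one or more id columns; they are
#'   pasted with `"@"` into the observation id.
#' @param split_column optional name of a column holding `"train"` /
#'   `"test"` flags.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return A [qsrr_dataset].
#' @export
load_dataset <- function(path, response_column = "k", id_columns,
                         split_column = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  for (col in c(response_column, id_columns))
    if (!col %in% names(raw)) stop("column not found: ", col)
  meta_cols <- c(id_columns, response_column, split_column)
  desc_cols <- setdiff(names(raw), meta_cols)
  ids <- do.call(paste, c(unname(raw[id_columns]), sep = "@"))
  if (anyDuplicated(ids))
    stop("duplicate observation ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  parse_num <- function(col) {
    v <- trimws(raw[[col]])
    bad <- which(is.na(v) | v == "" | v == "NA" |
                   is.na(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop("missing or non-numeric value in column '", col, "', row ",
           bad[1L], " (id ", ids[bad[1L]], ")")
    as.numeric(v)
  }
  y <- parse_num(response_column)
  if (any(y < 0))
    stop("retention factors must be >= 0; negative value in row ",
         which(y < 0)[1L])
  X <- if (length(desc_cols))
    do.call(cbind, lapply(desc_cols, parse_num))
  else
    matrix(numeric(0), nrow = length(y), ncol = 0L)
  colnames(X) <- desc_cols
  split <- if (!is.null(split_column)) raw[[split_column]] else "unassigned"
  ds <- qsrr_dataset(X, y, ids, descriptor_names = desc_cols, split = split)
  message("loaded ", length(y), " observations x ", length(desc_cols),
          " descriptors from ", basename(path))
  ds
}

#' Write a QSRR dataset to CSV
#'
#' Inverse of [load_dataset()]: writes `id`, the response column, the split
#' flag and every descriptor column. `load_dataset()` on the result
#' reproduces `X`, `y` and `ids` exactly at the written precision.
#'
#' @param dataset a [qsrr_dataset].
#' @param path output file path.
#' @param response_column name for the response column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, response_column = "k") {
  stopifnot(inherits(dataset, "qsrr_dataset"))
  df <- data.frame(id = dataset$ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[[response_column]] <- dataset$y
  df[["split"]] <- dataset$split
  if (length(dataset$descriptor_names))
    df <- cbind(df, as.data.frame(dataset$X, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Remove constant and all-zero descriptors
#'
#' Drops descriptor columns that carry no information: columns that are
#' identically zero or constant up to floating-point tolerance (relative
#' variance below `tol` of the column scale). Row count and ordering of the
#' surviving columns are unchanged. The removal log is attached as the
#' `"removal_log"` attribute, a data frame with one row per dropped
#' descriptor and its reason (`"all_zero"` or `"constant"`).
#'
#' @param dataset a [qsrr_dataset] with `p >= 1`.
#' @param tol relative variance tolerance below which a column counts as
#'   constant (default `1e-12`).
#' @return The filtered [qsrr_dataset]; inspect `attr(, "removal_log")`.
#' @export
filter_descriptors <- function(dataset, tol = 1e-12) {
  stopifnot(inherits(dataset, "qsrr_dataset"))
  p <- length(dataset$descriptor_names)
  if (p < 1L) stop("dataset has no descriptors to filter")
  X <- dataset$X
  scale2 <- pmax(apply(X, 2L, function(v) mean(v^2)), .Machine$double.eps)
  vars <- apply(X, 2L, stats::var)
  all_zero <- scale2 <= .Machine$double.eps
  constant <- !all_zero & (vars / scale2) < tol
  drop <- all_zero | constant
  if (all(drop))
    stop("all descriptors are constant or zero; no modeling possible")
  log <- data.frame(
    descriptor = dataset$descriptor_names[drop],
    reason = ifelse(all_zero[drop], "all_zero", "constant"),
    stringsAsFactors = FALSE)
  out <- qsrr_dataset(X[, !drop, drop = FALSE], dataset$y, dataset$ids,
                      dataset$descriptor_names[!drop], dataset$split)
  attr(out, "removal_log") <- log
  out
}

#' Assign the train/test split of a dataset
#'
#' Flags the named observations as the external test set and every other
#' observation as training. With an empty `test_ids` all observations are
#' assigned to training.
#'
#' @param dataset a [qsrr_dataset].
#' @param test_ids character vector of observation ids (subset of
#'   `dataset$ids`); may be empty.
#' @return The dataset with its `split` field updated.
#' @export
assign_split <- function(dataset, test_ids) {
  stopifnot(inherits(dataset, "qsrr_dataset"))
  test_ids <- as.character(test_ids)
  unknown <- setdiff(test_ids, dataset$ids)
  if (length(unknown))
    stop("unknown observation ids: ", paste(unknown, collapse = ", "))
  dataset$split <- ifelse(dataset$ids %in% test_ids, "test", "train")
  dataset
}

#' Prediction table for a fitted QSRR model
#'
#' Pairs experimental retention factors with model predictions: the
#' calibration prediction for training rows, the cross-validation
#' prediction for training rows, and the external prediction for test rows.
#' Residuals always follow the convention `residual = predicted -
#' experimental`.
#'
#' @param ids observation ids.
#' @param set `"train"`/`"test"` flag per observation.
#' @param observed experimental retention factors.
#' @param predicted calibration prediction (train rows) or external
#'   prediction (test rows).
#' @param cv_predicted cross-validation prediction; `NA` for test rows.
#' @return A data frame of class `qsrr_predictions` with columns `id`,
#'   `set`, `observed`, `predicted`, `cv_predicted`, `residual`,
#'   `cv_residual`.
#' @export
prediction_table <- function(ids, set, observed, predicted,
                             cv_predicted = NA_real_) {
  set <- match.arg(set, c("train", "test"), several.ok = TRUE)
  n <- length(ids)
  cv_predicted <- rep_len(cv_predicted, n)
  if (any(set == "test" & !is.na(cv_predicted)))
    stop("test rows cannot carry cross-validation predictions")
  out <- data.frame(
    id = as.character(ids), set = set,
    observed = as.numeric(observed), predicted = as.numeric(predicted),
    cv_predicted = as.numeric(cv_predicted),
    stringsAsFactors = FALSE)
  out$residual <- out$predicted - out$observed
  out$cv_residual <- out$cv_predicted - out$observed
  class(out) <- c("qsrr_predictions", "data.frame")
  out
}

#' Packaged retention and prediction fixtures
#'
#' Accessors for the retention-factor tables and model prediction tables
#' shipped with the package: quinolones (21 major-microspecies
#' observations across buffer pH values, dead time 2.9 min; 16 train / 5
#' test) and sulfonamides (13 compounds x 3 acetonitrile percentages, dead
#' time 2.0 min; 30 train / 9 test).
#'
#' @param which `"quinolones"` or `"sulfonamides"`.
#' @param what `"retention"` for the retention-factor table (returned as a
#'   [qsrr_dataset]; the sulfonamide set carries the acetonitrile
#'   percentage as its single descriptor column), or `"predictions"` for
#'   the experimental/predicted table (returned as a `qsrr_predictions`
#'   data frame).
#' @return See `what`.
#' @examples
#' qsrr_fixture("quinolones", "retention")
#' head(qsrr_fixture("sulfonamides", "predictions"))
#' @export
qsrr_fixture <- function(which = c("quinolones", "sulfonamides"),
                         what = c("retention", "predictions")) {
  which <- match.arg(which)
  what <- match.arg(what)
  fname <- paste0(which, "_", if (what == "retention") "k" else "predictions",
                  ".csv")
  path <- system.file("extdata", fname, package = "fireflyQSRR",
                      mustWork = TRUE)
  cond_col <- if (which == "quinolones") "pH" else "acn_percent"
  if (what == "retention") {
    ds <- suppressMessages(load_dataset(
      path, response_column = "k",
      id_columns = c("compound", cond_col), split_column = "split",
      sep = ","))
    if (which == "sulfonamides") {
      # the mobile-phase acetonitrile percentage doubles as a descriptor
      raw <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
      ds <- qsrr_dataset(matrix(as.numeric(raw$acn_percent),
                                dimnames = list(NULL, "acn_percent")),
                         ds$y, ds$ids, "acn_percent", ds$split)
    }
    ds
  } else {
    raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
    ids <- paste(raw$compound, raw[[cond_col]], sep = "@")
    pt <- prediction_table(ids, raw$set, raw$k_exp, raw$k_pred, raw$k_cv)
    # keep the table's printed residuals for integrity checks
    attr(pt, "printed_residual") <- raw$resid
    attr(pt, "printed_cv_residual") <- raw$resid_cv
    pt
  }
}
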