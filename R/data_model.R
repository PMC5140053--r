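# Expression containers and conversion to the dynamics-derived regression task.

#' Construct an expression dataset
#'
#' Bundles one data source's expression matrix with the condition metadata
#' needed to turn it into a regression problem under a linear model of
#' transcription dynamics. Conditions are either steady state or members of a
#' time series; a time-series condition may name its predecessor condition and
#' the time gap separating them.
#'
#' @param values Numeric matrix of expression values, genes in rows and
#'   conditions in columns. Row and column names are required and must be
#'   unique; missing entries are rejected.
#' @param tf_ids Character vector of gene ids declared as transcription
#'   factors. Must be a subset of `rownames(values)`.
#' @param condition_meta Data frame with one row per condition and columns
#'   `condition`, `is_time_series` (logical), `predecessor` (condition id or
#'   `NA`) and `delta_t` (minutes, `NA` unless a predecessor is given). When
#'   omitted, all conditions are treated as steady state.
#' @param source_id Label for this data source (species, strain or platform).
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, tf_ids, condition_meta = NULL,
                               source_id = "source1") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x conditions)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and condition column names")
  }
  if (anyNA(values)) {
    stop("expression matrix for source '", source_id,
         "' contains missing values; missing data are rejected, not imputed")
  }
  gene_ids <- rownames(values)
  cond_ids <- colnames(values)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(cond_ids)) {
    stop("duplicate condition ids: ",
         paste(unique(cond_ids[duplicated(cond_ids)]), collapse = ", "))
  }
  tf_ids <- as.character(tf_ids)
  missing_tfs <- setdiff(tf_ids, gene_ids)
  if (length(missing_tfs) > 0) {
    stop("tf_ids not present among gene ids: ",
         paste(missing_tfs, collapse = ", "))
  }
  if (anyDuplicated(tf_ids)) stop("duplicate tf_ids")

  if (is.null(condition_meta)) {
    condition_meta <- data.frame(
      condition = cond_ids,
      is_time_series = FALSE,
      predecessor = NA_character_,
      delta_t = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  required <- c("condition", "is_time_series", "predecessor", "delta_t")
  if (!all(required %in% names(condition_meta))) {
    stop("condition_meta must have columns: ", paste(required, collapse = ", "))
  }
  condition_meta <- condition_meta[, required]
  condition_meta$condition <- as.character(condition_meta$condition)
  condition_meta$predecessor <- as.character(condition_meta$predecessor)
  if (!setequal(condition_meta$condition, cond_ids) ||
      anyDuplicated(condition_meta$condition)) {
    stop("condition_meta rows must match the expression columns one-to-one")
  }
  # align metadata to column order
  condition_meta <- condition_meta[match(cond_ids, condition_meta$condition), ]
  rownames(condition_meta) <- NULL

  has_pred <- !is.na(condition_meta$predecessor)
  if (any(has_pred & !condition_meta$is_time_series)) {
    stop("steady-state conditions cannot declare a predecessor")
  }
  bad_pred <- has_pred & !(condition_meta$predecessor %in% cond_ids)
  if (any(bad_pred)) {
    stop("predecessor condition not found: ",
         paste(condition_meta$predecessor[bad_pred], collapse = ", "))
  }
  if (any(has_pred & (is.na(condition_meta$delta_t) |
                      condition_meta$delta_t <= 0))) {
    stop("every condition with a predecessor needs delta_t > 0")
  }
  if (any(condition_meta$predecessor[has_pred] ==
          condition_meta$condition[has_pred])) {
    stop("a condition cannot be its own predecessor")
  }

  structure(
    list(
      source_id = as.character(source_id)[1],
      values = values,
      gene_ids = gene_ids,
      tf_ids = tf_ids,
      condition_meta = condition_meta
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  n_ts <- sum(x$condition_meta$is_time_series)
  cat("expression_dataset '", x$source_id, "': ",
      length(x$gene_ids), " genes (", length(x$tf_ids), " TFs) x ",
      ncol(x$values), " conditions (", n_ts, " time-series)\n", sep = "")
  invisible(x)
}

#' Build the dynamics-derived regression task
#'
#' Converts expression data into a multi-output regression problem
#' `Y = X beta` under a linear model of transcription dynamics with a shared
#' first-order decay rate `alpha`. Each steady-state condition contributes a
#' row with response `alpha * x(t_k)`; each time-series condition with a
#' predecessor contributes a row with response
#' `(x(t_{k+1}) - x(t_k)) / delta_t + alpha * x(t_k)`. Predictors are the TF
#' values at `t_k` (expression, or estimated activities when `predictors` is
#' supplied). Time-series conditions without a predecessor contribute no row.
#'
#' @param ds An [expression_dataset()].
#' @param alpha Shared mRNA decay rate per minute. The default 0.1 corresponds
#'   to an exponential decay time constant of 10 minutes. `alpha = 0` is
#'   accepted only when the dataset has no steady-state conditions (the
#'   convention used by the synthetic two-timepoint generator, where responses
#'   are pure expression differences).
#' @param predictors Optional matrix of predictor values (TFs x conditions),
#'   e.g. transcription factor activities from [estimate_tfa()]. Defaults to
#'   the TF rows of the expression matrix.
#'
#' @return An object of class `regression_task` with elements `X`
#'   (rows = usable conditions, columns = TFs), `Y` (same rows, columns =
#'   genes), `alpha`, `tf_ids`, `gene_ids`, `x_means`, `x_sds` and a
#'   `standardized` flag.
#' @export
build_response_design <- function(ds, alpha = 0.1, predictors = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("`alpha` must be a single non-negative decay rate (per minute)")
  }
  meta <- ds$condition_meta
  if (is.null(predictors)) {
    predictors <- ds$values[ds$tf_ids, , drop = FALSE]
  } else {
    if (!all(ds$tf_ids %in% rownames(predictors)) ||
        !all(colnames(ds$values) %in% colnames(predictors))) {
      stop("`predictors` must cover all TFs and all conditions of `ds`")
    }
    predictors <- predictors[ds$tf_ids, colnames(ds$values), drop = FALSE]
  }

  ss <- meta$condition[!meta$is_time_series]
  if (alpha == 0 && length(ss) > 0) {
    stop("alpha = 0 is only meaningful for datasets without steady-state ",
         "conditions (simulated two-timepoint designs)")
  }
  ts <- meta[meta$is_time_series & !is.na(meta$predecessor), , drop = FALSE]
  n_rows <- length(ss) + nrow(ts)
  if (n_rows == 0) stop("zero usable conditions: no steady-state condition ",
                        "and no time-series condition with a predecessor")

  vals <- ds$values
  X <- matrix(0, n_rows, length(ds$tf_ids),
              dimnames = list(NULL, ds$tf_ids))
  Y <- matrix(0, n_rows, length(ds$gene_ids),
              dimnames = list(NULL, ds$gene_ids))
  row_ids <- character(n_rows)
  r <- 0L
  for (k in ss) {
    r <- r + 1L
    X[r, ] <- predictors[, k]
    Y[r, ] <- alpha * vals[, k]
    row_ids[r] <- k
  }
  if (nrow(ts) > 0) {
    for (i in seq_len(nrow(ts))) {
      r <- r + 1L
      k1 <- ts$condition[i]
      k0 <- ts$predecessor[i]
      dt <- ts$delta_t[i]
      X[r, ] <- predictors[, k0]
      Y[r, ] <- (vals[, k1] - vals[, k0]) / dt + alpha * vals[, k0]
      row_ids[r] <- k1
    }
  }
  rownames(X) <- rownames(Y) <- row_ids

  structure(
    list(
      source_id = ds$source_id,
      X = X,
      Y = Y,
      alpha = alpha,
      tf_ids = ds$tf_ids,
      gene_ids = ds$gene_ids,
      x_means = stats::setNames(rep(0, length(ds$tf_ids)), ds$tf_ids),
      x_sds = stats::setNames(rep(1, length(ds$tf_ids)), ds$tf_ids),
      constant_cols = stats::setNames(rep(FALSE, length(ds$tf_ids)),
                                      ds$tf_ids),
      standardized = FALSE
    ),
    class = "regression_task"
  )
}

#' @export
print.regression_task <- function(x, ...) {
  cat("regression_task '", x$source_id, "': ", nrow(x$X), " rows, ",
      ncol(x$X), " TFs -> ", ncol(x$Y), " genes",
      if (x$standardized) " (standardized)", "\n", sep = "")
  invisible(x)
}

#' Standardize the predictor columns of a regression task
#'
#' Centers each predictor column and scales it to unit variance under the
#' population (1/n) convention, the scale on which the ridge and fusion
#' penalties operate. Constant columns are centered only and flagged. The
#' original-scale means and standard deviations are recorded (and composed
#' under repeated application) so fitted coefficients can be reported on
#' either scale via [rescale_network()].
#'
#' @param task A `regression_task` with at least two rows.
#' @return The task with standardized `X` and updated `x_means`, `x_sds`,
#'   `constant_cols` and `standardized`.
#' @export
standardize_predictors <- function(task) {
  stopifnot(inherits(task, "regression_task"))
  if (nrow(task$X) < 2) stop("standardization needs at least 2 rows")
  m <- colMeans(task$X)
  s <- sqrt(colMeans(sweep(task$X, 2, m, "-")^2)) # population convention
  const <- !is.finite(s) | s < 1e-12
  s[const] <- 1
  task$X <- sweep(sweep(task$X, 2, m, "-"), 2, s, "/")
  # compose with any earlier standardization: x_orig = m_tot + s_tot * x_new
  task$x_means <- task$x_means + task$x_sds * m
  task$x_sds <- task$x_sds * s
  task$constant_cols <- task$constant_cols | const
  task$standardized <- TRUE
  task
}

#' Restrict a regression task to a subset of rows
#'
#' Used by cross-validation; standardization parameters are carried over
#' unchanged (folds are evaluated on the scale fixed by the training data).
#'
#' @param task A `regression_task`.
#' @param rows Integer or logical index of rows to keep.
#' @return A `regression_task` on the selected rows.
#' @export
subset_task <- function(task, rows) {
  stopifnot(inherits(task, "regression_task"))
  task$X <- task$X[rows, , drop = FALSE]
  task$Y <- task$Y[rows, , drop = FALSE]
  task
}
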