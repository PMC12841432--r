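# Metrics and statistical comparison harness: MAE / RMSE / R-squared,
# per-sample absolute-error series, and paired t-tests on absolute
# prediction errors between model pairs.

#' Regression metrics
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2), finite.
#' @return Named numeric vector `c(mae, rmse, r2)`. `r2` is `NaN` (with a
#'   warning) when `y_true` has zero variance.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("regression_metrics: length mismatch")
  if (length(y_true) < 2) stop("regression_metrics: need at least 2 observations")
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred))) {
    stop("regression_metrics: inputs must be finite")
  }
  e <- y_true - y_pred
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) {
    warning("regression_metrics: zero variance in y_true; R2 undefined")
    r2 <- NaN
  } else {
    r2 <- 1 - sum(e^2) / sst
  }
  c(mae = mae, rmse = rmse, r2 = r2)
}

#' Paired t-test on absolute prediction errors
#'
#' Tests whether a baseline model's absolute errors exceed a proposed
#' model's on the same test samples: `d = abs_err_baseline - abs_err_proposed`,
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p-value, so a better proposed model gives a positive t.
#' Degenerate cases: zero variance with nonzero mean gives `t = +/-Inf`,
#' `p = 0`; identical vectors give `t = 0`, `p = 1`.
#'
#' @param abs_err_baseline,abs_err_proposed equal-length (n >= 2) vectors of
#'   absolute errors, same samples in the same order.
#' @return List with `t`, `p`, `n`.
#' @export
paired_residual_ttest <- function(abs_err_baseline, abs_err_proposed) {
  n <- length(abs_err_baseline)
  if (length(abs_err_proposed) != n) stop("paired_residual_ttest: length mismatch")
  if (n < 2) stop("paired_residual_ttest: need n >= 2 pairs")
  d <- abs_err_baseline - abs_err_proposed
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (md == 0) return(list(t = 0, p = 1, n = n))
    return(list(t = sign(md) * Inf, p = 0, n = n))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), n = n)
}

#' Compare prediction models on a common test set
#'
#' Each model must work with `predict(model, x_test)`. Fills per-model
#' MAE/RMSE/R-squared, the per-sample absolute-error series, and the full
#' pairwise paired-t table on absolute errors (row model as baseline, column
#' model as proposed, so `t[i, j] = -t[j, i]`). Models whose `predict` call
#' fails are recorded and excluded from the pairwise table.
#'
#' @param models named list of fitted models.
#' @param x_test feature matrix / data.frame for prediction.
#' @param y_test true labels.
#' @param p_adjust `"none"` (default) or `"holm"` correction across the
#'   pairwise p-values.
#' @return Object of class `evaluation_report`: list with `metrics`
#'   (data.frame), `abs_errors` (n x models matrix), `t_matrix`, `p_matrix`,
#'   `pairs` (long-format data.frame), `failed` (character).
#' @export
compare_models <- function(models, x_test, y_test, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(models) >= 1, !is.null(names(models)))
  preds <- list(); failed <- character(0)
  for (nm in names(models)) {
    p <- tryCatch(as.numeric(predict(models[[nm]], x_test)),
                  error = function(e) e)
    if (inherits(p, "error") || length(p) != length(y_test) || !all(is.finite(p))) {
      warning("model '", nm, "' failed to predict; excluded")
      failed <- c(failed, nm)
    } else {
      preds[[nm]] <- p
    }
  }
  if (!length(preds)) stop("compare_models: no model produced predictions")
  metrics <- do.call(rbind, lapply(names(preds), function(nm) {
    m <- regression_metrics(y_test, preds[[nm]])
    data.frame(model = nm, mae = m["mae"], rmse = m["rmse"], r2 = m["r2"],
               row.names = NULL)
  }))
  abs_err <- vapply(preds, function(p) abs(y_test - p), numeric(length(y_test)))
  k <- length(preds)
  tmat <- matrix(NA_real_, k, k, dimnames = list(names(preds), names(preds)))
  pmat <- tmat
  pairs <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    tt <- paired_residual_ttest(abs_err[, i], abs_err[, j])
    tmat[i, j] <- tt$t; pmat[i, j] <- tt$p
    if (i < j) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        baseline = names(preds)[i], proposed = names(preds)[j],
        t = tt$t, p = tt$p, n = tt$n)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(baseline = character(0), proposed = character(0),
               t = numeric(0), p = numeric(0), n = integer(0))
  if (p_adjust == "holm" && nrow(pairs)) {
    pairs$p_holm <- stats::p.adjust(pairs$p, "holm")
  }
  structure(list(metrics = metrics, abs_errors = abs_err, t_matrix = tmat,
                 p_matrix = pmat, pairs = pairs, failed = failed,
                 predictions = preds, y_test = y_test),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Model comparison report\n")
  m <- x$metrics
  m$mae <- sprintf("%.4f", m$mae); m$rmse <- sprintf("%.4f", m$rmse)
  m$r2 <- sprintf("%.4f", m$r2)
  print(m, row.names = FALSE)
  if (nrow(x$pairs)) {
    cat("\nPaired t-tests on absolute errors (baseline vs proposed):\n")
    p <- x$pairs
    p$t <- sprintf("%.3f", p$t); p$p <- format(p$p, digits = 3)
    print(p, row.names = FALSE)
  }
  if (length(x$failed)) cat("\nFailed models:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits a JSON summary and a CSV of per-sample absolute errors.
#'
#' @param report an `evaluation_report`.
#' @param path_json,path_csv output files (either may be `NULL` to skip).
#' @return `report` invisibly.
#' @export
write_evaluation_report <- function(report, path_json = NULL, path_csv = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(metrics = report$metrics, pairs = report$pairs, failed = report$failed),
      path_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(path_csv)) {
    df <- data.frame(sample_index = seq_len(nrow(report$abs_errors)),
                     report$abs_errors, check.names = FALSE)
    write.csv(df, path_csv, row.names = FALSE)
  }
  invisible(report)
}

# ---- baseline adapters (comparison plumbing, not re-implementations) --------

.baseline <- function(fit, predict_fun, label) {
  structure(list(fit = fit, predict_fun = predict_fun, label = label),
            class = "grainrisk_baseline")
}

#' @export
predict.grainrisk_baseline <- function(object, newdata, ...) {
  object$predict_fun(object$fit, as.matrix(newdata))
}

#' @export
print.grainrisk_baseline <- function(x, ...) {
  cat("Baseline adapter:", x$label, "\n"); invisible(x)
}

#' Baseline model adapters
#'
#' Thin wrappers around established implementations, used only as comparison
#' points in the evaluation harness: random forest (`randomForest`),
#' gradient boosting (`xgboost`), RBF-kernel support vector regression
#' (`e1071`) and a single-hidden-layer backpropagation network (`nnet`).
#'
#' @param x feature matrix; `y` numeric response.
#' @param y numeric response vector.
#' @param ... passed to the underlying fitting function.
#' @return A fitted adapter usable with `predict(fit, newdata)`.
#' @name baselines
NULL

#' @rdname baselines
#' @export
baseline_random_forest <- function(x, y, ...) {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    stop("baseline_random_forest requires the 'randomForest' package")
  }
  fit <- randomForest::randomForest(as.matrix(x), y, ntree = 300, ...)
  .baseline(fit, function(f, nd) unname(predict(f, nd)), "random forest")
}

#' @rdname baselines
#' @param nrounds boosting rounds.
#' @export
baseline_xgboost <- function(x, y, nrounds = 300, ...) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("baseline_xgboost requires the 'xgboost' package")
  }
  fit <- xgboost::xgboost(as.matrix(x), y, objective = "reg:squarederror",
                          nrounds = nrounds, nthreads = 1, verbosity = 0, ...)
  .baseline(fit, function(f, nd) predict(f, nd), "gradient boosting (xgboost)")
}

#' @rdname baselines
#' @export
baseline_rbf_svm <- function(x, y, ...) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("baseline_rbf_svm requires the 'e1071' package")
  }
  fit <- e1071::svm(as.matrix(x), y, kernel = "radial", ...)
  .baseline(fit, function(f, nd) unname(predict(f, nd)), "RBF support vector regression")
}

#' @rdname baselines
#' @param size hidden-layer width.
#' @export
baseline_mlp <- function(x, y, size = 16, ...) {
  if (!requireNamespace("nnet", quietly = TRUE)) {
    stop("baseline_mlp requires the 'nnet' package")
  }
  fit <- nnet::nnet(as.matrix(x), y, size = size, linout = TRUE, trace = FALSE,
                    maxit = 500, decay = 1e-4, ...)
  .baseline(fit, function(f, nd) as.numeric(predict(f, nd)), "backprop MLP")
}
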