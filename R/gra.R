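# Grey Relational Analysis composite risk scoring.
#
# The score of a sample is a weighted combination of its range-normalized
# hazard-indicator profile; weights come from grey relational coefficients of
# each indicator against a reference (maximum-hazard) sequence, following the
# classical Deng formulation. All indicators are treated as larger-is-worse.

#' Range (min-max) normalization of a contaminant table
#'
#' Each indicator column is mapped to `[0, 1]` by
#' `Z = (X - min) / (max - min)`. A constant column (max == min) carries no
#' ordering information and is mapped to the neutral midpoint 0.5 with a
#' warning.
#'
#' @param table a `contaminant_table` (or a plain numeric matrix with
#'   samples in rows).
#' @return Object of class `normalized_matrix`: list with `Z` (n x m matrix in
#'   `[0,1]`), `column_min`, `column_max`.
#' @export
normalize_minmax <- function(table) {
  X <- if (is.matrix(table)) table else indicator_matrix(table)
  if (nrow(X) < 2) stop("normalization needs at least 2 rows")
  if (!all(is.finite(X))) stop("normalization requires finite values")
  cmin <- apply(X, 2, min)
  cmax <- apply(X, 2, max)
  rng <- cmax - cmin
  const <- rng == 0
  if (any(const)) {
    warning("constant indicator column(s) mapped to 0.5: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, cmin, "-"), 2, ifelse(const, 1, rng), "/")
  Z[, const] <- 0.5
  structure(list(Z = Z, column_min = cmin, column_max = cmax),
            class = "normalized_matrix")
}

#' Grey relational coefficients against a reference sequence
#'
#' For reference profile `x0` (by default the all-ones maximum-hazard profile
#' in normalized space) the coefficient of indicator `i` on sample `k` is
#' \deqn{\gamma_{ik} = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                          {|x_0(i) - Z_{ki}| + \rho\,\Delta_{max}}}
#' with \eqn{\Delta_{min}}/\eqn{\Delta_{max}} the global extremes of the
#' absolute deviations, so every coefficient lies in
#' `[rho/(1+rho), 1]`. The distinguishability factor `rho` in (0,1) controls
#' the contrast between coefficients; the conventional default is 0.5.
#'
#' @param Z a `normalized_matrix` (or plain matrix in `[0,1]`, samples in rows).
#' @param rho distinguishability factor in (0, 1).
#' @param reference `"ideal"` (all-ones profile) or `"worst_observed"`
#'   (profile of the sample with the largest row sum).
#' @return m x n matrix of coefficients (indicators in rows, samples in
#'   columns).
#' @export
relational_coefficients <- function(Z, rho = 0.5, reference = c("ideal", "worst_observed")) {
  reference <- match.arg(reference)
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) || rho <= 0 || rho >= 1) {
    stop("'rho' must lie strictly inside (0, 1)")
  }
  Zm <- if (inherits(Z, "normalized_matrix")) Z$Z else Z
  x0 <- if (reference == "ideal") {
    rep(1, ncol(Zm))
  } else {
    Zm[which.max(rowSums(Zm)), ]
  }
  # deviations: samples in rows
  dev <- abs(sweep(Zm, 2, x0, "-"))
  dmin <- min(dev)
  dmax <- max(dev)
  if (dmax == 0) {
    gam <- matrix(1, nrow(Zm), ncol(Zm))
  } else {
    gam <- (dmin + rho * dmax) / (dev + rho * dmax)
  }
  out <- t(gam)                       # indicators x samples
  dimnames(out) <- list(colnames(Zm), rownames(Zm))
  out
}

#' Indicator weights from a relational-coefficient matrix
#'
#' Each indicator's relational degree (its coefficient row sum) is normalized
#' by the grand total, yielding non-negative weights that sum to 1.
#'
#' @param gamma m x n relational-coefficient matrix (indicators in rows).
#' @return Numeric weight vector of length m.
#' @export
indicator_weights <- function(gamma) {
  if (!is.matrix(gamma) || !length(gamma)) stop("'gamma' must be a non-empty matrix")
  if (any(gamma <= 0)) stop("'gamma' entries must be positive")
  w <- rowSums(gamma) / sum(gamma)
  names(w) <- rownames(gamma)
  w
}

#' Composite risk values
#'
#' `R_k = sum_i w_i * Z_ki`: the weight-combined normalized contamination
#' profile of each sample, guaranteed to lie in `[0, 1]`.
#'
#' @param Z a `normalized_matrix` or plain matrix (samples in rows).
#' @param weights weight vector summing to 1.
#' @return Numeric vector of per-sample risk values.
#' @export
composite_risk <- function(Z, weights) {
  Zm <- if (inherits(Z, "normalized_matrix")) Z$Z else Z
  if (ncol(Zm) != length(weights)) stop("dimension mismatch between Z and weights")
  if (abs(sum(weights) - 1) > 1e-9) stop("'weights' must sum to 1")
  drop(Zm %*% weights)
}

#' Score a contaminant table by Grey Relational Analysis
#'
#' Runs the full chain — range normalization, relational coefficients,
#' indicator weights, composite risk — and attaches the risk values to the
#' table. The result carries a histogram of risk values over bins of width
#' 0.1 for reporting.
#'
#' @param table a `contaminant_table`.
#' @param rho distinguishability factor (default 0.5).
#' @param reference reference profile, see [relational_coefficients()].
#' @return Object of class `gra_result`: list with `normalized`
#'   (`normalized_matrix`), `coefficients` (m x n), `weights`, `risk`
#'   (length-n vector), `rho`, `reference`, `histogram` (counts over
#'   `[0,0.1), ..., [0.9,1]`), and `table` (the input with a `risk_value`
#'   column appended).
#' @export
#' @examples
#' tab <- generate_samples(generator_config(n_samples = 200, seed = 2))
#' sc <- gra_score(tab)
#' sc$weights
gra_score <- function(table, rho = 0.5, reference = c("ideal", "worst_observed")) {
  reference <- match.arg(reference)
  nm <- normalize_minmax(table)
  gam <- relational_coefficients(nm, rho, reference)
  w <- indicator_weights(gam)
  r <- composite_risk(nm, w)
  breaks <- seq(0, 1, by = 0.1)
  bin <- findInterval(r, breaks, rightmost.closed = TRUE)   # [0,.1), ..., [.9,1]
  hist_counts <- tabulate(bin, nbins = 10L)
  names(hist_counts) <- sprintf("[%.1f,%.1f)", breaks[1:10], breaks[2:11])
  labelled <- as.data.frame(table)
  labelled$risk_value <- unname(r)
  structure(
    list(normalized = nm, coefficients = gam, weights = w, risk = unname(r),
         rho = rho, reference = reference,
         histogram = hist_counts,
         table = labelled),
    class = "gra_result"
  )
}

#' @export
print.gra_result <- function(x, ...) {
  cat(sprintf("Grey relational risk scoring (rho = %.2f, reference = %s)\n",
              x$rho, x$reference))
  cat(sprintf("  %d samples, %d indicators\n", length(x$risk), length(x$weights)))
  cat("  indicator weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("  risk: min %.3f  median %.3f  max %.3f\n",
              min(x$risk), median(x$risk), max(x$risk)))
  invisible(x)
}

#' @export
summary.gra_result <- function(object, ...) {
  cat("Composite risk distribution (bin width 0.1):\n")
  print(object$histogram)
  cat("\nIndicator weights:\n")
  print(round(object$weights, 4))
  invisible(object)
}

#' Risk histogram as a plain data.frame
#'
#' @param result a `gra_result`.
#' @return data.frame with columns `bin` and `count`.
#' @export
risk_histogram <- function(result) {
  stopifnot(inherits(result, "gra_result"))
  data.frame(bin = names(result$histogram), count = unname(result$histogram),
             stringsAsFactors = FALSE)
}
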