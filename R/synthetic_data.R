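#' @importFrom stats qlnorm plnorm qgamma pgamma runif rnorm sd var predict
#'   coef residuals median qt pt quantile dist optim setNames dnorm pnorm
#' @importFrom utils read.csv write.csv head tail
#' @importFrom graphics matplot legend
"_PACKAGE"

# -- indicator specifications ------------------------------------------------

#' Default hazard-indicator specifications for wheat detection data
#'
#' Six indicators routinely monitored in wheat: total pesticide residues,
#' three heavy metals (lead, cadmium, arsenic) and two Fusarium mycotoxins
#' (deoxynivalenol, DON; zearalenone, ZEN). Concentrations follow
#' positively-skewed lognormal distributions; the regulatory-style limits
#' are configuration values with food-code-like defaults (mg/kg for
#' pesticides and metals, µg/kg for mycotoxins).
#'
#' @return A data.frame with one row per indicator and columns `name`,
#'   `family` (`"lognormal"` or `"gamma"`), `par1`, `par2` (meanlog/sdlog or
#'   shape/rate), `unit`, and `threshold` (the exceedance limit, same unit).
#' @export
#' @examples
#' default_indicators()
default_indicators <- function() {
  data.frame(
    name      = c("pesticide_residue", "lead", "cadmium", "arsenic", "DON", "ZEN"),
    family    = "lognormal",
    par1      = c(log(0.010), log(0.035), log(0.020), log(0.060), log(250), log(12)),
    par2      = c(0.50, 0.45, 0.45, 0.40, 0.45, 0.50),
    unit      = c("mg/kg", "mg/kg", "mg/kg", "mg/kg", "ug/kg", "ug/kg"),
    threshold = c(0.05, 0.2, 0.1, 0.5, 1000, 60),
    stringsAsFactors = FALSE
  )
}

#' Named vector of default exceedance thresholds
#'
#' @param indicators indicator specification data.frame
#'   (default [default_indicators()]).
#' @return Named numeric vector of limits, one per indicator.
#' @export
default_thresholds <- function(indicators = default_indicators()) {
  setNames(indicators$threshold, indicators$name)
}

# -- generator configuration -------------------------------------------------

#' Configuration for the synthetic contaminant-table generator
#'
#' The generator emulates a multi-year institutional wheat detection dataset:
#' six positively-skewed indicator concentrations, batch/region/date metadata
#' spanning a configurable window, and a controllable fraction of samples with
#' at least one indicator above its safety limit.
#'
#' @param n_samples number of sample rows to generate (>= 0).
#' @param indicators indicator specification data.frame as returned by
#'   [default_indicators()]; must have exactly the columns documented there.
#' @param exceedance_fraction proportion of rows in `[0, 1]` that carry at
#'   least one exceeding indicator.
#' @param date_range length-2 vector of dates (coercible by `as.Date`)
#'   giving the inclusive detection-date window.
#' @param n_batches number of production batches to spread samples over.
#' @param n_regions number of sampling regions.
#' @param seed integer seed driving all randomness of the generator.
#' @return An object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_samples = 100, seed = 1)
#' tab <- generate_samples(cfg)
generator_config <- function(n_samples = 6785,
                             indicators = default_indicators(),
                             exceedance_fraction = 0.15,
                             date_range = c("2018-01-01", "2023-12-31"),
                             n_batches = 40,
                             n_regions = 8,
                             seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || is.na(n_samples) ||
      n_samples < 0 || n_samples != round(n_samples)) {
    stop("invalid generator config: 'n_samples' must be a single non-negative integer")
  }
  req <- c("name", "family", "par1", "par2", "unit", "threshold")
  if (!is.data.frame(indicators) || !all(req %in% names(indicators))) {
    stop("invalid generator config: 'indicators' must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  if (anyDuplicated(indicators$name)) {
    stop("invalid generator config: 'indicators' names must be unique")
  }
  if (!all(indicators$family %in% c("lognormal", "gamma"))) {
    stop("invalid generator config: 'indicators' family must be 'lognormal' or 'gamma'")
  }
  if (!all(is.finite(indicators$par2)) || any(indicators$par2 <= 0)) {
    stop("invalid generator config: 'indicators' scale parameters (par2) must be strictly positive")
  }
  if (any(indicators$family == "gamma" & indicators$par1 <= 0)) {
    stop("invalid generator config: 'indicators' gamma shape (par1) must be strictly positive")
  }
  if (!all(is.finite(indicators$threshold)) || any(indicators$threshold <= 0)) {
    stop("invalid generator config: 'indicators' thresholds must be strictly positive")
  }
  if (!is.numeric(exceedance_fraction) || length(exceedance_fraction) != 1 ||
      is.na(exceedance_fraction) || exceedance_fraction < 0 || exceedance_fraction > 1) {
    stop("invalid generator config: 'exceedance_fraction' must lie in [0, 1]")
  }
  dr <- tryCatch(as.Date(date_range), error = function(e) NA)
  if (length(dr) != 2 || anyNA(dr) || dr[1] > dr[2]) {
    stop("invalid generator config: 'date_range' must be two ordered dates")
  }
  if (!is.numeric(n_batches) || length(n_batches) != 1 || n_batches < 1) {
    stop("invalid generator config: 'n_batches' must be a positive integer")
  }
  if (!is.numeric(n_regions) || length(n_regions) != 1 || n_regions < 1) {
    stop("invalid generator config: 'n_regions' must be a positive integer")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("invalid generator config: 'seed' must be a single integer")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      indicators = indicators,
      exceedance_fraction = exceedance_fraction,
      date_range = dr,
      n_batches = as.integer(n_batches),
      n_regions = as.integer(n_regions),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic contaminant-table generator configuration\n")
  cat(sprintf("  samples: %d   exceedance fraction: %.3f   seed: %d\n",
              x$n_samples, x$exceedance_fraction, x$seed))
  cat(sprintf("  dates: %s .. %s   batches: %d   regions: %d\n",
              format(x$date_range[1]), format(x$date_range[2]),
              x$n_batches, x$n_regions))
  cat(sprintf("  indicators: %s\n", paste(x$indicators$name, collapse = ", ")))
  invisible(x)
}

# truncated draw via inverse CDF; side = "below" keeps mass in [0, thr],
# "above" in (thr, Inf)
.draw_truncated <- function(n, family, par1, par2, thr, side) {
  if (n == 0) return(numeric(0))
  pf <- switch(family,
    lognormal = function(q) plnorm(q, par1, par2),
    gamma     = function(q) pgamma(q, shape = par1, rate = par2))
  qf <- switch(family,
    lognormal = function(p) qlnorm(p, par1, par2),
    gamma     = function(p) qgamma(p, shape = par1, rate = par2))
  pt_ <- pf(thr)
  u <- if (side == "below") runif(n, 0, pt_) else runif(n, pt_, 1)
  x <- qf(u)
  # guard against quantile rounding placing a draw on the wrong side of thr
  if (side == "below") pmin(x, thr) else pmax(x, thr * (1 + 1e-12))
}

#' Generate a synthetic contaminant detection table
#'
#' Draws `n_samples` rows. Exceedance status is assigned first
#' (Bernoulli with the configured fraction); compliant rows draw every
#' indicator from its distribution truncated below its limit, exceeding rows
#' draw one uniformly-chosen indicator truncated above its limit and the rest
#' truncated below. This two-component design guarantees a controllable
#' positive class for the downstream ledger routing.
#'
#' @param config a [generator_config()].
#' @return A `contaminant_table`: a data.frame with columns `sample_id`,
#'   `batch_id`, `region`, `detection_date` (Date) and one numeric column per
#'   indicator, plus an `indicators` attribute carrying the spec used.
#' @export
generate_samples <- function(config) {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  ind <- config$indicators
  m <- nrow(ind)
  n <- config$n_samples

  set.seed(config$seed)
  if (n == 0) {
    vals <- matrix(numeric(0), 0, m, dimnames = list(NULL, ind$name))
    tab <- data.frame(sample_id = character(0), batch_id = character(0),
                      region = character(0),
                      detection_date = as.Date(character(0)),
                      stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(vals))
    return(as_contaminant_table(tab, ind))
  }

  exceeding <- runif(n) < config$exceedance_fraction
  which_ind <- sample.int(m, n, replace = TRUE)   # violated indicator for exceeding rows

  vals <- matrix(NA_real_, n, m, dimnames = list(NULL, ind$name))
  for (j in seq_len(m)) {
    below <- !exceeding | which_ind != j
    vals[below, j] <- .draw_truncated(sum(below), ind$family[j], ind$par1[j],
                                      ind$par2[j], ind$threshold[j], "below")
    vals[!below, j] <- .draw_truncated(sum(!below), ind$family[j], ind$par1[j],
                                       ind$par2[j], ind$threshold[j], "above")
  }

  days <- as.integer(config$date_range[2] - config$date_range[1])
  dates <- config$date_range[1] + sample.int(days + 1L, n, replace = TRUE) - 1L
  batches <- sprintf("B%03d", sample.int(config$n_batches, n, replace = TRUE))
  regions <- sprintf("R%02d", sample.int(config$n_regions, n, replace = TRUE))

  tab <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n)),
    batch_id = batches,
    region = regions,
    detection_date = dates,
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(vals))
  as_contaminant_table(tab, ind)
}

# -- contaminant_table class -------------------------------------------------

.meta_cols <- c("sample_id", "batch_id", "region", "detection_date")

#' Coerce a data.frame to a contaminant table
#'
#' Validates the schema (metadata columns, unique sample IDs, finite
#' non-negative concentrations) and tags the object with its indicator spec.
#'
#' @param x data.frame with columns `sample_id`, `batch_id`, `region`,
#'   `detection_date`, then one numeric column per indicator.
#' @param indicators indicator spec data.frame; defaults to
#'   [default_indicators()] restricted to the value columns present.
#' @return A validated `contaminant_table`.
#' @export
as_contaminant_table <- function(x, indicators = NULL) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.meta_cols, names(x))
  if (length(missing_cols)) {
    stop("contaminant table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(indicators)) {
    def <- default_indicators()
    present <- intersect(def$name, names(x))
    if (!length(present)) stop("contaminant table has no recognised indicator columns")
    indicators <- def[match(present, def$name), , drop = FALSE]
  }
  missing_ind <- setdiff(indicators$name, names(x))
  if (length(missing_ind)) {
    stop("contaminant table is missing column(s): ", paste(missing_ind, collapse = ", "))
  }
  if (anyDuplicated(x$sample_id)) stop("contaminant table: 'sample_id' values must be unique")
  for (nm in indicators$name) {
    v <- x[[nm]]
    if (!is.numeric(v)) stop("indicator column '", nm, "' is not numeric")
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      stop("indicator column '", nm, "' has non-finite or negative value at row ", bad[1])
    }
  }
  x$detection_date <- as.Date(x$detection_date)
  rownames(x) <- NULL
  structure(x, indicators = indicators,
            class = c("contaminant_table", "data.frame"))
}

#' Extract the indicator value matrix of a contaminant table
#'
#' @param table a `contaminant_table`.
#' @return Numeric matrix, samples in rows, indicators in columns.
#' @export
indicator_matrix <- function(table) {
  ind <- attr(table, "indicators")
  m <- as.matrix(as.data.frame(table)[, ind$name, drop = FALSE])
  rownames(m) <- table$sample_id
  m
}

#' @export
print.contaminant_table <- function(x, ...) {
  ind <- attr(x, "indicators")
  cat(sprintf("Contaminant detection table: %d samples x %d indicators\n",
              nrow(x), nrow(ind)))
  if (nrow(x)) {
    cat(sprintf("  dates %s .. %s\n", format(min(x$detection_date)),
                format(max(x$detection_date))))
  }
  print(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

# -- splitting ---------------------------------------------------------------

#' Split a contaminant table into train / validation / test partitions
#'
#' @param table a `contaminant_table`.
#' @param ratios numeric triple of positive-or-zero proportions summing to 1.
#' @param seed integer seed for the permutation.
#' @return Named list of three `contaminant_table`s: `train`, `validation`,
#'   `test`. Partition sizes are the rounded proportions; the partition is
#'   disjoint and exhaustive and deterministic per seed.
#' @export
split_dataset <- function(table, ratios = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(inherits(table, "contaminant_table"))
  if (length(ratios) != 3 || any(ratios < 0)) {
    stop("'ratios' must be three non-negative proportions")
  }
  if (abs(sum(ratios) - 1) > 1e-9) stop("'ratios' must sum to 1")
  n <- nrow(table)
  n1 <- round(n * ratios[1])
  n2 <- round(n * ratios[2])
  n3 <- n - n1 - n2
  if (n3 < 0) { n2 <- n2 + n3; n3 <- 0 }
  set.seed(seed)
  perm <- sample.int(n)
  idx <- list(train = perm[seq_len(n1)],
              validation = perm[n1 + seq_len(n2)],
              test = perm[n1 + n2 + seq_len(n3)])
  ind <- attr(table, "indicators")
  lapply(idx, function(i) as_contaminant_table(as.data.frame(table)[sort(i), , drop = FALSE], ind))
}

# -- CSV I/O -----------------------------------------------------------------

#' Write a contaminant table to CSV
#'
#' Concentrations are rendered with `%.17g` so the file is byte-stable across
#' runs and round-trips exactly through [read_contaminant_table()].
#'
#' @param table a `contaminant_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_contaminant_table <- function(table, path) {
  stopifnot(inherits(table, "contaminant_table"))
  ind <- attr(table, "indicators")
  out <- as.data.frame(table)
  out$detection_date <- format(out$detection_date, "%Y-%m-%d")
  for (nm in ind$name) out[[nm]] <- sprintf("%.17g", out[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a contaminant table from CSV
#'
#' @param path CSV file with header `sample_id,batch_id,region,detection_date`
#'   followed by one column per indicator; dates ISO-8601.
#' @param indicators indicator spec the file must satisfy
#'   (default [default_indicators()]).
#' @return A validated `contaminant_table`.
#' @export
read_contaminant_table <- function(path, indicators = default_indicators()) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(c(.meta_cols, indicators$name), names(raw))
  if (length(missing_cols)) {
    stop("file '", path, "' is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- as.Date(raw$detection_date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("malformed detection_date at row ", which(is.na(d))[1])
  }
  raw$detection_date <- d
  for (nm in indicators$name) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v))
    if (length(bad)) stop("non-numeric value in column '", nm, "' at row ", bad[1])
    neg <- which(v < 0)
    if (length(neg)) stop("negative concentration in column '", nm, "' at row ", neg[1])
    raw[[nm]] <- v
  }
  as_contaminant_table(raw, indicators)
}
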