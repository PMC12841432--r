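# Gaussian-process Bayesian optimization for hyperparameter tuning.
#
# Small, self-contained GP surrogate (Matern-5/2 kernel on unit-scaled
# coordinates, log-scaled dimensions transformed first) with expected
# improvement acquisition maximized over a seeded quasi-random candidate
# pool. Integer dimensions are obtained by rounding.

#' Define a hyperparameter search space
#'
#' @param dims list of dimension specs, each a list with `name`, `lower`,
#'   `upper`, optional `integer = TRUE` and `log = TRUE` (log10-scaled).
#' @return Object of class `search_space`.
#' @export
search_space <- function(dims) {
  for (d in dims) {
    stopifnot(!is.null(d$name), is.numeric(d$lower), is.numeric(d$upper))
    if (!(d$lower < d$upper)) stop("search_space: lower must be < upper for ", d$name)
    if (isTRUE(d$log) && d$lower <= 0) stop("search_space: log dims need positive bounds")
  }
  structure(list(dims = dims), class = "search_space")
}

#' The TabNet hyperparameter search space
#'
#' Decision and attention widths in `[8, 128]` (integer), steps in
#' `[3, 10]` (integer), relaxation gamma in `[1, 2]`, sparsity coefficient
#' in `[1e-6, 0.01]` (log scale) and learning rate in `[1e-4, 0.01]`
#' (log scale).
#'
#' @return A `search_space`.
#' @export
tabnet_search_space <- function() {
  search_space(list(
    list(name = "n_d", lower = 8, upper = 128, integer = TRUE),
    list(name = "n_a", lower = 8, upper = 128, integer = TRUE),
    list(name = "n_steps", lower = 3, upper = 10, integer = TRUE),
    list(name = "gamma", lower = 1.0, upper = 2.0),
    list(name = "lambda_sparse", lower = 1e-6, upper = 0.01, log = TRUE),
    list(name = "learning_rate", lower = 1e-4, upper = 0.01, log = TRUE)
  ))
}

# map a config (named list) to the unit cube and back
.space_to_unit <- function(space, conf) {
  vapply(space$dims, function(d) {
    x <- conf[[d$name]]
    if (isTRUE(d$log)) {
      (log10(x) - log10(d$lower)) / (log10(d$upper) - log10(d$lower))
    } else {
      (x - d$lower) / (d$upper - d$lower)
    }
  }, numeric(1))
}

.space_from_unit <- function(space, u) {
  conf <- list()
  for (i in seq_along(space$dims)) {
    d <- space$dims[[i]]
    x <- if (isTRUE(d$log)) {
      10^(log10(d$lower) + u[i] * (log10(d$upper) - log10(d$lower)))
    } else {
      d$lower + u[i] * (d$upper - d$lower)
    }
    if (isTRUE(d$integer)) x <- as.integer(round(x))
    x <- min(max(x, d$lower), d$upper)
    conf[[d$name]] <- x
  }
  conf
}

# ---- GP surrogate -----------------------------------------------------------

.matern52 <- function(D, ell) {
  r <- sqrt(5) * D / ell
  (1 + r + r^2 / 3) * exp(-r)
}

# fit an isotropic Matern-5/2 GP with standardized targets; lengthscale and
# noise chosen by marginal likelihood over a small grid (robust, derivative
# free, deterministic)
.gp_fit <- function(U, y) {
  n <- nrow(U)
  mu <- mean(y); sdy <- sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  D <- as.matrix(dist(U))
  best <- NULL
  for (ell in c(0.05, 0.1, 0.2, 0.35, 0.5, 1, 2)) {
    for (nz in c(1e-6, 1e-4, 1e-2)) {
      K <- .matern52(D, ell) + diag(nz, n)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), ys))
      s2 <- max(drop(crossprod(ys, alpha)) / n, 1e-12)
      nll <- 0.5 * n * log(s2) + sum(log(diag(ch)))
      if (is.null(best) || nll < best$nll) {
        best <- list(nll = nll, ell = ell, nz = nz, chol = ch, alpha = alpha,
                     s2 = s2)
      }
    }
  }
  c(best, list(U = U, mu = mu, sdy = sdy, ys = ys))
}

.gp_predict <- function(gp, Unew) {
  Dx <- sqrt(pmax(outer(rowSums(Unew^2), rowSums(gp$U^2), "+") -
                    2 * tcrossprod(Unew, gp$U), 0))
  Ks <- .matern52(Dx, gp$ell)
  mean_s <- drop(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(Ks))
  var_s <- pmax(.matern52(0, gp$ell) + gp$nz - colSums(v^2), 0) * gp$s2
  list(mean = gp$mu + gp$sdy * mean_s, sd = gp$sdy * sqrt(var_s))
}

# expected improvement (minimization), jitter xi
.expected_improvement <- function(mean, sd, best, xi = 0.01) {
  imp <- best - mean - xi
  ei <- numeric(length(mean))
  pos <- sd > 0
  z <- imp[pos] / sd[pos]
  ei[pos] <- imp[pos] * pnorm(z) + sd[pos] * dnorm(z)
  ei[!pos] <- pmax(imp[!pos], 0)
  pmax(ei, 0)
}

# ---- suggest / optimize -----------------------------------------------------

.lhs_design <- function(n, d, seed) {
  set.seed(seed)
  lhs::randomLHS(n, d)
}

#' Suggest the next configuration to evaluate
#'
#' Below `n_init` completed evaluations the suggestion comes from a seeded
#' Latin-hypercube initial design; afterwards a Matern-5/2 GP is fitted to
#' the completed trials and the expected-improvement maximizer over a
#' seeded quasi-random candidate pool is returned (with a duplicate guard).
#'
#' @param trace a `tuning_trace` (may be empty, see [bo_optimize()]).
#' @param space a `search_space`.
#' @param seed integer seed.
#' @param n_init size of the initial design.
#' @param n_candidates candidate-pool size per iteration.
#' @param xi EI jitter.
#' @return Named list: the candidate configuration.
#' @export
suggest_next <- function(trace, space, seed, n_init = 5L,
                         n_candidates = 1000L, xi = 0.01) {
  if (!length(space$dims)) stop("suggest_next: empty search space")
  d <- length(space$dims)
  k <- length(trace$objective)
  done <- is.finite(trace$objective)
  if (k < n_init) {
    design <- .lhs_design(n_init, d, seed)
    return(.space_from_unit(space, design[k + 1L, ]))
  }
  if (sum(done) < 2) {       # surrogate needs completed trials; fall back
    set.seed(seed + 104729L * (k + 1L))
    return(.space_from_unit(space, runif(d)))
  }
  U <- do.call(rbind, lapply(trace$configs[done],
                             function(cf) .space_to_unit(space, cf)))
  y <- trace$objective[done]
  gp <- .gp_fit(U, y)
  set.seed(seed + 7919L * (k + 1L))
  cand <- lhs::randomLHS(n_candidates, d)
  pr <- .gp_predict(gp, cand)
  ei <- .expected_improvement(pr$mean, pr$sd, min(y), xi)
  ord <- order(ei, decreasing = TRUE)
  for (i in ord) {
    u <- cand[i, ]
    dup <- any(vapply(seq_len(nrow(U)),
                      function(j) sqrt(sum((U[j, ] - u)^2)) < 1e-8, logical(1)))
    # also guard against re-proposing an identical rounded config
    conf <- .space_from_unit(space, u)
    dup2 <- any(vapply(trace$configs[done], function(cf) {
      identical(.space_from_unit(space, .space_to_unit(space, cf)), conf)
    }, logical(1)))
    if (!dup && !dup2) return(conf)
  }
  .space_from_unit(space, cand[ord[1], ])
}

#' Run Bayesian optimization over a search space
#'
#' Evaluates exactly `budget` configurations: a seeded Latin-hypercube
#' initial design of `n_init` points followed by GP/EI suggestions. Failing
#' objective evaluations are recorded as `Inf` and skipped by the surrogate.
#'
#' @param objective function taking a configuration (named list) and
#'   returning a scalar to minimize.
#' @param space a `search_space`.
#' @param budget total number of evaluations (>= `n_init` recommended).
#' @param seed integer seed; the whole trace is deterministic given it.
#' @param n_init initial-design size.
#' @param xi EI jitter.
#' @return Object of class `tuning_trace`: list with `configs`, `objective`,
#'   `ei` (EI of each chosen point, `NA` during the initial design),
#'   `incumbent` (best config) and `incumbent_value`.
#' @export
bo_optimize <- function(objective, space, budget, seed = 1L, n_init = 5L,
                        xi = 0.01) {
  stopifnot(budget >= 1)
  n_init <- min(n_init, budget)
  trace <- list(configs = list(), objective = numeric(0), ei = numeric(0))
  class(trace) <- "tuning_trace"
  for (k in seq_len(budget)) {
    conf <- suggest_next(trace, space, seed, n_init = n_init, xi = xi)
    val <- tryCatch(as.numeric(objective(conf)), error = function(e) Inf)
    if (!is.finite(val)) val <- Inf
    trace$configs[[k]] <- conf
    trace$objective[k] <- val
  }
  best <- which.min(trace$objective)
  trace$incumbent <- trace$configs[[best]]
  trace$incumbent_value <- trace$objective[best]
  trace
}

#' @export
print.tuning_trace <- function(x, ...) {
  cat(sprintf("Bayesian-optimization trace: %d evaluation(s)\n",
              length(x$objective)))
  if (length(x$objective)) {
    cat(sprintf("  incumbent objective: %.6g\n", x$incumbent_value))
    cat("  incumbent config:\n")
    for (nm in names(x$incumbent)) {
      cat(sprintf("    %s = %s\n", nm, format(x$incumbent[[nm]])))
    }
  }
  invisible(x)
}

#' Running incumbent values along a trace
#'
#' @param trace a `tuning_trace`.
#' @return Numeric vector: best objective after each evaluation.
#' @export
incumbent_curve <- function(trace) cummin(trace$objective)

#' Persist a tuning trace as JSON Lines
#'
#' @param trace a `tuning_trace`; `path` output file (one trial per line).
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_tuning_trace <- function(trace, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_along(trace$objective)) {
    writeLines(canonical_json(list(trial = k, config = trace$configs[[k]],
                                   objective = if (is.finite(trace$objective[k]))
                                     trace$objective[k] else "failed")), con)
  }
  invisible(path)
}

#' Tune TabNet hyperparameters by Bayesian optimization
#'
#' The objective is the validation RMSE of a [tabnet()] fit under the
#' candidate configuration; non-searched fields (batch size, epoch budget)
#' come from `base_config`. The default epoch budget is deliberately small
#' so that tuning is desk-scale.
#'
#' @param x,y training features and labels.
#' @param x_valid,y_valid validation split used for the objective.
#' @param space a `search_space` (default [tabnet_search_space()]).
#' @param budget number of configurations to evaluate.
#' @param seed integer seed.
#' @param base_config a [tabnet_config()] supplying the fixed fields.
#' @return A `tuning_trace`; `$incumbent_config` holds the merged best
#'   `tabnet_config`.
#' @export
tune_tabnet <- function(x, y, x_valid, y_valid, space = tabnet_search_space(),
                        budget = 15L, seed = 1L,
                        base_config = tabnet_config(max_epochs = 50L,
                                                    patience = 15L)) {
  objective <- function(conf) {
    cfg <- base_config
    for (nm in names(conf)) cfg[[nm]] <- conf[[nm]]
    cfg$seed <- base_config$seed
    fit <- tabnet.default(x, y, x_valid = x_valid, y_valid = y_valid,
                          config = cfg)
    sqrt(fit$best_val)
  }
  trace <- bo_optimize(objective, space, budget, seed = seed)
  cfg <- base_config
  for (nm in names(trace$incumbent)) cfg[[nm]] <- trace$incumbent[[nm]]
  trace$incumbent_config <- cfg
  trace
}
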