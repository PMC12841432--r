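# Shared fixtures and independent oracles used across the test files.

# small table with fixed values (no RNG) for I/O and classification tests
tiny_table <- function() {
  ind <- default_indicators()
  df <- data.frame(
    sample_id = c("S1", "S2", "S3"),
    batch_id = c("B1", "B1", "B2"),
    region = c("R1", "R2", "R1"),
    detection_date = as.Date(c("2019-03-01", "2020-07-15", "2023-11-30")),
    stringsAsFactors = FALSE
  )
  vals <- rbind(
    c(0.011, 0.031, 0.016, 0.052, 214.0, 9.5),
    c(0.004, 0.052, 0.024, 0.071, 402.5, 15.25),
    c(0.082, 0.012, 0.009, 0.038, 1250.0, 4.125)   # exceeds pesticide + DON
  )
  colnames(vals) <- ind$name
  as_contaminant_table(cbind(df, as.data.frame(vals)), ind)
}

# straight-line, loop-based GRA re-implementation (independent oracle)
gra_oracle <- function(X, rho = 0.5) {
  n <- nrow(X); m <- ncol(X)
  Z <- matrix(0, n, m)
  for (j in 1:m) {
    lo <- min(X[, j]); hi <- max(X[, j])
    for (i in 1:n) {
      Z[i, j] <- if (hi > lo) (X[i, j] - lo) / (hi - lo) else 0.5
    }
  }
  dev <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) dev[i, j] <- abs(1 - Z[i, j])
  dmin <- Inf; dmax <- -Inf
  for (i in 1:n) for (j in 1:m) {
    if (dev[i, j] < dmin) dmin <- dev[i, j]
    if (dev[i, j] > dmax) dmax <- dev[i, j]
  }
  gam <- matrix(0, m, n)
  for (i in 1:n) for (j in 1:m) {
    gam[j, i] <- if (dmax == 0) 1 else (dmin + rho * dmax) / (dev[i, j] + rho * dmax)
  }
  tot <- 0
  for (j in 1:m) for (i in 1:n) tot <- tot + gam[j, i]
  w <- numeric(m)
  for (j in 1:m) {
    s <- 0
    for (i in 1:n) s <- s + gam[j, i]
    w[j] <- s / tot
  }
  r <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in 1:m) s <- s + w[j] * Z[i, j]
    r[i] <- s
  }
  list(Z = Z, gamma = gam, weights = w, risk = r)
}

# brute-force simplex projection by support enumeration: try every non-empty
# support, build the KKT candidate and keep the feasible point with the
# smallest squared distance to v
sparsemax_oracle <- function(v) {
  d <- length(v)
  best <- NULL; best_obj <- Inf
  for (mask in 1:(2^d - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1))) != 0)
    tau <- (sum(v[S]) - 1) / length(S)
    p <- rep(0, d)
    p[S] <- v[S] - tau
    if (any(p[S] < -1e-12)) next
    p[p < 0] <- 0
    obj <- sum((p - v)^2)
    if (obj < best_obj - 1e-15) { best_obj <- obj; best <- p }
  }
  best
}

# random contaminant table (values only need positivity, not realism)
random_table <- function(n, seed) {
  set.seed(seed)
  ind <- default_indicators()
  df <- data.frame(
    sample_id = sprintf("S%04d", 1:n),
    batch_id = sprintf("B%02d", sample.int(4, n, TRUE)),
    region = sprintf("R%02d", sample.int(3, n, TRUE)),
    detection_date = as.Date("2020-01-01") + sample.int(1000, n, TRUE),
    stringsAsFactors = FALSE
  )
  vals <- matrix(rexp(n * 6, rate = 2), n, 6)
  colnames(vals) <- ind$name
  as_contaminant_table(cbind(df, as.data.frame(vals)), ind)
}

# tiny tabnet configuration for fast unit tests
tiny_tabnet_config <- function(...) {
  tabnet_config(n_d = 4, n_a = 4, n_steps = 2, gamma = 1.5,
                lambda_sparse = 1e-4, learning_rate = 0.02,
                batch_size = 32, virtual_batch_size = 16,
                n_shared = 1, n_independent = 1,
                max_epochs = 5, patience = 5, seed = 1, ...)
}

# naive, loop-based eval-mode forward pass of a fitted tabnet model:
# an independent re-implementation used as a duplicate-implementation oracle
tabnet_forward_oracle <- function(model, X) {
  p <- model$params; s <- model$state; cfg <- model$config
  D <- ncol(X); B <- nrow(X)
  H <- cfg$n_d + cfg$n_a
  nb <- cfg$n_shared + cfg$n_independent
  bn_eval <- function(x, pre) {
    g <- p[[paste0(pre, ".gamma")]]; be <- p[[paste0(pre, ".beta")]]
    mu <- s[[paste0(pre, ".mean")]]; vv <- s[[paste0(pre, ".var")]]
    out <- x
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
      out[i, j] <- g[j] * (x[i, j] - mu[j]) / sqrt(vv[j] + 1e-5) + be[j]
    }
    out
  }
  transformer <- function(x, t) {
    h <- x
    for (k in 1:nb) {
      W <- if (k <= cfg$n_shared) p[[sprintf("sh%d.W", k)]] else
        p[[sprintf("st%d.b%d.W", t, k)]]
      z <- bn_eval(h %*% W, sprintf("st%d.b%d.bn", t, k))
      u <- z[, 1:H, drop = FALSE]
      v <- z[, (H + 1):(2 * H), drop = FALSE]
      glu <- u * (1 / (1 + exp(-v)))
      h <- if (k == 1) glu else (h + glu) * sqrt(0.5)
    }
    list(d = h[, 1:cfg$n_d, drop = FALSE],
         a = h[, (cfg$n_d + 1):H, drop = FALSE])
  }
  spmax_row <- function(v) {
    zs <- sort(v, decreasing = TRUE)
    cs <- cumsum(zs)
    k <- max(which(1 + (1:length(v)) * zs > cs))
    tau <- (cs[k] - 1) / k
    pmax(v - tau, 0)
  }
  Xbn <- bn_eval(X, "bn0")
  prior <- matrix(1, B, D)
  a <- transformer(Xbn, 0)$a
  agg <- matrix(0, B, cfg$n_d)
  sparsity <- 0
  for (t in 1:cfg$n_steps) {
    att <- bn_eval(a %*% p[[sprintf("att%d.W", t)]], sprintf("att%d.bn", t))
    M <- matrix(0, B, D)
    for (i in 1:B) M[i, ] <- spmax_row(att[i, ] * prior[i, ])
    sparsity <- sparsity + sum(-M * log(M + 1e-15))
    ft <- transformer(M * Xbn, t)
    agg <- agg + pmax(ft$d, 0)
    prior <- pmin(prior * (cfg$gamma - M), cfg$gamma)
    a <- ft$a
  }
  list(prediction = drop(agg %*% p[["head.W"]]) + p[["head.b"]],
       sparsity_loss = sparsity / (cfg$n_steps * B))
}

# planted-relevance training problem: target depends only on two indicators
planted_problem <- function(n, seed, active = c(1, 5)) {
  set.seed(seed)
  X <- matrix(runif(n * 6), n, 6)
  colnames(X) <- default_indicators()$name
  y <- 0.6 * X[, active[1]] + 0.4 * X[, active[2]]
  list(x = X, y = y, active = active)
}
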