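# Attentive tabular network for composite-risk regression.
#
# Architecture: an initial batch norm, then a multi-step decision process.
# Each step applies an attentive transformer (linear map + ghost batch norm,
# multiplied by a prior and passed through sparsemax) to produce a sparse
# feature mask, feeds the masked features through a feature transformer
# (shared + step-specific GLU blocks with sqrt(0.5)-scaled residuals), and
# accumulates the ReLU of the decision slice into the regression head.
# The prior is relaxed by gamma: P <- P * (gamma - M), so a feature fully
# consumed at one step is down-weighted (or, at gamma = 1, excluded) later.
# Training is plain reverse-mode differentiation written out by hand,
# optimized with Adam and a reduce-on-plateau learning-rate schedule.

#' TabNet hyperparameter configuration
#'
#' Defaults are the tuned values of the shipped risk-prediction model:
#' decision width 56, attention width 8, 7 decision steps, relaxation
#' gamma = 1.43, sparsity coefficient 1e-6, initial learning rate 0.0031,
#' batch and virtual batch size 32.
#'
#' @param n_d decision-output width (>= 1).
#' @param n_a attention width (>= 1).
#' @param n_steps number of decision steps (>= 1).
#' @param gamma prior relaxation parameter (>= 1).
#' @param lambda_sparse weight of the mask-entropy sparsity penalty (>= 0).
#' @param learning_rate initial Adam learning rate.
#' @param batch_size minibatch size.
#' @param virtual_batch_size ghost-batch-norm virtual batch size
#'   (<= `batch_size`).
#' @param n_shared,n_independent number of shared / step-specific GLU blocks.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param scheduler_factor,scheduler_patience,min_lr reduce-on-plateau
#'   schedule: multiply the learning rate by `scheduler_factor` after
#'   `scheduler_patience` stagnant epochs, never below `min_lr`.
#' @param bn_momentum running-statistics update rate of the batch norms.
#' @param seed integer seed controlling initialization and batching.
#' @return Object of class `tabnet_config`.
#' @export
tabnet_config <- function(n_d = 56L, n_a = 8L, n_steps = 7L, gamma = 1.43,
                          lambda_sparse = 1e-6, learning_rate = 0.0031,
                          batch_size = 32L, virtual_batch_size = 32L,
                          n_shared = 2L, n_independent = 2L,
                          max_epochs = 500L, patience = 50L,
                          scheduler_factor = 0.5, scheduler_patience = 10L,
                          min_lr = 1e-5, bn_momentum = 0.02, seed = 1L) {
  cfg <- list(n_d = as.integer(n_d), n_a = as.integer(n_a),
              n_steps = as.integer(n_steps), gamma = gamma,
              lambda_sparse = lambda_sparse, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              virtual_batch_size = as.integer(virtual_batch_size),
              n_shared = as.integer(n_shared),
              n_independent = as.integer(n_independent),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              scheduler_factor = scheduler_factor,
              scheduler_patience = as.integer(scheduler_patience),
              min_lr = min_lr, bn_momentum = bn_momentum, seed = as.integer(seed))
  if (cfg$n_d < 1 || cfg$n_a < 1 || cfg$n_steps < 1) {
    stop("tabnet_config: n_d, n_a and n_steps must all be >= 1")
  }
  if (cfg$gamma < 1) stop("tabnet_config: gamma must be >= 1")
  if (cfg$lambda_sparse < 0) stop("tabnet_config: lambda_sparse must be >= 0")
  if (cfg$virtual_batch_size > cfg$batch_size) {
    stop("tabnet_config: virtual_batch_size must not exceed batch_size")
  }
  if (cfg$n_shared + cfg$n_independent < 1) {
    stop("tabnet_config: need at least one GLU block")
  }
  structure(cfg, class = "tabnet_config")
}

#' @export
print.tabnet_config <- function(x, ...) {
  cat("TabNet configuration\n")
  cat(sprintf("  n_d=%d n_a=%d n_steps=%d gamma=%.3g lambda_sparse=%.3g\n",
              x$n_d, x$n_a, x$n_steps, x$gamma, x$lambda_sparse))
  cat(sprintf("  lr=%.4g batch=%d virtual_batch=%d blocks=%d shared + %d step\n",
              x$learning_rate, x$batch_size, x$virtual_batch_size,
              x$n_shared, x$n_independent))
  cat(sprintf("  max_epochs=%d patience=%d seed=%d\n",
              x$max_epochs, x$patience, x$seed))
  invisible(x)
}

# ---- parameter initialization ----------------------------------------------

.glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -lim, lim), fin, fout)
}

.tabnet_init <- function(D, config) {
  H <- config$n_d + config$n_a
  nb <- config$n_shared + config$n_independent
  params <- list(); state <- list()
  params[["bn0.gamma"]] <- rep(1, D); params[["bn0.beta"]] <- rep(0, D)
  state[["bn0.mean"]] <- rep(0, D); state[["bn0.var"]] <- rep(1, D)
  for (k in seq_len(config$n_shared)) {
    fin <- if (k == 1) D else H
    params[[sprintf("sh%d.W", k)]] <- .glorot(fin, 2 * H)
  }
  for (t in 0:config$n_steps) {
    for (k in seq_len(nb)) {
      if (k > config$n_shared) {
        fin <- if (k == 1) D else H
        params[[sprintf("st%d.b%d.W", t, k)]] <- .glorot(fin, 2 * H)
      }
      pre <- sprintf("st%d.b%d.bn", t, k)
      params[[paste0(pre, ".gamma")]] <- rep(1, 2 * H)
      params[[paste0(pre, ".beta")]] <- rep(0, 2 * H)
      state[[paste0(pre, ".mean")]] <- rep(0, 2 * H)
      state[[paste0(pre, ".var")]] <- rep(1, 2 * H)
    }
  }
  for (t in seq_len(config$n_steps)) {
    params[[sprintf("att%d.W", t)]] <- .glorot(config$n_a, D)
    params[[sprintf("att%d.bn.gamma", t)]] <- rep(1, D)
    params[[sprintf("att%d.bn.beta", t)]] <- rep(0, D)
    state[[sprintf("att%d.bn.mean", t)]] <- rep(0, D)
    state[[sprintf("att%d.bn.var", t)]] <- rep(1, D)
  }
  params[["head.W"]] <- .glorot(config$n_d, 1)
  params[["head.b"]] <- 0
  list(params = params, state = state)
}

# ---- ghost batch normalization ---------------------------------------------

.bn_eps <- 1e-5

# training-mode ghost batch norm over virtual batches of size bv.
# `senv` is the mutable running-statistics environment; `name` its key prefix.
.gbn_forward_train <- function(x, gamma, beta, senv, name, bv, momentum) {
  B <- nrow(x)
  nchunk <- ceiling(B / bv)
  grp <- ceiling(seq_len(B) / bv)
  y <- matrix(0, B, ncol(x))
  chunks <- vector("list", nchunk)
  rmean <- senv[[paste0(name, ".mean")]]
  rvar <- senv[[paste0(name, ".var")]]
  for (ci in seq_len(nchunk)) {
    idx <- which(grp == ci)
    xc <- x[idx, , drop = FALSE]
    m <- length(idx)
    mu <- colMeans(xc)
    xc_c <- sweep(xc, 2, mu, "-")
    v <- colMeans(xc_c^2)
    istd <- 1 / sqrt(v + .bn_eps)
    xhat <- sweep(xc_c, 2, istd, "*")
    y[idx, ] <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
    chunks[[ci]] <- list(idx = idx, xhat = xhat, istd = istd)
  }
  senv[[paste0(name, ".mean")]] <- rmean
  senv[[paste0(name, ".var")]] <- rvar
  list(y = y, cache = list(chunks = chunks, name = name))
}

.gbn_forward_eval <- function(x, gamma, beta, state, name) {
  mu <- state[[paste0(name, ".mean")]]
  v <- state[[paste0(name, ".var")]]
  xhat <- sweep(sweep(x, 2, mu, "-"), 2, 1 / sqrt(v + .bn_eps), "*")
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

# backward through ghost batch norm; accumulates gamma/beta grads into genv.
.gbn_backward <- function(cache, gamma, gy, genv) {
  name <- cache$name
  gx <- matrix(0, nrow(gy), ncol(gy))
  dgamma <- 0; dbeta <- 0
  for (ch in cache$chunks) {
    gych <- gy[ch$idx, , drop = FALSE]
    m <- length(ch$idx)
    dgamma <- dgamma + colSums(gych * ch$xhat)
    dbeta <- dbeta + colSums(gych)
    dxhat <- sweep(gych, 2, gamma, "*")
    s1 <- colSums(dxhat) / m
    s2 <- colSums(dxhat * ch$xhat) / m
    gc_ <- sweep(dxhat, 2, s1, "-") - sweep(ch$xhat, 2, s2, "*")
    gx[ch$idx, ] <- sweep(gc_, 2, ch$istd, "*")
  }
  gname <- paste0(name, ".gamma"); bname <- paste0(name, ".beta")
  genv$g[[gname]] <- genv$g[[gname]] + dgamma
  genv$g[[bname]] <- genv$g[[bname]] + dbeta
  gx
}

# ---- feature transformer ----------------------------------------------------

.ft_forward <- function(x, t, params, senv, config, training, bv) {
  H <- config$n_d + config$n_a
  nb <- config$n_shared + config$n_independent
  srt <- sqrt(0.5)
  h <- x
  caches <- vector("list", nb)
  for (k in seq_len(nb)) {
    Wname <- if (k <= config$n_shared) sprintf("sh%d.W", k) else sprintf("st%d.b%d.W", t, k)
    W <- params[[Wname]]
    pre <- h %*% W
    bname <- sprintf("st%d.b%d.bn", t, k)
    if (training) {
      bn <- .gbn_forward_train(pre, params[[paste0(bname, ".gamma")]],
                               params[[paste0(bname, ".beta")]],
                               senv, bname, bv, config$bn_momentum)
      z <- bn$y; bncache <- bn$cache
    } else {
      z <- .gbn_forward_eval(pre, params[[paste0(bname, ".gamma")]],
                             params[[paste0(bname, ".beta")]], senv, bname)
      bncache <- NULL
    }
    u <- z[, seq_len(H), drop = FALSE]
    vg <- z[, H + seq_len(H), drop = FALSE]
    sig <- 1 / (1 + exp(-vg))
    glu <- u * sig
    caches[[k]] <- list(h_in = h, u = u, sig = sig, bn = bncache,
                        Wname = Wname, W = W)
    h <- if (k == 1) glu else (h + glu) * srt
  }
  list(d = h[, seq_len(config$n_d), drop = FALSE],
       a = h[, config$n_d + seq_len(config$n_a), drop = FALSE],
       caches = caches)
}

# returns gradient wrt the transformer input; accumulates parameter grads.
.ft_backward <- function(ft, gd, ga, params, config, genv) {
  nb <- config$n_shared + config$n_independent
  srt <- sqrt(0.5)
  gh <- cbind(gd, ga)
  for (k in rev(seq_len(nb))) {
    ck <- ft$caches[[k]]
    g_glu <- if (k > 1) gh * srt else gh
    gu <- g_glu * ck$sig
    gv <- g_glu * ck$u * ck$sig * (1 - ck$sig)
    gz <- cbind(gu, gv)
    gpre <- .gbn_backward(ck$bn, params[[paste0(ck$bn$name, ".gamma")]], gz, genv)
    genv$g[[ck$Wname]] <- genv$g[[ck$Wname]] + crossprod(ck$h_in, gpre)
    g_hin <- tcrossprod(gpre, ck$W)
    gh <- if (k > 1) gh * srt + g_hin else g_hin
  }
  gh
}

# ---- full forward / backward ------------------------------------------------

# senv: environment holding running statistics (mutated in training mode).
.tabnet_forward_full <- function(params, senv, X, config, training) {
  D <- ncol(X); B <- nrow(X)
  bv <- min(config$virtual_batch_size, B)
  if (training) {
    bn0 <- .gbn_forward_train(X, params[["bn0.gamma"]], params[["bn0.beta"]],
                              senv, "bn0", B, config$bn_momentum)
    Xbn <- bn0$y; bn0cache <- bn0$cache
  } else {
    Xbn <- .gbn_forward_eval(X, params[["bn0.gamma"]], params[["bn0.beta"]],
                             senv, "bn0")
    bn0cache <- NULL
  }
  prior <- matrix(1, B, D)
  ft0 <- .ft_forward(Xbn, 0L, params, senv, config, training, bv)
  a <- ft0$a
  out_agg <- matrix(0, B, config$n_d)
  sparsity <- 0
  steps <- vector("list", config$n_steps)
  masks <- vector("list", config$n_steps)
  etas <- vector("list", config$n_steps)
  for (t in seq_len(config$n_steps)) {
    attW <- params[[sprintf("att%d.W", t)]]
    pre_att <- a %*% attW
    bname <- sprintf("att%d.bn", t)
    if (training) {
      bna <- .gbn_forward_train(pre_att, params[[paste0(bname, ".gamma")]],
                                params[[paste0(bname, ".beta")]],
                                senv, bname, bv, config$bn_momentum)
      att <- bna$y; bnacache <- bna$cache
    } else {
      att <- .gbn_forward_eval(pre_att, params[[paste0(bname, ".gamma")]],
                               params[[paste0(bname, ".beta")]], senv, bname)
      bnacache <- NULL
    }
    score <- att * prior
    M <- sparsemax(score)
    sparsity <- sparsity + sum(-M * log(M + 1e-15))
    mf <- M * Xbn
    ft <- .ft_forward(mf, t, params, senv, config, training, bv)
    relu_d <- pmax(ft$d, 0)
    out_agg <- out_agg + relu_d
    # relaxation update, capped at gamma so priors stay within [0, gamma]
    # (at gamma = 1 the cap never binds and this is the plain product rule)
    raw_prior <- prior * (config$gamma - M)
    capped <- raw_prior > config$gamma
    steps[[t]] <- list(att = att, prior = prior, M = M, ft = ft,
                       bn_att = bnacache, a_in = a, dt = ft$d,
                       capped = capped)
    masks[[t]] <- M
    etas[[t]] <- rowSums(relu_d)
    prior <- ifelse(capped, config$gamma, raw_prior)
    a <- ft$a
  }
  pred <- drop(out_agg %*% params[["head.W"]]) + params[["head.b"]]
  list(pred = pred, sparsity_loss = sparsity / (config$n_steps * B),
       masks = masks, etas = etas, out_agg = out_agg, Xbn = Xbn,
       steps = steps, ft0 = ft0, bn0 = bn0cache, final_prior = prior)
}

.zero_like <- function(params) lapply(params, function(p) p * 0)

# gradients of loss = MSE + lambda_sparse * sparsity_loss wrt all parameters.
.tabnet_backward_full <- function(params, fw, X, y, config) {
  B <- nrow(X)
  genv <- new.env(parent = emptyenv())
  genv$g <- .zero_like(params)
  resid <- fw$pred - y
  gpred <- matrix(2 * resid / B, ncol = 1)
  genv$g[["head.W"]] <- genv$g[["head.W"]] + crossprod(fw$out_agg, gpred)
  genv$g[["head.b"]] <- genv$g[["head.b"]] + sum(gpred)
  g_out <- tcrossprod(gpred, params[["head.W"]])         # B x n_d
  gXbn <- matrix(0, B, ncol(X))
  gP_next <- NULL
  ga_next <- matrix(0, B, config$n_a)
  sp_scale <- config$lambda_sparse / (config$n_steps * B)
  for (t in rev(seq_len(config$n_steps))) {
    st <- fw$steps[[t]]
    gd <- g_out * (st$dt > 0)
    gmf <- .ft_backward(st$ft, gd, ga_next, params, config, genv)
    gM <- gmf * fw$Xbn
    gM <- gM - sp_scale * (log(st$M + 1e-15) + st$M / (st$M + 1e-15))
    graw <- if (is.null(gP_next)) NULL else gP_next * !st$capped  # cap is flat
    if (!is.null(graw)) gM <- gM - st$prior * graw
    gscore <- sparsemax_backward(st$M, gM)
    g_att <- gscore * st$prior
    gP <- gscore * st$att
    if (!is.null(graw)) gP <- gP + (config$gamma - st$M) * graw
    gpre_att <- .gbn_backward(st$bn_att,
                              params[[sprintf("att%d.bn.gamma", t)]], g_att, genv)
    aname <- sprintf("att%d.W", t)
    genv$g[[aname]] <- genv$g[[aname]] + crossprod(st$a_in, gpre_att)
    ga_next <- tcrossprod(gpre_att, params[[aname]])
    gXbn <- gXbn + gmf * st$M
    gP_next <- gP
  }
  g0 <- .ft_backward(fw$ft0, matrix(0, B, config$n_d), ga_next,
                     params, config, genv)
  gXbn <- gXbn + g0
  .gbn_backward(fw$bn0, params[["bn0.gamma"]], gXbn, genv)
  genv$g
}

# ---- fitting ----------------------------------------------------------------

#' Fit an attentive tabular network for risk regression
#'
#' `tabnet()` is the central model-fitting function of the package. It trains
#' the multi-step attentive network on continuous features against a
#' composite-risk target by hand-written backpropagation (Adam optimizer,
#' reduce-on-plateau learning-rate schedule, early stopping on validation
#' loss with best-epoch weight restoration). Training is deterministic for a
#' fixed `config$seed` on a single thread.
#'
#' @param x numeric feature matrix (samples in rows), a `contaminant_table`,
#'   or a formula (see [tabnet.formula()]).
#' @param ... passed between methods.
#' @return Object of class `tabnet`.
#' @export
tabnet <- function(x, ...) UseMethod("tabnet")

#' @rdname tabnet
#' @param y numeric response vector (composite risk values).
#' @param x_valid,y_valid optional validation split; when omitted,
#'   `valid_fraction` of the training rows is held out (seeded).
#' @param config a [tabnet_config()].
#' @param valid_fraction fraction held out when no validation set is given.
#' @param verbose print per-epoch progress every 25 epochs.
#' @export
tabnet.default <- function(x, y, x_valid = NULL, y_valid = NULL,
                           config = tabnet_config(), valid_fraction = 0.15,
                           verbose = FALSE, ...) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("tabnet: empty training set")
  if (length(y) != nrow(x)) stop("tabnet: length(y) must equal nrow(x)")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("tabnet: features and labels must be finite")
  }
  set.seed(config$seed)
  if (is.null(x_valid)) {
    nv <- max(2L, round(nrow(x) * valid_fraction))
    vi <- sample.int(nrow(x), nv)
    x_valid <- x[vi, , drop = FALSE]; y_valid <- y[vi]
    x <- x[-vi, , drop = FALSE]; y <- y[-vi]
  } else {
    x_valid <- as.matrix(x_valid)
    if (ncol(x_valid) != ncol(x)) stop("tabnet: validation feature dimension mismatch")
  }
  D <- ncol(x)
  init <- .tabnet_init(D, config)
  params <- init$params
  senv <- list2env(init$state, parent = emptyenv())
  adam_m <- .zero_like(params); adam_v <- .zero_like(params)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8; tstep <- 0
  lr <- config$learning_rate
  n <- nrow(x)
  history <- vector("list", config$max_epochs)
  best_val <- Inf; best_params <- params; best_state <- as.list(senv)
  stale <- 0L; sched_stale <- 0L

  val_loss_of <- function(p, s) {
    fw <- .tabnet_forward_full(p, s, x_valid, config, training = FALSE)
    mean((fw$pred - y_valid)^2)
  }

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    tl <- 0; tn <- 0
    for (bi in seq_len(nb)) {
      idx <- perm[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n)]
      if (length(idx) < 2) next       # batch norm needs at least 2 rows
      xb <- x[idx, , drop = FALSE]; yb <- y[idx]
      fw <- .tabnet_forward_full(params, senv, xb, config, training = TRUE)
      loss <- mean((fw$pred - yb)^2) + config$lambda_sparse * fw$sparsity_loss
      if (!is.finite(loss)) {
        stop("tabnet: training loss became non-finite at epoch ", epoch)
      }
      grads <- .tabnet_backward_full(params, fw, xb, yb, config)
      tstep <- tstep + 1
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      for (nmp in names(params)) {
        g <- grads[[nmp]]
        adam_m[[nmp]] <- b1 * adam_m[[nmp]] + (1 - b1) * g
        adam_v[[nmp]] <- b2 * adam_v[[nmp]] + (1 - b2) * g * g
        params[[nmp]] <- params[[nmp]] -
          lr * corr * adam_m[[nmp]] / (sqrt(adam_v[[nmp]]) + aeps)
      }
      tl <- tl + loss * length(idx); tn <- tn + length(idx)
    }
    vl <- val_loss_of(params, senv)
    history[[epoch]] <- c(epoch = epoch, train_loss = tl / tn, val_loss = vl, lr = lr)
    if (verbose && epoch %% 25 == 0) {
      message(sprintf("epoch %d  train %.5f  val %.5f  lr %.5g",
                      epoch, tl / tn, vl, lr))
    }
    if (vl < best_val - 1e-9) {
      best_val <- vl; best_params <- params; best_state <- as.list(senv)
      stale <- 0L; sched_stale <- 0L
    } else {
      stale <- stale + 1L; sched_stale <- sched_stale + 1L
      if (sched_stale >= config$scheduler_patience) {
        lr <- max(lr * config$scheduler_factor, config$min_lr)
        sched_stale <- 0L
      }
      if (stale >= config$patience) break
    }
  }
  history <- as.data.frame(do.call(rbind, history[!vapply(history, is.null, TRUE)]))
  structure(
    list(params = best_params, state = best_state, config = config, D = D,
         feature_names = colnames(x), history = history, best_val = best_val,
         x_train = x, y_train = y, trained = TRUE),
    class = "tabnet"
  )
}

#' @rdname tabnet
#' @param formula model formula, e.g. `risk_value ~ .`.
#' @param data data.frame holding the variables of `formula`.
#' @export
tabnet.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, as.data.frame(data))
  y <- stats::model.response(mf)
  x <- as.matrix(mf[, -1, drop = FALSE])
  fit <- tabnet.default(x, y, ...)
  fit$call_formula <- formula
  fit
}

#' Evaluation-mode forward pass
#'
#' Runs the fitted network on a feature matrix and returns predictions, the
#' sparsity (mask entropy) loss, the per-step masks, and the per-step decision
#' contributions used for mask aggregation. Mask rows sum to 1.
#'
#' @param model a fitted `tabnet`.
#' @param x feature matrix or `contaminant_table`.
#' @return List with `prediction`, `sparsity_loss`, `masks` (list of
#'   batch x D matrices) and `etas` (per-step decision contributions).
#' @export
tabnet_forward <- function(model, x) {
  stopifnot(inherits(model, "tabnet"))
  if (inherits(x, "contaminant_table")) x <- indicator_matrix(x)
  x <- as.matrix(x)
  if (ncol(x) != model$D) {
    stop("tabnet_forward: model expects ", model$D, " features, got ", ncol(x))
  }
  senv <- list2env(model$state, parent = emptyenv())
  fw <- .tabnet_forward_full(model$params, senv, x, model$config, training = FALSE)
  list(prediction = fw$pred, sparsity_loss = fw$sparsity_loss,
       masks = fw$masks, etas = fw$etas)
}

#' @export
predict.tabnet <- function(object, newdata, ...) {
  if (missing(newdata)) newdata <- object$x_train
  if (is.data.frame(newdata) && !is.null(object$feature_names)) {
    keep <- intersect(object$feature_names, names(newdata))
    if (length(keep) == object$D) newdata <- newdata[, object$feature_names]
  }
  tabnet_forward(object, newdata)$prediction
}

#' Aggregate feature importances from the attentive masks
#'
#' Per-step masks are combined across steps, each weighted by that step's
#' decision contribution (the row sum of the ReLU-ed decision output), then
#' normalized so the importance vector sums to 1.
#'
#' @param model a fitted `tabnet`.
#' @param x feature matrix or `contaminant_table`; defaults to the stored
#'   training features.
#' @return Named numeric vector of length D summing to 1.
#' @export
feature_importances <- function(model, x = NULL) {
  stopifnot(inherits(model, "tabnet"))
  if (!isTRUE(model$trained)) stop("feature_importances: model is not trained")
  if (is.null(x)) x <- model$x_train
  fw <- tabnet_forward(model, x)
  B <- nrow(as.matrix(if (inherits(x, "contaminant_table")) indicator_matrix(x) else x))
  agg <- matrix(0, B, model$D)
  for (t in seq_along(fw$masks)) {
    agg <- agg + fw$masks[[t]] * fw$etas[[t]]
  }
  rs <- rowSums(agg)
  rs[rs == 0] <- 1
  agg <- agg / rs
  imp <- colSums(agg)
  imp <- imp / sum(imp)
  names(imp) <- model$feature_names
  imp
}

# ---- standard S3 methods -----------------------------------------------------

#' @export
print.tabnet <- function(x, ...) {
  cfg <- x$config
  cat("Attentive tabular network (risk regression)\n")
  cat(sprintf("  %d features; n_d=%d n_a=%d steps=%d gamma=%.3g\n",
              x$D, cfg$n_d, cfg$n_a, cfg$n_steps, cfg$gamma))
  cat(sprintf("  trained %d epochs; best validation MSE %.6g\n",
              nrow(x$history), x$best_val))
  invisible(x)
}

#' @export
summary.tabnet <- function(object, ...) {
  print(object)
  imp <- feature_importances(object)
  cat("  aggregate feature importances:\n")
  print(round(imp, 4))
  invisible(list(importances = imp, history = object$history))
}

#' @export
coef.tabnet <- function(object, ...) feature_importances(object)

#' @export
residuals.tabnet <- function(object, ...) {
  object$y_train - predict(object, object$x_train)
}

#' @export
plot.tabnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"),
                   lty = 1, col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
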