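# Dual-branch PointNet severity regressor.
#
# Two parallel branches embed the rest and peak point clouds: a shared
# per-point MLP (BN + ReLU after every linear map) lifts each point to a
# high-dimensional feature, and a symmetric max aggregation over the points
# produces one global feature per cloud, making the network exactly
# invariant to point order. The two global features, concatenated with the
# expression one-hot, feed a BN/ReLU fully-connected head whose linear
# output holds one severity score per expression; the score at the sample's
# own expression slot is the predicted grade. Training minimizes the half
# mean squared error of that slot with Adam. Forward, backward and the
# optimizer are implemented directly on (BLAS-backed) matrix operations.

#' Network and training configuration
#'
#' @param point_mlp Widths of the shared per-point MLP in each branch
#'   (default `c(64, 64, 128, 1024)`, the canonical PointNet sizing; the last
#'   width is the global feature size).
#' @param head Widths of the fully-connected head before the linear output
#'   (default `c(512, 256)`).
#' @param n_expressions Output dimension, one score per expression.
#' @param batch_size Mini-batch size (default 8; 768 training samples then
#'   give 96 iterations per epoch).
#' @param epochs Training epochs (default 200).
#' @param learning_rate,beta1,beta2,adam_eps Adam hyper-parameters.
#' @param lr_drop_epoch,lr_drop_factor Piecewise learning-rate schedule: from
#'   `lr_drop_epoch` (a fraction in (0, 1] of `epochs`, default 0.75) the
#'   learning rate is multiplied by `lr_drop_factor` (default 0.1). A factor
#'   of 1 keeps the rate constant.
#' @param weight_decay L2 regularisation of the weight matrices (biases and
#'   BN parameters excluded), added to the gradient before the Adam moments
#'   (default 1e-4).
#' @param dropout Inverted-dropout probability after each hidden
#'   fully-connected head layer during training (default 0.3, as in the
#'   original PointNet head; the per-point branches are never dropped).
#' @param bn_momentum,bn_eps Batch-normalisation running-statistics momentum
#'   and variance floor.
#' @param points Points per cloud; `NULL` uses every template vertex, an
#'   integer enables uniform subsampling for speed.
#' @param resample_points When subsampling, draw a fresh uniform vertex
#'   subset every epoch instead of freezing one subset for the whole run
#'   (default `FALSE`). Resampling makes the shared per-point MLP a true
#'   function of point geometry and lets inference average over several
#'   subsets (see `ensemble` in [predict.pointnet_model]), but it is a
#'   strong regulariser that needs training budgets well beyond a hundred
#'   epochs to pay off.
#' @param ensemble_eval Number of point subsets averaged at inference
#'   (default 4 when resampling, 1 otherwise).
#' @param loss_mode `"masked"` (default: supervise only the sample's own
#'   expression slot) or `"replicated"` (supervise all five slots with the
#'   same target).
#' @param seed Seed for weight initialization, subsampling and batch order.
#' @return A list of class `pointnet_config`.
#' @export
pointnet_config <- function(point_mlp = c(64, 64, 128, 1024),
                            head = c(512, 256), n_expressions = 5,
                            batch_size = 8, epochs = 200,
                            learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                            adam_eps = 1e-8, lr_drop_epoch = 0.75,
                            lr_drop_factor = 0.1, weight_decay = 1e-4,
                            dropout = 0.3, bn_momentum = 0.1,
                            bn_eps = 1e-5, points = NULL,
                            resample_points = FALSE, ensemble_eval = NULL,
                            loss_mode = c("masked", "replicated"), seed = 1) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(length(point_mlp) >= 1, batch_size >= 1, epochs >= 1,
            lr_drop_epoch > 0, lr_drop_epoch <= 1, lr_drop_factor > 0)
  structure(list(point_mlp = as.integer(point_mlp), head = as.integer(head),
                 n_expressions = as.integer(n_expressions),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, lr_drop_epoch = lr_drop_epoch,
                 lr_drop_factor = lr_drop_factor,
                 weight_decay = weight_decay, dropout = dropout,
                 bn_momentum = bn_momentum,
                 bn_eps = bn_eps,
                 points = if (is.null(points)) NULL else as.integer(points),
                 resample_points = isTRUE(resample_points),
                 ensemble_eval = if (is.null(ensemble_eval)) NULL
                 else as.integer(ensemble_eval),
                 loss_mode = loss_mode, seed = as.integer(seed)),
            class = "pointnet_config")
}

#' Iterations per training epoch
#' @param n_train Number of training samples.
#' @param batch_size Mini-batch size.
#' @return `ceiling(n_train / batch_size)`.
#' @export
iterations_per_epoch <- function(n_train, batch_size) {
  as.integer(ceiling(n_train / batch_size))
}

# --- parameter initialisation ------------------------------------------------

new_linear <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, scale), n_in, n_out),
       b = numeric(n_out))
}

new_bn <- function(n_out) {
  list(gamma = rep(1, n_out), beta = numeric(n_out),
       rmean = numeric(n_out), rvar = rep(1, n_out))
}

init_pointnet <- function(config) {
  with_seed(config$seed, {
    branch <- function() {
      widths <- config$point_mlp
      ins <- c(3L, widths[-length(widths)])
      lapply(seq_along(widths), function(l) {
        c(new_linear(ins[l], widths[l]), new_bn(widths[l]))
      })
    }
    feat <- config$point_mlp[length(config$point_mlp)]
    head_in <- c(2L * feat + config$n_expressions, config$head)
    head_layers <- lapply(seq_along(config$head), function(l) {
      c(new_linear(head_in[l], config$head[l]), new_bn(config$head[l]))
    })
    # Small final weights, bias at mid-scale grade 3: starts near the grand
    # mean of a 1-5 target.
    final <- new_linear(head_in[length(head_in)], config$n_expressions,
                        scale = 0.01)
    final$b <- rep(3, config$n_expressions)
    list(branch1 = branch(), branch2 = branch(),
         head = head_layers, final = final)
  })
}

# --- forward / backward primitives -------------------------------------------

# All dense activations are held feature-major (features x observations):
# per-feature vectors (bias, BN parameters) then broadcast down columns by
# R's native recycling, and per-sample column blocks are contiguous in
# memory, keeping every elementwise step in fast vectorized code while the
# matrix products run in BLAS.

# X: (n_in x N) feature-major activations. The fused BN+ReLU kernels live
# in src/fastops.cpp. keep_cache = FALSE skips the backward-pass caches
# (evaluation and statistics-calibration forwards). dropout > 0 applies
# inverted dropout after each layer's ReLU during training (used in the
# fully-connected head only, as in the original PointNet head).
mlp_forward <- function(layers, X, eps, momentum, train,
                        keep_cache = TRUE, dropout = 0) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  H <- X
  for (l in seq_along(layers)) {
    lay <- layers[[l]]
    Z <- crossprod(lay$W, H) + lay$b
    bn <- .bn_relu_forward(Z, lay$gamma, lay$beta, lay$rmean, lay$rvar,
                           eps, train)
    if (train) {
      lay$rmean <- (1 - momentum) * lay$rmean + momentum * bn$mu
      lay$rvar <- (1 - momentum) * lay$rvar + momentum * bn$var
      layers[[l]] <- lay
    }
    A <- bn$A
    drop <- NULL
    if (train && dropout > 0) {
      drop <- matrix(
        (stats::runif(length(A)) >= dropout) / (1 - dropout),
        nrow(A), ncol(A))
      A <- A * drop
    }
    if (keep_cache) {
      caches[[l]] <- list(X = H, A = bn$A, xhat = bn$xhat,
                          invstd = bn$invstd, drop = drop)
    }
    H <- A
  }
  list(out = H, caches = caches, layers = layers)
}

mlp_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dH <- dOut
  for (l in rev(seq_along(layers))) {
    lay <- layers[[l]]
    ch <- caches[[l]]
    if (!is.null(ch$drop)) dH <- dH * ch$drop
    bb <- .bn_relu_backward(dH, ch$A, ch$xhat, ch$invstd, lay$gamma)
    grads[[l]] <- list(W = tcrossprod(ch$X, bb$dZ), b = bb$dbias,
                       gamma = bb$dgamma, beta = bb$dbeta)
    dH <- lay$W %*% bb$dZ
  }
  list(grads = grads, dX = dH)
}

# Max over each sample's block of P columns; A is F x (B*P), sample-major.
max_pool <- function(A, B, P) {
  .block_max_pool(A, as.integer(B), as.integer(P))
}

max_pool_backward <- function(dG, Arg, B, P) {
  .block_max_pool_backward(dG, Arg, as.integer(B), as.integer(P))
}

# Full forward pass. Xr, Xp are 3 x (B*P) sample-major blocks; onehot is
# n_expressions x B.
pointnet_forward <- function(params, config, Xr, Xp, onehot, B, P,
                             train = FALSE, keep_cache = train,
                             momentum = config$bn_momentum,
                             use_dropout = train) {
  eps <- config$bn_eps; mom <- momentum
  f1 <- mlp_forward(params$branch1, Xr, eps, mom, train, keep_cache)
  f2 <- mlp_forward(params$branch2, Xp, eps, mom, train, keep_cache)
  mp1 <- max_pool(f1$out, B, P)
  mp2 <- max_pool(f2$out, B, P)
  H0 <- rbind(mp1$G, mp2$G, onehot)
  fh <- mlp_forward(params$head, H0, eps, mom, train, keep_cache,
                    dropout = if (use_dropout) config$dropout %||% 0 else 0)
  scores <- crossprod(params$final$W, fh$out) + params$final$b
  if (train) {
    params$branch1 <- f1$layers
    params$branch2 <- f2$layers
    params$head <- fh$layers
  }
  list(scores = scores, params = params,
       cache = list(f1 = f1, f2 = f2, mp1 = mp1, mp2 = mp2, H0 = H0,
                    fh = fh, B = B, P = P))
}

# dscores: n_expressions x B.
pointnet_backward <- function(params, config, cache, dscores) {
  gfinal <- list(W = tcrossprod(cache$fh$out, dscores),
                 b = rowSums(dscores))
  dHead <- params$final$W %*% dscores
  bh <- mlp_backward(params$head, cache$fh$caches, dHead)
  feat <- config$point_mlp[length(config$point_mlp)]
  dG1 <- bh$dX[seq_len(feat), , drop = FALSE]
  dG2 <- bh$dX[feat + seq_len(feat), , drop = FALSE]
  dA1 <- max_pool_backward(dG1, cache$mp1$Arg, cache$B, cache$P)
  dA2 <- max_pool_backward(dG2, cache$mp2$Arg, cache$B, cache$P)
  b1 <- mlp_backward(params$branch1, cache$f1$caches, dA1)
  b2 <- mlp_backward(params$branch2, cache$f2$caches, dA2)
  list(branch1 = b1$grads, branch2 = b2$grads, head = bh$grads,
       final = gfinal)
}

#' Half-mean-squared-error regression loss
#'
#' `0.5 * mean((selected prediction - target)^2)` over the batch, where the
#' selected prediction is the score at each sample's own expression slot.
#'
#' @param scores Numeric matrix, one row per sample, one column per
#'   expression.
#' @param targets Numeric vector of target grades.
#' @param expression_index Integer vector of each sample's expression slot.
#' @return Scalar loss.
#' @export
pointnet_loss <- function(scores, targets, expression_index) {
  sel <- scores[cbind(seq_len(nrow(scores)), expression_index)]
  0.5 * mean((sel - targets)^2)
}

# scores here are feature-major (n_expressions x B); returns the gradient in
# the same layout.
loss_grad <- function(scores, targets, expression_index, mode) {
  B <- ncol(scores)
  d <- matrix(0, nrow(scores), B)
  if (mode == "replicated") {
    d[] <- (scores - rep(targets, each = nrow(scores))) / (B * nrow(scores))
  } else {
    ij <- cbind(expression_index, seq_len(B))
    d[ij] <- (scores[ij] - targets) / B
  }
  d
}

# --- Adam over the nested parameter list -------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, config) {
  state$t <- state$t + 1L
  corr1 <- 1 - config$beta1^state$t
  corr2 <- 1 - config$beta2^state$t
  # The moment buffers are owned exclusively by `state` and updated in place
  # by the fused kernel; BN running stats sit next to the weights but are
  # not optimized.
  upd <- function(p, g, m, v, decay) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (nm %in% c("rmean", "rvar")) next
        # weights are regularised; biases and BN affine parameters are not
        p[[nm]] <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                       if (nm == "W") decay else 0)
      }
      return(p)
    }
    out <- .adam_update(p, g, m, v, config$learning_rate, config$beta1,
                        config$beta2, corr1, corr2, config$adam_eps, decay)
    if (is.matrix(p)) dim(out) <- dim(p)
    out
  }
  decay <- config$weight_decay %||% 0
  for (part in names(params)) {
    if (part %in% c("branch1", "branch2", "head")) {
      for (l in seq_along(params[[part]])) {
        params[[part]][[l]] <- upd(params[[part]][[l]], grads[[part]][[l]],
                                   state$m[[part]][[l]],
                                   state$v[[part]][[l]], decay)
      }
    } else {
      params[[part]] <- upd(params[[part]], grads[[part]],
                            state$m[[part]], state$v[[part]], decay)
    }
  }
  list(params = params, state = state)
}

# --- sample assembly ---------------------------------------------------------

# Stack samples into feature-major 3 x (n*P) arrays (sample-major column
# blocks), applying the model's fixed subsample index set.
stack_samples <- function(samples, sub_idx) {
  P <- length(sub_idx)
  n <- length(samples)
  Xr <- matrix(0, 3, n * P)
  Xp <- matrix(0, 3, n * P)
  for (i in seq_len(n)) {
    cols <- (i - 1L) * P + seq_len(P)
    Xr[, cols] <- t(samples[[i]]$rest_points[sub_idx, , drop = FALSE])
    Xp[, cols] <- t(samples[[i]]$peak_points[sub_idx, , drop = FALSE])
  }
  onehot <- vapply(samples, function(s) s$onehot,
                   numeric(length(samples[[1]]$onehot)))
  list(Xr = Xr, Xp = Xp, onehot = onehot,
       targets = vapply(samples, function(s) s$target_grade, 0),
       expr_idx = vapply(samples, function(s) s$expression_index, 0L),
       expression = vapply(samples, function(s) s$expression, ""),
       P = P, n = n)
}

# Recompute every BN layer's running statistics as the cumulative average
# of batch statistics over the given data, at a batch size large enough for
# the batch statistics to approximate the population ("precise BN"). The
# mini-batches used for optimization are too small (8 samples in the head)
# for momentum-smoothed running statistics to match the normalisation the
# weights were trained under.
calibrate_bn_params <- function(params, config, data, batch = 32,
                                points = NULL, seed = NULL) {
  n <- data$n; P0 <- data$P
  P <- if (!is.null(points) && points < P0) as.integer(points) else P0
  starts <- seq(1L, n, by = batch)
  with_seed(seed, {
    for (k in seq_along(starts)) {
      sel <- starts[k]:min(starts[k] + batch - 1L, n)
      idx <- if (P < P0) sort(sample.int(P0, P)) else seq_len(P0)
      cols <- rep((sel - 1L) * P0, each = P) + rep(idx, length(sel))
      fw <- pointnet_forward(params, config,
                             data$Xr[, cols, drop = FALSE],
                             data$Xp[, cols, drop = FALSE],
                             data$onehot[, sel, drop = FALSE],
                             length(sel), P, train = TRUE,
                             keep_cache = FALSE, momentum = 1 / k,
                             use_dropout = FALSE)
      params <- fw$params
    }
  })
  params
}

#' Recalibrate batch-normalisation statistics of a trained model
#'
#' Recomputes the running mean and variance of every batch-normalisation
#' layer as the average of large-batch statistics over the supplied samples
#' (normally the training split). Inference uses these running statistics;
#' after optimization with small mini-batches they can lag the final
#' weights, and recalibration restores consistency. [train_pointnet] calls
#' this automatically.
#'
#' @param model A trained [train_pointnet] model.
#' @param samples Samples to estimate the statistics on.
#' @param batch Calibration batch size (default 32).
#' @return The model with updated statistics.
#' @export
calibrate_bn <- function(model, samples, batch = 32) {
  P0 <- nrow(samples[[1]]$rest_points)
  resample <- isTRUE(model$config$resample_points) &&
    !is.null(model$config$points) && model$config$points < P0
  if (resample) {
    data <- stack_samples(samples, seq_len(P0))
    model$params <- calibrate_bn_params(model$params, model$config, data,
                                        batch = batch,
                                        points = model$config$points,
                                        seed = model$config$seed + 3L)
  } else {
    data <- stack_samples(samples, model$subsample_idx)
    model$params <- calibrate_bn_params(model$params, model$config, data,
                                        batch = batch)
  }
  model
}

#' Train the dual-branch PointNet regressor
#'
#' Runs `epochs * ceiling(n_train / batch_size)` Adam iterations over the
#' training partition, recording the per-epoch training RMSE and loss.
#' Training is deterministic given the configuration seed, up to
#' floating-point reduction order.
#'
#' @param split A [split_samples] result (or a list with a `train` element).
#' @param config A [pointnet_config].
#' @param verbose Print one line per `verbose` epochs (0 = silent).
#' @param init Optional trained `pointnet_model` to warm-start from (its
#'   weights and point subsample are reused; the optimizer state restarts).
#' @return A list of class `pointnet_model` with `params`, `config`,
#'   `history` (data frame `epoch`, `rmse`, `loss`) and `subsample_idx`.
#' @export
train_pointnet <- function(split, config = pointnet_config(), verbose = 0,
                           init = NULL) {
  train <- if (inherits(split, "dataset_split")) split$train else split$train
  if (length(train) == 0L) stop("empty training split", call. = FALSE)
  P0 <- nrow(train[[1]]$rest_points)
  subsampled <- !is.null(config$points) && config$points < P0
  resample <- subsampled && isTRUE(config$resample_points)
  sub_idx <- if (!is.null(init)) init$subsample_idx
  else if (subsampled) {
    with_seed(config$seed + 1L, sort(sample.int(P0, config$points)))
  } else seq_len(P0)
  # With per-epoch resampling the full-resolution clouds are stacked once
  # and a fresh vertex subset is gathered from them each epoch.
  data <- stack_samples(train, if (resample) seq_len(P0) else sub_idx)
  params <- if (!is.null(init)) init$params else init_pointnet(config)
  state <- adam_init(params)
  n <- data$n; bs <- config$batch_size
  P <- if (resample) config$points else data$P
  n_iter <- iterations_per_epoch(n, bs)
  history <- data.frame(epoch = seq_len(config$epochs), rmse = NA_real_,
                        loss = NA_real_)
  epoch_seeds <- derive_seeds(config$seed + 2L, config$epochs)
  cfg_step <- config
  Xr_ep <- data$Xr
  Xp_ep <- data$Xp
  for (ep in seq_len(config$epochs)) {
    cfg_step$learning_rate <- if (ep > config$lr_drop_epoch * config$epochs)
      config$learning_rate * config$lr_drop_factor else config$learning_rate
    sq_sum <- 0; n_seen <- 0; loss_sum <- 0
    # subset draw, batch order and dropout masks all flow from the epoch seed
    with_seed(epoch_seeds[ep], {
    if (resample) {
      idx_ep <- sort(sample.int(P0, P))
      gather <- rep((seq_len(n) - 1L) * P0, each = P) + rep(idx_ep, n)
      Xr_ep <- data$Xr[, gather, drop = FALSE]
      Xp_ep <- data$Xp[, gather, drop = FALSE]
    }
    perm <- sample.int(n)
    for (it in seq_len(n_iter)) {
      sel <- perm[((it - 1L) * bs + 1L):min(it * bs, n)]
      B <- length(sel)
      cols <- rep((sel - 1L) * P, each = P) + rep(seq_len(P), B)
      fw <- pointnet_forward(params, config,
                             Xr_ep[, cols, drop = FALSE],
                             Xp_ep[, cols, drop = FALSE],
                             data$onehot[, sel, drop = FALSE],
                             B, P, train = TRUE)
      params <- fw$params
      tgt <- data$targets[sel]
      eix <- data$expr_idx[sel]
      l <- pointnet_loss(t(fw$scores), tgt, eix)
      if (!is.finite(l)) {
        cond <- structure(class = c("palsy3d_training_error", "error",
                                    "condition"),
                          list(message = sprintf(
                            "training diverged at epoch %d, iteration %d",
                            ep, it), call = NULL,
                            history = history[seq_len(ep - 1L), ]))
        stop(cond)
      }
      selp <- fw$scores[cbind(eix, seq_len(B))]
      sq_sum <- sq_sum + sum((selp - tgt)^2)
      loss_sum <- loss_sum + l * B
      n_seen <- n_seen + B
      d <- loss_grad(fw$scores, tgt, eix, config$loss_mode)
      grads <- pointnet_backward(params, config, fw$cache, d)
      st <- adam_step(params, grads, state, cfg_step)
      params <- st$params
      state <- st$state
    }
    })
    history$rmse[ep] <- sqrt(sq_sum / n_seen)
    history$loss[ep] <- loss_sum / n_seen
    if (verbose > 0 && (ep %% verbose == 0L || ep == 1L)) {
      message(sprintf("epoch %4d/%d  rmse %.4f  loss %.4f",
                      ep, config$epochs, history$rmse[ep], history$loss[ep]))
    }
  }
  params <- calibrate_bn_params(params, config, data,
                                points = if (resample) P else NULL,
                                seed = config$seed + 3L)
  structure(list(params = params, config = config, history = history,
                 subsample_idx = sub_idx,
                 iterations_per_epoch = n_iter),
            class = "pointnet_model")
}

#' @export
print.pointnet_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<pointnet_model: %d epochs x %d iterations, %d points/cloud, final rmse %.4f>\n",
    nrow(x$history), x$iterations_per_epoch, length(x$subsample_idx),
    last$rmse))
  invisible(x)
}

#' Predict severity grades for samples
#'
#' For a model trained with per-epoch point resampling, the prediction is
#' the average of `ensemble` forward passes over different uniform vertex
#' subsets, which reduces the subsampling variance of the score; a model
#' trained on one fixed subset is evaluated on that subset only.
#'
#' @param object A trained [train_pointnet] model.
#' @param samples List of `palsy_sample`s.
#' @param batch Forward batch size.
#' @param ensemble Number of point subsets averaged; defaults to the
#'   configuration's `ensemble_eval` (4 for resampling models).
#' @param ... Unused.
#' @return Data frame with `capture_id`, `expression`, `target`,
#'   `predicted` (the score at the sample's expression slot), plus a
#'   `scores` attribute holding the full (averaged) score matrix.
#' @export
predict.pointnet_model <- function(object, samples, batch = 32,
                                   ensemble = NULL, ...) {
  config <- object$config
  P0 <- nrow(samples[[1]]$rest_points)
  resample <- isTRUE(config$resample_points) && !is.null(config$points) &&
    config$points < P0
  if (is.null(ensemble)) {
    ensemble <- config$ensemble_eval %||% (if (resample) 4L else 1L)
  }
  if (!resample) ensemble <- 1L
  forward_scores <- function(data, P, sub_cols) {
    n <- data$n
    scores <- matrix(0, n, config$n_expressions)
    for (start in seq(1L, n, by = batch)) {
      sel <- start:min(start + batch - 1L, n)
      cols <- if (is.null(sub_cols)) {
        rep((sel - 1L) * P, each = P) + rep(seq_len(P), length(sel))
      } else {
        rep((sel - 1L) * data$P, each = P) + rep(sub_cols, length(sel))
      }
      fw <- pointnet_forward(object$params, config,
                             data$Xr[, cols, drop = FALSE],
                             data$Xp[, cols, drop = FALSE],
                             data$onehot[, sel, drop = FALSE],
                             length(sel), P, train = FALSE)
      scores[sel, ] <- scores[sel, ] + t(fw$scores)
    }
    scores
  }
  if (resample) {
    data <- stack_samples(samples, seq_len(P0))
    P <- config$points
    subsets <- with_seed(config$seed + 4L, {
      lapply(seq_len(ensemble), function(k) {
        if (k == 1L) object$subsample_idx else sort(sample.int(P0, P))
      })
    })
    scores <- Reduce(`+`, lapply(subsets, function(idx)
      forward_scores(data, P, idx))) / ensemble
    n <- data$n
  } else {
    data <- stack_samples(samples, object$subsample_idx)
    scores <- forward_scores(data, data$P, NULL)
    n <- data$n
  }
  out <- data.frame(
    capture_id = vapply(samples, function(s) s$provenance$capture_id, ""),
    expression = data$expression,
    target = data$targets,
    predicted = scores[cbind(seq_len(n), data$expr_idx)],
    stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  out
}

#' Evaluate a trained model on test samples
#'
#' A prediction is counted correct when it lies strictly within `threshold`
#' of the consensus grade. Confusion matrices bin the predictions by rounding
#' to the nearest integer grade, clipped to 1-5.
#'
#' @param model A trained [train_pointnet] model.
#' @param samples Test samples.
#' @param threshold Correctness threshold on `|prediction - grade|`
#'   (default 0.5, strict inequality).
#' @return A list of class `evaluation_report` with `per_expression` (data
#'   frame `expression`, `n`, `accuracy`), `confusion` (list of 5 x 5
#'   matrices, rows = true grade, columns = rounded prediction), `mse`,
#'   `r_squared` and `predictions`.
#' @export
evaluate_pointnet <- function(model, samples, threshold = 0.5) {
  if (length(samples) == 0L) stop("empty test set", call. = FALSE)
  pred <- predict(model, samples)
  err <- pred$predicted - pred$target
  mse <- mean(err^2)
  sst <- sum((pred$target - mean(pred$target))^2)
  r2 <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
  exprs <- expression_types()
  per <- lapply(exprs, function(e) {
    sub <- pred[pred$expression == e, ]
    if (nrow(sub) == 0L) return(NULL)   # absent group: not reported as zero
    data.frame(expression = e, n = nrow(sub),
               accuracy = mean(abs(sub$predicted - sub$target) < threshold))
  })
  per <- do.call(rbind, per)
  confusion <- lapply(exprs, function(e) {
    sub <- pred[pred$expression == e, ]
    if (nrow(sub) == 0L) return(NULL)
    binned <- pmin(5L, pmax(1L, as.integer(round(sub$predicted))))
    tab <- table(factor(round(sub$target), levels = 1:5),
                 factor(binned, levels = 1:5))
    m <- unclass(as.matrix(tab))
    dimnames(m) <- list(true = 1:5, predicted = 1:5)
    m
  })
  names(confusion) <- exprs
  structure(list(per_expression = per, confusion = confusion, mse = mse,
                 r_squared = r2, threshold = threshold, predictions = pred),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: MSE %.4f, R^2 %.4f, |err| < %.2f rule>\n",
              x$mse, x$r_squared, x$threshold))
  for (i in seq_len(nrow(x$per_expression))) {
    cat(sprintf("  %-16s n = %3d  accuracy %.3f\n",
                x$per_expression$expression[i], x$per_expression$n[i],
                x$per_expression$accuracy[i]))
  }
  invisible(x)
}
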