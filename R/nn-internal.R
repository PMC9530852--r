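# Internal machinery for the fused model: forward/backward passes through
# the GCN branch and the batch-normalized feed-forward head, Adam updates,
# and the joint training loop with early stopping. Parameters live in a flat
# named list so that gradient checking and the optimizer stay trivial.

lrelu_grad <- function(x, slope = 0.2) {
  (x > 0) + slope * (x <= 0)
}

row_max <- function(logits) {
  logits[cbind(seq_len(nrow(logits)), max.col(logits, ties.method = "first"))]
}

softmax_rows <- function(logits) {
  e <- exp(logits - row_max(logits))
  e / rowSums(e)
}

row_log_softmax <- function(logits) {
  mx <- row_max(logits)
  logits - (mx + log(rowSums(exp(logits - mx))))
}

# GCN branch forward over the whole graph; caches per-layer inputs and
# pre-activations for backprop.
gcn_branch_forward <- function(params, arch, S, X) {
  L <- length(arch$gcn_hidden)
  M <- vector("list", L)  # S %*% H_{l-1}
  P <- vector("list", L)  # pre-activations
  H <- X
  for (l in seq_len(L)) {
    M[[l]] <- as.matrix(S %*% H)
    P[[l]] <- M[[l]] %*% params[[paste0("gW", l)]]
    H <- leaky_relu(P[[l]], arch$negative_slope)
  }
  list(H = H, M = M, P = P)
}

gcn_branch_backward <- function(params, arch, S, cache, dH) {
  L <- length(arch$gcn_hidden)
  grads <- list()
  for (l in rev(seq_len(L))) {
    dP <- dH * lrelu_grad(cache$P[[l]], arch$negative_slope)
    grads[[paste0("gW", l)]] <- crossprod(cache$M[[l]], dP)
    if (l > 1L)
      dH <- as.matrix(S %*% tcrossprod(dP, params[[paste0("gW", l)]]))
  }
  grads
}

# Feed-forward head: affine -> batch norm -> leaky ReLU per hidden layer,
# then affine -> softmax. In training mode batch statistics are used and the
# running statistics updated; in inference mode the running statistics are
# used, so repeated calls are deterministic.
dnn_head_forward <- function(params, arch, Z, training, state) {
  nh <- length(arch$dnn_widths)
  eps <- arch$bn_eps
  cache <- list(H = vector("list", nh + 1L), A = vector("list", nh),
                xhat = vector("list", nh), istd = vector("list", nh),
                B = vector("list", nh))
  cache$H[[1L]] <- Z
  H <- Z
  for (l in seq_len(nh)) {
    A <- sweep(H %*% params[[paste0("W", l)]], 2L,
               params[[paste0("b", l)]], "+")
    if (training) {
      mu <- colMeans(A)
      va <- colMeans(sweep(A, 2L, mu)^2)
      mom <- arch$bn_momentum
      state$rm[[l]] <- (1 - mom) * state$rm[[l]] + mom * mu
      state$rv[[l]] <- (1 - mom) * state$rv[[l]] + mom * va
    } else {
      mu <- state$rm[[l]]
      va <- state$rv[[l]]
    }
    istd <- 1 / sqrt(va + eps)
    xhat <- sweep(sweep(A, 2L, mu), 2L, istd, "*")
    B <- sweep(sweep(xhat, 2L, params[[paste0("g", l)]], "*"), 2L,
               params[[paste0("be", l)]], "+")
    H <- leaky_relu(B, arch$negative_slope)
    cache$A[[l]] <- A; cache$xhat[[l]] <- xhat
    cache$istd[[l]] <- istd; cache$B[[l]] <- B
    cache$H[[l + 1L]] <- H
  }
  lf <- nh + 1L
  logits <- sweep(H %*% params[[paste0("W", lf)]], 2L,
                  params[[paste0("b", lf)]], "+")
  list(logits = logits, cache = cache, state = state)
}

dnn_head_backward <- function(params, arch, fwd, dlogits) {
  nh <- length(arch$dnn_widths)
  cache <- fwd$cache
  grads <- list()
  lf <- nh + 1L
  grads[[paste0("W", lf)]] <- crossprod(cache$H[[nh + 1L]], dlogits)
  grads[[paste0("b", lf)]] <- colSums(dlogits)
  dH <- tcrossprod(dlogits, params[[paste0("W", lf)]])
  for (l in rev(seq_len(nh))) {
    dB <- dH * lrelu_grad(cache$B[[l]], arch$negative_slope)
    grads[[paste0("g", l)]] <- colSums(dB * cache$xhat[[l]])
    grads[[paste0("be", l)]] <- colSums(dB)
    dxhat <- sweep(dB, 2L, params[[paste0("g", l)]], "*")
    m <- nrow(dB)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat[[l]])
    dA <- sweep(
      m * dxhat - matrix(s1, m, length(s1), byrow = TRUE) -
        cache$xhat[[l]] * matrix(s2, m, length(s2), byrow = TRUE),
      2L, cache$istd[[l]] / m, "*")
    grads[[paste0("W", l)]] <- crossprod(cache$H[[l]], dA)
    grads[[paste0("b", l)]] <- colSums(dA)
    dH <- tcrossprod(dA, params[[paste0("W", l)]])
  }
  list(grads = grads, dZ = dH)
}

# Fused representation for all nodes. inputs: list(S, X, dw); arch$branches
# selects which blocks enter, always in the order deepwalk, gcn, raw.
fused_forward <- function(params, arch, inputs) {
  parts <- list()
  gcn_cache <- NULL
  if ("deepwalk" %in% arch$branches) parts$deepwalk <- inputs$dw
  if ("gcn" %in% arch$branches) {
    gcn_cache <- gcn_branch_forward(params, arch, inputs$S, inputs$X)
    parts$gcn <- gcn_cache$H
  }
  if ("raw" %in% arch$branches) parts$raw <- inputs$X
  Z <- do.call(cbind, unname(parts))
  list(Z = Z, gcn_cache = gcn_cache,
       gcn_cols = if (is.null(gcn_cache)) NULL else {
         off <- if ("deepwalk" %in% arch$branches) ncol(inputs$dw) else 0L
         off + seq_len(ncol(gcn_cache$H))
       })
}

# Mean softmax cross-entropy (the two-class case coincides with binary
# cross-entropy on the positive-class probability) and its gradients for one
# batch of labelled nodes.
joint_loss_grad <- function(params, arch, inputs, batch_idx, y, state) {
  ff <- fused_forward(params, arch, inputs)
  Zb <- ff$Z[batch_idx, , drop = FALSE]
  fwd <- dnn_head_forward(params, arch, Zb, training = TRUE, state = state)
  m <- length(batch_idx)
  logp <- row_log_softmax(fwd$logits)
  loss <- -mean(logp[cbind(seq_len(m), y + 1L)])
  dlogits <- exp(logp)
  dlogits[cbind(seq_len(m), y + 1L)] <-
    dlogits[cbind(seq_len(m), y + 1L)] - 1
  dlogits <- dlogits / m
  bwd <- dnn_head_backward(params, arch, fwd, dlogits)
  grads <- bwd$grads
  if ("gcn" %in% arch$branches) {
    dHfull <- matrix(0, nrow(ff$Z), length(ff$gcn_cols))
    dHfull[batch_idx, ] <- bwd$dZ[, ff$gcn_cols, drop = FALSE]
    grads <- c(grads, gcn_branch_backward(params, arch, inputs$S,
                                          ff$gcn_cache, dHfull))
  }
  list(loss = loss, grads = grads, state = fwd$state)
}

joint_eval <- function(params, arch, inputs, state, idx = NULL) {
  ff <- fused_forward(params, arch, inputs)
  Z <- if (is.null(idx)) ff$Z else ff$Z[idx, , drop = FALSE]
  fwd <- dnn_head_forward(params, arch, Z, training = FALSE, state = state)
  softmax_rows(fwd$logits)
}

joint_eval_loss <- function(params, arch, inputs, state, idx, y) {
  ff <- fused_forward(params, arch, inputs)
  fwd <- dnn_head_forward(params, arch, ff$Z[idx, , drop = FALSE],
                          training = FALSE, state = state)
  logp <- row_log_softmax(fwd$logits)
  -mean(logp[cbind(seq_along(idx), y + 1L)])
}

init_joint_params <- function(arch) {
  params <- list()
  if ("gcn" %in% arch$branches) {
    dims <- c(arch$n_features, arch$gcn_hidden)
    for (l in seq_along(arch$gcn_hidden))
      params[[paste0("gW", l)]] <- glorot(dims[l], dims[l + 1L])
  }
  zdim <- 0L
  if ("deepwalk" %in% arch$branches) zdim <- zdim + arch$dw_dim
  if ("gcn" %in% arch$branches)
    zdim <- zdim + arch$gcn_hidden[length(arch$gcn_hidden)]
  if ("raw" %in% arch$branches) zdim <- zdim + arch$n_features
  dims <- c(zdim, arch$dnn_widths, arch$n_classes)
  for (l in seq_len(length(dims) - 1L)) {
    params[[paste0("W", l)]] <- glorot(dims[l], dims[l + 1L])
    params[[paste0("b", l)]] <- numeric(dims[l + 1L])
  }
  for (l in seq_along(arch$dnn_widths)) {
    params[[paste0("g", l)]] <- rep(1, arch$dnn_widths[l])
    params[[paste0("be", l)]] <- rep(0, arch$dnn_widths[l])
  }
  params
}

init_bn_state <- function(arch) {
  list(rm = lapply(arch$dnn_widths, function(w) rep(0, w)),
       rv = lapply(arch$dnn_widths, function(w) rep(1, w)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# Stratified index split for the early-stopping validation set; guarantees at
# least one validation sample per class and at least one training sample per
# class. Draws from the current RNG stream.
split_validation <- function(y, fraction) {
  val <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_val <- max(1L, round(fraction * length(idx)))
    n_val <- min(n_val, length(idx) - 1L)
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

# Joint training loop: Adam on the mean cross-entropy over mini-batches,
# early stopping on validation loss with the configured patience, returning
# the parameters and batch-norm state of the best validation epoch.
train_joint <- function(inputs, arch, idx_lab, y_lab, cfg) {
  withr::with_seed(cfg$seed, {
    vpos <- split_validation(y_lab, cfg$validation_fraction)
    idx_val <- idx_lab[vpos]; y_val <- y_lab[vpos]
    idx_tr <- idx_lab[-vpos]; y_tr <- y_lab[-vpos]
    n_tr <- length(idx_tr)
    bs <- cfg$batch_size
    if (bs <= 0L || bs > n_tr) bs <- n_tr

    params <- init_joint_params(arch)
    state <- init_bn_state(arch)
    opt <- adam_init(params)

    best <- list(loss = Inf, params = params, state = state, epoch = 0L)
    since_best <- 0L
    tr_hist <- numeric(cfg$max_epochs)
    vl_hist <- numeric(cfg$max_epochs)
    n_done <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / bs))
      tl <- 0
      for (bt in batches) {
        lg <- joint_loss_grad(params, arch, inputs, idx_tr[bt], y_tr[bt],
                              state)
        state <- lg$state
        up <- adam_step(params, lg$grads, opt, cfg$learning_rate)
        params <- up$params; opt <- up$opt
        tl <- tl + lg$loss * length(bt)
      }
      vl <- joint_eval_loss(params, arch, inputs, state, idx_val, y_val)
      tr_hist[epoch] <- tl / n_tr
      vl_hist[epoch] <- vl
      n_done <- epoch
      if (vl < best$loss) {
        best <- list(loss = vl, params = params, state = state,
                     epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best > cfg$patience) break
      }
    }
    log <- data.frame(epoch = seq_len(n_done),
                      train_loss = tr_hist[seq_len(n_done)],
                      val_loss = vl_hist[seq_len(n_done)])
    list(params = best$params, state = best$state, log = log,
         best_epoch = best$epoch, val_idx = idx_val)
  })
}
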