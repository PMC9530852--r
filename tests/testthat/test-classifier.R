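test_that("fusion concatenates per node and guards node order", {
  ids <- sprintf("G%02d", 1:5)
  dw <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(ids, NULL))
  gc <- matrix(rnorm(5 * 2), 5, 2, dimnames = list(ids, NULL))
  fz <- fuse(dw, gc)
  expect_equal(ncol(fz), 5L)
  expect_equal(fz[, 1:3], dw)
  expect_equal(fz[3, 1:3], dw[3, ])
  # zero-width second block is the identity case
  empty <- matrix(numeric(0), 5, 0, dimnames = list(ids, NULL))
  expect_equal(fuse(dw, empty), dw)
  # shuffled node order is rejected
  gc_bad <- gc[c(2, 1, 3, 4, 5), ]
  expect_error(fuse(dw, gc_bad), "node-order mismatch")
})

test_that("classifier forward pass produces calibrated softmax rows", {
  withr::with_seed(2, {
    params <- init_dnn_params(6, widths = c(5L, 4L), seed = 3)
    Z <- matrix(rnorm(40 * 6), 40, 6)
    probs <- dnn_forward(Z, params, training = FALSE)
    expect_equal(dim(probs), c(40L, 2L))
    expect_true(all(probs >= 0 & probs <= 1))
    expect_lt(max(abs(rowSums(probs) - 1)), 1e-9)
    # inference mode is deterministic (running statistics, no dropout)
    expect_identical(probs, dnn_forward(Z, params, training = FALSE))
    expect_error(dnn_forward(matrix(0, 3, 4), params), "shape mismatch")
  })
})

test_that("zero logits give the uniform softmax", {
  # weights and biases all zero: the final affine yields zero logits
  params <- init_dnn_params(3, widths = c(4L, 4L), seed = 1)
  params$layer_weights <- lapply(params$layer_weights, function(W) W * 0)
  probs <- dnn_forward(matrix(rnorm(15), 5, 3), params)
  expect_equal(unname(probs), matrix(0.5, 5, 2))
})

test_that("binary cross-entropy matches closed forms and an independent path", {
  expect_lt(bce_loss(1, 1 - 1e-9), 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(0, 0.5), log(2))
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2))
  # clipping keeps the loss finite at the boundary
  expect_true(is.finite(bce_loss(1, 0)))
  # independent evaluation via log1p on 1000 random pairs
  withr::with_seed(4, {
    y <- rbinom(1000, 1, 0.5)
    p <- runif(1000, 1e-6, 1 - 1e-6)
    ref <- mean(ifelse(y == 1, -log(p), -log1p(-p)))
    expect_equal(bce_loss(y, p), ref, tolerance = 1e-9)
  })
})

test_that("analytic gradients agree with finite differences", {
  # 6-node toy problem exercising GCN + fused head with batch norm
  net <- random_network(6, seed = 21)
  arch <- list(branches = c("deepwalk", "gcn"), n_features = 3L,
               dw_dim = 2L, gcn_hidden = c(3L, 3L), dnn_widths = c(4L, 3L),
               n_classes = 2L, negative_slope = 0.2, bn_eps = 1e-5,
               bn_momentum = 0.1)
  withr::with_seed(22, {
    inputs <- list(
      S = Matrix::Matrix(normalize_adjacency(net)$matrix, sparse = TRUE),
      X = matrix(rnorm(6 * 3), 6, 3),
      dw = matrix(rnorm(6 * 2), 6, 2))
    params <- deeprw:::init_joint_params(arch)
  })
  state <- deeprw:::init_bn_state(arch)
  idx <- 1:6
  y <- c(1L, 0L, 1L, 0L, 1L, 0L)
  loss_at <- function(p) {
    deeprw:::joint_loss_grad(p, arch, inputs, idx, y, state)$loss
  }
  ana <- deeprw:::joint_loss_grad(params, arch, inputs, idx, y, state)$grads
  eps <- 1e-5
  worst <- 0
  for (nm in names(ana)) {
    g <- ana[[nm]]
    for (k in seq_along(g)) {
      pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      rel <- abs(num - g[k]) / max(1e-6, abs(num) + abs(g[k]))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training fits strongly separable data and respects early stopping", {
  cfg <- fast_config(max_epochs = 60L)
  for (s in 1:3) {
    bundle <- small_bundle(seed = 30 + s)
    corpus <- generate_walks(bundle$network, 5, 15, seed = s)
    dw <- train_skipgram(corpus, dim = 16, window = 3, iterations = 5,
                         seed = s)
    model <- train_model(bundle$network, bundle$features, dw,
                         bundle$labels, update_config(cfg, seed = s))
    pr <- predict(model)
    a <- auroc(pr$probability_positive, bundle$labels[pr$node_id])
    expect_gte(a, 0.98)
    # checkpoint is the validation-loss minimum over the log
    expect_equal(model$log$val_loss[model$best_epoch],
                 min(model$log$val_loss))
  }

  # patience 0: training ends at the first non-improving epoch
  bundle <- small_bundle(seed = 33)
  corpus <- generate_walks(bundle$network, 5, 15, seed = 1)
  dw <- train_skipgram(corpus, dim = 16, window = 3, iterations = 5,
                       seed = 1)
  m0 <- train_model(bundle$network, bundle$features, dw, bundle$labels,
                    fast_config(patience = 0L, max_epochs = 200L))
  vl <- m0$log$val_loss
  n <- length(vl)
  if (n < 200L) {
    # every epoch but the last improved on the running minimum
    expect_true(all(vl[-1][-(n - 1)] < cummin(vl)[-c(n - 1, n)]))
    expect_gte(vl[n], min(vl[-n]))
  }

  # single-class labels are rejected
  one_class <- bundle$labels
  one_class[] <- 1
  expect_error(train_model(bundle$network, bundle$features, dw, one_class,
                           fast_config()), "degenerate training set")
})

test_that("prediction output is a proper scored gene table", {
  bundle <- small_bundle(seed = 40)
  corpus <- generate_walks(bundle$network, 5, 15, seed = 2)
  dw <- train_skipgram(corpus, dim = 16, window = 3, iterations = 5,
                       seed = 2)
  model <- train_model(bundle$network, bundle$features, dw, bundle$labels,
                       fast_config(max_epochs = 20L))
  pr <- predict(model)
  expect_true(all(pr$probability_positive >= 0 & pr$probability_positive <= 1))
  expect_equal(pr$label, as.integer(pr$probability_positive >= 0.5))
  # repeated calls are identical; unknown nodes fail
  expect_identical(pr, predict(model))
  expect_error(predict(model, "NOPE"), "unknown node")
  sub <- predict(model, pr$node_id[3:5])
  expect_equal(sub$probability_positive, pr$probability_positive[3:5])
})
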