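test_that("binary cross-entropy matches its closed forms", {
  expect_lt(bce_loss(1, 1 - 1e-9), 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-6)
  expect_equal(bce_loss(0, 0.5), log(2), tolerance = 1e-6)
  expect_equal(bce_loss(c(1, 0), c(0.8, 0.3)),
               mean(-c(log(0.8), log(0.7))), tolerance = 1e-12)
  expect_error(bce_loss(c(1, 0), 0.5), "shape")
})

test_that("constant 0.5 predictions score the label-distribution entropy", {
  y <- c(rep(1, 30), rep(0, 10))
  onehot <- cbind(1 - y, y)
  expect_equal(bce_loss(onehot, matrix(0.5, nrow(onehot), 2)), log(2),
               tolerance = 1e-6)
})

test_that("k-fold split is a partition with near-equal sizes", {
  folds <- kfold_split(572L, k = 5L, seed = 2L)
  sizes <- sort(lengths(folds))
  expect_equal(as.integer(sizes), c(114L, 114L, 114L, 115L, 115L))
  expect_setequal(unlist(folds), seq_len(572L))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_length(intersect(folds[[i]], folds[[j]]), 0L)
    }
  }
  expect_error(kfold_split(10L, k = 1L), ">= 2")
  expect_error(kfold_split(3L, k = 5L), "exceeds")
})

test_that("classification metrics follow their defining ratios", {
  rep1 <- classification_report(list(TP = 100L, TN = 78L, FP = 6L, FN = 6L))
  expect_equal(rep1$specificity, 78 / 84)
  expect_equal(gliowave:::round_half_up(rep1$specificity), 0.93)
  expect_equal(rep1$sensitivity, 100 / 106)
  expect_equal(round(rep1$sensitivity, 4), 0.9434)
  expect_equal(rep1$accuracy, 178 / 190)

  rep2 <- classification_report(list(TP = 95L, TN = 84L, FP = 0L, FN = 11L))
  expect_equal(rep2$precision, 1.0)
  expect_equal(rep2$FPR, 0.0)
})

test_that("undefined metrics are NA, never zero", {
  rep <- classification_report(list(TP = 0L, TN = 5L, FP = 0L, FN = 0L))
  expect_true(is.na(rep$sensitivity))
  expect_true(is.na(rep$precision))
  expect_equal(rep$specificity, 1.0)
  expect_error(classification_report(list(TP = 0L, TN = 0L, FP = 0L,
                                          FN = 0L)), "empty")
})

test_that("rate identities hold exactly over randomized counts", {
  set.seed(6)
  for (rep in 1:200) {
    counts <- list(TP = sample(0:50, 1), TN = sample(0:50, 1),
                   FP = sample(0:50, 1), FN = sample(0:50, 1))
    if (sum(unlist(counts)) == 0) next
    r <- classification_report(counts)
    if (!is.na(r$sensitivity)) expect_identical(r$sensitivity + r$FNR, 1)
    if (!is.na(r$specificity)) expect_identical(r$specificity + r$FPR, 1)
    expect_identical(r$accuracy,
                     (counts$TP + counts$TN) / sum(unlist(counts)))
  }
})

test_that("training validates its inputs", {
  spec <- build_cnn2()
  x <- lapply(1:4, function(i) array(stats::rnorm(1320 * 15), c(1320, 15, 1)))
  expect_error(gw_train_config(epochs = 0L), "epochs")
  expect_error(gw_train(spec, x, rep(1L, 4), gw_train_config(epochs = 1L)),
               "both classes")
  expect_error(gw_train(spec, x, c(0L, 1L, 0L),
                        gw_train_config(epochs = 1L)), "sample count")
  bad <- lapply(1:4, function(i) array(0, c(10, 10, 1)))
  expect_error(gw_train(build_cnn2(), bad, c(0L, 1L, 0L, 1L),
                        gw_train_config(epochs = 1L)), "does not match")
})

test_that("network gradients match finite differences on a tiny architecture", {
  # miniature conv-pool-dense net exercising every layer kind
  spec <- gliowave:::new_model_spec(
    "tiny", c(6L, 6L, 1L),
    list(
      gliowave:::layer_conv("c1", 2L, padding = "same"),
      gliowave:::layer_maxpool("p1"),
      gliowave:::layer_conv("c2", 3L, padding = "valid"),
      gliowave:::layer_flatten(),
      gliowave:::layer_dense("d1", 4L),
      gliowave:::layer_dense("d2", 2L, activation = "sigmoid")
    ),
    list()
  )
  set.seed(8)
  net <- gliowave:::init_network(spec, seed = 9L)
  x <- array(stats::rnorm(6 * 6 * 1 * 3), c(6, 6, 1, 3))
  targets <- cbind(c(1, 0, 1), c(0, 1, 0))
  loss_fn <- function(net) {
    out <- gliowave:::nn_forward(net, x, training = FALSE)$out
    bce_loss(targets, out, eps = 1e-12)
  }
  fw <- gliowave:::nn_forward(net, x, training = FALSE)
  dpre <- (fw$out - targets) / length(targets)
  grads <- gliowave:::nn_backward(net, fw$caches, dpre)
  h <- 1e-6
  for (li in c(1L, 3L, 5L, 6L)) {
    w <- net$layers[[li]]$W
    for (k in sample(length(w), 4L)) {
      net2 <- net
      net2$layers[[li]]$W[k] <- w[k] + h
      net3 <- net
      net3$layers[[li]]$W[k] <- w[k] - h
      numeric_grad <- (loss_fn(net2) - loss_fn(net3)) / (2 * h)
      expect_equal(grads[[li]]$dW[k], numeric_grad, tolerance = 1e-4,
                   label = sprintf("layer %d weight %d", li, k))
    }
    net2 <- net
    net2$layers[[li]]$b[1] <- net$layers[[li]]$b[1] + h
    net3 <- net
    net3$layers[[li]]$b[1] <- net$layers[[li]]$b[1] - h
    expect_equal(grads[[li]]$db[1],
                 (loss_fn(net2) - loss_fn(net3)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("training a tiny dense net on separable data is deterministic and learns", {
  spec <- gliowave:::new_model_spec(
    "toy", c(4L, 4L, 1L),
    list(
      gliowave:::layer_flatten(),
      gliowave:::layer_dense("d1", 8L),
      gliowave:::layer_dense("d2", 2L, activation = "sigmoid")
    ),
    list()
  )
  set.seed(10)
  n <- 30L
  x <- c(lapply(seq_len(n), function(i) array(stats::rnorm(16, 2), c(4, 4, 1))),
         lapply(seq_len(n), function(i) array(stats::rnorm(16, -2), c(4, 4, 1))))
  y <- rep(c(1L, 0L), each = n)
  cfg <- gw_train_config(epochs = 20L, learning_rate = 0.01, batch_size = 8L,
                         validation_split = 0, seed = 11L)
  fit1 <- gw_train(spec, x, y, cfg)
  fit2 <- gw_train(spec, x, y, cfg)
  expect_identical(fit1$curves, fit2$curves)
  expect_gte(utils::tail(fit1$curves$train_accuracy, 1), 0.95)
  expect_true(all(fit1$curves$train_loss >= 0))
  expect_equal(predict(fit1, x[1:4], type = "class"),
               as.integer(predict(fit1, x[1:4], type = "prob")[, 2] > 0.5))
})
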