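# tiny deterministic crop set: bright-center (positive) vs dark (negative)
toy_tensor <- function(n_per_class = 12, size = 16, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(stats::runif(size * size * 2 * n, 0, 0.1), dim = c(size, size, 2, n))
  y <- rep(c(1, 0), each = n_per_class)
  for (i in which(y == 1)) x[5:12, 5:12, 1, i] <- x[5:12, 5:12, 1, i] + 0.8
  list(x = x, y = y)
}

small_cfg <- function(...) {
  cnn_config(input_size = 16, channels_used = c("dapi", "cep8"),
             batch_size = 8, epochs = 5, ...)
}

test_that("forward pass produces one in-range score per crop", {
  m <- build_model(small_cfg(seed = 2))
  toy <- toy_tensor()
  m <- train_cnn(m, toy$x, toy$y, epochs = 1)
  sc <- predict(m, toy$x[, , , 1:4, drop = FALSE])
  expect_length(sc, 4)
  expect_true(all(sc >= 0 & sc <= 1))
  # purity: duplicate crops in a batch get identical scores
  dup <- toy$x[, , , c(1, 1, 2), drop = FALSE]
  sd <- predict(m, dup)
  expect_identical(sd[1], sd[2])
})

test_that("training is deterministic under a fixed seed", {
  toy <- toy_tensor()
  run <- function() {
    m <- build_model(small_cfg(seed = 7))
    m <- train_cnn(m, toy$x, toy$y, epochs = 2)
    model_checksum(m)
  }
  expect_identical(run(), run())
})

test_that("architecture catalogue orders parameter counts and rejects unknowns", {
  base <- build_model(cnn_config(input_size = 32, seed = 1, epochs = 1))
  res18 <- build_model(cnn_config("resnet18", input_size = 32, seed = 1, epochs = 1))
  expect_gt(n_params(res18), n_params(base))
  expect_error(cnn_config("lenet"), "unknown architecture")
})

test_that("a linearly separable toy problem is learned to training accuracy 1", {
  toy <- toy_tensor(n_per_class = 16)
  m <- train_cnn(build_model(small_cfg(seed = 3)), toy$x, toy$y)
  acc <- mean((predict(m, toy$x) >= 0.5) == toy$y)
  expect_equal(acc, 1)
  expect_equal(nrow(m$history), 5)
  expect_true(all(is.finite(m$history$loss)))
})

test_that("degenerate training inputs are rejected", {
  toy <- toy_tensor()
  m <- build_model(small_cfg(seed = 1))
  expect_error(train_cnn(m, toy$x, toy$y, epochs = 0), "at least 1")
  expect_error(train_cnn(m, toy$x, rep(1, length(toy$y))), "single class")
  expect_error(predict(build_model(small_cfg(seed = 1)), toy$x), "untrained")
})

test_that("transfer freezes feature blocks and reinitializes the head", {
  toy <- toy_tensor(n_per_class = 10)
  src <- train_cnn(build_model(small_cfg(seed = 11)), toy$x, 1 - toy$y, epochs = 2)
  spec <- transfer_spec(list(space = "crops", marginal = "aux"),
                        list(space = "crops", marginal = "ctc"),
                        frozen_depth = 3)
  tgt <- transfer_init(small_cfg(seed = 12), src, spec)
  expect_true(tgt$config$transfer)
  # features copied from the source
  expect_identical(model_checksum(tgt, "features"), model_checksum(src, "features"))
  expect_false(identical(model_checksum(tgt, "head"), model_checksum(src, "head")))
  feat <- model_checksum(tgt, "features")
  head <- model_checksum(tgt, "head")
  tuned <- train_cnn(tgt, toy$x, toy$y, epochs = 2)
  expect_identical(model_checksum(tuned, "features"), feat)  # frozen bit-identical
  expect_false(identical(model_checksum(tuned, "head"), head))

  # frozen_depth = 0 is a warm start: features may change
  warm <- transfer_init(small_cfg(seed = 12), src,
                        transfer_spec(list(m = "a"), list(m = "b"), frozen_depth = 0))
  warm <- train_cnn(warm, toy$x, toy$y, epochs = 2)
  expect_false(identical(model_checksum(warm, "features"), feat))
  expect_error(transfer_init(small_cfg(seed = 1), src,
                             transfer_spec(list(m = "a"), list(m = "b"),
                                           frozen_depth = 9)),
               "feature blocks")
  expect_error(transfer_init(cnn_config(input_size = 32, epochs = 1), src, spec),
               "incompatible")
})

test_that("layer gradients match finite differences", {
  ns <- asNamespace("ctcfish")
  layers <- ns$nn_init(list(
    ns$L_conv(3, 3, 2, 3, 1L, 1L), ns$L_relu(), ns$L_pool(2L),
    ns$L_res(list(ns$L_conv(3, 3, 3, 4, 2L, 1L), ns$L_bn(4), ns$L_relu(),
                  ns$L_conv(3, 3, 4, 4, 1L, 1L), ns$L_bn(4)),
             list(ns$L_conv(1, 1, 3, 4, 2L, 0L), ns$L_bn(4))),
    ns$L_gap(), ns$L_dense(4, 1)))
  set.seed(13)
  x <- array(stats::rnorm(8 * 8 * 2 * 3), dim = c(8, 8, 2, 3))
  y <- c(1, 0, 1)
  loss_fn <- function(L) {
    p <- 1 / (1 + exp(-as.numeric(ns$nn_forward(L, x, train = TRUE)$out)))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fw <- ns$nn_forward(layers, x, train = TRUE)
  p <- 1 / (1 + exp(-as.numeric(fw$out)))
  bw <- ns$nn_backward(layers, fw$caches, matrix((p - y) / 3, nrow = 1))
  eps <- 1e-6
  set.seed(14)
  # conv weight, dense weight, and a residual-branch batchnorm gamma
  for (probe in list(
    list(g = bw$grads[[1]]$W,
         bump = function(L, i, d) { L[[1]]$params$W[i] <- L[[1]]$params$W[i] + d; L },
         n = length(layers[[1]]$params$W)),
    list(g = bw$grads[[6]]$W,
         bump = function(L, i, d) { L[[6]]$params$W[i] <- L[[6]]$params$W[i] + d; L },
         n = length(layers[[6]]$params$W)),
    list(g = bw$grads[[4]]$f[[2]]$gamma,
         bump = function(L, i, d) {
           L[[4]]$f[[2]]$params$gamma[i] <- L[[4]]$f[[2]]$params$gamma[i] + d; L },
         n = 4))) {
    for (i in sample(probe$n, min(5, probe$n))) {
      num <- (loss_fn(probe$bump(layers, i, eps)) -
              loss_fn(probe$bump(layers, i, -eps))) / (2 * eps)
      expect_equal(probe$g[i], num, tolerance = 1e-5)
    }
  }
})
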