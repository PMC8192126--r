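test_that("build_model produces the stated architecture", {
  set.seed(71)
  # m = 256, k = 7: bins dimension after the blocks is 2
  net <- build_model(model_config(m = 256, k = 7), c(256, 256))
  convs <- Filter(function(l) l$type == "conv", net$layers)
  expect_length(convs, 7)
  expect_equal(convs[[7]]$plan$oh, 2)
  # layer sequence: input bn, then (bn, conv, lrelu) blocks, then dense
  types <- vapply(net$layers, `[[`, "", "type")
  expect_equal(types[1], "bn")
  expect_equal(types[length(types)], "dense")
  expect_equal(sum(types == "bn"), 7)      # input bn + 6 in-block bns
  # k = 0 degenerates to logistic regression on normalised input
  net0 <- build_model(model_config(m = 32, k = 0), c(32, 8))
  expect_equal(vapply(net0$layers, `[[`, "", "type"), c("bn", "dense"))
  # too-deep networks are rejected
  expect_error(build_model(model_config(m = 32, k = 6), c(32, 8)), "too deep")
})

test_that("parameter count matches layer arithmetic", {
  set.seed(72)
  m <- 32; n <- 16; k <- 3; f <- 4; kh <- 4; kw <- 4
  net <- build_model(model_config(m = m, k = k, filters = f), c(m, n))
  # hand-computed: input bn 2; block1 conv 4*4*1*f+f; blocks 2..k each
  # bn 2f + conv 4*4*f*f+f; dense (m/8 * n/8 * f) + 1
  want <- 2 +
    (kh * kw * 1 * f + f) +
    (k - 1) * (2 * f + kh * kw * f * f + f) +
    (m / 2^k) * (n / 2^k) * f + 1
  expect_equal(n_parameters(net), want)
})

test_that("split_train_val stratifies, partitions and reproduces", {
  labels <- rep(c(0, 1), c(300, 100))
  set.seed(73)
  sp <- split_train_val(labels, 0.9)
  expect_equal(sort(c(sp$train, sp$val)), seq_along(labels))
  expect_length(intersect(sp$train, sp$val), 0)
  expect_equal(sum(labels[sp$train] == 1), 90)
  expect_equal(sum(labels[sp$val] == 0), 30)
  set.seed(73)
  sp2 <- split_train_val(labels, 0.9)
  expect_identical(sp, sp2)
})

test_that("predictions are probabilities, deterministic, batch-invariant", {
  set.seed(74)
  net <- build_model(model_config(m = 16, k = 2, filters = 4), c(16, 8))
  x <- array(rpois(16 * 8 * 7, 2), c(16, 8, 7))
  p <- predict(net, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict(net, x))
  # batch vs single-item prediction agree
  p1 <- vapply(1:7, function(i) predict(net, x[, , i]), 0)
  expect_equal(p, p1, tolerance = 1e-6)
  # duplicated inputs give identical outputs
  xd <- array(c(x[, , 1], x[, , 1]), c(16, 8, 2))
  pd <- predict(net, xd)
  expect_equal(pd[1], pd[2])
  expect_error(predict(net, array(0, c(8, 8, 2))), "shape mismatch")
})

test_that("training separates an easy synthetic task within 3 epochs", {
  set.seed(75)
  mk <- function(cl) {
    m <- matrix(rpois(24 * 16, 1), 24, 16)
    if (cl == 1) m[8:16, 4:10] <- m[8:16, 4:10] + 3L
    m
  }
  n <- 800
  labs <- rep(0:1, each = n / 2)
  arr <- array(0, c(24, 16, n))
  for (i in 1:n) arr[, , i] <- mk(labs[i])
  sp <- split_train_val(labs, 0.9)
  net <- build_model(model_config(m = 24, k = 2, filters = 8), c(24, 16))
  net <- train_classifier(net, arr[, , sp$train], labs[sp$train],
                          training_config(epochs = 3),
                          arr[, , sp$val], labs[sp$val])
  expect_equal(nrow(net$history), 3)
  acc <- tail(net$history$val_accuracy, 1)
  expect_gt(acc, 0.8)
  # train/val metric convergence on the easy task
  expect_lt(abs(tail(net$history$accuracy, 1) - acc), 0.15)
  expect_error(train_classifier(net, array(0, c(8, 8, 4)), rep(0, 4)),
               "shape mismatch")
})

test_that("training is reproducible from a fixed seed", {
  mk_data <- function() {
    arr <- array(rpois(16 * 8 * 200, 2), c(16, 8, 200))
    list(arr = arr, labs = rbinom(200, 1, 0.5))
  }
  run <- function() {
    set.seed(76)
    d <- mk_data()
    net <- build_model(model_config(m = 16, k = 2, filters = 4), c(16, 8))
    net <- train_classifier(net, d$arr, d$labs, training_config(epochs = 2))
    net
  }
  n1 <- run(); n2 <- run()
  expect_identical(n1$history, n2$history)
  expect_identical(n1$layers, n2$layers)
})

test_that("classifiers round-trip through save/load", {
  set.seed(77)
  net <- build_model(model_config(m = 16, k = 1, filters = 2), c(16, 8))
  f <- tempfile(fileext = ".rds")
  save_classifier(net, f)
  net2 <- load_classifier(f)
  x <- array(rpois(16 * 8 * 3, 2), c(16, 8, 3))
  expect_identical(predict(net, x), predict(net2, x))
})
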