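# Engine correctness: analytic gradients against central finite differences,
# and the individual layer primitives against hand-computed values.

numeric_grad_check <- function(g, in_ch = 1, size = 8, seed = 3,
                               train = FALSE) {
  arch <- decode_architecture(g, in_channels = in_ch)
  net <- build_network(arch, seed = seed)
  set.seed(seed)
  x <- array(runif(size * size * in_ch), c(size, size, in_ch))
  truth <- array((runif(size * size) > 0.6) * 1, c(size, size, 1))
  loss_of <- function(net) {
    out <- network_forward(net, x, train = train)$out
    dice_loss(out, truth, eps = 1)
  }
  fw <- network_forward(net, x, train = train)
  num <- 2 * sum(fw$out * truth) + 1
  den <- sum(fw$out) + sum(truth) + 1
  dprob <- (num - 2 * truth * den) / den^2
  grads <- gaunet:::network_backward(net, fw$cache, dprob)
  errs <- c()
  for (nm in names(grads)) {
    w <- net$params[[nm]]
    for (i in sample(length(w), min(2, length(w)))) {
      h <- 1e-5
      np <- net
      np$params[[nm]][i] <- w[i] + h
      lp <- loss_of(np)
      nn <- net
      nn$params[[nm]][i] <- w[i] - h
      lm <- loss_of(nn)
      fd <- (lp - lm) / (2 * h)
      errs <- c(errs, abs(fd - grads[[nm]][i]) /
                  max(1e-6, abs(fd) + abs(grads[[nm]][i])))
    }
  }
  max(errs)
}

test_that("backpropagated gradients match finite differences", {
  # odd kernel, ReLU, max-pool
  expect_lt(numeric_grad_check(genome(3, 2, 3, activation = 1)), 1e-4)
  # even kernel, ELU, average-pool, batch norm, depth 2
  expect_lt(numeric_grad_check(genome(5, 2, 4, activation = 2, pooling = 2,
                                      batch_norm = 1)), 1e-4)
  # LeakyReLU, RGB input, batch norm in training mode
  expect_lt(numeric_grad_check(genome(3, 2, 5, activation = 3,
                                      batch_norm = 1),
                               in_ch = 3, train = TRUE), 1e-4)
})

test_that("pooling operators compute the right 2x2 reductions", {
  x <- array(c(1, 3, 2, 4,
               5, 7, 6, 8,
               9, 11, 10, 12,
               13, 15, 14, 16), c(4, 4, 1))
  mx <- gaunet:::pool_fw(x, "max")$out
  av <- gaunet:::pool_fw(x, "average")$out
  # column-major layout: x[,1] = 1,3,2,4; window (1:2, 1:2) = {1,3,5,7}
  expect_equal(as.vector(mx), c(7, 8, 15, 16))
  expect_equal(as.vector(av), c(4, 5, 12, 13))
  # max-pool routes gradient only to the argmax
  r <- gaunet:::pool_fw(x, "max")
  dx <- gaunet:::pool_bw(array(1, c(2, 2, 1)), "max", r$cache)
  expect_equal(sum(dx), 4)
  expect_equal(dx[2, 2, 1], 1)  # position of the 7
  expect_error(gaunet:::pool_fw(array(0, c(3, 3, 1)), "max"), "even")
})

test_that("convolution preserves spatial size for odd and even kernels", {
  for (k in 3:7) {
    W <- array(0.1, c(k, k, 2, 3))
    x <- array(runif(12 * 12 * 2), c(12, 12, 2))
    out <- gaunet:::conv2d_fw(x, W, rep(0, 3))$out
    expect_equal(dim(out), c(12L, 12L, 3L))
  }
})

test_that("a 1x1 identity convolution is a no-op", {
  x <- array(runif(6 * 6), c(6, 6, 1))
  W <- array(1, c(1, 1, 1, 1))
  expect_equal(gaunet:::conv2d_fw(x, W, 0)$out, x)
})

test_that("transposed convolution doubles resolution with phase-wise products", {
  x <- array(1:4, c(2, 2, 1))
  W <- array(c(10, 20, 30, 40), c(2, 2, 1, 1))  # W[a, b, 1, 1]
  out <- gaunet:::upconv_fw(x, W, 0)$out
  expect_equal(dim(out), c(4L, 4L, 1L))
  # each input pixel paints its 2x2 footprint with x * W
  expect_equal(out[1, 1, 1], 1 * 10)
  expect_equal(out[2, 1, 1], 1 * 20)
  expect_equal(out[1, 2, 1], 1 * 30)
  expect_equal(out[2, 2, 1], 1 * 40)
  expect_equal(out[3, 3, 1], 4 * 10)
})

test_that("training reduces the Dice loss on separable phantoms", {
  ds <- tiny_dataset(n = 10, size = 16)
  g <- genome(3, 4, 3, activation = 1, learning_rate = 1e-3, optimizer = 3,
              batch_size = 4)
  fit <- train_network(g, ds$images, ds$masks, epochs = 4, seed = 2)
  expect_false(fit$diverged)
  expect_equal(nrow(fit$history), 4L)
  expect_lt(fit$history$loss[4], fit$history$loss[1])
})

test_that("training is deterministic given the seed", {
  ds <- tiny_dataset(n = 6, size = 16)
  g <- genome(3, 2, 3, learning_rate = 1e-3)
  f1 <- train_network(g, ds$images, ds$masks, epochs = 2, seed = 9)
  f2 <- train_network(g, ds$images, ds$masks, epochs = 2, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$params, f2$network$params)
})
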