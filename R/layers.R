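# Low-level layer primitives for the built-in CNN engine. Feature maps are
# arrays [H, W, C]; all heavy lifting is shifted-slice matrix multiplication
# so the inner loops run in BLAS. Each forward returns list(out, cache); each
# backward consumes (dout, cache) and returns gradients.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99
LEAKY_SLOPE <- 0.3

as_map <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

# -- 2D convolution, same-size output; even kernels pad extra bottom/right --

conv_pad <- function(k) {
  before <- (k - 1L) %/% 2L
  c(before = before, after = (k - 1L) - before)
}

conv2d_fw <- function(x, W, b) {
  dW <- dim(W)
  k <- dW[1]; cin <- dW[3]; cout <- dW[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  pad <- conv_pad(k)
  xpad <- array(0, c(H + k - 1L, Wd + k - 1L, cin))
  xpad[pad[1] + seq_len(H), pad[1] + seq_len(Wd), ] <- x
  ymat <- matrix(rep(b, each = H * Wd), H * Wd, cout)
  for (a in seq_len(k)) {
    for (bb in seq_len(k)) {
      z <- xpad[a:(a + H - 1L), bb:(bb + Wd - 1L), , drop = FALSE]
      dim(z) <- c(H * Wd, cin)
      ymat <- ymat + z %*% matrix(W[a, bb, , ], cin, cout)
    }
  }
  list(out = array(ymat, c(H, Wd, cout)),
       cache = list(xpad = xpad, k = k, H = H, W = Wd, cin = cin,
                    cout = cout))
}

conv2d_bw <- function(dout, W, cache) {
  k <- cache$k; H <- cache$H; Wd <- cache$W
  cin <- cache$cin; cout <- cache$cout
  dymat <- dout; dim(dymat) <- c(H * Wd, cout)
  dWarr <- array(0, dim(W))
  dxpad <- array(0, dim(cache$xpad))
  for (a in seq_len(k)) {
    for (bb in seq_len(k)) {
      z <- cache$xpad[a:(a + H - 1L), bb:(bb + Wd - 1L), , drop = FALSE]
      dim(z) <- c(H * Wd, cin)
      dWarr[a, bb, , ] <- crossprod(z, dymat)
      g <- dymat %*% t(matrix(W[a, bb, , ], cin, cout))
      dim(g) <- c(H, Wd, cin)
      dxpad[a:(a + H - 1L), bb:(bb + Wd - 1L), ] <-
        dxpad[a:(a + H - 1L), bb:(bb + Wd - 1L), , drop = FALSE] + g
    }
  }
  pad <- conv_pad(k)
  list(dx = dxpad[pad[1] + seq_len(H), pad[1] + seq_len(Wd), , drop = FALSE],
       dW = dWarr, db = colSums(dymat))
}

# -- 2x2 stride-2 pooling ---------------------------------------------------

pool_fw <- function(x, type) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  if (H %% 2L != 0L || Wd %% 2L != 0L) {
    stop("pooling requires even spatial size, got ", H, "x", Wd,
         call. = FALSE)
  }
  io <- seq(1L, H, 2L); ie <- seq(2L, H, 2L)
  jo <- seq(1L, Wd, 2L); je <- seq(2L, Wd, 2L)
  x11 <- x[io, jo, , drop = FALSE]; x21 <- x[ie, jo, , drop = FALSE]
  x12 <- x[io, je, , drop = FALSE]; x22 <- x[ie, je, , drop = FALSE]
  if (type == "max") {
    y <- pmax(x11, x21, x12, x22)
    list(out = y, cache = list(x11 = x11, x21 = x21, x12 = x12, x22 = x22,
                               y = y, H = H, W = Wd))
  } else {
    list(out = (x11 + x21 + x12 + x22) / 4,
         cache = list(H = H, W = Wd))
  }
}

pool_bw <- function(dout, type, cache) {
  H <- cache$H; Wd <- cache$W
  C <- dim(dout)[3]
  dx <- array(0, c(H, Wd, C))
  io <- seq(1L, H, 2L); ie <- seq(2L, H, 2L)
  jo <- seq(1L, Wd, 2L); je <- seq(2L, Wd, 2L)
  if (type == "max") {
    w1 <- cache$x11 == cache$y
    w2 <- (cache$x21 == cache$y) & !w1
    w3 <- (cache$x12 == cache$y) & !w1 & !w2
    w4 <- !w1 & !w2 & !w3
    dx[io, jo, ] <- dout * w1
    dx[ie, jo, ] <- dout * w2
    dx[io, je, ] <- dout * w3
    dx[ie, je, ] <- dout * w4
  } else {
    q <- dout / 4
    dx[io, jo, ] <- q; dx[ie, jo, ] <- q
    dx[io, je, ] <- q; dx[ie, je, ] <- q
  }
  dx
}

# -- 2x2 stride-2 transposed convolution (upsampling) -----------------------
# Kernel equals stride, so output sub-grids do not overlap: each of the four
# phases is a plain matrix product.

upconv_fw <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  xmat <- x; dim(xmat) <- c(H * Wd, cin)
  y <- array(0, c(2L * H, 2L * Wd, cout))
  io <- seq(1L, 2L * H, 2L); ie <- seq(2L, 2L * H, 2L)
  jo <- seq(1L, 2L * Wd, 2L); je <- seq(2L, 2L * Wd, 2L)
  bmat <- matrix(rep(b, each = H * Wd), H * Wd, cout)
  phase <- function(a, bb) {
    array(xmat %*% matrix(W[a, bb, , ], cin, cout) + bmat, c(H, Wd, cout))
  }
  y[io, jo, ] <- phase(1L, 1L)
  y[ie, jo, ] <- phase(2L, 1L)
  y[io, je, ] <- phase(1L, 2L)
  y[ie, je, ] <- phase(2L, 2L)
  list(out = y, cache = list(xmat = xmat, H = H, W = Wd, cin = cin,
                             cout = cout))
}

upconv_bw <- function(dout, W, cache) {
  H <- cache$H; Wd <- cache$W
  cin <- cache$cin; cout <- cache$cout
  io <- seq(1L, 2L * H, 2L); ie <- seq(2L, 2L * H, 2L)
  jo <- seq(1L, 2L * Wd, 2L); je <- seq(2L, 2L * Wd, 2L)
  slabs <- list(`11` = dout[io, jo, , drop = FALSE],
                `21` = dout[ie, jo, , drop = FALSE],
                `12` = dout[io, je, , drop = FALSE],
                `22` = dout[ie, je, , drop = FALSE])
  dW <- array(0, dim(W))
  dxmat <- matrix(0, H * Wd, cin)
  db <- numeric(cout)
  for (nm in names(slabs)) {
    a <- as.integer(substr(nm, 1, 1)); bb <- as.integer(substr(nm, 2, 2))
    dymat <- slabs[[nm]]; dim(dymat) <- c(H * Wd, cout)
    dW[a, bb, , ] <- crossprod(cache$xmat, dymat)
    dxmat <- dxmat + dymat %*% t(matrix(W[a, bb, , ], cin, cout))
    db <- db + colSums(dymat)
  }
  list(dx = array(dxmat, c(H, Wd, cin)), dW = dW, db = db)
}

# -- batch normalization ----------------------------------------------------
# The engine processes samples one at a time, so training-mode statistics
# are per-sample spatial moments; inference uses running averages.

bn_fw <- function(x, gamma, beta, run_mean, run_var, train) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  xmat <- x; dim(xmat) <- c(H * Wd, C)
  if (train) {
    mu <- colMeans(xmat)
    vv <- colMeans(xmat^2) - mu^2
    vv[vv < 0] <- 0
    new_mean <- BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu
    new_var <- BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * vv
  } else {
    mu <- run_mean
    vv <- run_var
    new_mean <- run_mean
    new_var <- run_var
  }
  inv_std <- 1 / sqrt(vv + BN_EPS)
  xhat <- sweep(xmat, 2L, mu, "-")
  xhat <- sweep(xhat, 2L, inv_std, "*")
  ymat <- sweep(xhat, 2L, gamma, "*")
  ymat <- sweep(ymat, 2L, beta, "+")
  list(out = array(ymat, c(H, Wd, C)),
       cache = list(xhat = xhat, inv_std = inv_std, H = H, W = Wd, C = C,
                    train = train),
       run_mean = new_mean, run_var = new_var)
}

bn_bw <- function(dout, gamma, cache) {
  H <- cache$H; Wd <- cache$W; C <- cache$C
  n <- H * Wd
  dymat <- dout; dim(dymat) <- c(n, C)
  dgamma <- colSums(dymat * cache$xhat)
  dbeta <- colSums(dymat)
  dxhat <- sweep(dymat, 2L, gamma, "*")
  if (cache$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxmat <- dxhat - matrix(s1 / n, n, C, byrow = TRUE) -
      cache$xhat * matrix(s2 / n, n, C, byrow = TRUE)
    dxmat <- sweep(dxmat, 2L, cache$inv_std, "*")
  } else {
    dxmat <- sweep(dxhat, 2L, cache$inv_std, "*")
  }
  list(dx = array(dxmat, c(H, Wd, C)), dgamma = dgamma, dbeta = dbeta)
}

# -- activations ------------------------------------------------------------

act_fw <- function(x, type) {
  out <- switch(type,
    relu = pmax(x, 0),
    elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
    leaky_relu = ifelse(x > 0, x, LEAKY_SLOPE * x),
    sigmoid = 1 / (1 + exp(-x)),
    stop("unknown activation: ", type))
  list(out = out, cache = list(x = x, out = out))
}

act_bw <- function(dout, type, cache) {
  switch(type,
    relu = dout * (cache$x > 0),
    elu = dout * ifelse(cache$x > 0, 1, cache$out + 1),
    leaky_relu = dout * ifelse(cache$x > 0, 1, LEAKY_SLOPE),
    sigmoid = dout * cache$out * (1 - cache$out),
    stop("unknown activation: ", type))
}

# -- inverted dropout -------------------------------------------------------

dropout_fw <- function(x, rate, train) {
  if (!train || rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, cache = list(mask = mask))
}

dropout_bw <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}
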