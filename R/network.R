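# Network assembly: a built network is a list with the architecture, a flat
# named list of parameter tensors, and a flat named list of batch-norm
# running statistics. Tensor names follow the block layout, e.g.
# "enc1.conv1.W", "dec2.bn2.gamma", "up1.W", "head.W".

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_conv <- function(params, name, k, cin, cout) {
  params[[paste0(name, ".W")]] <-
    glorot_uniform(c(k, k, cin, cout), k * k * cin, k * k * cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

init_bn <- function(params, state, name, c) {
  params[[paste0(name, ".gamma")]] <- rep(1, c)
  params[[paste0(name, ".beta")]] <- rep(0, c)
  state[[paste0(name, ".mean")]] <- rep(0, c)
  state[[paste0(name, ".var")]] <- rep(1, c)
  list(params = params, state = state)
}

init_block <- function(params, state, prefix, k, cin, cout, use_bn) {
  params <- init_conv(params, paste0(prefix, ".conv1"), k, cin, cout)
  if (use_bn) {
    r <- init_bn(params, state, paste0(prefix, ".bn1"), cout)
    params <- r$params; state <- r$state
  }
  params <- init_conv(params, paste0(prefix, ".conv2"), k, cout, cout)
  if (use_bn) {
    r <- init_bn(params, state, paste0(prefix, ".bn2"), cout)
    params <- r$params; state <- r$state
  }
  list(params = params, state = state)
}

#' Build a trainable network from an architecture plan
#'
#' Instantiates every parameterized layer of the plan with seeded
#' Glorot-uniform weights (zero biases; batch-norm scale 1, shift 0, running
#' mean 0 and variance 1). The returned handle is consumed by
#' [network_forward()], [train_network()] and [predict_network()].
#'
#' @param arch A `unet_arch` (or a `ga_genome`, decoded with defaults).
#' @param seed Integer seed for weight initialization.
#' @param in_channels,n_classes Used only when `arch` is a genome.
#' @return An object of class `unet_network`.
#' @export
#' @examples
#' net <- build_network(decode_architecture("lung"), seed = 1)
#' network_num_params(net)  # equals count_parameters()
build_network <- function(arch, seed = 1L, in_channels = 1L, n_classes = 1L) {
  if (inherits(arch, "ga_genome")) {
    arch <- decode_architecture(arch, in_channels, n_classes)
  }
  stopifnot(inherits(arch, "unet_arch"))
  params <- list()
  state <- list()
  k <- arch$kernel_size
  d <- arch$depth
  with_local_seed(seed, {
    cin <- arch$in_channels
    for (l in seq_len(d)) {
      cout <- arch$encoder_channels[l]
      r <- init_block(params, state, paste0("enc", l), k, cin, cout,
                      arch$use_bn)
      params <- r$params; state <- r$state
      cin <- cout
    }
    r <- init_block(params, state, "bott", k, cin,
                    arch$bottleneck_channels, arch$use_bn)
    params <- r$params; state <- r$state
    cin <- arch$bottleneck_channels
    for (l in rev(seq_len(d))) {
      cout <- arch$encoder_channels[l]
      up <- paste0("up", l)
      params[[paste0(up, ".W")]] <-
        glorot_uniform(c(2L, 2L, cin, cout), 4L * cin, 4L * cout)
      params[[paste0(up, ".b")]] <- numeric(cout)
      r <- init_block(params, state, paste0("dec", l), k, 2L * cout, cout,
                      arch$use_bn)
      params <- r$params; state <- r$state
      cin <- cout
    }
    params <- init_conv(params, "head", 1L, cin, arch$n_classes)
  })
  structure(list(arch = arch, params = params, state = state),
            class = "unet_network")
}

#' Total parameter count reported by a built network
#'
#' Sums the sizes of every stored tensor: convolution and transposed-
#' convolution weights and biases, batch-norm scale/shift, and the batch-norm
#' running statistics. By construction this equals the analytic
#' [count_parameters()] of the same architecture.
#'
#' @param net A `unet_network`.
#' @return Integer count.
#' @export
network_num_params <- function(net) {
  stopifnot(inherits(net, "unet_network"))
  sum(vapply(net$params, length, integer(1))) +
    sum(vapply(net$state, length, integer(1)))
}

block_fw <- function(net, prefix, x, train) {
  arch <- net$arch
  p <- net$params
  cache <- list()
  updates <- list()
  for (i in 1:2) {
    cname <- paste0(prefix, ".conv", i)
    r <- conv2d_fw(x, p[[paste0(cname, ".W")]], p[[paste0(cname, ".b")]])
    cache[[paste0("conv", i)]] <- r$cache
    x <- r$out
    if (arch$use_bn) {
      bname <- paste0(prefix, ".bn", i)
      r <- bn_fw(x, p[[paste0(bname, ".gamma")]],
                 p[[paste0(bname, ".beta")]],
                 net$state[[paste0(bname, ".mean")]],
                 net$state[[paste0(bname, ".var")]], train)
      cache[[paste0("bn", i)]] <- r$cache
      updates[[paste0(bname, ".mean")]] <- r$run_mean
      updates[[paste0(bname, ".var")]] <- r$run_var
      x <- r$out
    }
    r <- act_fw(x, arch$activation)
    cache[[paste0("act", i)]] <- r$cache
    x <- r$out
  }
  if (arch$use_dropout) {
    r <- dropout_fw(x, arch$dropout_rate, train)
    cache$dropout <- r$cache
    x <- r$out
  }
  list(out = x, cache = cache, updates = updates)
}

block_bw <- function(net, prefix, dout, cache, grads) {
  arch <- net$arch
  p <- net$params
  if (arch$use_dropout) dout <- dropout_bw(dout, cache$dropout)
  for (i in 2:1) {
    dout <- act_bw(dout, arch$activation, cache[[paste0("act", i)]])
    if (arch$use_bn) {
      bname <- paste0(prefix, ".bn", i)
      r <- bn_bw(dout, p[[paste0(bname, ".gamma")]],
                 cache[[paste0("bn", i)]])
      grads[[paste0(bname, ".gamma")]] <- r$dgamma
      grads[[paste0(bname, ".beta")]] <- r$dbeta
      dout <- r$dx
    }
    cname <- paste0(prefix, ".conv", i)
    r <- conv2d_bw(dout, p[[paste0(cname, ".W")]],
                   cache[[paste0("conv", i)]])
    grads[[paste0(cname, ".W")]] <- r$dW
    grads[[paste0(cname, ".b")]] <- r$db
    dout <- r$dx
  }
  list(dx = dout, grads = grads)
}

#' Forward pass through a built network
#'
#' Maps an `H x W x in_channels` image to an `H x W x n_classes` probability
#' map in `[0, 1]`. Spatial dimensions must be divisible by `2^depth` so the
#' pooling/upsampling ladder closes.
#'
#' @param net A `unet_network`.
#' @param x Input image, `[H, W]` or `[H, W, C]` array.
#' @param train Logical; training mode enables dropout and per-sample
#'   batch-norm statistics (with running-average updates).
#' @return A list with `out` (probability map), `cache` (for the internal
#'   backward pass) and `state` (updated running statistics).
#' @export
network_forward <- function(net, x, train = FALSE) {
  stopifnot(inherits(net, "unet_network"))
  arch <- net$arch
  x <- as_map(x)
  H <- dim(x)[1]; Wd <- dim(x)[2]
  div <- 2L^arch$depth
  if (H %% div != 0L || Wd %% div != 0L) {
    stop("input spatial size ", H, "x", Wd, " must be divisible by ", div,
         " (depth ", arch$depth, ")", call. = FALSE)
  }
  if (dim(x)[3] != arch$in_channels) {
    stop("input has ", dim(x)[3], " channel(s); architecture expects ",
         arch$in_channels, call. = FALSE)
  }
  d <- arch$depth
  cache <- list()
  updates <- list()
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    r <- block_fw(net, paste0("enc", l), x, train)
    cache[[paste0("enc", l)]] <- r$cache
    updates <- modifyList(updates, r$updates)
    skips[[l]] <- r$out
    rp <- pool_fw(r$out, arch$pooling)
    cache[[paste0("pool", l)]] <- rp$cache
    x <- rp$out
  }
  r <- block_fw(net, "bott", x, train)
  cache$bott <- r$cache
  updates <- modifyList(updates, r$updates)
  x <- r$out
  for (l in rev(seq_len(d))) {
    up <- paste0("up", l)
    r <- upconv_fw(x, net$params[[paste0(up, ".W")]],
                   net$params[[paste0(up, ".b")]])
    cache[[up]] <- r$cache
    cskip <- dim(skips[[l]])[3]
    x <- array(c(skips[[l]], r$out),
               c(dim(r$out)[1], dim(r$out)[2], cskip + dim(r$out)[3]))
    cache[[paste0("concat", l)]] <- cskip
    r <- block_fw(net, paste0("dec", l), x, train)
    cache[[paste0("dec", l)]] <- r$cache
    updates <- modifyList(updates, r$updates)
    x <- r$out
  }
  r <- conv2d_fw(x, net$params[["head.W"]], net$params[["head.b"]])
  cache$head <- r$cache
  rs <- act_fw(r$out, "sigmoid")
  cache$sigmoid <- rs$cache
  list(out = rs$out, cache = cache,
       state = modifyList(net$state, updates))
}

# Backward pass from d(loss)/d(probability map); returns parameter grads.
network_backward <- function(net, cache, dprob) {
  arch <- net$arch
  d <- arch$depth
  grads <- list()
  dout <- act_bw(dprob, "sigmoid", cache$sigmoid)
  r <- conv2d_bw(dout, net$params[["head.W"]], cache$head)
  grads[["head.W"]] <- r$dW
  grads[["head.b"]] <- r$db
  dout <- r$dx
  dskips <- vector("list", d)
  for (l in seq_len(d)) {
    r <- block_bw(net, paste0("dec", l), dout, cache[[paste0("dec", l)]],
                  grads)
    grads <- r$grads
    dcat <- r$dx
    cskip <- cache[[paste0("concat", l)]]
    dskips[[l]] <- dcat[, , seq_len(cskip), drop = FALSE]
    dup <- dcat[, , (cskip + 1L):dim(dcat)[3], drop = FALSE]
    up <- paste0("up", l)
    r <- upconv_bw(dup, net$params[[paste0(up, ".W")]], cache[[up]])
    grads[[paste0(up, ".W")]] <- r$dW
    grads[[paste0(up, ".b")]] <- r$db
    dout <- r$dx
  }
  r <- block_bw(net, "bott", dout, cache$bott, grads)
  grads <- r$grads
  dout <- r$dx
  for (l in rev(seq_len(d))) {
    dout <- pool_bw(dout, arch$pooling, cache[[paste0("pool", l)]])
    dout <- dout + dskips[[l]]
    r <- block_bw(net, paste0("enc", l), dout, cache[[paste0("enc", l)]],
                  grads)
    grads <- r$grads
    dout <- r$dx
  }
  grads
}

#' Predict probability maps for a set of images
#'
#' Runs the network in inference mode (dropout off, batch-norm running
#' statistics) over a list of images.
#'
#' @param net A `unet_network`.
#' @param images A list of `[H, W]` or `[H, W, C]` arrays, or a single array.
#' @return A list of `[H, W]` probability matrices (for `n_classes = 1`).
#' @export
predict_network <- function(net, images) {
  if (!is.list(images)) images <- list(images)
  lapply(images, function(x) {
    out <- network_forward(net, x, train = FALSE)$out
    if (dim(out)[3] == 1L) dim(out) <- dim(out)[1:2]
    out
  })
}

#' @export
print.unet_network <- function(x, ...) {
  cat("built U-shaped network\n")
  print(x$arch)
  invisible(x)
}
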