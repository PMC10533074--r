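#' Decode a genome into a U-shaped architecture plan
#'
#' Expands the ten-gene genome into a concrete layer plan: `d = (B - 1) / 2`
#' encoder levels whose channel counts double from `first_filters`
#' (`C, 2C, ..., C 2^(d-1)`), a bottleneck at `C 2^d`, and a mirrored decoder
#' reached through 2x2 stride-2 transposed convolutions, with the same-level
#' encoder output concatenated into each decoder block (skip connections).
#' Every block holds two `F x F` convolutions, each followed by the genome's
#' activation, with batch normalization (when on) between convolution and
#' activation. The head is a 1x1 convolution to `n_classes` with a sigmoid.
#'
#' All convolutions use same-size padding; even kernels pad the extra pixel
#' on the bottom/right.
#'
#' @param g A `ga_genome` (or the name of a shipped discovered genome).
#' @param in_channels Input image channels (1 for CT-like grayscale, 3 for
#'   RGB microscopy).
#' @param n_classes Output channels; 1 for binary segmentation.
#' @return An object of class `unet_arch`.
#' @export
#' @examples
#' arch <- decode_architecture(discovered_genome("lung"), in_channels = 1)
#' arch$encoder_channels
#' count_parameters(arch)
decode_architecture <- function(g, in_channels = 1L, n_classes = 1L) {
  if (is.character(g)) g <- discovered_genome(g)
  validate_genome(g)
  stopifnot(in_channels >= 1L, n_classes >= 1L)
  d <- genome_depth(g)
  enc <- g$first_filters * 2L^(seq_len(d) - 1L)
  arch <- structure(list(
    depth = d,
    in_channels = as.integer(in_channels),
    n_classes = as.integer(n_classes),
    encoder_channels = as.integer(enc),
    bottleneck_channels = as.integer(g$first_filters * 2L^d),
    decoder_channels = as.integer(rev(enc)),
    kernel_size = g$kernel_size,
    activation = names(ACTIVATION_CODES)[match(g$activation,
                                               ACTIVATION_CODES)],
    pooling = names(POOLING_CODES)[match(g$pooling, POOLING_CODES)],
    use_bn = g$batch_norm == 1L,
    use_dropout = g$dropout == 1L,
    dropout_rate = DROPOUT_RATE,
    genome = g
  ), class = "unet_arch")
  arch
}

# Hand-specified architecture (used for the classic U-Net baseline):
# encoder channel list, bottleneck, kernel, no genome attached.
make_arch <- function(encoder_channels, bottleneck_channels, kernel_size,
                      in_channels = 1L, n_classes = 1L, activation = "relu",
                      pooling = "max", use_bn = FALSE, use_dropout = FALSE) {
  structure(list(
    depth = length(encoder_channels),
    in_channels = as.integer(in_channels),
    n_classes = as.integer(n_classes),
    encoder_channels = as.integer(encoder_channels),
    bottleneck_channels = as.integer(bottleneck_channels),
    decoder_channels = as.integer(rev(encoder_channels)),
    kernel_size = as.integer(kernel_size),
    activation = activation,
    pooling = pooling,
    use_bn = use_bn,
    use_dropout = use_dropout,
    dropout_rate = DROPOUT_RATE,
    genome = NULL
  ), class = "unet_arch")
}

#' The original U-Net baseline architecture
#'
#' The classic four-level U-Net: encoder channels 64, 128, 256, 512,
#' bottleneck 1024, two 3x3 convolutions per block, 2x2 max-pooling, 2x2
#' transposed-convolution upsampling, no batch normalization, single-class
#' 1x1 sigmoid head, same-size padding.
#'
#' @param in_channels Input image channels.
#' @param n_classes Output channels.
#' @return A `unet_arch`.
#' @export
#' @examples
#' count_parameters(unet_baseline())  # 31,030,593
unet_baseline <- function(in_channels = 1L, n_classes = 1L) {
  make_arch(encoder_channels = c(64L, 128L, 256L, 512L),
            bottleneck_channels = 1024L, kernel_size = 3L,
            in_channels = in_channels, n_classes = n_classes)
}

# Per-layer parameter closed forms. BN counts 4 per channel: gamma and beta
# (trainable) plus running mean and variance.
conv_params <- function(k, cin, cout) k * k * cin * cout + cout
upconv_params <- function(cin, cout) 4L * cin * cout + cout
bn_params <- function(c) 4L * c

#' Layer-by-layer decomposition of an architecture
#'
#' Flattens a `unet_arch` into one row per layer with kind (conv, bn,
#' activation, pool, upconv, concat, dropout, output), kernel size, input and
#' output channels, and exact parameter count. [count_parameters()] is the
#' column sum; the table is also the blueprint [build_network()] follows.
#'
#' @param arch A `unet_arch`.
#' @return A `data.frame` with columns `stage`, `kind`, `kernel`, `cin`,
#'   `cout`, `params`.
#' @export
#' @examples
#' head(layer_table(decode_architecture(discovered_genome("lung"))))
layer_table <- function(arch) {
  stopifnot(inherits(arch, "unet_arch"))
  k <- arch$kernel_size
  rows <- list()
  add <- function(stage, kind, kernel, cin, cout, params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, kind = kind, kernel = kernel, cin = cin, cout = cout,
      params = params, stringsAsFactors = FALSE)
  }
  add_block <- function(stage, cin, cout) {
    add(stage, "conv", k, cin, cout, conv_params(k, cin, cout))
    if (arch$use_bn) add(stage, "bn", 0L, cout, cout, bn_params(cout))
    add(stage, "activation", 0L, cout, cout, 0L)
    add(stage, "conv", k, cout, cout, conv_params(k, cout, cout))
    if (arch$use_bn) add(stage, "bn", 0L, cout, cout, bn_params(cout))
    add(stage, "activation", 0L, cout, cout, 0L)
    if (arch$use_dropout) add(stage, "dropout", 0L, cout, cout, 0L)
  }
  d <- arch$depth
  cin <- arch$in_channels
  for (l in seq_len(d)) {
    cout <- arch$encoder_channels[l]
    add_block(sprintf("encoder%d", l), cin, cout)
    add(sprintf("encoder%d", l), "pool", 2L, cout, cout, 0L)
    cin <- cout
  }
  add_block("bottleneck", cin, arch$bottleneck_channels)
  cin <- arch$bottleneck_channels
  for (l in rev(seq_len(d))) {
    cout <- arch$encoder_channels[l]
    stage <- sprintf("decoder%d", l)
    add(stage, "upconv", 2L, cin, cout, upconv_params(cin, cout))
    add(stage, "concat", 0L, cout, 2L * cout, 0L)
    add_block(stage, 2L * cout, cout)
    cin <- cout
  }
  add("head", "output", 1L, cin, arch$n_classes,
      conv_params(1L, cin, arch$n_classes))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact total parameter count of an architecture
#'
#' Sums the closed-form per-layer counts over [layer_table()]: a `k x k`
#' convolution `cin -> cout` holds `k^2 cin cout + cout` parameters, a 2x2
#' transposed convolution `4 cin cout + cout`, batch normalization 4 per
#' channel (scale, shift, running mean and variance), the 1x1 output head
#' `cin n_classes + n_classes`; pooling, activations, concatenation and
#' dropout are parameter-free. The total therefore includes the
#' non-trainable batch-norm running statistics, matching the total reported
#' by [build_network()].
#'
#' @param arch A `unet_arch` (or a `ga_genome`, decoded with defaults).
#' @param in_channels,n_classes Used only when `arch` is a genome.
#' @return Integer total parameter count.
#' @export
#' @examples
#' count_parameters(decode_architecture(discovered_genome("liver")))  # 207265
count_parameters <- function(arch, in_channels = 1L, n_classes = 1L) {
  if (inherits(arch, "ga_genome")) {
    arch <- decode_architecture(arch, in_channels, n_classes)
  }
  sum(layer_table(arch)$params)
}

#' Format a parameter count in printed millions
#'
#' Divides by one million and truncates (floors): to three decimals for
#' sub-million models, to two otherwise. Truncation, not rounding, is the
#' convention used for all printed complexity figures.
#'
#' @param count Non-negative parameter count.
#' @return Numeric value in millions.
#' @export
#' @examples
#' params_in_millions(76553)     # 0.076
#' params_in_millions(31030593)  # 31.03
params_in_millions <- function(count) {
  stopifnot(count >= 0)
  ifelse(count < 1e6, floor(count / 1e3) / 1e3, floor(count / 1e4) / 1e2)
}

#' Parameter-count reduction relative to a baseline
#'
#' Compares two counts on the printed-millions scale (the truncated values a
#' reader sees): `percent_of` is `100 * small / big` and `percent_fewer` is
#' its complement, both rounded to two decimals. For the lung architecture
#' against the classic U-Net this yields 0.24% of the parameters, i.e.
#' 99.76% fewer.
#'
#' @param count Parameter count of the compact model.
#' @param baseline Parameter count of the reference model.
#' @return A list with `percent_of` and `percent_fewer`.
#' @export
#' @examples
#' param_reduction(count_parameters(decode_architecture("lung")),
#'                 count_parameters(unet_baseline()))
param_reduction <- function(count, baseline) {
  ratio <- params_in_millions(count) / params_in_millions(baseline)
  list(percent_of = round(100 * ratio, 2),
       percent_fewer = round(100 * (1 - ratio), 2))
}

#' @export
print.unet_arch <- function(x, ...) {
  cat("U-shaped architecture (depth ", x$depth, ", ", x$in_channels,
      " -> ", x$n_classes, " channels)\n", sep = "")
  cat("  encoder:   ", paste(x$encoder_channels, collapse = " -> "), "\n",
      sep = "")
  cat("  bottleneck:", x$bottleneck_channels, "\n")
  cat("  decoder:   ", paste(x$decoder_channels, collapse = " -> "), "\n",
      sep = "")
  cat(sprintf("  %dx%d convs, %s, %s-pool, batch norm %s, dropout %s\n",
              x$kernel_size, x$kernel_size, x$activation, x$pooling,
              ifelse(x$use_bn, "on", "off"),
              ifelse(x$use_dropout, sprintf("%.1f", x$dropout_rate), "off")))
  n <- count_parameters(x)
  cat(sprintf("  parameters: %s (%.3g M printed as %s)\n",
              format(n, big.mark = ","), n / 1e6,
              format(params_in_millions(n))))
  invisible(x)
}

#' Write the architecture summary as CSV
#'
#' One [layer_table()] row per line; a plain-text artifact describing the
#' decoded plan.
#'
#' @param arch A `unet_arch`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_architecture_csv <- function(arch, path) {
  utils::write.csv(layer_table(arch), path, row.names = FALSE)
  invisible(path)
}
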