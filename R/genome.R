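GENE_NAMES <- c("n_blocks", "first_filters", "kernel_size", "activation",
                "pooling", "batch_norm", "dropout", "optimizer",
                "learning_rate", "batch_size")

ACTIVATION_CODES <- c("relu" = 1L, "elu" = 2L, "leaky_relu" = 3L)
POOLING_CODES <- c("max" = 1L, "average" = 2L)
OPTIMIZER_CODES <- c("sgd" = 1L, "rmsprop" = 2L, "adam" = 3L, "adamax" = 4L)
DROPOUT_RATE <- 0.3

#' Construct an architecture genome
#'
#' A genome is the ten-gene integer/real vector describing one candidate
#' U-shaped network and its training recipe. Total block count `n_blocks`
#' must be odd: the encoder and decoder have the same number of blocks with
#' a single bottleneck block between them, so `n_blocks = 2 * depth + 1`.
#'
#' @param n_blocks Total block count (odd).
#' @param first_filters Filter count of the first encoder block; channels
#'   double at every deeper level.
#' @param kernel_size Square convolution kernel size.
#' @param activation Activation code: 1 = ReLU, 2 = ELU, 3 = LeakyReLU.
#' @param pooling Pooling code: 1 = max, 2 = average (2x2, stride 2).
#' @param batch_norm 0/1, batch normalization between each convolution and
#'   its activation.
#' @param dropout 0/1, dropout (rate 0.3) after each block.
#' @param optimizer Optimizer code: 1 = SGD, 2 = RMSprop, 3 = Adam,
#'   4 = Adamax.
#' @param learning_rate Positive learning rate.
#' @param batch_size Mini-batch size used in training.
#' @param space Search space the genome must lie in.
#'
#' @return An object of class `ga_genome` (a named list of the ten genes).
#' @export
#' @examples
#' g <- genome(5, 8, 5, activation = 2, learning_rate = 1e-4)
#' genome_depth(g)
genome <- function(n_blocks, first_filters, kernel_size, activation = 1,
                   pooling = 1, batch_norm = 0, dropout = 0, optimizer = 3,
                   learning_rate = 1e-4, batch_size = 8,
                   space = search_space()) {
  g <- structure(list(
    n_blocks = as.integer(n_blocks),
    first_filters = as.integer(first_filters),
    kernel_size = as.integer(kernel_size),
    activation = as.integer(activation),
    pooling = as.integer(pooling),
    batch_norm = as.integer(batch_norm),
    dropout = as.integer(dropout),
    optimizer = as.integer(optimizer),
    learning_rate = as.numeric(learning_rate),
    batch_size = as.integer(batch_size)
  ), class = "ga_genome")
  validate_genome(g, space)
  g
}

#' Validate a genome against a search space
#'
#' Checks that every gene lies in its domain and that the block count is odd
#' (so the decoded depth is a positive integer).
#'
#' @param g A `ga_genome`.
#' @param space A `ga_search_space`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_genome <- function(g, space = search_space()) {
  stopifnot(inherits(g, "ga_genome"))
  validate_search_space(space)
  in_dom <- function(value, dom, nm) {
    if (!value %in% dom) {
      stop("gene '", nm, "' = ", value, " outside domain {",
           paste(dom, collapse = ", "), "}", call. = FALSE)
    }
  }
  in_dom(g$n_blocks, space$blocks_domain, "n_blocks")
  if (g$n_blocks %% 2L != 1L) {
    stop("n_blocks must be odd (encoder + bottleneck + mirrored decoder)",
         call. = FALSE)
  }
  in_dom(g$first_filters, space$filters_domain, "first_filters")
  in_dom(g$kernel_size, space$kernel_domain, "kernel_size")
  in_dom(g$activation, space$activation_domain, "activation")
  in_dom(g$pooling, space$pooling_domain, "pooling")
  in_dom(g$batch_norm, space$bn_domain, "batch_norm")
  in_dom(g$dropout, space$dropout_domain, "dropout")
  in_dom(g$optimizer, space$optimizer_domain, "optimizer")
  if (is.na(g$learning_rate) || g$learning_rate < space$lr_range[1] ||
      g$learning_rate > space$lr_range[2]) {
    stop("gene 'learning_rate' = ", g$learning_rate, " outside [",
         space$lr_range[1], ", ", space$lr_range[2], "]", call. = FALSE)
  }
  in_dom(g$batch_size, space$batch_domain, "batch_size")
  invisible(g)
}

#' Decoded U-depth of a genome
#'
#' @param g A `ga_genome`.
#' @return `(n_blocks - 1) / 2`, the number of encoder (= decoder) levels.
#' @export
genome_depth <- function(g) {
  (g$n_blocks - 1L) %/% 2L
}

#' Draw a random genome from a search space
#'
#' Discrete genes are drawn uniformly from their domains; the learning rate
#' is drawn log-uniformly from `lr_range`. Uses the current R random stream,
#' so results are reproducible under [set.seed()].
#'
#' @param space A `ga_search_space`.
#' @return A valid `ga_genome` (odd block count guaranteed via repair).
#' @export
#' @examples
#' set.seed(1)
#' sample_genome()
sample_genome <- function(space = search_space()) {
  validate_search_space(space)
  draw <- function(dom) dom[sample.int(length(dom), 1L)]
  lr <- exp(stats::runif(1, log(space$lr_range[1]), log(space$lr_range[2])))
  raw <- c(
    draw(space$blocks_domain), draw(space$filters_domain),
    draw(space$kernel_domain), draw(space$activation_domain),
    draw(space$pooling_domain), draw(space$bn_domain),
    draw(space$dropout_domain), draw(space$optimizer_domain),
    lr, draw(space$batch_domain)
  )
  repair_genome(raw, space)
}

#' Repair a raw gene vector into a valid genome
#'
#' Maps any finite ten-entry vector onto the search space: discrete genes are
#' snapped to the nearest allowed value (ties toward the smaller value,
#' biasing toward cheaper architectures), the learning rate is clamped to its
#' interval, and an even block count is decremented by one so the decoded
#' depth is integral.
#'
#' @param raw A `ga_genome`, named list, or plain numeric vector of ten genes
#'   in the order n_blocks, first_filters, kernel_size, activation, pooling,
#'   batch_norm, dropout, optimizer, learning_rate, batch_size.
#' @param space A `ga_search_space`.
#' @return A valid `ga_genome`.
#' @export
#' @examples
#' repair_genome(c(4, 5, 9, 1, 1, 0, 0, 3, 5e-5, 10))
repair_genome <- function(raw, space = search_space()) {
  validate_search_space(space)
  if (inherits(raw, "ga_genome") || is.list(raw)) {
    missing <- setdiff(GENE_NAMES, names(raw))
    if (length(missing) > 0L) {
      stop("gene vector missing entries: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    raw <- unlist(raw[GENE_NAMES], use.names = FALSE)
  }
  raw <- as.numeric(raw)
  if (length(raw) != 10L || anyNA(raw) || any(!is.finite(raw))) {
    stop("a raw genome must be 10 finite values", call. = FALSE)
  }
  snap <- function(value, dom) {
    d <- abs(dom - value)
    dom[which.min(d)]  # ties resolve to the smaller (sorted) value
  }
  b <- snap(raw[1], space$blocks_domain)
  if (b %% 2L == 0L) {
    b <- b - 1L
    if (!b %in% space$blocks_domain) {
      odd <- space$blocks_domain[space$blocks_domain %% 2L == 1L]
      b <- snap(b, odd)
    }
  }
  lr <- min(max(raw[9], space$lr_range[1]), space$lr_range[2])
  genome(
    n_blocks = b,
    first_filters = snap(raw[2], space$filters_domain),
    kernel_size = snap(raw[3], space$kernel_domain),
    activation = snap(raw[4], space$activation_domain),
    pooling = snap(raw[5], space$pooling_domain),
    batch_norm = snap(raw[6], space$bn_domain),
    dropout = snap(raw[7], space$dropout_domain),
    optimizer = snap(raw[8], space$optimizer_domain),
    learning_rate = lr,
    batch_size = snap(raw[10], space$batch_domain),
    space = space
  )
}

#' @export
print.ga_genome <- function(x, ...) {
  act <- names(ACTIVATION_CODES)[match(x$activation, ACTIVATION_CODES)]
  pool <- names(POOLING_CODES)[match(x$pooling, POOLING_CODES)]
  opt <- names(OPTIMIZER_CODES)[match(x$optimizer, OPTIMIZER_CODES)]
  cat("architecture genome (depth ", genome_depth(x), ")\n", sep = "")
  cat(sprintf("  blocks %d | filters %d | kernel %dx%d | %s | %s-pool\n",
              x$n_blocks, x$first_filters, x$kernel_size, x$kernel_size,
              act, pool))
  cat(sprintf("  batch norm %s | dropout %s | %s, lr %g, batch %d\n",
              ifelse(x$batch_norm == 1L, "on", "off"),
              ifelse(x$dropout == 1L, sprintf("%.1f", DROPOUT_RATE), "off"),
              opt, x$learning_rate, x$batch_size))
  invisible(x)
}

#' @export
format.ga_genome <- function(x, ...) {
  paste0("(", paste(c(x$n_blocks, x$first_filters, x$kernel_size,
                      x$activation, x$pooling, x$batch_norm, x$dropout,
                      x$optimizer, format(x$learning_rate), x$batch_size),
                    collapse = ","), ")")
}

#' @export
as.numeric.ga_genome <- function(x, ...) {
  unlist(x[GENE_NAMES], use.names = FALSE)
}

# Deterministic 31-bit hash of a genome, used to derive per-candidate
# training seeds so that identical genomes always train identically.
genome_hash <- function(g, seed = 0L) {
  txt <- paste(format(as.numeric(g), digits = 15), collapse = "|")
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}
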