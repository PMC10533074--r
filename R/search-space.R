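#' Architecture search space
#'
#' Defines the admissible domain of every gene in the ten-gene architecture
#' genome. The defaults describe the published search space: 3--7 blocks
#' (restricted to odd totals, see [repair_genome()]), first-block filters in
#' \{2, 4, 8\}, square kernels 3--7, three activations (1 = ReLU, 2 = ELU,
#' 3 = LeakyReLU), two pooling operators (1 = max, 2 = average, both 2x2
#' stride 2), binary batch-normalization and dropout switches, four
#' optimizers (1 = SGD, 2 = RMSprop, 3 = Adam, 4 = Adamax), a continuous
#' learning-rate interval [1e-4, 1e-3], and batch sizes \{4, 8, 16, 32\}.
#'
#' @param blocks_domain Integer vector of allowed total block counts
#'   (encoder + bottleneck + decoder).
#' @param filters_domain Integer vector of allowed first-block filter counts.
#' @param kernel_domain Integer vector of allowed square kernel sizes.
#' @param activation_domain Integer activation codes.
#' @param pooling_domain Integer pooling codes.
#' @param bn_domain Batch-normalization switch values.
#' @param dropout_domain Dropout switch values (rate 0.3 when on).
#' @param optimizer_domain Integer optimizer codes.
#' @param lr_range Length-2 numeric, closed learning-rate interval.
#' @param batch_domain Integer vector of allowed batch sizes.
#'
#' @return An object of class `ga_search_space`.
#' @export
#' @examples
#' space <- search_space()
#' space$lr_range
search_space <- function(blocks_domain = 3:7,
                         filters_domain = c(2L, 4L, 8L),
                         kernel_domain = 3:7,
                         activation_domain = 1:3,
                         pooling_domain = 1:2,
                         bn_domain = 0:1,
                         dropout_domain = 0:1,
                         optimizer_domain = 1:4,
                         lr_range = c(1e-4, 1e-3),
                         batch_domain = c(4L, 8L, 16L, 32L)) {
  space <- structure(list(
    blocks_domain = sort(as.integer(blocks_domain)),
    filters_domain = sort(as.integer(filters_domain)),
    kernel_domain = sort(as.integer(kernel_domain)),
    activation_domain = sort(as.integer(activation_domain)),
    pooling_domain = sort(as.integer(pooling_domain)),
    bn_domain = sort(as.integer(bn_domain)),
    dropout_domain = sort(as.integer(dropout_domain)),
    optimizer_domain = sort(as.integer(optimizer_domain)),
    lr_range = as.numeric(lr_range),
    batch_domain = sort(as.integer(batch_domain))
  ), class = "ga_search_space")
  validate_search_space(space)
  space
}

validate_search_space <- function(space) {
  stopifnot(inherits(space, "ga_search_space"))
  discrete <- c("blocks_domain", "filters_domain", "kernel_domain",
                "activation_domain", "pooling_domain", "bn_domain",
                "dropout_domain", "optimizer_domain", "batch_domain")
  for (nm in discrete) {
    dom <- space[[nm]]
    if (length(dom) == 0L || anyNA(dom)) {
      stop("search space domain '", nm, "' must be non-empty and finite",
           call. = FALSE)
    }
  }
  lr <- space$lr_range
  if (length(lr) != 2L || anyNA(lr) || lr[1] <= 0 || lr[2] < lr[1]) {
    stop("lr_range must be a positive, ordered interval", call. = FALSE)
  }
  if (!any(space$blocks_domain %% 2L == 1L)) {
    stop("blocks_domain must contain at least one odd value ",
         "(total blocks = 2 * depth + 1)", call. = FALSE)
  }
  invisible(space)
}

#' @export
print.ga_search_space <- function(x, ...) {
  cat("U-shaped architecture search space\n")
  cat("  blocks (B):      ", paste(x$blocks_domain, collapse = ", "),
      " (odd totals used)\n", sep = "")
  cat("  filters (C):     ", paste(x$filters_domain, collapse = ", "), "\n",
      sep = "")
  cat("  kernel (F):      ", paste(x$kernel_domain, collapse = ", "), "\n",
      sep = "")
  cat("  activation (A):  ", paste(x$activation_domain, collapse = ", "),
      "  [1=ReLU 2=ELU 3=LeakyReLU]\n", sep = "")
  cat("  pooling (P):     ", paste(x$pooling_domain, collapse = ", "),
      "  [1=max 2=average]\n", sep = "")
  cat("  batch norm (BN): ", paste(x$bn_domain, collapse = ", "), "\n",
      sep = "")
  cat("  dropout (D):     ", paste(x$dropout_domain, collapse = ", "), "\n",
      sep = "")
  cat("  optimizer (O):   ", paste(x$optimizer_domain, collapse = ", "),
      "  [1=SGD 2=RMSprop 3=Adam 4=Adamax]\n", sep = "")
  cat("  learning rate:   [", format(x$lr_range[1]), ", ",
      format(x$lr_range[2]), "]\n", sep = "")
  cat("  batch size (BA): ", paste(x$batch_domain, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
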