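# Optimizers and the training loop for the built-in engine. The four
# optimizers mirror the usual framework defaults: plain SGD; RMSprop with
# rho 0.9; Adam with beta1 0.9, beta2 0.999 and bias correction; Adamax with
# the infinity-norm second moment. Epsilon 1e-7 throughout.

OPT_EPS <- 1e-7

make_optimizer <- function(name, lr) {
  name <- if (is.numeric(name)) {
    names(OPTIMIZER_CODES)[match(as.integer(name), OPTIMIZER_CODES)]
  } else {
    name
  }
  if (is.na(name) || !name %in% names(OPTIMIZER_CODES)) {
    stop("unknown optimizer: must be one of ",
         paste(names(OPTIMIZER_CODES), collapse = ", "), call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$t <- 0L
  env$m <- list()
  env$v <- list()
  step <- switch(name,
    sgd = function(params, grads) {
      for (nm in names(grads)) {
        params[[nm]] <- params[[nm]] - lr * grads[[nm]]
      }
      params
    },
    rmsprop = function(params, grads) {
      for (nm in names(grads)) {
        g <- grads[[nm]]
        v <- env$v[[nm]] %||% (g * 0)
        v <- 0.9 * v + 0.1 * g^2
        env$v[[nm]] <- v
        params[[nm]] <- params[[nm]] - lr * g / (sqrt(v) + OPT_EPS)
      }
      params
    },
    adam = function(params, grads) {
      env$t <- env$t + 1L
      c1 <- 1 - 0.9^env$t
      c2 <- 1 - 0.999^env$t
      for (nm in names(grads)) {
        g <- grads[[nm]]
        m <- env$m[[nm]] %||% (g * 0)
        v <- env$v[[nm]] %||% (g * 0)
        m <- 0.9 * m + 0.1 * g
        v <- 0.999 * v + 0.001 * g^2
        env$m[[nm]] <- m
        env$v[[nm]] <- v
        params[[nm]] <- params[[nm]] -
          lr * (m / c1) / (sqrt(v / c2) + OPT_EPS)
      }
      params
    },
    adamax = function(params, grads) {
      env$t <- env$t + 1L
      c1 <- 1 - 0.9^env$t
      for (nm in names(grads)) {
        g <- grads[[nm]]
        m <- env$m[[nm]] %||% (g * 0)
        u <- env$v[[nm]] %||% (g * 0)
        m <- 0.9 * m + 0.1 * g
        u <- pmax(0.999 * u, abs(g))
        env$m[[nm]] <- m
        env$v[[nm]] <- u
        params[[nm]] <- params[[nm]] - (lr / c1) * m / (u + OPT_EPS)
      }
      params
    })
  list(name = name, step = step)
}

# Gradient of the smoothed Dice loss w.r.t. the probability map.
dice_loss_grad <- function(prob, truth, eps = DICE_EPS) {
  num <- 2 * sum(prob * truth) + eps
  den <- sum(prob) + sum(truth) + eps
  list(loss = 1 - num / den, dprob = (num - 2 * truth * den) / den^2)
}

#' Train a network on paired images and masks
#'
#' Minimizes the smoothed Dice loss by mini-batch gradient descent with the
#' genome's (or explicitly given) optimizer, learning rate and batch size.
#' Images are shuffled every epoch; gradients are averaged over each
#' mini-batch. If the loss becomes non-finite, training stops and the
#' returned handle is flagged `diverged`.
#'
#' @param arch A `unet_arch`, `ga_genome`, or an already built
#'   `unet_network` (resumed training).
#' @param images List of input images (`[H, W]` or `[H, W, C]` arrays in
#'   `[0, 1]`).
#' @param masks List of binary ground-truth masks (`[H, W]`, values 0/1).
#' @param epochs Number of passes over the data.
#' @param optimizer,learning_rate,batch_size Training recipe; default to the
#'   genome attached to the architecture (Adam, 1e-4, 8 when none).
#' @param seed Seed controlling weight initialization, shuffling and dropout.
#' @param val_images,val_masks Optional validation split; when given, pixel
#'   accuracy at threshold 0.5 is recorded per epoch.
#' @param verbose Print per-epoch progress.
#' @return A list of class `unet_fit` with elements `network`, `history`
#'   (data.frame: epoch, loss, and val_accuracy when validated) and
#'   `diverged`.
#' @export
train_network <- function(arch, images, masks, epochs = 20L,
                          optimizer = NULL, learning_rate = NULL,
                          batch_size = NULL, seed = 1L,
                          val_images = NULL, val_masks = NULL,
                          verbose = FALSE) {
  stopifnot(length(images) == length(masks), length(images) > 0L)
  g <- NULL
  if (inherits(arch, "ga_genome")) {
    g <- arch
    arch <- decode_architecture(g, in_channels = n_channels_of(images[[1]]))
  } else if (inherits(arch, "unet_arch")) {
    g <- arch$genome
  }
  if (inherits(arch, "unet_network")) {
    net <- arch
    g <- net$arch$genome
  } else {
    net <- build_network(arch, seed = seed)
  }
  optimizer <- optimizer %||% (if (!is.null(g)) g$optimizer else "adam")
  learning_rate <- learning_rate %||%
    (if (!is.null(g)) g$learning_rate else 1e-4)
  batch_size <- as.integer(batch_size %||%
                             (if (!is.null(g)) g$batch_size else 8L))
  opt <- make_optimizer(optimizer, learning_rate)
  n <- length(images)
  images <- lapply(images, as_map)
  # shape check up front so failures precede any training work
  invisible(network_forward(net, images[[1]], train = FALSE))
  history <- vector("list", epochs)
  diverged <- FALSE
  with_local_seed(seed + 1L, {
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        batch <- idx[start:min(start + batch_size - 1L, n)]
        acc_grads <- NULL
        batch_loss <- 0
        for (i in batch) {
          fw <- network_forward(net, images[[i]], train = TRUE)
          net$state <- fw$state
          dl <- dice_loss_grad(fw$out, as_map(masks[[i]]))
          batch_loss <- batch_loss + dl$loss
          grads <- network_backward(net, fw$cache, dl$dprob)
          acc_grads <- if (is.null(acc_grads)) {
            grads
          } else {
            Map(`+`, acc_grads, grads)
          }
        }
        nb <- length(batch)
        acc_grads <- lapply(acc_grads, function(x) x / nb)
        batch_loss <- batch_loss / nb
        if (!is.finite(batch_loss)) {
          diverged <- TRUE
          break
        }
        net$params <- opt$step(net$params, acc_grads)
        losses <- c(losses, batch_loss)
      }
      rec <- data.frame(epoch = epoch,
                        loss = if (length(losses)) mean(losses) else NA_real_)
      if (!is.null(val_images)) {
        rec$val_accuracy <- if (diverged) {
          0
        } else {
          mean_pixel_accuracy(net, val_images, val_masks)
        }
      }
      history[[epoch]] <- rec
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f%s", epoch, epochs, rec$loss,
                        if (!is.null(rec$val_accuracy)) {
                          sprintf("  val acc %.4f", rec$val_accuracy)
                        } else ""))
      }
      if (diverged) break
    }
  })
  structure(list(network = net,
                 history = do.call(rbind, history[!vapply(history, is.null,
                                                          logical(1))]),
                 diverged = diverged),
            class = "unet_fit")
}

n_channels_of <- function(x) {
  if (length(dim(x)) == 3L) dim(x)[3] else 1L
}

# Mean pixel accuracy at threshold 0.5 over a set of images.
mean_pixel_accuracy <- function(net, images, masks, threshold = 0.5) {
  preds <- predict_network(net, images)
  mean(vapply(seq_along(preds), function(i) {
    pred <- (preds[[i]] >= threshold) * 1
    truth <- masks[[i]]
    dim(truth) <- dim(pred)
    mean(pred == truth)
  }, numeric(1)))
}

#' @export
print.unet_fit <- function(x, ...) {
  cat("trained network (", nrow(x$history), " epochs",
      if (x$diverged) ", DIVERGED" else "", ")\n", sep = "")
  if (nrow(x$history) > 0) {
    cat("final loss:", format(x$history$loss[nrow(x$history)]), "\n")
  }
  invisible(x)
}
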