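#' Configuration for the organ-phantom generator
#'
#' Describes a seeded synthetic dataset of binary "organ" phantoms: each
#' mask is a union of randomly placed filled ellipses (bright blobs standing
#' in for lungs, livers or nuclei), and each image renders the mask at a
#' foreground intensity over a background intensity plus Gaussian noise,
#' clipped to `[0, 1]`. Defaults produce 60 single-channel 64 x 64 images
#' with 1--3 blobs of 6--20 px semi-axes, intensities 0.8 over 0.2, and
#' noise sigma 0.05 -- small images so a full search runs quickly on one
#' CPU; the size is configurable up to real-data scale (must stay divisible
#' by 8, the deepest decodable pooling ladder).
#'
#' @param n_images Number of images.
#' @param image_size Square image side, divisible by 8.
#' @param channels 1 (grayscale) or 3 (RGB with shared structure).
#' @param blobs_per_image Length-2 integer range of ellipse counts.
#' @param blob_axis_range Length-2 range of ellipse semi-axes in pixels.
#' @param foreground_intensity,background_intensity Intensities in `[0, 1]`,
#'   distinct.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 60L, image_size = 64L,
                             channels = 1L, blobs_per_image = c(1L, 3L),
                             blob_axis_range = c(6, 20),
                             foreground_intensity = 0.8,
                             background_intensity = 0.2,
                             noise_sigma = 0.05, seed = 1L) {
  cfg <- structure(list(
    n_images = as.integer(n_images),
    image_size = as.integer(image_size),
    channels = as.integer(channels),
    blobs_per_image = as.integer(blobs_per_image),
    blob_axis_range = as.numeric(blob_axis_range),
    foreground_intensity = foreground_intensity,
    background_intensity = background_intensity,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  if (cfg$n_images < 1L) stop("n_images must be positive", call. = FALSE)
  if (cfg$image_size %% 8L != 0L) {
    stop("image_size must be divisible by 8", call. = FALSE)
  }
  if (!cfg$channels %in% c(1L, 3L)) {
    stop("channels must be 1 or 3", call. = FALSE)
  }
  if (cfg$foreground_intensity == cfg$background_intensity) {
    stop("foreground and background intensities must differ", call. = FALSE)
  }
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (any(cfg$blob_axis_range <= 0) ||
      cfg$blob_axis_range[2] < cfg$blob_axis_range[1]) {
    stop("blob_axis_range must be a positive ordered range", call. = FALSE)
  }
  cfg
}

ellipse_mask <- function(size, cx, cy, a, b, theta) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  dx <- xs - cx
  dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a seeded phantom dataset
#'
#' @param config A [synthetic_config()].
#' @return A list of class `phantom_dataset` with `images` (list of `[H, W]`
#'   or `[H, W, 3]` arrays in `[0, 1]`), `masks` (list of binary `[H, W]`
#'   matrices) and the `config`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_images = 4, seed = 7))
#' range(ds$masks[[1]])
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  s <- config$image_size
  with_local_seed(config$seed, {
    masks <- vector("list", config$n_images)
    images <- vector("list", config$n_images)
    for (i in seq_len(config$n_images)) {
      n_blobs <- sample(config$blobs_per_image[1]:config$blobs_per_image[2],
                        1L)
      mask <- matrix(FALSE, s, s)
      for (j in seq_len(n_blobs)) {
        a <- stats::runif(1, config$blob_axis_range[1],
                          config$blob_axis_range[2])
        b <- stats::runif(1, config$blob_axis_range[1],
                          config$blob_axis_range[2])
        margin <- max(a, b)
        lo <- min(1 + margin / 2, (s + 1) / 2)
        hi <- max(s - margin / 2, (s + 1) / 2)
        cx <- stats::runif(1, lo, hi)
        cy <- stats::runif(1, lo, hi)
        theta <- stats::runif(1, 0, pi)
        mask <- mask | ellipse_mask(s, cx, cy, a, b, theta)
      }
      mask <- mask * 1
      base <- ifelse(mask == 1, config$foreground_intensity,
                     config$background_intensity)
      if (config$channels == 1L) {
        img <- base + stats::rnorm(s * s, 0, config$noise_sigma)
        img <- matrix(pmin(pmax(img, 0), 1), s, s)
      } else {
        img <- array(rep(base, config$channels) +
                       stats::rnorm(s * s * config$channels, 0,
                                    config$noise_sigma),
                     c(s, s, config$channels))
        img <- pmin(pmax(img, 0), 1)
      }
      masks[[i]] <- mask
      images[[i]] <- img
    }
    structure(list(images = images, masks = masks, config = config),
              class = "phantom_dataset")
  })
}

#' Train / validation / test split
#'
#' Shuffles `n` indices with the given seed and assigns 20% (floored) to the
#' test set, then 10% of the remaining training portion (floored, at least
#' one image) to validation, and the rest to training.
#'
#' @param n Total number of images (at least 10).
#' @param seed Integer shuffle seed.
#' @return A list of class `dataset_split` with disjoint integer vectors
#'   `train`, `validation`, `test` covering `1:n`.
#' @export
#' @examples
#' lengths(split_dataset(100, seed = 1))  # train 72, validation 8, test 20
split_dataset <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (n < 10L) stop("need at least 10 images to split", call. = FALSE)
  n_test <- floor(0.2 * n)
  n_val <- max(1L, floor(0.1 * (n - n_test)))
  with_local_seed(seed, {
    idx <- sample.int(n)
    structure(list(
      train = sort(idx[(n_test + n_val + 1L):n]),
      validation = sort(idx[(n_test + 1L):(n_test + n_val)]),
      test = sort(idx[seq_len(n_test)])
    ), class = "dataset_split")
  })
}

#' Write / read a phantom dataset as PNG directories
#'
#' Writes `images/*.png` and `masks/*.png` (masks stored as 0/255) with
#' matching file stems, plus `split.json` when a split is given. Reading
#' restores images in `[0, 1]` (8-bit quantized) and binary 0/1 masks, and
#' errors when image and mask stems do not match.
#'
#' @param dataset A `phantom_dataset` (or a list with `images` and `masks`).
#' @param dir Dataset directory.
#' @param split Optional `dataset_split` stored alongside.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a list with `images`, `masks` and `split` (NULL when absent).
#' @export
write_dataset <- function(dataset, dir, split = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  n <- length(dataset$images)
  stems <- sprintf("img_%03d", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(dataset$images[[i]],
                  file.path(dir, "images", paste0(stems[i], ".png")))
    png::writePNG(dataset$masks[[i]],
                  file.path(dir, "masks", paste0(stems[i], ".png")))
  }
  if (!is.null(split)) {
    jsonlite::write_json(unclass(split), file.path(dir, "split.json"))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  img_dir <- file.path(dir, "images")
  mask_dir <- file.path(dir, "masks")
  if (!dir.exists(img_dir) || !dir.exists(mask_dir)) {
    stop("dataset directory must contain images/ and masks/: ", dir,
         call. = FALSE)
  }
  img_files <- sort(list.files(img_dir, pattern = "\\.png$"))
  mask_files <- sort(list.files(mask_dir, pattern = "\\.png$"))
  if (length(img_files) == 0L) {
    stop("no PNG images found under ", img_dir, call. = FALSE)
  }
  stems_i <- sub("\\.png$", "", img_files)
  stems_m <- sub("\\.png$", "", mask_files)
  missing <- c(setdiff(stems_i, stems_m), setdiff(stems_m, stems_i))
  if (length(missing) > 0L) {
    stop("image/mask stem mismatch, missing: ",
         paste(sort(unique(missing)), collapse = ", "), call. = FALSE)
  }
  images <- lapply(img_files, function(f) {
    png::readPNG(file.path(img_dir, f))
  })
  masks <- lapply(mask_files, function(f) {
    m <- png::readPNG(file.path(mask_dir, f))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    (m > 0.5) * 1
  })
  split_file <- file.path(dir, "split.json")
  split <- NULL
  if (file.exists(split_file)) {
    split <- structure(lapply(jsonlite::read_json(split_file,
                                                  simplifyVector = TRUE),
                              as.integer),
                       class = "dataset_split")
  }
  list(images = images, masks = masks, split = split)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "phantom dataset: %d images, %dx%d, %d channel(s), noise sigma %g\n",
    cfg$n_images, cfg$image_size, cfg$image_size, cfg$channels,
    cfg$noise_sigma))
  cat(sprintf("mean foreground fraction: %.3f\n",
              mean(vapply(x$masks, mean, numeric(1)))))
  invisible(x)
}
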