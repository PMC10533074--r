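# Shared fixtures built in code.

# 4x4 toy masks: truth has 4 foreground pixels, prediction has 4, 3 shared.
# Hand count: tp = 3, fp = 1, fn = 1, tn = 11.
toy_truth <- function() {
  matrix(c(1, 1, 0, 0,
           1, 1, 0, 0,
           0, 0, 0, 0,
           0, 0, 0, 0), 4, 4, byrow = TRUE)
}

toy_pred <- function() {
  matrix(c(1, 1, 0, 0,
           1, 0, 0, 0,
           0, 1, 0, 0,
           0, 0, 0, 0), 4, 4, byrow = TRUE)
}

# Small noiseless phantom set for fast learnability checks.
tiny_dataset <- function(n = 12, size = 16, seed = 99) {
  generate_dataset(synthetic_config(
    n_images = n, image_size = size, blobs_per_image = c(1, 2),
    blob_axis_range = c(3, 6), foreground_intensity = 1,
    background_intensity = 0, noise_sigma = 0, seed = seed))
}

random_binary_mask <- function(n = 16, p = 0.4) {
  matrix((stats::runif(n * n) < p) * 1, n, n)
}

# The published genomes, constructed in code (independent of the JSON
# fixtures, so the two can cross-check each other).
lung_genome <- function() {
  genome(5, 8, 5, activation = 2, pooling = 1, batch_norm = 0, dropout = 0,
         optimizer = 3, learning_rate = 1e-4, batch_size = 8)
}

dsb_genome <- function() {
  genome(5, 8, 7, activation = 1, pooling = 1, batch_norm = 1, dropout = 0,
         optimizer = 4, learning_rate = 5e-4, batch_size = 16)
}

liver_genome <- function() {
  genome(7, 8, 4, activation = 1, pooling = 1, batch_norm = 1, dropout = 0,
         optimizer = 3, learning_rate = 1e-4, batch_size = 4)
}
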