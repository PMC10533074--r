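# Run code under a temporary RNG seed, restoring the caller's stream so that
# nested seeded work (e.g. per-candidate training inside a GA generation)
# does not perturb outer-level reproducibility.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647))
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
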