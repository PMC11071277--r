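# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a local RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Signed integer frequency indices of an n-point DFT (0, 1, ..., -1), i.e.
# cycles per box edge along that axis.
fft_freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

stop_dims <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("volume dimensions do not match")
}
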