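# Internal helpers shared across the package.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministically derive a sub-seed from a base seed and up to two stream
# indices; kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, i = 0L, j = 0L) {
  s <- (as.double(seed) * 7919 + as.double(i) * 104729 + as.double(j) * 13007) %% 2147483587
  as.integer(s) + 1L
}

# Linear index into a 3D array for an n x 3 matrix of 1-based voxel indices.
linear_index <- function(coords, shape) {
  coords[, 1L] + (coords[, 2L] - 1L) * shape[1L] +
    (coords[, 3L] - 1L) * shape[1L] * shape[2L]
}

stop_if_not_volume <- function(v, what = "volume") {
  if (!is.array(v) || length(dim(v)) != 3L || !is.numeric(v))
    stop(sprintf("%s must be a 3D numeric array", what), call. = FALSE)
  if (!all(is.finite(v)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(v)
}
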