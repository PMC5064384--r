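# Internal helpers shared across modules.

# Deterministically derive a child seed from a master seed and one or more
# integer stream identifiers. Kept below 2^31 - 1 so it is a valid R seed.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  x <- as.double(seed) %% 2147483647
  for (id in ids) {
    x <- (x * 48271 + as.double(id) * 7919 + 1) %% 2147483647
  }
  as.integer(x)
}

# Stack a named list of equal-shape 3-D arrays along a new 4th dimension.
stack4d <- function(volumes) {
  d <- dim(volumes[[1]])
  array(unlist(volumes, use.names = FALSE), dim = c(d, length(volumes)))
}

# Matrix view of a 4-D array: rows = voxels, columns = 4th dimension.
flatten4d <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
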