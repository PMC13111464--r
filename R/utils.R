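# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All randomized operations in the package go
# through this so a single integer seed fixes their output bit-exactly.
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed, staying inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

# Squared Euclidean distances from one point (length-3) to all rows of `m`.
sqdist_to <- function(p, m) {
  dx <- m[, 1L] - p[1L]; dy <- m[, 2L] - p[2L]; dz <- m[, 3L] - p[3L]
  dx * dx + dy * dy + dz * dz
}

cloud_diameter <- function(coords) {
  # Diagonal of the axis-aligned bounding box: cheap upper bound on the true
  # diameter, sufficient wherever a length scale is needed.
  if (nrow(coords) == 0L) return(0)
  rng <- apply(coords, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}
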