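# Small vector-geometry helpers shared by scoring, mining and fixtures.
# All angles in degrees, all distances in Angstroms.

vec_norm <- function(v) sqrt(sum(v * v))

# Angle at the middle point b of the a-b-c triple, degrees in [0, 180].
point_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

# Rotation matrix for angle `deg` (degrees) about unit axis `axis`
# (Rodrigues' formula).
rotation_matrix <- function(axis, deg) {
  axis <- axis / vec_norm(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's
# RNG state afterwards (so seeded utilities don't perturb user code).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniformly random unit 3-vector.
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vec_norm(v)
    if (n > 1e-12) return(v / n)
  }
}
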