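# Internal geometry/numeric helpers shared across modules.

euclid <- function(p, q) sqrt((p$x - q$x)^2 + (p$y - q$y)^2)

# TRUE when all points lie on one line (or a single point). Uses the ratio of
# singular values of the centered coordinates, so it is scale invariant.
points_collinear <- function(mat, tol = 1e-10) {
  if (nrow(mat) < 3L) return(TRUE)
  cm <- sweep(mat, 2L, colMeans(mat))
  d <- svd(cm, nu = 0L, nv = 0L)$d
  d[1] == 0 || d[2] / d[1] < tol
}

# Fold an angle in degrees into (-90, 90] (undirected axis angle).
fold_axis_angle <- function(deg) {
  a <- deg %% 180
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  a
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

# Deterministic per-image substream seed: adding images never changes the
# draws of earlier ones. Kept strictly below 2^31 - 1.
substream_seed <- function(master_seed, index) {
  m <- 2147483587
  s <- (as.double(master_seed) %% m) * 48271 + as.double(index) * 16807 + 11
  as.integer(s %% m)
}
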