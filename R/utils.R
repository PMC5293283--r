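# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Coordinates come in two layouts: an n x 3 matrix (one structure / one frame)
# or a length-3N vector (bio3d xyz convention). Normalise to n x 3.
as_coord_matrix <- function(x) {
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  if (is.numeric(x) && length(x) %% 3L == 0L)
    return(matrix(x, ncol = 3L, byrow = TRUE))
  stop("coordinates must be an n x 3 matrix or a length-3N numeric vector")
}

# Back to the flat bio3d layout (x1,y1,z1,x2,...).
as_xyz_vector <- function(m) as.numeric(t(as_coord_matrix(m)))

# Column indices into a flat 3N xyz layout for atom indices `idx`.
xyz_columns <- function(idx) {
  idx <- as.integer(idx)
  as.integer(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
}

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fd <- function(...) stop(sprintf(...), call. = FALSE)
warn_fd <- function(...) warning(sprintf(...), call. = FALSE)
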