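# Internal helpers shared across modules.

vnorm <- function(x) sqrt(sum(x * x))

row_norms <- function(m) sqrt(rowSums(m * m))

unit <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector", call. = FALSE)
  x / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
    return(p)
  }
  if (length(p) != 3L) stop("a point must have 3 coordinates", call. = FALSE)
  matrix(p, nrow = 1L)
}

# Run code with a temporary RNG state; restores (or removes) .Random.seed after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive reproducible child seeds from a parent seed (kept within 32-bit range).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
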