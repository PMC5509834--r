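#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded helpers do not perturb outer simulations.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

#' Derive a table of independent substream seeds from one master seed
#'
#' @param master integer master seed.
#' @param n number of seeds to draw.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @keywords internal
spawn_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Pairwise Euclidean cross-distances between rows of A (n x d) and B (m x d).
cross_dist <- function(A, B) {
  A <- as_point_matrix(A)
  B <- as_point_matrix(B)
  if (ncol(A) != ncol(B))
    stop("point sets have mismatched dimensionality: ", ncol(A), " vs ", ncol(B))
  s <- outer(rowSums(A^2), rowSums(B^2), `+`)
  d2 <- s - 2 * tcrossprod(A, B)
  # coincident points must give an exact zero (kernels with a cusp at the
  # origin are sensitive to the O(eps * |x|^2) noise of this expansion)
  d2[d2 < 1e-13 * s] <- 0
  sqrt(pmax(d2, 0))
}

# Coerce a vector or matrix to an n x d numeric matrix (a bare numeric
# vector is taken as a single point).
as_point_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  matrix(as.numeric(x), nrow = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
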