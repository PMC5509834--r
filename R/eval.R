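#' Structural similarity (SSIM) index between two 2D fields
#'
#' Classic single-scale SSIM: an 11 x 11 Gaussian window (sigma = 1.5),
#' stability constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L` the
#' dynamic range of the reference field, local statistics by valid
#' (interior-only) convolution, and the mean of the resulting SSIM map
#' returned. Values lie in `[-1, 1]`; 1 means identical fields.
#'
#' @param est_grid estimated field as a 2D numeric matrix.
#' @param truth_grid reference field, same shape; its range sets `L`.
#' @return Mean SSIM (scalar).
#' @export
ssim_index <- function(est_grid, truth_grid) {
  est_grid <- as.matrix(est_grid)
  truth_grid <- as.matrix(truth_grid)
  if (!all(dim(est_grid) == dim(truth_grid)))
    stop("fields must have the same shape")
  win <- 11L
  if (any(dim(est_grid) < win))
    stop("fields smaller than the ", win, "x", win, " SSIM window")
  L <- diff(range(truth_grid))
  if (L == 0) {
    if (isTRUE(all.equal(est_grid, truth_grid, tolerance = 1e-12))) return(1)
    stop("reference field has zero dynamic range")
  }
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  g <- gauss_win(win, 1.5)
  mu_x <- filter2_valid(est_grid, g)
  mu_y <- filter2_valid(truth_grid, g)
  xx <- filter2_valid(est_grid^2, g) - mu_x^2
  yy <- filter2_valid(truth_grid^2, g) - mu_y^2
  xy <- filter2_valid(est_grid * truth_grid, g) - mu_x * mu_y
  ssim_map <- ((2 * mu_x * mu_y + C1) * (2 * xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (xx + yy + C2))
  mean(ssim_map)
}

# Normalized 1D Gaussian window of odd length n.
gauss_win <- function(n, sigma) {
  x <- seq_len(n) - (n + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable weighted local mean with a 1D window `g` applied along rows
# then columns, valid region only.
filter2_valid <- function(M, g) {
  n <- length(g)
  nr <- nrow(M); nc <- ncol(M)
  # along columns (vertical): result (nr - n + 1) x nc
  A <- matrix(0, nr - n + 1, nc)
  for (i in seq_len(n)) A <- A + g[i] * M[i:(nr - n + i), , drop = FALSE]
  # along rows (horizontal): result (nr - n + 1) x (nc - n + 1)
  B <- matrix(0, nrow(A), nc - n + 1)
  for (i in seq_len(n)) B <- B + g[i] * A[, i:(nc - n + i), drop = FALSE]
  B
}

#' Mean L1 error between two value vectors
#'
#' The per-vertex mean absolute difference between an estimated and a
#' ground-truth field; the regression-error measure for mapping runs.
#'
#' @param est,truth equal-length numeric vectors.
#' @return Scalar mean absolute error.
#' @export
mean_l1_error <- function(est, truth) {
  if (length(est) != length(truth)) stop("vectors differ in length")
  mean(abs(est - truth))
}
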