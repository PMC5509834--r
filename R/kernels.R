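#' Kernel specification for the Gaussian-process surrogate
#'
#' Bundles a covariance-function family with its hyperparameters and the
#' observation-noise variance. The planner, the particle filter and the
#' kernel-prior learner all share this representation; the fitted prior
#' hyperparameter (often written theta0) is simply a `kernel_spec`.
#'
#' Supported families:
#' \describe{
#'   \item{`matern`}{Matern covariance; `nu` (smoothness) must be one of
#'     1/2, 3/2, 5/2 (closed forms). Default 5/2: twice-differentiable
#'     sample paths matching smooth voltage fields.}
#'   \item{`squared_exponential`}{`sf2 * exp(-r^2 / (2 l^2))`.}
#'   \item{`rational_quadratic`}{`sf2 * (1 + r^2/(2 alpha l^2))^(-alpha)`,
#'     a scale mixture of squared exponentials; `alpha` is the mixture
#'     parameter.}
#'   \item{`linear`}{`sf2 * (x . x' + bias)`; non-stationary, no length
#'     scale (the `length_scale` slot is ignored). `bias >= 0` allows
#'     affine trends under a zero-mean prior.}
#' }
#'
#' @param family kernel family, one of `"matern"`, `"squared_exponential"`,
#'   `"rational_quadratic"`, `"linear"`.
#' @param length_scale positive length scale `l`, in coordinate units.
#' @param sf2 positive signal variance (value units squared).
#' @param sigma2 non-negative observation-noise variance.
#' @param nu Matern smoothness; one of 1/2, 3/2, 5/2.
#' @param alpha rational-quadratic mixture parameter (positive).
#' @param bias linear-kernel offset (non-negative).
#' @return An object of class `kernel_spec`.
#' @examples
#' ks <- kernel_spec("matern", length_scale = 1, sf2 = 1, sigma2 = 0.01)
#' kernel_eval(ks, c(0, 0), c(1, 0))
#' @export
kernel_spec <- function(family = c("matern", "squared_exponential",
                                   "rational_quadratic", "linear"),
                        length_scale = 1, sf2 = 1, sigma2 = 0,
                        nu = 5 / 2, alpha = 1, bias = 0) {
  family <- match.arg(family)
  spec <- structure(
    list(family = family, length_scale = as.numeric(length_scale),
         sf2 = as.numeric(sf2), sigma2 = as.numeric(sigma2),
         nu = as.numeric(nu), alpha = as.numeric(alpha),
         bias = as.numeric(bias)),
    class = "kernel_spec")
  validate_kernel_spec(spec)
  spec
}

validate_kernel_spec <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.finite(spec$sf2) || spec$sf2 <= 0)
    stop("signal variance sf2 must be strictly positive")
  if (!is.finite(spec$sigma2) || spec$sigma2 < 0)
    stop("noise variance sigma2 must be non-negative")
  if (spec$family != "linear" &&
      (!is.finite(spec$length_scale) || spec$length_scale <= 0))
    stop("length_scale must be strictly positive")
  if (spec$family == "matern" && !spec$nu %in% c(1 / 2, 3 / 2, 5 / 2))
    stop("matern smoothness nu must be one of 1/2, 3/2, 5/2")
  if (spec$family == "rational_quadratic" &&
      (!is.finite(spec$alpha) || spec$alpha <= 0))
    stop("rational-quadratic alpha must be strictly positive")
  if (spec$family == "linear" && (!is.finite(spec$bias) || spec$bias < 0))
    stop("linear-kernel bias must be non-negative")
  invisible(spec)
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$family,
    matern = sprintf(", nu = %g", x$nu),
    rational_quadratic = sprintf(", alpha = %g", x$alpha),
    linear = sprintf(", bias = %g", x$bias),
    "")
  cat(sprintf("<kernel_spec> %s (l = %g, sf2 = %g, sigma2 = %g%s)\n",
              x$family, x$length_scale, x$sf2, x$sigma2, extra))
  invisible(x)
}

# Stationary kernel value as a function of Euclidean distance r (vectorized;
# r may be a matrix). Only meaningful for stationary families.
kernel_from_dist <- function(spec, r) {
  l <- spec$length_scale
  sf2 <- spec$sf2
  switch(spec$family,
    squared_exponential = sf2 * exp(-r^2 / (2 * l^2)),
    rational_quadratic = sf2 * (1 + r^2 / (2 * spec$alpha * l^2))^(-spec$alpha),
    matern = {
      if (spec$nu == 1 / 2) {
        sf2 * exp(-r / l)
      } else if (spec$nu == 3 / 2) {
        a <- sqrt(3) * r / l
        sf2 * (1 + a) * exp(-a)
      } else {
        a <- sqrt(5) * r / l
        sf2 * (1 + a + a^2 / 3) * exp(-a)
      }
    },
    stop("kernel family '", spec$family, "' is not stationary"))
}

is_stationary <- function(spec) spec$family != "linear"

#' Evaluate the covariance function between two point sets
#'
#' @param spec a [kernel_spec()].
#' @param A_pts n x d matrix of points (a bare vector is one point).
#' @param B_pts m x d matrix of points; defaults to `A_pts`.
#' @return The n x m covariance matrix `K(A_pts, B_pts)`; symmetric
#'   positive semi-definite when `B_pts` is `A_pts`. The noise variance is
#'   \emph{not} added here.
#' @export
kernel_eval <- function(spec, A_pts, B_pts = A_pts) {
  validate_kernel_spec(spec)
  A_pts <- as_point_matrix(A_pts)
  B_pts <- as_point_matrix(B_pts)
  if (ncol(A_pts) != ncol(B_pts))
    stop("point sets have mismatched dimensionality")
  if (spec$family == "linear")
    return(spec$sf2 * (tcrossprod(A_pts, B_pts) + spec$bias))
  kernel_from_dist(spec, cross_dist(A_pts, B_pts))
}

# Prior (marginal) variance k(x, x) per point, without noise.
kernel_diag <- function(spec, pts) {
  pts <- as_point_matrix(pts)
  if (spec$family == "linear")
    return(spec$sf2 * (rowSums(pts^2) + spec$bias))
  rep(spec$sf2, nrow(pts))
}
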