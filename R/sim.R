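#' Random 2D Gaussian-mixture ground-truth specification
#'
#' Draws `k` isotropic Gaussian bumps: means uniform on `[0, extent]^2`,
#' variances log-uniform on `[(extent/20)^2, (extent/4)^2]` (bump widths
#' from fine, grid-scale structure to quadrant-scale lobes), amplitudes
#' uniform on `[0.5, 1.5]`. Small `k` gives simple near-unimodal fields;
#' large `k` gives complex fields — a stand-in for voltage maps of varying
#' complexity.
#'
#' @param k number of mixture components (>= 1).
#' @param extent side of the square domain.
#' @param seed integer seed.
#' @return An object of class `mixture_spec` with `means` (k x 2),
#'   `variances` (k), `amplitudes` (k), `extent`.
#' @export
sample_mixtures <- function(k, extent = 10, seed = NULL) {
  stopifnot(k >= 1, extent > 0)
  with_seed(seed, {
    means <- cbind(stats::runif(k, 0, extent), stats::runif(k, 0, extent))
    lv <- stats::runif(k, log((extent / 20)^2), log((extent / 4)^2))
    amps <- stats::runif(k, 0.5, 1.5)
    structure(list(means = means, variances = exp(lv), amplitudes = amps,
                   extent = extent, k = k),
              class = "mixture_spec")
  })
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> k = %d on [0, %g]^2\n", x$k, x$extent))
  invisible(x)
}

#' Evaluate a Gaussian-mixture field
#'
#' `value(x) = sum_j amp_j * exp(-|x - mu_j|^2 / (2 var_j))` (unnormalized
#' bumps, so the value at a component mean is its amplitude).
#'
#' @param spec a `mixture_spec` from [sample_mixtures()].
#' @param domain a 2D [sample_domain] or an n x 2 matrix of points.
#' @return Numeric value per point.
#' @export
mixture_field <- function(spec, domain) {
  pts <- if (inherits(domain, "sample_domain")) domain$points else as_point_matrix(domain)
  if (ncol(pts) != 2) stop("mixture fields are defined on 2D domains")
  D2 <- cross_dist(pts, spec$means)^2
  as.numeric(exp(-sweep(D2, 2, 2 * spec$variances, `/`)) %*% spec$amplitudes)
}

#' Sample a field from a GP prior over a domain
#'
#' One draw from `N(0, K(V, V))` by dense Cholesky (with jitter); a
#' generative fixture for recovery and learning-curve experiments.
#'
#' @param domain a [sample_domain] with at most 5000 points.
#' @param spec a [kernel_spec()] (noise variance not added).
#' @param seed integer seed.
#' @return Numeric field over the domain points.
#' @export
sample_gp_field <- function(domain, spec, seed = NULL) {
  pts <- domain$points
  if (nrow(pts) > 5000) stop("domain too large for a dense GP draw (N > 5000)")
  K <- kernel_eval(spec, pts, pts)
  R <- chol_jitter(K, start = 1e-10, max_jitter = 1e-6)
  with_seed(seed, as.numeric(crossprod(R, stats::rnorm(nrow(pts)))))
}
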