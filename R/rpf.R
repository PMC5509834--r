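#' Regularized particle filter over GP kernel hyperparameters
#'
#' The implicit-exploration planner treats the kernel hyperparameter as a
#' random variable with distribution `p(theta_A)`, updated after each new
#' observation by a regularized particle filter: importance weighting by
#' the one-step GP predictive density, systematic resampling, and an
#' Epanechnikov-kernel resample-move step that jitters each particle
#' (avoiding sample impoverishment). Particles live in the log domain of
#' `(length_scale, sf2)`; the noise variance and Matern smoothness stay
#' fixed at the prior's values.
#'
#' @name rpf
NULL

new_particle_set <- function(theta, weights, base_spec) {
  stopifnot(is.matrix(theta), ncol(theta) == 2, nrow(theta) >= 2,
            length(weights) == nrow(theta), all(weights >= 0))
  weights <- weights / sum(weights)
  structure(list(theta = theta,            # m x 2, columns log_l, log_sf2
                 weights = weights,
                 base_spec = base_spec),   # carries family, sigma2, nu
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  m <- particle_mean(x)
  cat(sprintf("<particle_set> %d particles, ESS %.1f; mean l = %.3g, sf2 = %.3g\n",
              nrow(x$theta), effective_sample_size(x),
              m$length_scale, m$sf2))
  invisible(x)
}

# kernel_spec for particle i (or for explicit log-theta values).
particle_spec <- function(ps, i = NULL, log_theta = NULL) {
  lt <- if (is.null(log_theta)) ps$theta[i, ] else log_theta
  sp <- ps$base_spec
  sp$length_scale <- exp(lt[1])
  sp$sf2 <- exp(lt[2])
  sp
}

#' Weighted mean hyperparameter of a particle set
#'
#' The weighted mean is taken in the log domain (a weighted geometric mean
#' in linear units), matching the particles' support.
#'
#' @param ps a `particle_set`.
#' @return A [kernel_spec()] at the weighted mean hyperparameter.
#' @export
particle_mean <- function(ps) {
  lt <- colSums(ps$theta * ps$weights)
  particle_spec(ps, log_theta = lt)
}

#' Initialize the particle set around the prior hyperparameter
#'
#' Particles are drawn uniformly in the log domain on
#' `[theta0/(1+spread), theta0*(1+spread)]` per component, with equal
#' weights `1/m`; the support is symmetric about `log(theta0)`, so the
#' prior expectation equals theta0 (a discrete uniform centred on the
#' learned prior).
#'
#' @param theta0 prior [kernel_spec()] (the learned hyperparameter).
#' @param m number of particles (>= 2); 100 by default.
#' @param spread half-width of the uniform support as a relative factor
#'   (0.5 = +/-50% in log domain).
#' @param seed integer seed.
#' @return A `particle_set`.
#' @export
init_particles <- function(theta0, m = 100, spread = 0.5, seed = NULL) {
  validate_kernel_spec(theta0)
  stopifnot(m >= 2, spread > 0)
  ctr <- c(log(theta0$length_scale), log(theta0$sf2))
  hw <- log(1 + spread)
  theta <- with_seed(seed, {
    cbind(stats::runif(m, ctr[1] - hw, ctr[1] + hw),
          stats::runif(m, ctr[2] - hw, ctr[2] + hw))
  })
  new_particle_set(theta, rep(1 / m, m), theta0)
}

#' Importance-weight update on a new observation
#'
#' Multiplies each particle's weight by the one-step GP predictive density
#' of the new value at the new point given the previous observations under
#' that particle's hyperparameters, then renormalizes. If every particle's
#' likelihood underflows, weights are reset to uniform with a warning.
#'
#' @param ps a `particle_set`.
#' @param obs_before [obs_set()] of observations prior to the new one
#'   (values centred as used throughout the run).
#' @param new_point position of the new observation (d-vector).
#' @param new_value its (centred) measured value.
#' @return The updated `particle_set`.
#' @export
update_weights <- function(ps, obs_before, new_point, new_value) {
  m <- nrow(ps$theta)
  ll <- vapply(seq_len(m), function(i) {
    gp_predictive_logdens(particle_spec(ps, i), obs_before,
                          new_point, new_value)
  }, numeric(1))
  lw <- log(ps$weights) + ll
  lw <- lw - max(lw)
  w <- exp(lw)
  if (!any(is.finite(w)) || sum(w) == 0) {
    warning("all particle likelihoods underflowed; resetting to uniform weights")
    w <- rep(1, m)
  }
  new_particle_set(ps$theta, w / sum(w), ps$base_spec)
}

# Systematic resampling: indices drawn with one uniform offset.
systematic_resample <- function(weights, m = length(weights)) {
  u <- (stats::runif(1) + 0:(m - 1)) / m
  findInterval(u, cumsum(weights) / sum(weights)) + 1L
}

# Draw n samples from the 2D Epanechnikov kernel density (support the unit
# disc, density proportional to 1 - |x|^2): uniform direction, radius by
# inverse CDF r^2 = 1 - sqrt(1 - u).
repanechnikov2 <- function(n) {
  ang <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - sqrt(1 - stats::runif(n)))
  cbind(r * cos(ang), r * sin(ang))
}

#' Resample-move step (Epanechnikov regularization)
#'
#' Systematic resampling proportional to the weights, followed by a move:
#' each particle is jittered by a draw from the Epanechnikov kernel scaled
#' by the optimal bandwidth `h = A_K * m^(-1/(d+4))` (with
#' `A_K = (8 (d+4) (2 sqrt(pi))^d / c_d)^(1/(d+4))`, `c_d` the unit-ball
#' volume, d = 2) and the Cholesky factor of the weighted empirical
#' particle covariance — equivalent to resampling from a kernel-smoothed
#' continuous approximation of the posterior. Output weights are uniform.
#'
#' @param ps a `particle_set`.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   consumed).
#' @param bandwidth_scale multiplier on the optimal bandwidth (default 1).
#' @return The regularized `particle_set` with uniform weights.
#' @export
resample_move <- function(ps, seed = NULL, bandwidth_scale = 1) {
  run <- function() {
    m <- nrow(ps$theta)
    d <- 2
    idx <- systematic_resample(ps$weights, m)
    th <- ps$theta[idx, , drop = FALSE]
    mu <- colSums(ps$theta * ps$weights)
    ctrd <- sweep(ps$theta, 2, mu)
    S <- crossprod(ctrd * sqrt(ps$weights))     # weighted covariance
    cd <- pi                                    # unit-ball volume, d = 2
    A_K <- (8 / cd * (d + 4) * (2 * sqrt(pi))^d)^(1 / (d + 4))
    h <- bandwidth_scale * A_K * m^(-1 / (d + 4))
    eps <- repanechnikov2(m)
    D <- tryCatch(chol(S + diag(1e-12, d)), error = function(e) NULL)
    if (!is.null(D)) th <- th + h * eps %*% D   # D upper: x %*% D ~ cov h^2 S
    new_particle_set(th, rep(1 / m, m), ps$base_spec)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Effective sample size of a particle set
#'
#' `1 / sum(w_i^2)`, in `[1, m]`; a degeneracy diagnostic (resample-move
#' runs every update regardless, so this is logged, not acted on).
#'
#' @param ps a `particle_set`.
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(ps) 1 / sum(ps$weights^2)

#' Write particle snapshot to CSV
#'
#' @param ps a `particle_set`.
#' @param path output CSV path (`particle_id,log_l,log_sf2,weight`).
#' @export
write_particles_csv <- function(ps, path) {
  df <- data.frame(particle_id = seq_len(nrow(ps$theta)),
                   log_l = ps$theta[, 1], log_sf2 = ps$theta[, 2],
                   weight = ps$weights)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
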