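#' Observation sets
#'
#' An observation set pairs mapped positions with measured values: the set
#' `A` of (position, voltage) pairs accumulated during mapping, or a
#' demonstration case used for kernel learning.
#'
#' @param X n x d numeric matrix of positions (d = 2 or 3), or NULL/0-row
#'   for an empty set.
#' @param y numeric vector of n measured values.
#' @param case_id optional identifier carried through concatenation.
#' @return An object of class `obs_set` with elements `X`, `y`, `case_id`.
#' @examples
#' obs <- obs_set(matrix(runif(6), 3, 2), rnorm(3))
#' n_obs(obs)
#' @export
obs_set <- function(X = NULL, y = numeric(0), case_id = NULL) {
  if (is.null(X)) X <- matrix(numeric(0), nrow = 0, ncol = 2)
  X <- as_point_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("X has ", nrow(X), " rows but y has ", length(y), " values")
  structure(list(X = X, y = y, case_id = case_id), class = "obs_set")
}

#' @rdname obs_set
#' @param obs an `obs_set`.
#' @export
n_obs <- function(obs) nrow(obs$X)

#' @export
print.obs_set <- function(x, ...) {
  cat(sprintf("<obs_set> %d points in %dD%s\n", n_obs(x), ncol(x$X),
              if (is.null(x$case_id)) "" else paste0(" (case ", x$case_id, ")")))
  invisible(x)
}

# Cholesky factorization with adaptive jitter.  Returns the upper factor R
# such that t(R) %*% R = M + jitter*I.  Jitter starts at `start` and grows
# tenfold up to `max_jitter`; failure past that signals ill-conditioning.
chol_jitter <- function(M, start = 1e-10, max_jitter = 1e-4) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(R)) return(R)
  jit <- start * max(1, mean(diag(M)))
  cap <- max_jitter * max(1, mean(diag(M)))
  while (jit <= cap) {
    R <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- jit * 10
  }
  stop("Gram matrix is numerically singular even after jitter ",
       "(possible duplicate points with sigma2 = 0); condition estimate: ",
       format(kappa(M), digits = 3))
}

#' Gaussian-process posterior at query points
#'
#' Computes the zero-mean GP posterior conditioned on the observation set:
#' `mu* = K(X*,X) [K(X,X) + sigma2 I]^-1 y` and
#' `Sigma* = K(X*,X*) - K(X*,X) [K(X,X) + sigma2 I]^-1 K(X,X*)`.
#' Values are assumed centred by the caller (the planner centres by the
#' running observation mean). Linear systems are solved by Cholesky with
#' adaptive jitter, never by explicit inversion.
#'
#' @param spec a [kernel_spec()] (its `sigma2` is the noise variance added
#'   to the training Gram matrix).
#' @param obs an [obs_set()]; may be empty, in which case the prior is
#'   returned (`mu* = 0`, `Sigma* = K(X*,X*)`).
#' @param query_pts q x d matrix of query points.
#' @param diag_only if TRUE, skip the full covariance and return only the
#'   posterior variance vector (the planner's fast path).
#' @return A list of class `gp_posterior` with `mean` (q-vector), `cov`
#'   (q x q matrix, or NULL when `diag_only`), and `var` (q-vector of
#'   posterior variances, clamped at 0).
#' @export
gp_posterior <- function(spec, obs, query_pts, diag_only = FALSE) {
  validate_kernel_spec(spec)
  query_pts <- as_point_matrix(query_pts)
  q <- nrow(query_pts)
  if (q < 1) stop("query_pts must be non-empty")
  if (n_obs(obs) == 0) {
    if (diag_only) {
      v <- kernel_diag(spec, query_pts)
      return(structure(list(mean = rep(0, q), cov = NULL, var = v),
                       class = "gp_posterior"))
    }
    Kqq <- kernel_eval(spec, query_pts, query_pts)
    return(structure(list(mean = rep(0, q), cov = Kqq,
                          var = pmax(diag(Kqq), 0)),
                     class = "gp_posterior"))
  }
  if (spec$sigma2 == 0 && anyDuplicated(round(obs$X, 12)))
    stop("Gram matrix is singular: duplicate observation points with sigma2 = 0")
  Kxx <- kernel_eval(spec, obs$X, obs$X)
  diag(Kxx) <- diag(Kxx) + spec$sigma2
  R <- chol_jitter(Kxx)
  Kqx <- kernel_eval(spec, query_pts, obs$X)      # q x n
  alpha <- backsolve(R, backsolve(R, obs$y, transpose = TRUE))
  mu <- as.numeric(Kqx %*% alpha)
  V <- backsolve(R, t(Kqx), transpose = TRUE)     # n x q
  if (diag_only) {
    v <- kernel_diag(spec, query_pts) - colSums(V^2)
    return(structure(list(mean = mu, cov = NULL, var = pmax(v, 0)),
                     class = "gp_posterior"))
  }
  Kqq <- kernel_eval(spec, query_pts, query_pts)
  Sig <- Kqq - crossprod(V)
  Sig <- (Sig + t(Sig)) / 2
  structure(list(mean = mu, cov = Sig, var = pmax(diag(Sig), 0)),
            class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior> %d query points; mean in [%.3g, %.3g], sd in [%.3g, %.3g]\n",
              length(x$mean), min(x$mean), max(x$mean),
              sqrt(min(x$var)), sqrt(max(x$var))))
  invisible(x)
}

#' Differential entropy of a Gaussian posterior
#'
#' `H = 1/2 log det(cov) + (D/2) log(2 pi e)` in nats. For the sequential
#' planner D = 1 and `cov` is the scalar posterior variance.
#'
#' @param cov a D x D symmetric positive semi-definite matrix, or a scalar
#'   variance.
#' @return Entropy in nats (can be -Inf for a singular covariance).
#' @examples
#' posterior_entropy(1)  # 0.5 * log(2 * pi * exp(1)) ~ 1.41894
#' @export
posterior_entropy <- function(cov) {
  if (length(cov) == 1) {
    v <- as.numeric(cov)
    if (v < 0) stop("variance must be non-negative")
    return(0.5 * log(v) + 0.5 * log(2 * pi * exp(1)))
  }
  cov <- as.matrix(cov)
  if (!isSymmetric(cov, tol = 1e-8)) stop("covariance must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    stop("covariance is not positive semi-definite")
  D <- nrow(cov)
  0.5 * sum(log(pmax(ev, 0))) + (D / 2) * log(2 * pi * exp(1))
}

# Entropy of a scalar (D = 1) Gaussian from its variance, vectorized.
entropy_from_var <- function(v) 0.5 * log(v) + 0.5 * log(2 * pi * exp(1))

#' Log marginal likelihood of a GP
#'
#' `log N(y | 0, K(X,X) + sigma2 I)` — the evidence maximized during kernel
#' learning and the basis of the particle-filter weight updates.
#'
#' @inheritParams gp_posterior
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(spec, obs) {
  validate_kernel_spec(spec)
  n <- n_obs(obs)
  if (n < 1) stop("log marginal likelihood needs at least one observation")
  K <- kernel_eval(spec, obs$X, obs$X)
  diag(K) <- diag(K) + spec$sigma2
  R <- chol_jitter(K)
  alpha <- backsolve(R, backsolve(R, obs$y, transpose = TRUE))
  -0.5 * sum(obs$y * alpha) - sum(log(diag(R))) - (n / 2) * log(2 * pi)
}

# One-step GP predictive density of value y_new at point x_new given obs
# (centred values), returning the log density under spec. Used by the RPF
# weight update. Predictive variance includes the noise variance.
gp_predictive_logdens <- function(spec, obs, x_new, y_new) {
  if (n_obs(obs) == 0) {
    v <- kernel_diag(spec, x_new) + spec$sigma2
    return(stats::dnorm(y_new, 0, sqrt(v), log = TRUE))
  }
  post <- gp_posterior(spec, obs, x_new, diag_only = TRUE)
  stats::dnorm(y_new, post$mean, sqrt(post$var + spec$sigma2), log = TRUE)
}
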