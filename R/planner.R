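#' Planner configuration
#'
#' @param strategy `"PE"` (pure exploitation: entropy under the fixed
#'   prior hyperparameter theta0) or `"IE"` (implicit exploration:
#'   particle-averaged entropy under the tracked hyperparameter
#'   distribution).
#' @param use_travel_cost divide each candidate's entropy by the Euclidean
#'   distance from the current catheter point, and exclude candidates
#'   closer than `s_min`.
#' @param s_min exclusion radius (coordinate units); `NULL` defaults to 5%
#'   of the domain bounding-box diagonal when travel cost is on.
#' @param m number of mapping points to take (>= 1).
#' @param start_index domain index of the first mapping point (required
#'   input; the rest of the run is fully determined).
#' @param n_particles particles for the IE filter.
#' @param spread initial particle-support half-width (see
#'   [init_particles()]).
#' @param seed integer seed driving the IE filter's randomness (PE
#'   consumes no randomness).
#' @param ie_entropy `"expectation"` scores IE candidates by the
#'   particle-weighted average of per-particle entropies (the expectation
#'   reading); `"mean_theta"` instead evaluates entropy at the weighted
#'   mean hyperparameter.
#' @param geodesic reserved switch for geodesic travel distances on
#'   meshes; straight-line Euclidean (the default) is what the selection
#'   rule states.
#' @return A list of class `plan_config`.
#' @export
plan_config <- function(strategy = c("PE", "IE"), use_travel_cost = FALSE,
                        s_min = NULL, m = 30, start_index = 1,
                        n_particles = 100, spread = 0.5, seed = 1,
                        ie_entropy = c("expectation", "mean_theta"),
                        geodesic = FALSE) {
  strategy <- match.arg(strategy)
  ie_entropy <- match.arg(ie_entropy)
  stopifnot(m >= 1, is.null(s_min) || s_min >= 0, n_particles >= 2)
  if (geodesic) stop("geodesic travel distances are not implemented")
  structure(list(strategy = strategy, use_travel_cost = use_travel_cost,
                 s_min = s_min, m = as.integer(m),
                 start_index = as.integer(start_index),
                 n_particles = as.integer(n_particles), spread = spread,
                 seed = as.integer(seed), ie_entropy = ie_entropy,
                 geodesic = geodesic),
            class = "plan_config")
}

default_s_min <- function(domain) {
  rng <- apply(domain$points, 2, range)
  0.05 * sqrt(sum((rng[2, ] - rng[1, ])^2))
}

# Posterior variance (latent, no noise) from precomputed observed-observed
# and observed-candidate distance matrices (stationary kernels).
post_var_from_dist <- function(spec, Dxx, Dxc) {
  Kxx <- kernel_from_dist(spec, Dxx)
  diag(Kxx) <- diag(Kxx) + spec$sigma2
  R <- chol_jitter(Kxx)
  V <- backsolve(R, kernel_from_dist(spec, Dxc), transpose = TRUE)
  pmax(spec$sf2 - colSums(V^2), 0)
}

# Posterior variance (latent, no noise) at candidate indices given observed
# indices, using the domain's cached pairwise distances for stationary
# kernels.  Values are irrelevant to the variance, so none are passed.
post_var_at <- function(spec, domain, obs_idx, cand_idx) {
  if (length(obs_idx) == 0) return(kernel_diag(spec, domain$points[cand_idx, , drop = FALSE]))
  if (is_stationary(spec) && !is.null(domain$pdist)) {
    return(post_var_from_dist(spec,
                              domain$pdist[obs_idx, obs_idx, drop = FALSE],
                              domain$pdist[obs_idx, cand_idx, drop = FALSE]))
  }
  X <- domain$points[obs_idx, , drop = FALSE]
  Xc <- domain$points[cand_idx, , drop = FALSE]
  gp_posterior(spec, obs_set(X, numeric(length(obs_idx))), Xc,
               diag_only = TRUE)$var
}

# Internal planner state constructor (exported pieces operate on this).
plan_state <- function(domain, theta0, config, particles = NULL,
                       obs_idx = integer(0), obs_val = numeric(0),
                       current_idx = NA_integer_) {
  list(domain = domain, theta0 = theta0, config = config,
       particles = particles, obs_idx = obs_idx, obs_val = obs_val,
       current_idx = current_idx)
}

#' Score candidate mapping points
#'
#' PE scores each candidate by the scalar posterior entropy of the GP
#' prediction under theta0; IE by the particle-weighted average of the
#' per-particle entropies. With travel cost on, scores are divided by the
#' Euclidean distance `s` from the current point and candidates within
#' `s_min` are masked (`-Inf`).
#'
#' @param state planner state as built by [run_mapping()] (a list with
#'   `domain`, `theta0`, `config`, `particles`, `obs_idx`, `current_idx`).
#' @param candidates integer vector of candidate domain indices (must be
#'   unobserved).
#' @return Numeric score per candidate (`-Inf` for masked candidates).
#' @export
score_candidates <- function(state, candidates) {
  cfg <- state$config
  if (any(candidates %in% state$obs_idx))
    stop("candidates must be unobserved points")
  tiny <- .Machine$double.xmin
  if (cfg$strategy == "PE" ||
      (cfg$strategy == "IE" && cfg$ie_entropy == "mean_theta")) {
    spec <- if (cfg$strategy == "PE") state$theta0 else particle_mean(state$particles)
    v <- post_var_at(spec, state$domain, state$obs_idx, candidates)
    H <- entropy_from_var(pmax(v, tiny))
  } else {
    ps <- state$particles
    w <- ps$weights
    H <- numeric(length(candidates))
    dom <- state$domain
    fast <- is_stationary(ps$base_spec) && !is.null(dom$pdist) &&
      length(state$obs_idx) > 0
    if (fast) {   # hoist shared distance sub-matrices out of the particle loop
      Dxx <- dom$pdist[state$obs_idx, state$obs_idx, drop = FALSE]
      Dxc <- dom$pdist[state$obs_idx, candidates, drop = FALSE]
    }
    for (i in seq_len(nrow(ps$theta))) {
      if (w[i] == 0) next
      sp_i <- particle_spec(ps, i)
      v <- if (fast) post_var_from_dist(sp_i, Dxx, Dxc)
           else post_var_at(sp_i, dom, state$obs_idx, candidates)
      H <- H + w[i] * 0.5 * log(pmax(v, tiny))
    }
    H <- H + 0.5 * log(2 * pi * exp(1))
  }
  if (isTRUE(cfg$use_travel_cost)) {
    cur <- state$domain$points[state$current_idx, ]
    s <- sqrt(colSums((t(state$domain$points[candidates, , drop = FALSE]) - cur)^2))
    s_min <- cfg$s_min %||% default_s_min(state$domain)
    H <- H / s
    H[s < s_min] <- -Inf
    if (all(is.infinite(H) & H < 0))
      stop("all candidates lie within s_min of the current point; relax s_min")
  }
  H
}

#' Select the next mapping point
#'
#' Returns the candidate index maximizing the score; ties break to the
#' lowest domain index (candidates are scanned in ascending order), so
#' selection is deterministic.
#'
#' @inheritParams score_candidates
#' @return A single domain index.
#' @export
select_next <- function(state, candidates = NULL) {
  if (is.null(candidates))
    candidates <- setdiff(seq_len(nrow(state$domain$points)), state$obs_idx)
  candidates <- sort(candidates)
  if (length(candidates) == 0) stop("no eligible candidates remain")
  sc <- score_candidates(state, candidates)
  candidates[which.max(sc)]
}

#' Run a closed-loop mapping sequence
#'
#' The full sequential strategy: observe the value at the current point,
#' append it to the observed set `A`; for IE, update the particle weights
#' with the one-step predictive density and apply the Epanechnikov
#' resample-move; then score every unobserved candidate and move to the
#' argmax. Only the first mapping point is an input — the rest of the run
#' is fully determined by the start point, the oracle, theta0 and the
#' config (same seed, same run).
#'
#' Values are centred internally by the running mean of the observations
#' (the GP prior mean is zero); reported estimates have the mean added
#' back. The per-step estimate field and uncertainty summaries use theta0
#' for PE and the particle-weighted mean hyperparameter for IE.
#'
#' @param domain a [sample_domain].
#' @param value_oracle numeric vector of values over all domain points, or
#'   a function `f(index)` returning the (possibly noisy) value there.
#' @param theta0 prior [kernel_spec()].
#' @param config a [plan_config()].
#' @return An object of class `mapping_run`: `indices`, `positions`,
#'   `values`, `travel` (cumulative distance per step), `metrics` (data
#'   frame `step,max_sd,median_sd,mean_l1`), `fields` (m x N matrix of
#'   per-step estimates), `estimate` (final field), `theta_trace` (IE
#'   hyperparameter track), `particles` (final set), `config`, `theta0`.
#' @export
run_mapping <- function(domain, value_oracle, theta0, config) {
  stopifnot(inherits(domain, "sample_domain"), inherits(config, "plan_config"))
  validate_kernel_spec(theta0)
  N <- nrow(domain$points)
  if (config$start_index < 1 || config$start_index > N)
    stop("start_index out of domain range")
  oracle <- if (is.function(value_oracle)) value_oracle
            else {
              vals <- as.numeric(value_oracle)
              if (length(vals) != N) stop("value oracle vector length != domain size")
              function(i) vals[i]
            }
  domain <- precompute_distances(domain)
  ie <- config$strategy == "IE"
  run_body <- function() {
    particles <- if (ie) init_particles(theta0, config$n_particles,
                                        config$spread) else NULL
    obs_idx <- integer(0)
    obs_val <- numeric(0)
    travel <- numeric(0)
    fields <- matrix(NA_real_, config$m, N)
    metrics <- data.frame(step = seq_len(config$m), max_sd = NA_real_,
                          median_sd = NA_real_, mean_l1 = NA_real_)
    theta_trace <- if (ie) matrix(NA_real_, config$m, 2,
                                  dimnames = list(NULL, c("log_l", "log_sf2")))
    cur <- config$start_index
    for (step in seq_len(config$m)) {
      y <- oracle(cur)
      if (!is.finite(y)) {
        warning("value oracle failed at index ", cur, "; aborting with partial run")
        return(finish(step - 1L, obs_idx, obs_val, travel, fields, metrics,
                      theta_trace, particles, domain, theta0, config))
      }
      if (ie && length(obs_idx) >= 1) {
        mu_prev <- mean(obs_val)
        obs_before <- obs_set(domain$points[obs_idx, , drop = FALSE],
                              obs_val - mu_prev)
        particles <- update_weights(particles, obs_before,
                                    domain$points[cur, ], y - mu_prev)
      }
      obs_idx <- c(obs_idx, cur)
      obs_val <- c(obs_val, y)
      travel <- c(travel, if (step == 1) 0 else
        travel[step - 1] + sqrt(sum((domain$points[cur, ] -
                                     domain$points[obs_idx[step - 1], ])^2)))
      # per-step estimate and uncertainty under the reporting hyperparameter
      rep_spec <- if (ie) particle_mean(particles) else theta0
      if (ie) theta_trace[step, ] <- colSums(particles$theta * particles$weights)
      mu_y <- mean(obs_val)
      cobs <- obs_set(domain$points[obs_idx, , drop = FALSE], obs_val - mu_y)
      est <- gp_posterior(rep_spec, cobs, domain$points,
                          diag_only = TRUE)$mean + mu_y
      fields[step, ] <- est
      unobs <- setdiff(seq_len(N), obs_idx)
      sd_u <- sqrt(post_var_at(rep_spec, domain, obs_idx, unobs))
      metrics$max_sd[step] <- max(sd_u)
      metrics$median_sd[step] <- stats::median(sd_u)
      if (!is.null(domain$truth))
        metrics$mean_l1[step] <- mean(abs(est - domain$truth))
      # regularization step: prepare the particle generation used to score
      # and select the next point (estimates above use the weighted
      # posterior before the resampling noise is injected)
      if (ie && step >= 2) particles <- resample_move(particles)
      if (step < config$m) {
        st <- plan_state(domain, theta0, config, particles, obs_idx,
                         obs_val, cur)
        cur <- select_next(st)
      }
    }
    finish(config$m, obs_idx, obs_val, travel, fields, metrics, theta_trace,
           particles, domain, theta0, config)
  }
  finish <- function(n_done, obs_idx, obs_val, travel, fields, metrics,
                     theta_trace, particles, domain, theta0, config) {
    structure(list(indices = obs_idx,
                   positions = domain$points[obs_idx, , drop = FALSE],
                   values = obs_val, travel = travel,
                   metrics = metrics[seq_len(n_done), , drop = FALSE],
                   fields = fields[seq_len(n_done), , drop = FALSE],
                   estimate = if (n_done >= 1) fields[n_done, ] else NULL,
                   theta_trace = if (!is.null(theta_trace))
                     theta_trace[seq_len(n_done), , drop = FALSE],
                   particles = particles, config = config, theta0 = theta0,
                   n_done = n_done),
              class = "mapping_run")
  }
  if (ie) with_seed(config$seed, run_body()) else run_body()
}

#' @export
print.mapping_run <- function(x, ...) {
  cat(sprintf("<mapping_run> %s: %d points, travel %.3g; final max sd %.3g, median sd %.3g\n",
              x$config$strategy %||% "geometry", x$n_done,
              if (length(x$travel)) x$travel[x$n_done] else 0,
              utils::tail(x$metrics$max_sd, 1), utils::tail(x$metrics$median_sd, 1)))
  invisible(x)
}

#' Write a mapping run to CSV files and a JSON manifest
#'
#' Writes `<prefix>_sequence.csv` (`step,index,x,y,z,value,travel_dist`),
#' `<prefix>_metrics.csv` (`step,max_sd,median_sd,mean_l1`), and
#' `<prefix>_manifest.json` (config, theta0, seed, package version).
#'
#' @param run a `mapping_run`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_mapping_run <- function(run, prefix) {
  pos <- run$positions
  if (ncol(pos) == 2) pos <- cbind(pos, 0)
  seq_df <- data.frame(step = seq_len(run$n_done), index = run$indices,
                       x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       value = run$values, travel_dist = run$travel)
  p1 <- paste0(prefix, "_sequence.csv")
  p2 <- paste0(prefix, "_metrics.csv")
  p3 <- paste0(prefix, "_manifest.json")
  utils::write.csv(seq_df, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(run$metrics, p2, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(config = unclass(run$config), theta0 = spec_to_list(run$theta0),
         package_version = as.character(utils::packageVersion("voltmapr"))),
    p3, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(p1, p2, p3))
}
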