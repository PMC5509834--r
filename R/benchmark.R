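#' 2D grid mapping benchmark
#'
#' For each group (number of mixture components `k`) and trial: draw a
#' Gaussian-mixture ground-truth field over the grid, run each method for
#' `m` mapping points from the same centre start point, GP-regress each
#' method's observations onto the full grid, and score the estimate
#' against the truth with [ssim_index()]. Both methods see the identical
#' field within a trial. IE's final regression uses its tracked
#' (particle-weighted mean) hyperparameter; the geometry baseline, which
#' learns nothing, is regressed under the same prior theta0 the IE filter
#' starts from.
#'
#' @param groups integer vector of mixture counts `k` (one experiment
#'   group each).
#' @param trials trials per group.
#' @param m mapping points per run.
#' @param methods subset of `"IE"` (entropy planner, no travel cost) and
#'   `"geometry"` (distance-only coverage baseline, ratio = 1).
#' @param seed master seed; all per-trial seeds derive from it.
#' @param theta0 prior [kernel_spec()]; the default is a Matern 5/2 with
#'   `l = 1`, `sf2 = 1` and a 1% noise floor, the hyperparameter-free
#'   setting used when no demonstration data relates the trials.
#' @param extent,n_per_side grid geometry (defaults: 3600 points on
#'   `[0, 10]^2`).
#' @param n_particles IE particle count.
#' @return A `benchmark_report`: `results` (data frame
#'   `group_k,trial,method,ssim,seed`), `means` (group x method), the
#'   echoed config, and `n_failed`.
#' @export
run_benchmark <- function(groups = c(5, 20, 40, 60), trials = 20, m = 30,
                          methods = c("IE", "geometry"), seed = 1,
                          theta0 = kernel_spec("matern", length_scale = 1,
                                               sf2 = 1, sigma2 = 0.01),
                          extent = 10, n_per_side = 60, n_particles = 100) {
  valid <- c("IE", "geometry")
  if (!all(methods %in% valid))
    stop("unknown method(s) ", paste(setdiff(methods, valid), collapse = ", "),
         "; valid methods: ", paste(valid, collapse = ", "))
  domain <- precompute_distances(make_grid_domain(extent, n_per_side))
  ctr <- colMeans(apply(domain$points, 2, range))
  start <- which.min(rowSums(sweep(domain$points, 2, ctr)^2))
  seeds <- matrix(spawn_seeds(seed, 2 * length(groups) * trials),
                  ncol = 2)
  rows <- list()
  n_failed <- 0L
  ti <- 0L
  for (k in groups) {
    for (tr in seq_len(trials)) {
      ti <- ti + 1L
      s_field <- seeds[ti, 1]
      s_run <- seeds[ti, 2]
      res <- tryCatch({
        mspec <- sample_mixtures(k, extent, seed = s_field)
        truth <- mixture_field(mspec, domain)
        dom_t <- domain
        dom_t$truth <- truth
        truth_mat <- matrix(truth, n_per_side, n_per_side)
        out <- list()
        for (meth in methods) {
          est <- if (meth == "IE") {
            cfg <- plan_config("IE", m = m, start_index = start,
                               n_particles = n_particles, seed = s_run)
            run_mapping(dom_t, truth, theta0, cfg)$estimate
          } else {
            g <- plan_geometry(dom_t, m, ratio = 1, start_index = start)
            yv <- truth[g$indices]
            mu <- mean(yv)
            gp_posterior(theta0, obs_set(dom_t$points[g$indices, , drop = FALSE],
                                         yv - mu),
                         dom_t$points, diag_only = TRUE)$mean + mu
          }
          out[[meth]] <- ssim_index(matrix(est, n_per_side, n_per_side),
                                    truth_mat)
        }
        out
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("trial failed (k = ", k, ", trial ", tr, "): ",
                conditionMessage(res))
        n_failed <- n_failed + 1L
        next
      }
      for (meth in methods)
        rows[[length(rows) + 1]] <- data.frame(
          group_k = k, trial = tr, method = meth, ssim = res[[meth]],
          seed = s_field)
    }
  }
  results <- do.call(rbind, rows)
  means <- stats::aggregate(ssim ~ group_k + method, results, mean)
  structure(list(results = results, means = means,
                 config = list(groups = groups, trials = trials, m = m,
                               methods = methods, seed = seed,
                               theta0 = spec_to_list(theta0),
                               extent = extent, n_per_side = n_per_side,
                               n_particles = n_particles,
                               start_index = start),
                 n_failed = n_failed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> mean SSIM by group and method\n")
  wide <- stats::reshape(x$means, idvar = "group_k", timevar = "method",
                         direction = "wide")
  print(wide, row.names = FALSE)
  if (x$n_failed > 0) cat(x$n_failed, "trial(s) failed\n")
  invisible(x)
}

#' Write a benchmark report to CSV and JSON
#'
#' Writes `<prefix>_trials.csv` (`group_k,trial,method,ssim,seed`) and
#' `<prefix>_summary.json` (group means, config, master seed).
#'
#' @param report a `benchmark_report`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_benchmark <- function(report, prefix) {
  p1 <- paste0(prefix, "_trials.csv")
  p2 <- paste0(prefix, "_summary.json")
  utils::write.csv(report$results, p1, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(means = report$means, config = report$config,
                            n_failed = report$n_failed),
                       p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
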