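#' Demonstration sets for kernel-prior learning
#'
#' A demonstration set is a list of observation sets, one per mapping case
#' (one prior procedure each): the raw material from which the prior
#' kernel hyperparameter theta0 is learned.
#'
#' @param cases list of [obs_set()] objects, each with a `case_id`.
#' @return An object of class `demo_set`.
#' @export
demo_set <- function(cases) {
  stopifnot(is.list(cases), length(cases) >= 1,
            all(vapply(cases, inherits, logical(1), "obs_set")))
  ids <- vapply(seq_along(cases), function(i)
    as.character(cases[[i]]$case_id %||% i), character(1))
  if (anyDuplicated(ids)) stop("duplicate case identifiers")
  names(cases) <- ids
  structure(list(cases = cases), class = "demo_set")
}

#' @export
print.demo_set <- function(x, ...) {
  cat(sprintf("<demo_set> %d cases, %d points total\n", length(x$cases),
              sum(vapply(x$cases, n_obs, integer(1)))))
  invisible(x)
}

#' Read demonstration mapping sequences from CSV
#'
#' Expects a header `case_id,x,y,z,value` (a `z` column of zeros works for
#' 2D demonstrations). Duplicate points within each case are removed with
#' [dedupe_points()].
#'
#' @param path CSV file path.
#' @param dedupe_tol tolerance passed to [dedupe_points()].
#' @return A [demo_set()].
#' @export
read_demonstrations <- function(path, dedupe_tol = 1e-6) {
  df <- utils::read.csv(path)
  need <- c("case_id", "x", "y", "z", "value")
  if (!all(need %in% names(df)))
    stop("demonstration CSV must have columns ", paste(need, collapse = ","))
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop("malformed demonstration row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "))
  cases <- lapply(split(df, df$case_id), function(s) {
    dedupe_points(obs_set(as.matrix(s[, c("x", "y", "z")]), s$value,
                          case_id = s$case_id[1]), tol = dedupe_tol)
  })
  if (any(vapply(cases, n_obs, integer(1)) == 0))
    stop("a demonstration case is empty after deduplication")
  demo_set(cases)
}

#' Concatenate demonstration cases into one training set
#'
#' Row-stacks positions and values across cases without further
#' modification (pairing preserved); excluding one case supports
#' leave-one-out experiments.
#'
#' @param demos a [demo_set()].
#' @param exclude case id to leave out, or `NULL`.
#' @return An [obs_set()] with all remaining points.
#' @export
concatenate_demonstrations <- function(demos, exclude = NULL) {
  stopifnot(inherits(demos, "demo_set"))
  keep <- demos$cases
  if (!is.null(exclude)) keep <- keep[setdiff(names(keep), as.character(exclude))]
  if (length(keep) == 0) stop("no demonstration cases remain after exclusion")
  obs_set(do.call(rbind, lapply(keep, `[[`, "X")),
          unlist(lapply(keep, `[[`, "y"), use.names = FALSE))
}

# Default random-initialization ranges (log-uniform), scale-aware:
# l over [0.05, 5] x domain diameter, sf2 over [0.1, 10] x var(y).
init_ranges <- function(obs) {
  diam <- max(cross_dist(obs$X, obs$X))
  vy <- stats::var(obs$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  list(l = c(0.05, 5) * max(diam, .Machine$double.eps),
       sf2 = c(0.1, 10) * vy,
       sigma2 = c(1e-4, 1e-1) * vy)
}

# Log marginal likelihood and its gradient w.r.t. log-domain parameters
# p = (log l | log bias, log sf2, log sigma2).  D is the precomputed
# observation distance matrix (stationary families) and XXt the Gram of
# raw coordinates (linear family).  Gradient uses the standard identity
# d lml / d theta = tr((alpha alpha' - K^-1) dK/dtheta) / 2.
lml_with_grad <- function(p, family, D, XXt, y, nu) {
  n <- length(y)
  l <- exp(p[1]); sf2 <- exp(p[2]); s2 <- exp(p[3])
  if (family == "linear") {
    Kf <- sf2 * (XXt + l)              # p[1] is log bias here
    dK1 <- matrix(sf2 * l, n, n)
  } else if (family == "squared_exponential") {
    Kf <- sf2 * exp(-D^2 / (2 * l^2))
    dK1 <- Kf * D^2 / l^2
  } else if (family == "rational_quadratic") {
    b <- D^2 / (2 * l^2)               # alpha fixed at 1
    Kf <- sf2 / (1 + b)
    dK1 <- sf2 * 2 * b / (1 + b)^2
  } else {                             # matern
    if (nu == 1 / 2) {
      a <- D / l
      Kf <- sf2 * exp(-a)
      dK1 <- Kf * a
    } else if (nu == 3 / 2) {
      a <- sqrt(3) * D / l
      E <- exp(-a)
      Kf <- sf2 * (1 + a) * E
      dK1 <- sf2 * a^2 * E
    } else {
      a <- sqrt(5) * D / l
      E <- exp(-a)
      Kf <- sf2 * (1 + a + a^2 / 3) * E
      dK1 <- sf2 * a^2 * (1 + a) / 3 * E
    }
  }
  K <- Kf
  diag(K) <- diag(K) + s2
  R <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  alpha <- backsolve(R, backsolve(R, y, transpose = TRUE))
  val <- -0.5 * sum(y * alpha) - sum(log(diag(R))) - (n / 2) * log(2 * pi)
  A <- tcrossprod(alpha) - chol2inv(R)
  list(value = val,
       grad = c(0.5 * sum(A * dK1),
                0.5 * sum(A * Kf),
                0.5 * s2 * sum(diag(A))))
}

# Optimize the log marginal likelihood for one family from one random
# initialization; parameters handled in log domain via optim/L-BFGS-B
# with the analytic gradient above.
fit_one <- function(obs, family, ranges, nu = 5 / 2) {
  n_par <- 3L   # (l or bias, sf2, sigma2) in log domain
  draw_init <- function() {
    if (family == "linear")
      c(stats::runif(1, log(1e-3), log(10)),
        log(exp(stats::runif(1, log(ranges$sf2[1]), log(ranges$sf2[2]))) /
              max(mean(rowSums(obs$X^2)), 1e-8)),
        stats::runif(1, log(ranges$sigma2[1]), log(ranges$sigma2[2])))
    else
      c(stats::runif(1, log(ranges$l[1]), log(ranges$l[2])),
        stats::runif(1, log(ranges$sf2[1]), log(ranges$sf2[2])),
        stats::runif(1, log(ranges$sigma2[1]), log(ranges$sigma2[2])))
  }
  to_spec <- function(p) {
    if (family == "linear")
      kernel_spec("linear", sf2 = exp(p[2]), sigma2 = exp(p[3]),
                  bias = exp(p[1]))
    else
      kernel_spec(family, length_scale = exp(p[1]), sf2 = exp(p[2]),
                  sigma2 = exp(p[3]), nu = nu)
  }
  D <- if (family == "linear") NULL else cross_dist(obs$X, obs$X)
  XXt <- if (family == "linear") tcrossprod(obs$X) else NULL
  cache <- new.env(parent = emptyenv())
  eval_p <- function(p) {
    key <- paste(format(p, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$res)
    res <- tryCatch(lml_with_grad(p, family, D, XXt, obs$y, nu),
                    error = function(e) NULL)
    if (!is.null(res) && !all(is.finite(c(res$value, res$grad)))) res <- NULL
    cache$key <- key
    cache$res <- res
    res
  }
  nll <- function(p) {
    r <- eval_p(p)
    if (is.null(r)) 1e10 else -r$value
  }
  ngr <- function(p) {
    r <- eval_p(p)
    if (is.null(r)) rep(0, n_par) else -r$grad
  }
  p0 <- draw_init()
  fit <- tryCatch(
    stats::optim(p0, nll, gr = ngr, method = "L-BFGS-B",
                 lower = rep(-20, n_par), upper = rep(20, n_par),
                 control = list(maxit = 300)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9)
    return(NULL)
  list(spec = to_spec(fit$par), lml = -fit$value,
       converged = fit$convergence == 0)
}

# Held-out RMSE of GP regression under `spec`, k-fold over points.
# Training-fold values are centred by their own mean.
cv_rmse <- function(spec, obs, folds) {
  errs <- numeric(0)
  for (f in unique(folds)) {
    tr <- obs_set(obs$X[folds != f, , drop = FALSE], obs$y[folds != f])
    te_X <- obs$X[folds == f, , drop = FALSE]
    te_y <- obs$y[folds == f]
    mu_tr <- mean(tr$y)
    tr$y <- tr$y - mu_tr
    pred <- gp_posterior(spec, tr, te_X, diag_only = TRUE)$mean + mu_tr
    errs <- c(errs, te_y - pred)
  }
  sqrt(mean(errs^2))
}

#' Learn the prior kernel hyperparameter from demonstrations
#'
#' For each candidate kernel family, hyperparameters are optimized by
#' gradient ascent on the log marginal likelihood from `restarts` random
#' initializations; families are then compared by held-out root-mean-square
#' error of the GP-regressed values (k-fold over points) and the winner's
#' best spec is returned as theta0. Training-set RMSE is recorded alongside
#' for reference.
#'
#' @param obs an [obs_set()] (typically from
#'   [concatenate_demonstrations()]); values are centred internally.
#' @param families character vector of families to compare.
#' @param restarts random restarts per family (>= 1).
#' @param seed integer seed (fold assignment and initializations).
#' @param k_folds folds for the held-out comparison.
#' @param nu Matern smoothness used by the matern family.
#' @return A list of class `kernel_fit` with `theta0` (the winning
#'   [kernel_spec()]), `family` and `report` (per-family spec,
#'   log marginal likelihood, CV-RMSE, train RMSE, convergence flag).
#' @export
fit_kernel <- function(obs,
                       families = c("linear", "squared_exponential",
                                    "matern", "rational_quadratic"),
                       restarts = 3, seed = 1, k_folds = 5, nu = 5 / 2) {
  stopifnot(n_obs(obs) >= 10, restarts >= 1)
  mu_y <- mean(obs$y)
  cobs <- obs_set(obs$X, obs$y - mu_y)
  ranges <- init_ranges(cobs)
  with_seed(seed, {
    folds <- sample(rep_len(seq_len(k_folds), n_obs(cobs)))
    report <- list()
    for (fam in families) {
      best <- NULL
      for (r in seq_len(restarts)) {
        cand <- fit_one(cobs, fam, ranges, nu = nu)
        if (!is.null(cand) && (is.null(best) || cand$lml > best$lml))
          best <- cand
      }
      if (is.null(best)) {
        report[[fam]] <- list(failed = TRUE)
        next
      }
      best$cv_rmse <- cv_rmse(best$spec, cobs, folds)
      tr_pred <- gp_posterior(best$spec, cobs, cobs$X, diag_only = TRUE)$mean
      best$train_rmse <- sqrt(mean((cobs$y - tr_pred)^2))
      best$failed <- FALSE
      report[[fam]] <- best
    }
    ok <- names(report)[!vapply(report, `[[`, logical(1), "failed")]
    if (length(ok) == 0) stop("all kernel families failed to fit")
    scores <- vapply(report[ok], `[[`, numeric(1), "cv_rmse")
    win <- ok[which.min(scores)]
    structure(list(theta0 = report[[win]]$spec, family = win,
                   report = report, seed = seed, k_folds = k_folds,
                   y_mean = mu_y),
              class = "kernel_fit")
  })
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit> selected family:", x$family, "\n")
  for (fam in names(x$report)) {
    r <- x$report[[fam]]
    if (isTRUE(r$failed)) cat(sprintf("  %-22s failed\n", fam))
    else cat(sprintf("  %-22s lml %10.3f  cv-rmse %.5f  train-rmse %.5f\n",
                     fam, r$lml, r$cv_rmse, r$train_rmse))
  }
  invisible(x)
}

spec_to_list <- function(spec) unclass(spec)

list_to_spec <- function(l) {
  kernel_spec(l$family, length_scale = l$length_scale, sf2 = l$sf2,
              sigma2 = l$sigma2, nu = l$nu %||% (5 / 2),
              alpha = l$alpha %||% 1, bias = l$bias %||% 0)
}

#' Serialize / restore a kernel fit as JSON
#'
#' @param fit a `kernel_fit` from [fit_kernel()].
#' @param path JSON file path.
#' @return `write_kernel_fit` returns `path` invisibly; `read_kernel_fit`
#'   returns the restored `kernel_fit`.
#' @export
write_kernel_fit <- function(fit, path) {
  out <- list(family = fit$family, theta0 = spec_to_list(fit$theta0),
              seed = fit$seed, k_folds = fit$k_folds, y_mean = fit$y_mean,
              report = lapply(fit$report, function(r) {
                if (isTRUE(r$failed)) return(list(failed = TRUE))
                list(failed = FALSE, spec = spec_to_list(r$spec),
                     lml = r$lml, cv_rmse = r$cv_rmse,
                     train_rmse = r$train_rmse, converged = r$converged)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kernel_fit
#' @export
read_kernel_fit <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(theta0 = list_to_spec(l$theta0), family = l$family,
                 report = lapply(l$report, function(r) {
                   if (isTRUE(r$failed)) return(list(failed = TRUE))
                   list(spec = list_to_spec(r$spec), lml = r$lml,
                        cv_rmse = r$cv_rmse, train_rmse = r$train_rmse,
                        converged = r$converged, failed = FALSE)
                 }),
                 seed = l$seed, k_folds = l$k_folds, y_mean = l$y_mean),
            class = "kernel_fit")
}
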