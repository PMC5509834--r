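#' Geometry-coverage baseline planner (baseline-approx)
#'
#' A greedy coverage rule approximating the geometry-based mapping
#' planner used as the comparison method: at each step the next point
#' maximizes `ratio * dhat(x) + (1 - ratio) * chat(x)`, where `dhat` is
#' the minimum distance from `x` to the already-selected set and `chat`
#' is the per-vertex curvature magnitude, each min-max normalized over
#' the remaining candidates. `ratio = 1` is the distance-only
#' (farthest-point) variant; `ratio = 0.5` weights distance and curvature
#' equally, drawing points toward high-curvature regions. The rule is an
#' approximation reconstructed from the described behaviours, labelled
#' `baseline-approx` in outputs; it ignores field values entirely.
#'
#' @param domain a [sample_domain].
#' @param m number of points to select.
#' @param ratio weight on distance, in `[0, 1]`; curvature is required
#'   (mesh domain) when `ratio < 1`.
#' @param start_index first selected point.
#' @return A `mapping_run` carrying positions only (`values` are `NA`);
#'   `method` is `"geometry-baseline-approx"`.
#' @export
plan_geometry <- function(domain, m, ratio = 1, start_index = 1) {
  stopifnot(inherits(domain, "sample_domain"), m >= 1,
            ratio >= 0, ratio <= 1)
  N <- nrow(domain$points)
  start_index <- as.integer(start_index)
  m <- as.integer(m)
  if (start_index < 1 || start_index > N) stop("start_index out of range")
  if (m > N) stop("m exceeds the number of domain points")
  curv <- NULL
  if (ratio < 1) {
    curv <- domain$curvature
    if (is.null(curv)) {
      if (is.null(domain$faces))
        stop("ratio < 1 needs per-point curvature, unavailable on this domain")
      curv <- vertex_curvature(domain)
    }
  }
  sel <- integer(m)
  sel[1] <- start_index
  # min distance from every point to the selected set, updated incrementally
  mind <- sqrt(colSums((t(domain$points) - domain$points[start_index, ])^2))
  for (step in seq_len(m - 1) + 1) {
    remaining <- setdiff(seq_len(N), sel[seq_len(step - 1)])
    dhat <- minmax_norm(mind[remaining])
    score <- if (ratio == 1) dhat
             else ratio * dhat + (1 - ratio) * minmax_norm(curv[remaining])
    nxt <- remaining[which.max(score)]
    sel[step] <- nxt
    mind <- pmin(mind, sqrt(colSums((t(domain$points) - domain$points[nxt, ])^2)))
  }
  travel <- c(0, cumsum(sqrt(rowSums(
    (domain$points[sel[-1], , drop = FALSE] -
     domain$points[sel[-m], , drop = FALSE])^2))))
  structure(list(indices = sel,
                 positions = domain$points[sel, , drop = FALSE],
                 values = rep(NA_real_, m), travel = travel,
                 metrics = data.frame(step = seq_len(m), max_sd = NA_real_,
                                      median_sd = NA_real_, mean_l1 = NA_real_),
                 fields = NULL, estimate = NULL, theta_trace = NULL,
                 particles = NULL,
                 config = list(method = "geometry-baseline-approx",
                               ratio = ratio, m = m,
                               start_index = start_index),
                 theta0 = NULL, n_done = m),
            class = "mapping_run")
}

minmax_norm <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}
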