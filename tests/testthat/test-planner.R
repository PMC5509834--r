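theta0 <- kernel_spec("matern", length_scale = 1, sf2 = 1, sigma2 = 0.01)

small_state <- function(domain, obs_idx, truth, config, particles = NULL) {
  voltmapr:::plan_state(domain, theta0, config, particles, obs_idx,
                        truth[obs_idx], utils::tail(obs_idx, 1))
}

test_that("IE scores equal PE scores when every particle sits at theta0", {
  d <- voltmapr:::precompute_distances(make_grid_domain(5, 7))
  truth <- mixture_field(sample_mixtures(3, 5, seed = 1), d)
  obs_idx <- c(10L, 25L, 40L)
  cands <- setdiff(seq_len(49), obs_idx)
  pe <- score_candidates(small_state(d, obs_idx, truth,
                                     plan_config("PE", m = 5)), cands)
  ps <- init_particles(theta0, m = 20, spread = 1e-12, seed = 2)
  ie <- score_candidates(small_state(d, obs_idx, truth,
                                     plan_config("IE", m = 5), ps), cands)
  expect_equal(ie, pe, tolerance = 1e-10)
  # a lone candidate is selected whatever its score
  st <- small_state(d, obs_idx, truth, plan_config("PE", m = 5))
  expect_identical(select_next(st, candidates = 17L), 17L)
  # observed points are not scoreable
  expect_error(score_candidates(st, c(10L, 11L)), "unobserved")
})

test_that("selection matches the exhaustive entropy argmax (with and without travel cost)", {
  set.seed(3)
  for (trial in 1:10) {
    npts <- 40
    pts <- matrix(runif(npts * 2, 0, 8), npts, 2)
    d <- voltmapr:::precompute_distances(
      voltmapr:::new_sample_domain(pts, "grid"))
    truth <- rnorm(npts)
    obs_idx <- sample(npts, 5)
    cands <- sort(setdiff(seq_len(npts), obs_idx))
    obs <- obs_set(pts[obs_idx, , drop = FALSE], truth[obs_idx])
    # plain entropy
    st <- small_state(d, obs_idx, truth, plan_config("PE", m = 6))
    want <- cands[which.max(vapply(cands, function(i)
      brute_entropy_at(theta0, obs, pts[i, ]), numeric(1)))]
    expect_identical(select_next(st), want)
    # entropy per unit travel distance, with an exclusion radius
    cfg <- plan_config("PE", m = 6, use_travel_cost = TRUE, s_min = 0.4)
    st2 <- small_state(d, obs_idx, truth, cfg)
    cur <- pts[utils::tail(obs_idx, 1), ]
    sc <- vapply(cands, function(i) {
      s <- sqrt(sum((pts[i, ] - cur)^2))
      if (s < 0.4) -Inf else brute_entropy_at(theta0, obs, pts[i, ]) / s
    }, numeric(1))
    expect_identical(select_next(st2), cands[which.max(sc)])
  }
})

test_that("ties break deterministically to the lowest index", {
  d <- voltmapr:::precompute_distances(make_grid_domain(4, 5))
  truth <- rep(0, 25)
  # empty A and a stationary kernel: all candidates score identically
  st <- voltmapr:::plan_state(d, theta0, plan_config("PE", m = 2), NULL,
                              integer(0), numeric(0), NA_integer_)
  expect_identical(select_next(st), 1L)
})

test_that("travel cost prefers the nearer of two equally informative candidates", {
  # one observation far away; two candidates symmetric in information,
  # at travel distances 1 and 2 from the current point
  pts <- rbind(c(0, 0), c(1, 0), c(2, 0))
  d <- voltmapr:::new_sample_domain(rbind(pts, c(50, 50)), "grid")
  d <- voltmapr:::precompute_distances(d)
  big <- kernel_spec("matern", length_scale = 1, sf2 = 10, sigma2 = 0.01)
  cfg <- plan_config("PE", m = 2, use_travel_cost = TRUE, s_min = 0.1)
  # catheter at (0,0); the lone far-away observation leaves both candidates
  # at (essentially) the prior variance, hence equal entropy
  st <- voltmapr:::plan_state(d, big, cfg, NULL, 4L, 0.5, 1L)
  sc <- score_candidates(st, c(2L, 3L))
  expect_gt(sc[1], sc[2])
})

test_that("an all-masked candidate set reports the s_min conflict", {
  d <- voltmapr:::precompute_distances(make_grid_domain(1, 3))
  cfg <- plan_config("PE", m = 2, use_travel_cost = TRUE, s_min = 10)
  st <- voltmapr:::plan_state(d, theta0, cfg, NULL, 5L, 0.2, 5L)
  expect_error(select_next(st), "s_min")
})

test_that("a one-point run returns the start observation and its posterior", {
  d <- make_grid_domain(5, 6)
  truth <- mixture_field(sample_mixtures(2, 5, seed = 4), d)
  run <- run_mapping(d, truth, theta0, plan_config("PE", m = 1,
                                                   start_index = 14))
  expect_identical(run$indices, 14L)
  expect_equal(run$values, truth[14])
  mu <- truth[14]
  want <- gp_posterior(theta0, obs_set(d$points[14, , drop = FALSE], 0),
                       d$points, diag_only = TRUE)$mean + mu
  expect_equal(run$estimate, want, tolerance = 1e-10)
})

test_that("runs are reproducible and PE consumes no randomness", {
  d <- make_grid_domain(6, 8)
  truth <- mixture_field(sample_mixtures(4, 6, seed = 5), d)
  d$truth <- truth
  cfg <- plan_config("IE", m = 6, start_index = 30, n_particles = 30,
                     seed = 77)
  r1 <- run_mapping(d, truth, theta0, cfg)
  r2 <- run_mapping(d, truth, theta0, cfg)
  expect_identical(r1$indices, r2$indices)
  expect_equal(r1$fields, r2$fields, tolerance = 1e-15)
  # PE leaves the RNG stream untouched
  set.seed(123)
  before <- .Random.seed
  run_mapping(d, truth, theta0, plan_config("PE", m = 4, start_index = 30))
  expect_identical(.Random.seed, before)
})

test_that("travel-cost runs respect the exclusion radius between consecutive points", {
  d <- make_grid_domain(10, 12)
  truth <- mixture_field(sample_mixtures(5, 10, seed = 6), d)
  cfg <- plan_config("PE", m = 10, start_index = 1, use_travel_cost = TRUE,
                     s_min = 1.5)
  run <- run_mapping(d, truth, theta0, cfg)
  steps <- sqrt(rowSums((run$positions[-1, ] - run$positions[-10, ])^2))
  expect_true(all(steps >= 1.5))
  expect_true(all(diff(run$travel) >= 0))
  expect_identical(anyDuplicated(run$indices), 0L)
})

test_that("PE median uncertainty never rises; IE error falls as mapping proceeds", {
  d <- voltmapr:::precompute_distances(make_grid_domain(10, 15))
  gen <- kernel_spec("matern", length_scale = 2, sf2 = 1, sigma2 = 0.01)
  wins <- 0L
  for (s in 1:10) {
    f <- sample_gp_field(d, gen, seed = 1300 + s)
    d$truth <- f
    ri <- run_mapping(d, f, theta0, plan_config("IE", m = 30, start_index = 1,
                                                seed = 1400 + s))
    if (ri$metrics$mean_l1[30] < ri$metrics$mean_l1[5]) wins <- wins + 1L
    if (s == 1) {
      rp <- run_mapping(d, f, theta0, plan_config("PE", m = 30,
                                                  start_index = 1))
      expect_true(all(diff(rp$metrics$median_sd) <= 1e-10))
    }
  }
  expect_gte(wins, 9)
})

test_that("mapping runs serialize to the declared CSV layout", {
  d <- make_grid_domain(5, 6)
  truth <- mixture_field(sample_mixtures(2, 5, seed = 7), d)
  run <- run_mapping(d, truth, theta0, plan_config("PE", m = 5,
                                                   start_index = 3))
  pre <- file.path(withr::local_tempdir(), "run")
  write_mapping_run(run, pre)
  seq_df <- read.csv(paste0(pre, "_sequence.csv"))
  expect_identical(names(seq_df),
                   c("step", "index", "x", "y", "z", "value", "travel_dist"))
  expect_equal(nrow(seq_df), 5)
  met <- read.csv(paste0(pre, "_metrics.csv"))
  expect_identical(names(met), c("step", "max_sd", "median_sd", "mean_l1"))
  man <- jsonlite::read_json(paste0(pre, "_manifest.json"))
  expect_identical(man$config$strategy, "PE")
})
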