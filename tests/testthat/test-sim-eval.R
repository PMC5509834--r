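test_that("mixture draws are seeded, in-domain, and centred on average", {
  s1 <- sample_mixtures(5, 10, seed = 1)
  s2 <- sample_mixtures(5, 10, seed = 1)
  expect_equal(s1$means, s2$means)
  expect_equal(s1$variances, s2$variances)
  big <- sample_mixtures(10000, 10, seed = 2)
  expect_true(all(big$means >= 0 & big$means <= 10))
  se <- 10 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(big$means[, 1]) - 5), 3 * se)
  expect_lt(abs(mean(big$means[, 2]) - 5), 3 * se)
  expect_true(all(big$variances >= (10 / 20)^2 & big$variances <= (10 / 4)^2))
  expect_true(all(big$amplitudes >= 0.5 & big$amplitudes <= 1.5))
})

test_that("mixture fields evaluate bumps exactly and superpose", {
  spec <- sample_mixtures(1, 10, seed = 3)
  expect_equal(mixture_field(spec, spec$means), spec$amplitudes,
               tolerance = 1e-12)
  a <- sample_mixtures(3, 10, seed = 4)
  b <- sample_mixtures(2, 10, seed = 5)
  both <- structure(list(means = rbind(a$means, b$means),
                         variances = c(a$variances, b$variances),
                         amplitudes = c(a$amplitudes, b$amplitudes),
                         extent = 10, k = 5), class = "mixture_spec")
  g <- make_grid_domain(10, 12)
  expect_equal(mixture_field(both, g),
               mixture_field(a, g) + mixture_field(b, g), tolerance = 1e-12)
  # pointwise oracle: direct per-point, per-component evaluation
  spec20 <- sample_mixtures(20, 10, seed = 6)
  got <- mixture_field(spec20, g)
  want <- apply(g$points, 1, function(p)
    sum(spec20$amplitudes *
          exp(-colSums((t(spec20$means) - p)^2) / (2 * spec20$variances))))
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("SSIM is 1 on identical fields, negative on anti-correlated ones", {
  set.seed(7)
  A <- matrix(runif(400), 20, 20)
  expect_equal(ssim_index(A, A), 1, tolerance = 1e-12)
  # anti-correlation: on a locally zero-mean pattern the luminance term
  # stays positive while the structure term flips sign
  Z <- outer(1:20, 1:20, function(i, j) (-1)^(i + j)) +
    matrix(rnorm(400, sd = 0.05), 20, 20)
  expect_lt(ssim_index(-Z, Z), 0)
  expect_error(ssim_index(A[, 1:15], A), "shape")
  expect_error(ssim_index(matrix(1, 5, 5), matrix(1, 5, 5)), "window")
  expect_equal(ssim_index(matrix(2, 20, 20), matrix(2, 20, 20)), 1)
})

test_that("SSIM agrees with the brute-force windowed oracle", {
  set.seed(8)
  truth <- matrix(cumsum(rnorm(400, sd = 0.2)), 20, 20)
  est <- truth + matrix(rnorm(400, sd = 0.3), 20, 20)
  expect_equal(ssim_index(est, truth), brute_ssim(est, truth),
               tolerance = 1e-10)
  # bounded in [-1, 1] over assorted random pairs
  for (i in 1:5) {
    a <- matrix(rnorm(400), 20, 20)
    b <- matrix(rnorm(400), 20, 20)
    v <- ssim_index(a, b)
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("mean L1 error is the arithmetic mean of absolute differences", {
  expect_equal(mean_l1_error(1:5, 1:5), 0)
  expect_equal(mean_l1_error(1:5 + 1, 1:5), 1)
  set.seed(9)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(mean_l1_error(a, b), sum(abs(a - b)) / 100, tolerance = 1e-14)
  expect_error(mean_l1_error(1:3, 1:4), "length")
})

test_that("GP field draws are seeded and match their target covariance", {
  d <- make_grid_domain(5, 6)
  spec <- kernel_spec("matern", length_scale = 2, sf2 = 1)
  f1 <- sample_gp_field(d, spec, seed = 10)
  f2 <- sample_gp_field(d, spec, seed = 10)
  expect_equal(f1, f2)
  # vanishing signal variance gives a (numerically) flat field
  tiny <- kernel_spec("matern", length_scale = 2, sf2 = 1e-12)
  expect_lt(max(abs(sample_gp_field(d, tiny, seed = 11))), 1e-5)
  # empirical covariance at 5 fixed points over 1000 draws
  pts <- voltmapr:::new_sample_domain(
    cbind(c(0, 1, 3, 4, 2), c(0, 2, 1, 4, 3)), "grid")
  draws <- sapply(1:1000, function(s) sample_gp_field(pts, spec, seed = s))
  emp <- tcrossprod(draws - rowMeans(draws)) / 999
  K <- kernel_eval(spec, pts$points, pts$points)
  expect_lt(norm(emp - K, "F") / norm(K, "F"), 0.1)
})

test_that("small benchmark runs are reproducible with the declared layout", {
  r1 <- run_benchmark(groups = 5, trials = 2, m = 6, seed = 12,
                      n_per_side = 15, n_particles = 20)
  r2 <- run_benchmark(groups = 5, trials = 2, m = 6, seed = 12,
                      n_per_side = 15, n_particles = 20)
  expect_equal(r1$results, r2$results)
  expect_equal(nrow(r1$results), 2 * 2)   # 2 trials x 2 methods
  expect_true(all(r1$results$ssim >= -1 & r1$results$ssim <= 1))
  expect_setequal(unique(r1$results$method), c("geometry", "IE"))
  expect_error(run_benchmark(methods = "nonsense"), "valid methods")
  pre <- file.path(withr::local_tempdir(), "bench")
  write_benchmark(r1, pre)
  df <- read.csv(paste0(pre, "_trials.csv"))
  expect_identical(names(df), c("group_k", "trial", "method", "ssim", "seed"))
})
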