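test_that("identical configurations reproduce identical tables", {
  a <- simulate_study(n_train = 10, n_test = 20, m = 3, noise_sd = 0.7,
                      bias = c(0, 0.2, -0.1), seed = 123)
  b <- simulate_study(n_train = 10, n_test = 20, m = 3, noise_sd = 0.7,
                      bias = c(0, 0.2, -0.1), seed = 123)
  expect_identical(a$train, b$train)
  expect_identical(a$test, b$test)
  expect_false(identical(
    a$test,
    simulate_study(n_train = 10, n_test = 20, m = 3, noise_sd = 0.7,
                   bias = c(0, 0.2, -0.1), seed = 124)$test))
  # train and test ids never collide
  expect_length(intersect(a$train$id, a$test$id), 0)
})

test_that("the noiseless limit gives perfect correlation everywhere", {
  sim <- simulate_study(m = 3, noise_sd = 0, seed = 5)
  for (scale in c("log10", "raw")) {
    perf <- evaluate_systems(sim$test, scale = scale)
    expect_equal(perf$r, rep(1, 3), tolerance = 1e-12)
  }
  expect_equal(recover_noise_sd(sim$test, "S1"), 0, tolerance = 1e-12)
})

test_that("generator parameters are recovered from large simulations", {
  sim <- simulate_study(n_train = 0, n_test = 10000, m = 1, noise_sd = 0.5,
                        seed = 17)
  # chi-distribution standard error of a Gaussian SD estimate
  se <- 0.5 / sqrt(2 * (10000 - 1))
  expect_equal(recover_noise_sd(sim$test, "S1"), 0.5, tolerance = 3 * se / 0.5)

  shifted <- simulate_study(n_train = 0, n_test = 100, m = 1, noise_sd = 0,
                            bias = 1, seed = 18)
  expect_equal(recover_bias(shifted$test, "S1"), 1, tolerance = 1e-12)
  expect_equal(recover_noise_sd(shifted$test, "S1"), 0, tolerance = 1e-12)
})

test_that("invalid simulation arguments are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2)       # off-diagonal beyond +/-1, not PSD
  expect_error(simulate_study(m = 2, noise_corr = bad, seed = 1),
               class = "qsarfuse_argument_error")
  asym <- matrix(c(1, 0.2, 0.6, 1), 2)
  expect_error(simulate_study(m = 2, noise_corr = asym, seed = 1),
               class = "qsarfuse_argument_error")
  expect_error(simulate_study(m = 0, seed = 1),
               class = "qsarfuse_argument_error")
  expect_error(simulate_study(noise_sd = -1, seed = 1),
               class = "qsarfuse_argument_error")
  expect_error(recover_noise_sd(toy_study(), "nope"),
               class = "qsarfuse_coverage_error")
})

test_that("fusing two independent equal-noise systems improves r as theory predicts", {
  span <- 4.6
  sigma_t <- span / sqrt(12)
  noise <- 1
  r_ind_theory <- sigma_t / sqrt(sigma_t^2 + noise^2)
  r_comb_theory <- sigma_t / sqrt(sigma_t^2 + noise^2 / 2)

  res <- vapply(1:200, function(i) {
    sim <- simulate_study(n_train = 0, n_test = 2000, span_orders = span,
                          m = 2, noise_sd = noise, seed = 5000 + i)
    perf <- evaluate_systems(sim$test)
    lb <- fusion_leaderboard(sim$test)
    c(ind = mean(perf$r), comb = lb$r_test[lb$label == "S1+S2"])
  }, numeric(2))

  expect_gt(mean(res["comb", ]), mean(res["ind", ]))
  expect_equal(mean(res["ind", ]), r_ind_theory, tolerance = 0.01)
  expect_equal(mean(res["comb", ]), r_comb_theory, tolerance = 0.01)
})

test_that("perfectly correlated noise leaves only the bias gap and no fusion gain", {
  sim <- simulate_study(n_train = 0, n_test = 150, m = 2, noise_sd = 0.8,
                        bias = c(0, 0.7), noise_corr = 1, seed = 31)
  # identical noise realizations: every diversity score is the bias gap
  d <- diversity_score(sim$test, "S1", "S2")
  expect_equal(unname(d), rep(0.7, 150), tolerance = 1e-6)
  prof <- diversity_profile(sim$test, "S1", "S2")
  expect_equal(attr(prof, "aggregate"), 0.7 * 150, tolerance = 1e-4)

  # and the combination cannot improve on the individuals
  perf <- evaluate_systems(sim$test)
  lb <- fusion_leaderboard(sim$test)
  expect_equal(lb$r_test[lb$label == "S1+S2"], perf$r[1], tolerance = 1e-6)
})

test_that("the fusion gain shrinks as the noise correlation rises", {
  gain_at <- function(rho) {
    g <- vapply(1:100, function(i) {
      sim <- simulate_study(n_train = 0, n_test = 400, m = 2, noise_sd = 1,
                            noise_corr = rho, seed = 7000 + i)
      perf <- evaluate_systems(sim$test)
      lb <- fusion_leaderboard(sim$test)
      lb$r_test[lb$label == "S1+S2"] - max(perf$r)
    }, numeric(1))
    mean(g)
  }
  gains <- vapply(c(0, 0.6, 0.95), gain_at, numeric(1))
  expect_true(all(diff(gains) < 0))
  expect_gt(gains[1], 0)
  expect_lt(abs(gains[3]), 0.02)
})
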