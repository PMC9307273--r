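test_that("simulators honor their deterministic limits and seeds", {
  still <- simulate_brownian(3, length = 6, sigma = 0, seed = 1)
  expect_true(all(still$tracks$x == 0) && all(still$tracks$y == 0))

  drift <- simulate_directed(1, length = 4, sigma = 0, mu = c(1, -2), seed = 1)
  expect_equal(drift$tracks$x, c(0, 1, 2, 3))
  expect_equal(drift$tracks$y, c(0, -2, -4, -6))

  a <- simulate_brownian(5, length = 10, seed = 99)
  b <- simulate_brownian(5, length = 10, seed = 99)
  expect_identical(a$tracks, b$tracks)

  # zero drift reduces the directed model to Brownian, path for path
  d0 <- simulate_directed(5, length = 10, mu = c(0, 0), seed = 7)
  bm <- simulate_brownian(5, length = 10, seed = 7)
  expect_equal(d0$tracks$x, bm$tracks$x)

  # lambda = 0 reduces the confined update to the Brownian update exactly
  ou0 <- simulate_confined(5, length = 10, lambda = 0, seed = 7)
  expect_equal(ou0$tracks$x, bm$tracks$x)
  expect_equal(ou0$tracks$y, bm$tracks$y)
})

test_that("Brownian mean squared displacement follows 2 sigma^2 t", {
  sigma <- sqrt(2)
  n <- 1e4
  ts <- simulate_brownian(n, length = 11, sigma = sigma, seed = 17)
  X <- matrix(ts$tracks$x, ncol = 11, byrow = TRUE)
  Y <- matrix(ts$tracks$y, ncol = 11, byrow = TRUE)
  for (lag in c(1, 5, 10)) {
    sq <- (X[, 1 + lag] - X[, 1])^2 + (Y[, 1 + lag] - Y[, 1])^2
    se <- sd(sq) / sqrt(n)
    expect_lt(abs(mean(sq) - 2 * sigma^2 * lag), 3 * se)
  }
  # per-coordinate increments pass a normality check at variance sigma^2 dt
  dx <- as.vector(X[, -1] - X[, -11])[1:10000]
  expect_gt(stats::shapiro.test(dx[1:5000])$p.value, 1e-4)
  expect_lt(abs(var(dx) - sigma^2), 0.1)
})

test_that("the confined process matches Ornstein-Uhlenbeck closed forms", {
  sigma <- sqrt(2); lambda <- 1
  ts <- simulate_confined(5000, length = 40, sigma = sigma, lambda = lambda,
                          seed = 23)
  X <- matrix(ts$tracks$x, ncol = 40, byrow = TRUE)
  # started at the center (stationary mean), variance relaxes to sigma^2/(2 lambda)
  tail_var <- var(as.vector(X[, 20:40]))
  expect_lt(abs(tail_var - sigma^2 / (2 * lambda)) / (sigma^2 / (2 * lambda)), 0.05)

  # autocorrelation of centered positions decays as exp(-lambda * lag)
  for (lag in 1:3) {
    ac <- mean(X[, 30] * X[, 30 + lag]) / mean(X[, 30]^2)
    expect_lt(abs(ac - exp(-lambda * lag)), 0.05)
  }

  # strong confinement collapses positions onto the center
  tight <- simulate_confined(3, length = 20, sigma = 1, lambda = 50,
                             mu = c(2, -1), seed = 5)
  expect_lt(max(abs(tight$tracks$x - 2)), 0.5)
  expect_error(simulate_confined(2, lambda = -1), "lambda")
})

test_that("confinement accuracy starts at the test level and rises with lambda and N", {
  qt <- test_quantiles(n_mc = 2e5)
  n <- 2000
  res <- accuracy_vs_confinement(N = 5, lambda_grid = c(0, 1, 3, 6),
                                 n_per_point = n, quantiles = qt, seed = 31)
  se3 <- 3 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(res$accuracy[1] - 0.05), se3 + 0.002)
  expect_true(all(diff(res$accuracy) > -0.03))

  # longer tracklets separate confined from Brownian better
  qt10 <- test_quantiles(N = 10, n_mc = 2e5)
  res10 <- accuracy_vs_confinement(N = 10, lambda_grid = 6, n_per_point = n,
                                   quantiles = qt10, seed = 31)
  expect_gt(res10$accuracy, res$accuracy[res$lambda == 6] - 0.03)

  expect_error(accuracy_vs_confinement(N = 10, quantiles = qt, seed = 1), "N = 10")
})

test_that("mistracking penalty follows the exponential-perturbation formula", {
  expect_equal(mistracking_adjusted_accuracy(0.8, 0, 5), 0.8)
  expect_equal(mistracking_adjusted_accuracy(0.8, 0.1, 5), 0.8 * exp(-0.5))
  expect_lt(mistracking_adjusted_accuracy(1, 0.1, 1e4), 1e-300)
  expect_error(mistracking_adjusted_accuracy(0.8, -1, 5), "rho")
  expect_error(mistracking_adjusted_accuracy(1.2, 0.1, 5), "p_N_0")
})

test_that("mixture simulation allocates ground truth deterministically", {
  mix <- simulate_mixture(1000, fraction_confined = 0.5, length = 6, seed = 41)
  expect_equal(sum(mix$truth$true_model == "confined"), 500L)
  expect_equal(mix$truth$track_id, unique(mix$tracks$tracks$track_id))

  all_conf <- simulate_mixture(10, fraction_confined = 1, seed = 1)
  expect_true(all(all_conf$truth$true_model == "confined"))

  m1 <- simulate_mixture(50, 0.3, seed = 6)
  m2 <- simulate_mixture(50, 0.3, seed = 6)
  expect_identical(m1$tracks$tracks, m2$tracks$tracks)
  expect_identical(m1$truth, m2$truth)

  # full-classifier recall of restricted motion on the well-separated mixture:
  # at lambda = 6 most confined tracklets are tight enough to read as immobile,
  # so restricted (immobile + confined) is the recovered super-label
  qt <- test_quantiles(n_mc = 2e5)
  big <- simulate_mixture(1000, 0.5, length = 6, lambda = 6, seed = 43)
  cls <- classify_tracks(big$tracks, qt)
  truth <- setNames(big$truth$true_model, big$truth$track_id)
  restricted <- cls$label %in% c("immobile", "confined")
  recall <- mean(restricted[truth[as.character(cls$track_id)] == "confined"])
  expect_gte(recall, 0.9)
})
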