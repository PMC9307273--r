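#' Simulate 2-D Brownian tracks
#'
#' Pure diffusion: increments are i.i.d. Gaussian with per-coordinate variance
#' `sigma^2 * dt`, so the 2-D mean squared displacement at lag `t` is
#' `2 sigma^2 t`.
#'
#' @param n number of tracks.
#' @param length positions per track (>= 2).
#' @param sigma diffusion coefficient (pixel units per sqrt(frame)).
#' @param dt frame interval in frame units (default 1).
#' @param start 2-vector starting position (all tracks).
#' @param seed RNG seed (`NULL` to use the current stream).
#' @param id_prefix prefix for generated track ids.
#' @return A [track_set] of `n` tracks with consecutive frames `0 ... length-1`.
#' @export
simulate_brownian <- function(n, length = 6L, sigma = sqrt(2), dt = 1,
                              start = c(0, 0), seed = NULL, id_prefix = "bm") {
  simulate_drift_diffusion(n, length, sigma, dt, mu = c(0, 0), start = start,
                           seed = seed, id_prefix = id_prefix)
}

#' Simulate directed (drift-diffusion) tracks
#'
#' Transport by a deterministic force plus diffusion:
#' `X_{k+1} = X_k + mu * dt + sigma * sqrt(dt) * xi_k` with `xi_k` standard
#' 2-D Gaussian. With `mu = c(0, 0)` this reduces exactly to
#' [simulate_brownian].
#'
#' @inheritParams simulate_brownian
#' @param mu 2-vector drift (pixels per frame unit).
#' @export
simulate_directed <- function(n, length = 6L, sigma = sqrt(2), mu = c(1, 0),
                              dt = 1, start = c(0, 0), seed = NULL,
                              id_prefix = "dir") {
  simulate_drift_diffusion(n, length, sigma, dt, mu = mu, start = start,
                           seed = seed, id_prefix = id_prefix)
}

simulate_drift_diffusion <- function(n, length, sigma, dt, mu, start, seed,
                                     id_prefix) {
  check_sim_args(n, length, sigma, dt)
  stopifnot(length(mu) == 2, length(start) == 2)
  L <- as.integer(length)
  with_seed(seed, {
    sd_step <- sigma * sqrt(dt)
    dx <- matrix(rnorm(n * (L - 1L), mean = mu[1] * dt, sd = sd_step), n, L - 1L)
    dy <- matrix(rnorm(n * (L - 1L), mean = mu[2] * dt, sd = sd_step), n, L - 1L)
    build_track_set(start[1] + cbind(0, t(apply_cumsum(dx))),
                    start[2] + cbind(0, t(apply_cumsum(dy))), id_prefix)
  })
}

#' Simulate confined (Ornstein-Uhlenbeck) tracks
#'
#' Diffusion under a linear restoring force of strength `lambda` toward a
#' center `mu`: `dX_t = -lambda (X_t - mu) dt + sigma dB_t`. Each step uses
#' the exact discrete-time transition
#' `X_{k+1} = mu + (X_k - mu) e^{-lambda dt} + zeta_k`, with `zeta_k`
#' zero-mean Gaussian of per-coordinate variance
#' `sigma^2 (1 - e^{-2 lambda dt}) / (2 lambda)` — stable for any
#' `lambda >= 0` and identical to the Brownian update at `lambda = 0`.
#' Tracks start at the confinement center (the stationary mean).
#'
#' @inheritParams simulate_brownian
#' @param lambda confinement strength (>= 0, per frame unit).
#' @param mu 2-vector confinement center.
#' @param start starting position; defaults to `mu`.
#' @export
simulate_confined <- function(n, length = 6L, sigma = sqrt(2), lambda = 1,
                              mu = c(0, 0), dt = 1, start = mu, seed = NULL,
                              id_prefix = "ou") {
  check_sim_args(n, length, sigma, dt)
  if (lambda < 0) stopf("`lambda` must be >= 0")
  stopifnot(length(mu) == 2, length(start) == 2)
  L <- as.integer(length)
  a <- exp(-lambda * dt)
  step_var <- if (lambda > 0) sigma^2 * (1 - exp(-2 * lambda * dt)) / (2 * lambda)
  else sigma^2 * dt
  with_seed(seed, {
    zx <- matrix(rnorm(n * (L - 1L), sd = sqrt(step_var)), n, L - 1L)
    zy <- matrix(rnorm(n * (L - 1L), sd = sqrt(step_var)), n, L - 1L)
    X <- matrix(0, n, L); Y <- matrix(0, n, L)
    X[, 1] <- start[1]; Y[, 1] <- start[2]
    for (j in 2:L) {
      X[, j] <- mu[1] + (X[, j - 1] - mu[1]) * a + zx[, j - 1]
      Y[, j] <- mu[2] + (Y[, j - 1] - mu[2]) * a + zy[, j - 1]
    }
    build_track_set(X, Y, id_prefix)
  })
}

check_sim_args <- function(n, length, sigma, dt) {
  if (n < 1) stopf("`n` must be >= 1")
  if (length < 2) stopf("`length` must be >= 2")
  if (sigma < 0) stopf("`sigma` must be >= 0")
  if (dt <= 0) stopf("`dt` must be > 0")
}

# X, Y: n x L position matrices -> track_set with 0-based consecutive frames
build_track_set <- function(X, Y, id_prefix) {
  n <- nrow(X); L <- ncol(X)
  ids <- sprintf("%s_%0*d", id_prefix, nchar(n), seq_len(n))
  track_set(data.frame(
    track_id = rep(ids, each = L),
    frame = rep.int(0:(L - 1L), n),
    x = as.vector(t(X)),
    y = as.vector(t(Y))
  ))
}

#' Classification accuracy versus confinement strength
#'
#' For each `lambda` on a grid, simulates `n_per_point` confined
#' (Ornstein-Uhlenbeck) tracklets of `N` increments at diffusion coefficient
#' `sigma`, computes the excursion statistic of each, and reports the fraction
#' falling below the lower Brownian quantile — i.e. correctly labeled
#' confined. At `lambda = 0` the input is Brownian, so the curve starts at the
#' test level `alpha`; it rises toward 1 as confinement strengthens, faster
#' for longer tracklets.
#'
#' @param N increments per simulated tracklet; must equal `quantiles$N`.
#' @param lambda_grid confinement strengths (default `seq(0, 6, by = 0.2)`).
#' @param sigma diffusion coefficient (default `sqrt(2)`).
#' @param n_per_point simulated tracklets per grid point (default 100).
#' @param quantiles a `quantile_table` from [calibrate_quantiles].
#' @param seed RNG seed.
#' @return data.frame `lambda`, `accuracy`, with attributes `N`,
#'   `n_per_point`, `seed`.
#' @export
accuracy_vs_confinement <- function(N = 5L, lambda_grid = seq(0, 6, by = 0.2),
                                    sigma = sqrt(2), n_per_point = 100L,
                                    quantiles, seed = NULL) {
  stopifnot(inherits(quantiles, "quantile_table"))
  if (length(lambda_grid) == 0) stopf("`lambda_grid` must be non-empty")
  if (quantiles$N != N) {
    stopf("quantile table N = %d does not match requested N = %d", quantiles$N, N)
  }
  acc <- with_seed(seed, vapply(lambda_grid, function(lam) {
    ts <- simulate_confined(n_per_point, length = N + 1L, sigma = sigma,
                            lambda = lam)
    X <- matrix(ts$tracks$x, ncol = N + 1L, byrow = TRUE)
    Y <- matrix(ts$tracks$y, ncol = N + 1L, byrow = TRUE)
    S <- excursion_statistic_mat(X, Y)
    mean(S < quantiles$q_lo)
  }, numeric(1)))
  structure(
    data.frame(lambda = lambda_grid, accuracy = acc),
    N = as.integer(N), n_per_point = as.integer(n_per_point), seed = seed
  )
}

#' Mistracking-adjusted classification accuracy
#'
#' Tracking perturbations (mislinking, a genuine change of dynamics) arriving
#' at exponential rate `rho` leave a tracklet of length `N` unperturbed with
#' probability `exp(-rho * N)`, so the probability of correct classification
#' degrades from `p_N(0)` to `p_N(rho) = p_N(0) * exp(-rho * N)`.
#'
#' @param p_N_0 unperturbed accuracy, in \[0, 1\].
#' @param rho perturbation rate (>= 0, per frame).
#' @param N tracklet length.
#' @return The adjusted accuracy.
#' @export
mistracking_adjusted_accuracy <- function(p_N_0, rho, N) {
  if (any(p_N_0 < 0 | p_N_0 > 1)) stopf("`p_N_0` must be in [0, 1]")
  if (any(rho < 0)) stopf("`rho` must be >= 0")
  p_N_0 * exp(-rho * N)
}

#' Simulate a Brownian / confined mixture with ground truth
#'
#' Draws `n` tracks of which a deterministic `ceiling(fraction_confined * n)`
#' are confined (Ornstein-Uhlenbeck) and the rest Brownian, shuffled by the
#' seed, with a ground-truth label per track for benchmarking.
#'
#' @param n total number of tracks.
#' @param fraction_confined fraction of confined tracks in \[0, 1\].
#' @param length positions per track.
#' @param sigma diffusion coefficient (both classes).
#' @param lambda confinement strength of the confined class.
#' @param dt frame interval (frame units).
#' @param seed RNG seed.
#' @return A list: `tracks` (a [track_set]) and `truth` (data.frame
#'   `track_id`, `true_model`, `lambda`, `sigma`).
#' @export
simulate_mixture <- function(n, fraction_confined = 0.5, length = 6L,
                             sigma = sqrt(2), lambda = 6, dt = 1, seed = NULL) {
  if (fraction_confined < 0 || fraction_confined > 1) {
    stopf("`fraction_confined` must be in [0, 1]")
  }
  n_conf <- as.integer(ceiling(fraction_confined * n))
  n_bm <- n - n_conf
  with_seed(seed, {
    model <- sample(rep(c("confined", "brownian"), c(n_conf, n_bm)))
    L <- as.integer(length)
    X <- matrix(0, n, L); Y <- matrix(0, n, L)
    if (n_conf > 0) {
      ou <- simulate_confined(n_conf, length = L, sigma = sigma,
                              lambda = lambda, dt = dt)
      X[model == "confined", ] <- matrix(ou$tracks$x, ncol = L, byrow = TRUE)
      Y[model == "confined", ] <- matrix(ou$tracks$y, ncol = L, byrow = TRUE)
    }
    if (n_bm > 0) {
      bm <- simulate_brownian(n_bm, length = L, sigma = sigma, dt = dt)
      X[model == "brownian", ] <- matrix(bm$tracks$x, ncol = L, byrow = TRUE)
      Y[model == "brownian", ] <- matrix(bm$tracks$y, ncol = L, byrow = TRUE)
    }
    ts <- build_track_set(X, Y, "mix")
    truth <- data.frame(
      track_id = unique(ts$tracks$track_id),
      true_model = model,
      lambda = ifelse(model == "confined", lambda, 0),
      sigma = sigma
    )
    list(tracks = ts, truth = truth)
  })
}
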