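#' Fit a 1-D Gaussian mixture to spot intensities
#'
#' Maximum-likelihood fit by expectation-maximization of the density
#' `e(x) = sum_i alpha_i * Normal(mu_i, sigma2_i)` with `p` components,
#' free weights, means and per-component variances (`k = 3p - 1` free
#' parameters). Initialization is by seeded k-means on the sample; the best of
#' `n_restarts` runs by log-likelihood is kept, and components are returned
#' sorted by mean. In spot-intensity stoichiometry each component is read as
#' an oligomeric species whose mean is a multiple of the single-fluorophore
#' brightness.
#'
#' @param intensities numeric sample (length >= 3p).
#' @param p number of Gaussian components (>= 1).
#' @param seed RNG seed for initialization.
#' @param n_restarts EM restarts (default 10).
#' @param tol stop when the log-likelihood gain per iteration falls below
#'   this (default 1e-6).
#' @param max_iter maximum EM iterations per restart.
#' @return An object of class `intensity_mixture`: `p`, `weights`, `means`,
#'   `variances`, `log_likelihood`, `aic`, `k` (= 3p - 1), `n`, `n_iter`.
#' @export
fit_mixture <- function(intensities, p, seed = NULL, n_restarts = 10L,
                        tol = 1e-6, max_iter = 500L) {
  x <- as.numeric(intensities)
  if (p < 1) stopf("`p` must be >= 1")
  n <- length(x)
  if (n < 3 * p) stopf("need at least 3p = %d observations to fit %d components", 3 * p, p)

  if (p == 1L) {
    mu <- mean(x)
    v <- mean((x - mu)^2)  # ML variance
    ll <- sum(dnorm(x, mu, sqrt(v), log = TRUE))
    return(new_intensity_mixture(1L, 1, mu, v, ll, n, 0L))
  }

  var_floor <- 1e-6 * stats::var(x)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(em_gmm1d(x, p, tol, max_iter, var_floor),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
    }
    if (is.null(best)) {
      stopf("EM failed in all %d restarts (degenerate components)", n_restarts)
    }
    ord <- order(best$mu)
    new_intensity_mixture(as.integer(p), best$w[ord], best$mu[ord],
                          best$v[ord], best$ll, n, best$iter)
  })
}

new_intensity_mixture <- function(p, w, mu, v, ll, n, iter) {
  k <- 3L * p - 1L
  structure(
    list(p = p, weights = w, means = mu, variances = v,
         log_likelihood = ll, aic = 2 * k - 2 * ll, k = k, n = n,
         n_iter = iter),
    class = "intensity_mixture"
  )
}

em_gmm1d <- function(x, p, tol, max_iter, var_floor) {
  n <- length(x)
  km <- suppressWarnings(kmeans(x, centers = p, nstart = 1, iter.max = 50))
  mu <- as.numeric(km$centers)
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(p)))) / n
  v <- vapply(seq_len(p), function(i) {
    xi <- x[km$cluster == i]
    max(mean((xi - mu[i])^2), var_floor)
  }, numeric(1))
  w <- pmax(w, 1e-8); w <- w / sum(w)

  ll_old <- -Inf
  iter <- 0L
  ll_trace <- numeric(0)
  repeat {
    iter <- iter + 1L
    dens <- vapply(seq_len(p), function(i) w[i] * dnorm(x, mu[i], sqrt(v[i])),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    if (any(rowsum_d <= 0) || any(!is.finite(rowsum_d))) stop("degenerate fit")
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("empty component")
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- vapply(seq_len(p), function(i) {
      max(sum(resp[, i] * (x - mu[i])^2) / nk[i], var_floor)
    }, numeric(1))
    if (ll - ll_old < tol && iter > 1L) break
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(w = w, mu = mu, v = v, ll = ll, iter = iter, ll_trace = ll_trace)
}

#' @export
print.intensity_mixture <- function(x, ...) {
  cat(sprintf("<intensity_mixture> p = %d (k = %d), logL = %.2f, AIC = %.2f\n",
              x$p, x$k, x$log_likelihood, x$aic))
  for (i in seq_len(x$p)) {
    cat(sprintf("  component %d: weight %.3f, mean %.1f, sd %.1f\n",
                i, x$weights[i], x$means[i], sqrt(x$variances[i])))
  }
  invisible(x)
}

#' @export
logLik.intensity_mixture <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, nobs = object$n,
            class = "logLik")
}

#' Akaike information criterion of a fitted mixture
#'
#' `AIC_p = 2 k_p - 2 log(L_p)` with `k_p = 3p - 1` free parameters
#' (`p - 1` weights, `p` means, `p` variances). Equivalent to
#' `stats::AIC(fit)`.
#'
#' @param fit an `intensity_mixture`.
#' @return The AIC value.
#' @export
mixture_aic <- function(fit) {
  stopifnot(inherits(fit, "intensity_mixture"))
  2 * fit$k - 2 * fit$log_likelihood
}

#' Select the number of intensity modes by AIC
#'
#' Fits mixtures with `p = 1 ... p_max` components and returns the `p`
#' minimizing the AIC — the estimated number of distinct oligomeric species in
#' the intensity distribution. Ties (within 1e-9) break toward smaller `p`.
#'
#' @inheritParams fit_mixture
#' @param p_max largest component count to try; counts the sample cannot
#'   support (`n < 3p`) are skipped.
#' @return A list of class `mode_selection`: `p_star`, `fits` (list indexed by
#'   `p`), `aic` (data.frame `p`, `aic`, `log_likelihood`, `k`).
#' @export
select_components <- function(intensities, p_max = 5L, seed = NULL, ...) {
  if (p_max < 1) stopf("`p_max` must be >= 1")
  x <- as.numeric(intensities)
  if (length(x) < 3) stopf("need at least 3 observations")
  ps <- seq_len(p_max)
  ps <- ps[length(x) >= 3 * ps]
  fits <- lapply(ps, function(p) {
    fit_mixture(x, p, seed = if (is.null(seed)) NULL else seed + p, ...)
  })
  aics <- vapply(fits, mixture_aic, numeric(1))
  p_star <- ps[which(aics <= min(aics) + 1e-9)[1]]
  structure(
    list(
      p_star = p_star,
      fits = setNames(fits, ps),
      aic = data.frame(p = ps, aic = aics,
                       log_likelihood = vapply(fits, function(f) f$log_likelihood, numeric(1)),
                       k = vapply(fits, function(f) f$k, integer(1)))
    ),
    class = "mode_selection"
  )
}

#' @export
print.mode_selection <- function(x, ...) {
  cat(sprintf("<mode_selection> p* = %d by AIC\n", x$p_star))
  print(x$aic, row.names = FALSE)
  invisible(x)
}

#' Assign intensities to mixture modes
#'
#' Each observation goes to the component with the largest posterior
#' `alpha_i * Normal(x; mu_i, sigma2_i)` — its estimated oligomeric species.
#' Posterior ties break toward the lower-mean component.
#'
#' @param intensities numeric sample.
#' @param fit an `intensity_mixture` (components sorted by mean).
#' @return A list: `labels` (component index per observation) and `fractions`
#'   (population fraction per component).
#' @export
assign_modes <- function(intensities, fit) {
  stopifnot(inherits(fit, "intensity_mixture"))
  x <- as.numeric(intensities)
  post <- vapply(seq_len(fit$p), function(i) {
    fit$weights[i] * dnorm(x, fit$means[i], sqrt(fit$variances[i]))
  }, numeric(length(x)))
  post <- matrix(post, nrow = length(x))
  labels <- apply(post, 1, which.max)  # first max = lower mean on ties
  fractions <- tabulate(labels, nbins = fit$p) / length(x)
  list(labels = labels, fractions = fractions)
}

#' Synthetic spot-intensity scenarios
#'
#' Presets mirror a receptor whose single-fluorophore brightness is ~300 au:
#' `"wt"` draws from modes 300/600/900 au with weights 0.5/0.4/0.1 (monomer,
#' dimer, trimer-like species); `"l196k"` (an oligomerization-impaired
#' mutant-like preset) from 300/600 au with weights 0.75/0.25. Common
#' component sd 60 au.
#'
#' @param name `"wt"` or `"l196k"`.
#' @return A list: `means`, `weights`, `sd`.
#' @export
stoichiometry_scenario <- function(name = c("wt", "l196k")) {
  name <- match.arg(name)
  switch(name,
    wt = list(means = c(300, 600, 900), weights = c(0.5, 0.4, 0.1), sd = 60),
    l196k = list(means = c(300, 600), weights = c(0.75, 0.25), sd = 60)
  )
}

#' Draw a synthetic spot-intensity sample
#'
#' @param n sample size.
#' @param means component means (au).
#' @param weights component weights (sum 1).
#' @param sd common component standard deviation (au), or one per component.
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_intensities <- function(n, means = c(300, 600, 900),
                                 weights = c(0.5, 0.4, 0.1), sd = 60,
                                 seed = NULL) {
  if (n < 0) stopf("`n` must be >= 0")
  if (length(weights) != length(means)) stopf("`means` and `weights` lengths differ")
  if (abs(sum(weights) - 1) > 1e-8) stopf("`weights` must sum to 1")
  sds <- rep_len(sd, length(means))
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
    rnorm(n, mean = means[comp], sd = sds[comp])
  })
}
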