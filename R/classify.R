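#' Classifier configuration
#'
#' @param N increments per tracklet (default 5).
#' @param alpha two-sided test level for the Brownian null (default 0.05).
#' @param object_size_l apparent object size `l` in pixels (default 2).
#' @param immobility_factor multiple of `l` below which the maximal pairwise
#'   displacement marks a tracklet immobile. The default `sqrt(2)` makes the
#'   threshold the diagonal of the square of edge `l`; set 2 for the looser
#'   reading.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(N = 5L, alpha = 0.05, object_size_l = 2,
                              immobility_factor = sqrt(2)) {
  if (N < 2) stopf("`N` must be >= 2")
  if (alpha <= 0 || alpha > 0.5) stopf("`alpha` must be in (0, 0.5]")
  if (object_size_l <= 0 || immobility_factor <= 0) {
    stopf("`object_size_l` and `immobility_factor` must be positive")
  }
  structure(
    list(N = as.integer(N), alpha = alpha, object_size_l = object_size_l,
         immobility_factor = immobility_factor),
    class = "classifier_config"
  )
}

#' The four motion labels
#' @export
motion_labels <- function() c("immobile", "confined", "brownian", "directed")

as_positions <- function(tracklet) {
  if (is.list(tracklet) && !is.null(tracklet$positions)) tracklet$positions
  else if (is.matrix(tracklet) && ncol(tracklet) == 2) tracklet
  else stopf("a tracklet is a list with a `positions` matrix or an n x 2 matrix")
}

#' Immobility test
#'
#' A tracklet is immobile when the maximal Euclidean distance between any two
#' of its positions stays below `immobility_factor * object_size_l`
#' (by default `sqrt(2) * l`, the diagonal of the square of edge `l`): the
#' particle never left a box the size of the object itself.
#'
#' @param tracklet a tracklet (see [split_track]) or an `n x 2` position matrix.
#' @param config a [classifier_config].
#' @return `TRUE` if immobile.
#' @export
is_immobile <- function(tracklet, config = classifier_config()) {
  P <- as_positions(tracklet)
  if (nrow(P) < 2) stopf("immobility test needs at least 2 positions")
  max(stats::dist(P)) < config$immobility_factor * config$object_size_l
}

#' Maximal-excursion statistic of a tracklet
#'
#' The test statistic for motion classification: the maximal distance reached
#' from the starting point, normalised by the root of half the summed squared
#' step lengths,
#' \deqn{S = \max_{i=0..N} \|X_i - X_0\| \Big/ \sqrt{\tfrac12 \sum_{i=1}^N \|X_i - X_{i-1}\|^2}.}
#' Under 2-D Brownian motion its distribution depends only on `N`; confinement
#' pushes it down, directed transport pushes it up. `S` is invariant under
#' translation, rotation and uniform scaling of the tracklet.
#'
#' @inheritParams is_immobile
#' @return The statistic, a positive scalar.
#' @export
excursion_statistic <- function(tracklet) {
  P <- as_positions(tracklet)
  if (nrow(P) < 2) stopf("tracklet must have at least 2 positions")
  d <- diff(P)
  ss <- sum(d * d)
  if (ss == 0) stopf("degenerate tracklet: all increments are zero (run is_immobile first)")
  excursion <- sqrt((P[, 1] - P[1, 1])^2 + (P[, 2] - P[1, 2])^2)
  max(excursion) / sqrt(0.5 * ss)
}

# Vectorised excursion statistic over many tracklets: X, Y are
# n x (N+1) position matrices, one tracklet per row.
excursion_statistic_mat <- function(X, Y) {
  n <- nrow(X)
  m <- ncol(X)
  dx <- X[, -1, drop = FALSE] - X[, -m, drop = FALSE]
  dy <- Y[, -1, drop = FALSE] - Y[, -m, drop = FALSE]
  denom <- sqrt(0.5 * rowSums(dx * dx + dy * dy))
  num <- rep(0, n)
  for (j in 2:m) {
    num <- pmax(num, sqrt((X[, j] - X[, 1])^2 + (Y[, j] - Y[, 1])^2))
  }
  num / denom
}

# Vectorised immobility test: TRUE where the max pairwise distance among the
# (N+1) row positions is below `thr`.
immobile_mat <- function(X, Y, thr) {
  n <- nrow(X)
  m <- ncol(X)
  mx <- rep(0, n)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      mx <- pmax(mx, (X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2)
    }
  }
  sqrt(mx) < thr
}

#' Monte Carlo calibration of Brownian null quantiles
#'
#' Simulates `n_mc` pure Brownian tracklets of `N` i.i.d. Gaussian increments
#' in `dim` dimensions, computes the excursion statistic for each, and returns
#' the empirical quantiles of order `alpha` and `1 - alpha`. These are the
#' classification thresholds: the statistic's null distribution depends only
#' on `N` (and `dim`), not on the diffusion coefficient or frame interval, so
#' one table serves any acquisition.
#'
#' For the default planar convention (`dim = 2`, matching the 2-D statistic
#' computed on tracklets) with `N = 5`, `alpha = 0.05`, the thresholds are
#' approximately 0.798 and 2.317, and classifying Brownian input against them
#' yields confined/directed fractions of exactly `alpha` each. Thresholds of
#' about 0.727 and 2.484 — close to the 0.724/2.464 often quoted for this
#' statistic — arise instead from a one-dimensional calibration over five
#' positions (`N = 4`, `dim = 1`); mixing that calibration with the 2-D
#' statistic shifts the realized test levels to roughly 2.5% (confined) and
#' 3.5% (directed). See the package vignette.
#'
#' @param N increments per tracklet.
#' @param alpha quantile order in (0, 0.5].
#' @param n_mc number of Monte Carlo replicates (>= 10000; default 1e6).
#' @param seed RNG seed (required, for a reproducible table).
#' @param dim dimension of the simulated Brownian null (default 2; must match
#'   the dimension of the data statistic for the test level to be exact).
#' @return A list of class `quantile_table`: `N`, `alpha`, `q_lo`, `q_hi`,
#'   `n_mc`, `seed`, `dim`.
#' @examples
#' calibrate_quantiles(N = 5, alpha = 0.05, n_mc = 1e4, seed = 1)
#' @export
calibrate_quantiles <- function(N = 5L, alpha = 0.05, n_mc = 1e6, seed,
                                dim = 2L) {
  if (N < 2) stopf("`N` must be >= 2")
  if (alpha <= 0 || alpha > 0.5) stopf("`alpha` must be in (0, 0.5]")
  if (n_mc < 1e4) stopf("`n_mc` must be at least 10000")
  if (!dim %in% c(1L, 2L)) stopf("`dim` must be 1 or 2")
  if (missing(seed) || is.null(seed)) stopf("`seed` is required for a reproducible table")
  n_mc <- as.integer(n_mc)
  s <- with_seed(seed, {
    dx <- matrix(rnorm(n_mc * N), n_mc, N)
    dy <- if (dim == 2L) matrix(rnorm(n_mc * N), n_mc, N) else matrix(0, n_mc, N)
    X <- cbind(0, t(apply_cumsum(dx)))
    Y <- if (dim == 2L) cbind(0, t(apply_cumsum(dy))) else matrix(0, n_mc, N + 1L)
    excursion_statistic_mat(X, Y)
  })
  q <- quantile(s, c(alpha, 1 - alpha), type = 1, names = FALSE)
  structure(
    list(N = as.integer(N), alpha = alpha, q_lo = q[1], q_hi = q[2],
         n_mc = n_mc, seed = seed, dim = as.integer(dim)),
    class = "quantile_table"
  )
}

# column-wise running sum, returned transposed (N x n) to avoid an apply()
# over a million rows
apply_cumsum <- function(m) {
  out <- t(m)
  if (nrow(out) > 1) {
    for (j in 2:nrow(out)) out[j, ] <- out[j, ] + out[j - 1, ]
  }
  out
}

#' @export
print.quantile_table <- function(x, ...) {
  cat(sprintf(
    "<quantile_table> N = %d, alpha = %g: q_lo = %.4f, q_hi = %.4f (n_mc = %d, seed = %s)\n",
    x$N, x$alpha, x$q_lo, x$q_hi, x$n_mc, format(x$seed)
  ))
  invisible(x)
}

#' Serialise / read a quantile table
#'
#' @param qt a `quantile_table` (from [calibrate_quantiles]).
#' @param path file path for the JSON document.
#' @return `read_quantile_table` returns a `quantile_table`.
#' @export
write_quantile_table <- function(qt, path) {
  stopifnot(inherits(qt, "quantile_table"))
  jsonlite::write_json(unclass(qt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_quantile_table
#' @export
read_quantile_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("N", "alpha", "q_lo", "q_hi")
  if (!all(required %in% names(x))) stopf("%s is not a quantile table document", path)
  structure(
    list(N = as.integer(x$N), alpha = x$alpha, q_lo = x$q_lo, q_hi = x$q_hi,
         n_mc = x$n_mc %||% NA_integer_, seed = x$seed %||% NA_integer_,
         dim = x$dim %||% 2L),
    class = "quantile_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a single tracklet
#'
#' Applies the immobility test first; mobile tracklets are labeled by the
#' excursion statistic against the Brownian null quantiles: `confined` if
#' `S < q_lo`, `directed` if `S >= q_hi`, `brownian` in between.
#'
#' @inheritParams is_immobile
#' @param quantiles a `quantile_table` whose `N` matches the tracklet.
#' @return A list with `S` (`NA` for immobile tracklets) and `label`.
#' @export
classify_tracklet <- function(tracklet, quantiles, config = classifier_config()) {
  P <- as_positions(tracklet)
  if (nrow(P) != quantiles$N + 1L) {
    stopf("tracklet has %d increments but the quantile table was calibrated for N = %d",
          nrow(P) - 1L, quantiles$N)
  }
  if (is_immobile(P, config)) {
    return(list(S = NA_real_, label = "immobile"))
  }
  S <- excursion_statistic(P)
  label <- if (S < quantiles$q_lo) "confined"
  else if (S >= quantiles$q_hi) "directed"
  else "brownian"
  list(S = S, label = label)
}

#' Classify every tracklet of a track set
#'
#' The full local-classification pipeline: tracks are (optionally) screened by
#' the virtual-detection quality filter, split into tracklets of `config$N`
#' increments, and each tracklet is labeled immobile / confined / brownian /
#' directed.
#'
#' @param ts a [track_set].
#' @param quantiles a `quantile_table` (see [calibrate_quantiles]) with
#'   `N == config$N`.
#' @param config a [classifier_config].
#' @param filter apply [filter_virtual] track screening first (default `TRUE`).
#' @param max_fraction,max_run,rule passed to [filter_virtual].
#' @return A data.frame with one row per tracklet: `track_id`, `cell_id`,
#'   `tracklet_index`, `start_frame`, `S` (`NA` when immobile) and `label`
#'   (factor with levels immobile, confined, brownian, directed).
#' @export
classify_tracks <- function(ts, quantiles, config = classifier_config(),
                            filter = TRUE, max_fraction = 0.10, max_run = 3L,
                            rule = c("either", "both")) {
  stopifnot(inherits(ts, "track_set"), inherits(quantiles, "quantile_table"))
  rule <- match.arg(rule)
  if (quantiles$N != config$N) {
    stopf("quantile table N = %d does not match config N = %d", quantiles$N, config$N)
  }
  df <- ts$tracks
  empty <- data.frame(
    track_id = character(), cell_id = character(), tracklet_index = integer(),
    start_frame = integer(), S = numeric(),
    label = factor(character(), levels = motion_labels())
  )
  if (nrow(df) == 0) return(empty)

  # df is sorted by (track_id, frame); locate each track as a contiguous block
  r <- rle(df$track_id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  if (filter) {
    keep <- vapply(seq_along(starts), function(i) {
      filter_virtual(df$is_virtual[starts[i]:ends[i]],
                     max_fraction = max_fraction, max_run = max_run, rule = rule)
    }, logical(1))
  } else {
    keep <- rep(TRUE, length(starts))
  }

  N <- config$N
  n_tl <- pmax(0L, (r$lengths - 1L) %/% N) * keep
  total <- sum(n_tl)
  if (total == 0) return(empty)

  # row index of the first position of every tracklet, then the (N+1) offsets
  tl_track <- rep(seq_along(starts), n_tl)
  tl_k <- sequence(n_tl) - 1L
  first_row <- starts[tl_track] + N * tl_k
  idx <- outer(first_row, 0:N, `+`)  # total x (N+1) row indices

  X <- matrix(df$x[idx], nrow = total)
  Y <- matrix(df$y[idx], nrow = total)

  thr <- config$immobility_factor * config$object_size_l
  imm <- immobile_mat(X, Y, thr)
  S <- excursion_statistic_mat(X, Y)
  label <- ifelse(imm, "immobile",
                  ifelse(S < quantiles$q_lo, "confined",
                         ifelse(S >= quantiles$q_hi, "directed", "brownian")))
  S[imm] <- NA_real_
  data.frame(
    track_id = df$track_id[first_row],
    cell_id = df$cell_id[first_row],
    tracklet_index = tl_k,
    start_frame = df$frame[first_row],
    S = S,
    label = factor(label, levels = motion_labels())
  )
}

#' Write a classification table
#'
#' @param cls classification data.frame from [classify_tracks].
#' @param path output CSV path.
#' @export
write_classification <- function(cls, path) {
  write.csv(cls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
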