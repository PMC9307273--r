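# Shared fixtures, built in code.

# Memoised default-convention quantile table for unit tests (moderate n_mc;
# the acceptance suite calibrates its own full-size table).
.qt_cache <- new.env(parent = emptyenv())
test_quantiles <- function(N = 5L, n_mc = 5e4, seed = 424242) {
  key <- sprintf("N%d_%d_%d", N, n_mc, seed)
  if (is.null(.qt_cache[[key]])) {
    .qt_cache[[key]] <- calibrate_quantiles(N = N, alpha = 0.05, n_mc = n_mc,
                                            seed = seed)
  }
  .qt_cache[[key]]
}

# A quantile table with hand-set thresholds, for boundary-convention tests.
fixed_quantiles <- function(q_lo, q_hi, N = 5L, alpha = 0.05) {
  structure(
    list(N = as.integer(N), alpha = alpha, q_lo = q_lo, q_hi = q_hi,
         n_mc = NA_integer_, seed = NA_integer_, dim = 2L),
    class = "quantile_table"
  )
}

# straight unit-step track along x: S = L-1 / sqrt((L-1)/2) on each tracklet
line_track <- function(id = "line", L = 6L, cell = NA_character_) {
  data.frame(track_id = id, cell_id = cell, frame = 0:(L - 1L),
             x = as.numeric(0:(L - 1L)), y = 0)
}

# alternating (0,0)/(amp,0) positions: maximal excursion `amp`; pick
# amp > 2*sqrt(2) to stay clear of the immobility test
alternating_track <- function(id = "alt", L = 6L, amp = 1, cell = NA_character_) {
  data.frame(track_id = id, cell_id = cell, frame = 0:(L - 1L),
             x = as.numeric(rep_len(c(0, amp), L)), y = 0)
}

frozen_track <- function(id = "ice", L = 6L, x0 = 3, y0 = 4) {
  data.frame(track_id = id, cell_id = NA_character_, frame = 0:(L - 1L),
             x = x0, y = y0)
}

# random mobile tracklet positions, guaranteed non-degenerate
random_tracklet <- function(n_pos = 6L) {
  cbind(x = cumsum(c(0, rnorm(n_pos - 1L, sd = 2))),
        y = cumsum(c(0, rnorm(n_pos - 1L, sd = 2))))
}

rotate <- function(P, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  P %*% R
}

# noiseless rendered frame (background + spots), for detector ground truths
noiseless_frame <- function(x, y, params) {
  matrix(params$background * params$gain + params$offset,
         params$field_px, params$field_px) +
    params$gain * sptmotion:::spot_image(x, y, params)
}
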