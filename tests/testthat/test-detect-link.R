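test_that("detection finds isolated spots with sub-pixel accuracy and no false alarms", {
  p <- imaging_params(field_px = 100, n_frames = 1, target_snr = 10)

  # featureless frame: nothing to detect
  expect_equal(nrow(detect_spots(matrix(130, 100, 100))), 0L)

  set.seed(90)
  frame <- matrix(rpois(100 * 100, 50) + 100, 100, 100)
  expect_lte(nrow(detect_spots(frame)), 1L)  # pure noise: at most a stray peak

  # one spot at a sub-pixel position, SNR 10
  ts <- track_set(data.frame(track_id = "s", frame = 0L, x = 50.4, y = 49.7))
  m <- render_timelapse(ts, p, seed = 91)
  d <- detect_spots(m$frames[[1]])
  expect_equal(nrow(d), 1L)
  expect_lt(sqrt((d$x - 50.4)^2 + (d$y - 49.7)^2), 0.5)

  # two spots 20 px apart
  ts2 <- track_set(data.frame(track_id = c("a", "b"), frame = 0L,
                              x = c(40, 60), y = 50))
  m2 <- render_timelapse(ts2, p, seed = 92)
  expect_equal(nrow(detect_spots(m2$frames[[1]])), 2L)
})

test_that("detection on noiseless renders has perfect recall and precision", {
  p <- imaging_params(field_px = 120, n_frames = 1, target_snr = 10)
  set.seed(93)
  x <- runif(12, 15, 105); y <- runif(12, 15, 105)
  frame <- noiseless_frame(x, y, p)
  d <- detect_spots(frame)
  expect_equal(nrow(d), 12L)
  dist_to_truth <- vapply(seq_len(nrow(d)), function(k) {
    sqrt(min((x - d$x[k])^2 + (y - d$y[k])^2))
  }, numeric(1))
  expect_true(all(dist_to_truth < 0.5))
})

test_that("ROI intensity is background-subtracted and linear in amplitude", {
  expect_equal(measure_spot_intensity(matrix(7, 30, 30), c(15, 15)), 0)

  p <- imaging_params(field_px = 41, n_frames = 1, target_snr = 40)
  frame <- noiseless_frame(21, 21, p)
  total <- p$gain * p$peak_amplitude * 2 * pi * p$psf_sigma^2
  measured <- measure_spot_intensity(frame, c(21, 21), radius = 2)
  corrected <- measured / psf_mass_fraction(2, p$psf_sigma)
  expect_lt(abs(corrected - total) / total, 0.15)

  p2 <- imaging_params(field_px = 41, n_frames = 1,
                       peak_amplitude = 2 * p$peak_amplitude)
  frame2 <- noiseless_frame(21, 21, p2)
  expect_lt(abs(measure_spot_intensity(frame2, c(21, 21)) / measured - 2), 0.05)

  expect_error(measure_spot_intensity(matrix(0, 30, 30), c(2, 15)), "border")
})

test_that("nearest-neighbor linking reconstructs simple motions", {
  # one spot drifting less than max_disp per frame -> one track
  det <- data.frame(frame = 0:9, x = seq(10, 19), y = 5)
  ts <- link_nearest_neighbor(det, max_disp = 3)
  expect_length(unique(ts$tracks$track_id), 1L)
  expect_equal(nrow(ts$tracks), 10L)

  # two distant stationary spots -> two parallel tracks
  det2 <- data.frame(frame = rep(0:4, each = 2), x = rep(c(10, 40), 5),
                     y = rep(c(10, 40), 5))
  ts2 <- link_nearest_neighbor(det2, max_disp = 3)
  expect_length(unique(ts2$tracks$track_id), 2L)

  # a jump beyond max_disp breaks the track
  det3 <- data.frame(frame = 0:5, x = c(1, 2, 3, 30, 31, 32), y = 0)
  ts3 <- link_nearest_neighbor(det3, max_disp = 5)
  expect_length(unique(ts3$tracks$track_id), 2L)

  # permutation invariance over detection input order
  set.seed(94)
  det4 <- data.frame(frame = rep(0:5, each = 4),
                     x = rep(c(10, 25, 40, 55), 6) + rnorm(24, sd = 0.5),
                     y = rep(c(10, 25, 40, 55), 6) + rnorm(24, sd = 0.5))
  ref <- link_nearest_neighbor(det4, max_disp = 4)
  shuffled <- det4[sample(nrow(det4)), ]
  alt <- link_nearest_neighbor(shuffled, max_disp = 4)
  key <- function(ts) {
    df <- ts$tracks[order(ts$tracks$x), ]
    split(paste(df$frame, round(df$x, 6), round(df$y, 6)), df$track_id)
  }
  expect_setequal(unname(key(ref)), unname(key(alt)))
})

test_that("detect-link recovers ground-truth links at low density and high SNR", {
  # sparse field at SNR 10: most frame-to-frame links should be correct
  mix <- simulate_mixture(15, 0.5, length = 12, lambda = 6, seed = 95)
  placed <- sptmotion:::scatter_tracks(mix$tracks, 300, margin = 10)
  p <- imaging_params(field_px = 300, n_frames = 12, target_snr = 10)
  m <- render_timelapse(placed, p, seed = 96)
  det <- do.call(rbind, lapply(seq_along(m$frames), function(f) {
    d <- detect_spots(m$frames[[f]])
    if (nrow(d) > 0) d$frame <- f - 1L
    d
  }))
  linked <- link_nearest_neighbor(det, max_disp = 5)
  # correct links stay near one ground-truth particle: check per-track position
  # scatter relative to matched truth
  gt <- placed$tracks
  n_links <- 0L; n_good <- 0L
  for (id in unique(linked$tracks$track_id)) {
    tr <- linked$tracks[linked$tracks$track_id == id, ]
    if (nrow(tr) < 2) next
    # match by first detection
    g0 <- gt[gt$frame == tr$frame[1], ]
    j <- which.min((g0$x - tr$x[1])^2 + (g0$y - tr$y[1])^2)
    truth <- gt[gt$track_id == g0$track_id[j], ]
    for (r in 2:nrow(tr)) {
      tru <- truth[truth$frame == tr$frame[r], ]
      n_links <- n_links + 1L
      if (nrow(tru) == 1 &&
          sqrt((tru$x - tr$x[r])^2 + (tru$y - tr$y[r])^2) < 1.5) {
        n_good <- n_good + 1L
      }
    }
  }
  expect_gt(n_links, 100)
  expect_gte(n_good / n_links, 0.9)
})
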