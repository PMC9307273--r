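test_that("immobility triggers only below the object-diagonal threshold", {
  cfg <- classifier_config()  # l = 2, factor sqrt(2): threshold ~2.828 px
  expect_true(is_immobile(matrix(c(3, 3, 3, 3, 3, 3, 4, 4, 4, 4, 4, 4), 6, 2)))
  # a 3 px displacement exceeds 2*sqrt(2)
  P <- cbind(c(0, 3, 0, 0, 0, 0), rep(0, 6))
  expect_false(is_immobile(P, cfg))
  # everything inside the unit square: max pairwise <= sqrt(2) < 2.828
  set.seed(1)
  Q <- cbind(runif(6), runif(6))
  expect_true(is_immobile(Q, cfg))
  # the looser "2 l" reading changes the verdict for spans in (2.83, 4)
  P3 <- cbind(c(0, 3.5, rep(0, 4)), rep(0, 6))
  expect_false(is_immobile(P3, cfg))
  expect_true(is_immobile(P3, classifier_config(immobility_factor = 2)))
})

test_that("excursion statistic matches hand-computed values and is similarity-invariant", {
  line <- cbind(0:5, rep(0, 6))
  expect_equal(excursion_statistic(line), 5 / sqrt(2.5))
  alt <- cbind(c(0, 1, 0, 1, 0, 1), rep(0, 6))
  expect_equal(excursion_statistic(alt), 1 / sqrt(2.5))
  expect_error(excursion_statistic(matrix(1, 6, 2)), "degenerate")

  set.seed(42)
  for (i in 1:20) {
    P <- random_tracklet()
    s <- excursion_statistic(P)
    expect_equal(excursion_statistic(P * 7.3), s)
    expect_equal(excursion_statistic(sweep(P, 2, c(-12, 40), `+`)), s)
    expect_equal(excursion_statistic(rotate(P, runif(1, 0, 2 * pi))), s)
  }
})

test_that("null calibration is reproducible and depends only on N", {
  qt1 <- calibrate_quantiles(5, 0.05, 1e4, seed = 9)
  qt2 <- calibrate_quantiles(5, 0.05, 1e4, seed = 9)
  expect_identical(qt1[c("q_lo", "q_hi")], qt2[c("q_lo", "q_hi")])
  expect_true(qt1$q_lo < qt1$q_hi)

  # two independent calibrations agree within Monte Carlo error
  qt3 <- calibrate_quantiles(5, 0.05, 5e4, seed = 10)
  qt4 <- calibrate_quantiles(5, 0.05, 5e4, seed = 11)
  expect_lt(abs(qt3$q_lo - qt4$q_lo), 0.02)
  expect_lt(abs(qt3$q_hi - qt4$q_hi), 0.05)

  # the statistic is scale-free: quantiles insensitive to the step variance
  # used by the data simulator (classification fractions tested below)
  qt_med <- calibrate_quantiles(5, 0.5, 1e4, seed = 12)
  expect_identical(qt_med$q_lo, qt_med$q_hi)

  expect_error(calibrate_quantiles(5, 0.6, 1e4, seed = 1), "alpha")
  expect_error(calibrate_quantiles(5, 0.05, 100, seed = 1), "n_mc")
  expect_error(calibrate_quantiles(5, 0.05, 1e4), "seed")
})

test_that("quantile monotonicity in alpha", {
  alphas <- c(0.05, 0.15, 0.3, 0.5)
  qts <- lapply(alphas, function(a) calibrate_quantiles(5, a, 2e4, seed = 77))
  q_lo <- vapply(qts, `[[`, numeric(1), "q_lo")
  q_hi <- vapply(qts, `[[`, numeric(1), "q_hi")
  expect_true(all(diff(q_lo) >= 0))
  expect_true(all(diff(q_hi) <= 0))
  expect_identical(q_lo[4], q_hi[4])
})

test_that("tracklet labels follow the threshold conventions", {
  qt <- fixed_quantiles(0.724, 2.464)
  cfg <- classifier_config()
  # construct tracklets with prescribed S: straight line scaled has fixed S
  expect_equal(classify_tracklet(cbind(0:5, 0) * 10, qt, cfg)$label, "directed")
  alt <- cbind(c(0, 1, 0, 1, 0, 1) * 10, 0)  # S ~ 0.632 < 0.724
  expect_equal(classify_tracklet(alt, qt, cfg)$label, "confined")
  frozen <- classify_tracklet(matrix(c(1, 1, 1, 1, 1, 1.0001), 6, 2)[, c(1, 1)] * 0 + 1, qt, cfg)
  expect_equal(frozen$label, "immobile")
  expect_true(is.na(frozen$S))

  # boundary: S exactly at q_lo is Brownian; S at q_hi is directed
  P <- cbind(c(0, 1, 0, 1, 0, 1) * 10, 0)
  s_alt <- excursion_statistic(P)
  qt_edge <- fixed_quantiles(q_lo = s_alt, q_hi = 2.464)
  expect_equal(classify_tracklet(P, qt_edge, cfg)$label, "brownian")
  qt_edge2 <- fixed_quantiles(q_lo = 0.1, q_hi = s_alt)
  expect_equal(classify_tracklet(P, qt_edge2, cfg)$label, "directed")

  expect_error(classify_tracklet(cbind(0:6, 0), qt, cfg), "N = 5")
})

test_that("track-set classification agrees with per-tracklet classification", {
  qt <- test_quantiles()
  cfg <- classifier_config()
  ts <- simulate_brownian(40, length = 23, sigma = 1.3, seed = 21)
  cls <- classify_tracks(ts, qt, cfg)
  expect_equal(nrow(cls), 40 * ((23 - 1) %/% 5))

  by_track <- split(ts$tracks, ts$tracks$track_id)
  for (id in names(by_track)[1:10]) {
    tls <- split_track(by_track[[id]], N = 5)
    for (k in seq_along(tls)) {
      ref <- classify_tracklet(tls[[k]], qt, cfg)
      row <- cls[cls$track_id == id & cls$tracklet_index == k - 1L, ]
      expect_equal(as.character(row$label), ref$label)
      expect_equal(row$S, ref$S)
    }
  }
})

test_that("classification pipeline handles degenerate and filtered inputs", {
  qt <- test_quantiles()
  frozen <- track_set(rbind(frozen_track("f1"), frozen_track("f2", x0 = 9)))
  cls <- classify_tracks(frozen, qt)
  expect_true(all(cls$label == "immobile"))

  # mixed fixture: straight lines directed, alternating (mobile) confined
  mixed <- track_set(rbind(line_track("l1"), alternating_track("a1", amp = 10)))
  cls2 <- classify_tracks(mixed, qt)
  expect_equal(as.character(cls2$label[cls2$track_id == "l1"]), "directed")
  expect_equal(as.character(cls2$label[cls2$track_id == "a1"]), "confined")

  # virtual-heavy track is dropped by the filter
  bad <- line_track("v1", L = 10)
  bad$is_virtual <- c(rep(TRUE, 4), rep(FALSE, 6))
  both <- track_set(rbind(cbind(line_track("ok", L = 10), is_virtual = FALSE), bad))
  cls3 <- classify_tracks(both, qt)
  expect_equal(unique(cls3$track_id), "ok")
  expect_equal(nrow(classify_tracks(both, qt, filter = FALSE)), 2L)

  # empty set -> empty result
  empty <- track_set(data.frame(track_id = character(), frame = integer(),
                                x = numeric(), y = numeric()))
  expect_equal(nrow(classify_tracks(empty, qt)), 0L)
})

test_that("Brownian input is labeled at the nominal test level by its own calibration", {
  qt <- test_quantiles(n_mc = 2e5)
  n <- 2e4
  for (sigma in c(1, 10)) {  # scale invariance of the labels
    ts <- simulate_brownian(n, length = 6, sigma = sigma, seed = 33)
    X <- matrix(ts$tracks$x, ncol = 6, byrow = TRUE)
    Y <- matrix(ts$tracks$y, ncol = 6, byrow = TRUE)
    S <- sptmotion:::excursion_statistic_mat(X, Y)
    se3 <- 3 * sqrt(0.05 * 0.95 / n)
    expect_lt(abs(mean(S < qt$q_lo) - 0.05), se3 + 0.002)
    expect_lt(abs(mean(S >= qt$q_hi) - 0.05), se3 + 0.002)
  }
})

test_that("quantile tables serialise to JSON and back", {
  qt <- test_quantiles()
  path <- withr::local_tempfile(fileext = ".json")
  write_quantile_table(qt, path)
  back <- read_quantile_table(path)
  expect_equal(back$q_lo, qt$q_lo)
  expect_equal(back$q_hi, qt$q_hi)
  expect_equal(back$N, qt$N)
  expect_equal(back$dim, qt$dim)
})
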