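# shift a matrix by (dr, dc), zero-filling the vacated edge
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# separable Gaussian smoothing (zero-padded borders)
gauss_smooth <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  tmp <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) tmp <- tmp + k[i] * shift_mat(img, i - r - 1L, 0L)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(tmp, 0L, i - r - 1L)
  out
}

#' Detect spots in a single frame
#'
#' A minimal blob detector standing in for an external tracker's detection
#' stage: the frame is Gaussian-smoothed at the expected PSF scale, a
#' negated discrete Laplacian gives the blob response, and local maxima above
#' a threshold become detections. Sub-pixel positions are intensity-weighted
#' centroids in a 5x5 window; each detection carries a background-subtracted
#' ROI intensity (see [measure_spot_intensity]).
#'
#' @param img numeric matrix (row = y, col = x; pixel centers at integers).
#' @param expected_sigma expected PSF standard deviation in pixels.
#' @param threshold absolute response threshold; `NULL` (default) uses
#'   `threshold_factor` times the robust (MAD) spread of the response.
#' @param threshold_factor multiplier for the automatic threshold (default 5).
#' @param roi_radius ROI radius in pixels for intensity measurement.
#' @return data.frame with `x`, `y` (sub-pixel), `response`, `roi_intensity`.
#' @export
detect_spots <- function(img, expected_sigma = 1.3, threshold = NULL,
                         threshold_factor = 5, roi_radius = 2) {
  stopifnot(is.matrix(img))
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  sm <- gauss_smooth(img, expected_sigma)
  resp <- 4 * sm - shift_mat(sm, 1L, 0L) - shift_mat(sm, -1L, 0L) -
    shift_mat(sm, 0L, 1L) - shift_mat(sm, 0L, -1L)
  if (is.null(threshold)) {
    noise <- mad(resp)
    if (noise == 0) noise <- sd(resp)
    threshold <- threshold_factor * noise
  }
  empty <- data.frame(x = numeric(), y = numeric(), response = numeric(),
                      roi_intensity = numeric())
  if (!is.finite(threshold) || threshold <= 0) return(empty)

  is_max <- resp > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (resp > shift_mat(resp, dr, dc))
  }
  margin <- max(ceiling(2 * expected_sigma) + 2L, as.integer(roi_radius) + 4L)
  nr <- nrow(img); nc <- ncol(img)
  is_max[c(1:margin, (nr - margin + 1):nr), ] <- FALSE
  is_max[, c(1:margin, (nc - margin + 1):nc)] <- FALSE
  peaks <- which(is_max, arr.ind = TRUE)
  if (nrow(peaks) == 0) return(empty)

  out <- lapply(seq_len(nrow(peaks)), function(k) {
    py <- peaks[k, 1]; px <- peaks[k, 2]
    rows <- (py - 2):(py + 2); cols <- (px - 2):(px + 2)
    w <- img[rows, cols]
    w <- pmax(w - median(w), 0)
    tot <- sum(w)
    if (tot == 0) {
      cx <- px; cy <- py
    } else {
      cy <- sum(rows * rowSums(w)) / tot
      cx <- sum(cols * colSums(w)) / tot
    }
    c(x = cx, y = cy, response = resp[py, px],
      roi_intensity = measure_spot_intensity(img, c(cx, cy), radius = roi_radius))
  })
  as.data.frame(do.call(rbind, out))
}

#' Background-subtracted ROI intensity of a spot
#'
#' Sums the pixel values within `radius` of the center and subtracts the local
#' median background (estimated from an annulus between `radius + 1` and
#' `radius + 3`) times the ROI pixel count. Note a radius-2 ROI captures only
#' part of a Gaussian spot's photons; divide by [psf_mass_fraction] to correct.
#'
#' @param img numeric matrix (row = y, col = x).
#' @param center numeric `c(x, y)` in pixel coordinates.
#' @param radius ROI radius in pixels (default 2).
#' @return Background-subtracted summed intensity (counts).
#' @export
measure_spot_intensity <- function(img, center, radius = 2) {
  cx <- center[1]; cy <- center[2]
  outer_r <- radius + 3
  if (cx - outer_r < 1 || cx + outer_r > ncol(img) ||
      cy - outer_r < 1 || cy + outer_r > nrow(img)) {
    stopf("ROI at (%.1f, %.1f) is clipped by the image border", cx, cy)
  }
  cols <- floor(cx - outer_r):ceiling(cx + outer_r)
  rows <- floor(cy - outer_r):ceiling(cy + outer_r)
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  patch <- img[rows, cols]
  in_roi <- d2 <= radius^2
  in_annulus <- d2 > (radius + 1)^2 & d2 <= outer_r^2
  bg <- median(patch[in_annulus])
  sum(patch[in_roi]) - bg * sum(in_roi)
}

#' Link detections into tracks by mutual nearest neighbors
#'
#' Greedy frame-to-frame linking standing in for an external tracker: a
#' detection in frame `t + 1` extends a track ending in frame `t` when the two
#' are mutual nearest neighbors within `max_disp` pixels. Unmatched detections
#' start new tracks; tracks simply end when unmatched (no gap closing, so no
#' virtual detections are produced).
#'
#' @param detections data.frame with columns `frame` (integer), `x`, `y`, and
#'   optionally `roi_intensity`/`intensity`.
#' @param max_disp maximum linking displacement in pixels (> 0).
#' @param pixel_size_um,frame_interval_s metadata for the resulting
#'   [track_set].
#' @return A [track_set].
#' @export
link_nearest_neighbor <- function(detections, max_disp,
                                  pixel_size_um = 0.1,
                                  frame_interval_s = 1 / 30) {
  if (max_disp <= 0) stopf("`max_disp` must be positive")
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  det <- detections[order(detections$frame), , drop = FALSE]
  inten <- det$roi_intensity %||% det$intensity %||% rep(0, nrow(det))
  det$intensity <- inten
  det$track <- NA_integer_
  next_id <- 0L
  frames <- sort(unique(det$frame))

  prev_idx <- integer(0)
  prev_frame <- -Inf
  for (f in frames) {
    cur_idx <- which(det$frame == f)
    if (f == prev_frame + 1 && length(prev_idx) > 0) {
      dx <- outer(det$x[prev_idx], det$x[cur_idx], `-`)
      dy <- outer(det$y[prev_idx], det$y[cur_idx], `-`)
      d <- sqrt(dx * dx + dy * dy)
      best_for_prev <- apply(d, 1, which.min)
      best_for_cur <- apply(d, 2, which.min)
      for (i in seq_along(prev_idx)) {
        j <- best_for_prev[i]
        if (best_for_cur[j] == i && d[i, j] <= max_disp) {
          det$track[cur_idx[j]] <- det$track[prev_idx[i]]
        }
      }
    }
    new <- cur_idx[is.na(det$track[cur_idx])]
    if (length(new) > 0) {
      det$track[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
    prev_frame <- f
  }
  track_set(
    data.frame(
      track_id = sprintf("nn_%06d", det$track),
      frame = det$frame,
      x = det$x, y = det$y,
      intensity = det$intensity
    ),
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s
  )
}

#' End-to-end robustness benchmark on synthetic movies
#'
#' Runs the full pipeline — simulate a Brownian/confined mixture, render a
#' noisy movie, detect, link, classify — over a grid of SNR and spot density,
#' and scores tracklet labels against the simulation ground truth. A detected
#' track inherits the ground-truth model of the nearest true position at its
#' first frame (within `match_radius`). A ground-truth-confined tracklet
#' counts as correct when labeled restricted (immobile or confined); a
#' Brownian one when labeled brownian. The same scoring applied to the
#' noise-free ground-truth tracks gives the reference column
#' `accuracy_truth`.
#'
#' @param snr_grid target SNR values.
#' @param density_grid spot densities (spots per square micrometer); the field
#'   size is derived from `n_spots` and the density.
#' @param n_spots simulated particles per movie.
#' @param n_frames frames per movie.
#' @param fraction_confined,lambda,sigma mixture parameters
#'   (see [simulate_mixture]).
#' @param quantiles a `quantile_table`.
#' @param config a [classifier_config].
#' @param max_disp linker search radius in pixels.
#' @param match_radius ground-truth matching radius in pixels.
#' @param pixel_size_um micrometers per pixel.
#' @param seed RNG seed; tracks are shared across the SNR grid at fixed
#'   density so SNR is the only moving part.
#' @return data.frame with one row per (snr, density):
#'   `snr`, `density`, `field_px`, `n_tracklets`, `accuracy`,
#'   `accuracy_truth`.
#' @export
end_to_end_benchmark <- function(snr_grid = c(2, 6, 10),
                                 density_grid = c(0.039, 0.63),
                                 n_spots = 200L, n_frames = 50L,
                                 fraction_confined = 0.5, lambda = 6,
                                 sigma = sqrt(2), quantiles,
                                 config = classifier_config(),
                                 max_disp = 5, match_radius = 3,
                                 pixel_size_um = 0.1, seed = NULL) {
  stopifnot(inherits(quantiles, "quantile_table"))
  rows <- list()
  for (di in seq_along(density_grid)) {
    dens <- density_grid[di]
    field_px <- as.integer(round(sqrt(n_spots / dens) / pixel_size_um))
    mix <- with_seed(if (is.null(seed)) NULL else seed + di, {
      m <- simulate_mixture(n_spots, fraction_confined, length = n_frames,
                            sigma = sigma, lambda = lambda)
      m$tracks <- scatter_tracks(m$tracks, field_px, margin = 8)
      m
    })
    truth_lab <- setNames(mix$truth$true_model, mix$truth$track_id)

    cls_gt <- classify_tracks(mix$tracks, quantiles, config)
    acc_truth <- score_against_truth(cls_gt$label,
                                     truth_lab[as.character(cls_gt$track_id)])

    gt_by_frame <- split(mix$tracks$tracks, mix$tracks$tracks$frame)
    for (si in seq_along(snr_grid)) {
      snr <- snr_grid[si]
      params <- imaging_params(field_px = field_px, n_frames = n_frames,
                               target_snr = snr, pixel_size_um = pixel_size_um)
      movie_seed <- if (is.null(seed)) NULL else seed + 100L * di + si
      movie <- render_timelapse(mix$tracks, params, seed = movie_seed)
      det <- do.call(rbind, lapply(seq_along(movie$frames), function(f) {
        d <- detect_spots(movie$frames[[f]], expected_sigma = params$psf_sigma)
        if (nrow(d) > 0) d$frame <- f - 1L
        d
      }))
      # a cell whose movie yields no classifiable tracklet scores 0:
      # end-to-end accuracy includes the detection and linking stages
      acc <- 0
      n_tl <- 0L
      if (!is.null(det) && nrow(det) > 0) {
        linked <- link_nearest_neighbor(det, max_disp = max_disp,
                                        pixel_size_um = pixel_size_um)
        cls <- classify_tracks(linked, quantiles, config)
        if (nrow(cls) > 0) {
          matched <- match_tracks_to_truth(cls, linked, gt_by_frame,
                                           match_radius)
          true_model <- truth_lab[matched]
          ok <- !is.na(true_model)
          n_tl <- sum(ok)
          if (n_tl > 0) acc <- score_against_truth(cls$label[ok], true_model[ok])
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        snr = snr, density = dens, field_px = field_px,
        n_tracklets = n_tl, accuracy = acc, accuracy_truth = acc_truth
      )
    }
  }
  do.call(rbind, rows)
}

score_against_truth <- function(label, true_model) {
  label <- as.character(label)
  mean((true_model == "confined" & label %in% c("immobile", "confined")) |
         (true_model == "brownian" & label == "brownian"))
}

# translate each track by a uniform offset whose feasible range keeps the
# whole track at least `margin` px inside the field
scatter_tracks <- function(ts, field_px, margin = 8) {
  df <- ts$tracks
  parts <- split(seq_len(nrow(df)), df$track_id)
  for (idx in parts) {
    for (coord in c("x", "y")) {
      v <- df[[coord]][idx]
      lo <- 1 + margin - min(v)
      hi <- field_px - margin - max(v)
      off <- if (hi >= lo) runif(1, lo, hi) else (lo + hi) / 2
      df[[coord]][idx] <- pmin(pmax(v + off, 1), field_px)
    }
  }
  track_set(df, pixel_size_um = ts$pixel_size_um,
            frame_interval_s = ts$frame_interval_s)
}

# first-detection position of each classified track -> ground-truth track id
match_tracks_to_truth <- function(cls, linked, gt_by_frame, match_radius) {
  df <- linked$tracks
  first_rows <- df[!duplicated(df$track_id), , drop = FALSE]
  lookup <- setNames(rep(NA_character_, nrow(first_rows)), first_rows$track_id)
  for (k in seq_len(nrow(first_rows))) {
    gt <- gt_by_frame[[as.character(first_rows$frame[k])]]
    if (is.null(gt)) next
    d2 <- (gt$x - first_rows$x[k])^2 + (gt$y - first_rows$y[k])^2
    j <- which.min(d2)
    if (d2[j] <= match_radius^2) lookup[k] <- gt$track_id[j]
  }
  unname(lookup[as.character(cls$track_id)])
}
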