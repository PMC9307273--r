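#' Imaging parameters for the synthetic movie renderer
#'
#' Describes the virtual microscope: field size, optics (Gaussian PSF), photon
#' budget, and the mixed Poisson-Gaussian camera model
#' `counts = gain * Poisson(photons) + Normal(offset, read_noise_sd^2)`.
#' The spot peak amplitude (photons above background at the PSF center) is
#' solved from `target_snr`:
#' `SNR = gain * A / sqrt(gain^2 * background + read_noise_sd^2)`, i.e. peak
#' signal in counts over the background-pixel standard deviation.
#'
#' With 1000 spots, fields of 1600/800/400 px at 0.1 um/px give spot densities
#' 0.039/0.16/0.63 per square micrometer.
#'
#' @param field_px square field edge in pixels.
#' @param pixel_size_um micrometers per pixel (default 0.1).
#' @param psf_sigma Gaussian PSF standard deviation in pixels (default 1.3).
#' @param background photons per pixel per frame (default 50).
#' @param gain camera counts per photon (default 1).
#' @param read_noise_sd read-noise standard deviation in counts (default 2).
#' @param offset camera offset in counts (default 100).
#' @param n_frames frames per movie.
#' @param target_snr requested spot signal-to-noise ratio (default 10);
#'   ignored when `peak_amplitude` is given.
#' @param peak_amplitude spot peak amplitude in photons, overriding
#'   `target_snr`.
#' @return A list of class `imaging_params` (with the solved `peak_amplitude`).
#' @export
imaging_params <- function(field_px = 400L, pixel_size_um = 0.1,
                           psf_sigma = 1.3, background = 50, gain = 1,
                           read_noise_sd = 2, offset = 100, n_frames = 50L,
                           target_snr = 10, peak_amplitude = NULL) {
  vals <- c(field_px, pixel_size_um, psf_sigma, background, gain, n_frames)
  if (any(vals <= 0) || read_noise_sd < 0 || offset < 0) {
    stopf("imaging parameters must be positive (read noise and offset non-negative)")
  }
  noise_sd <- sqrt(gain^2 * background + read_noise_sd^2)
  if (is.null(peak_amplitude)) {
    if (target_snr <= 0) stopf("`target_snr` must be positive")
    peak_amplitude <- target_snr * noise_sd / gain
  }
  structure(
    list(field_px = as.integer(field_px), pixel_size_um = pixel_size_um,
         psf_sigma = psf_sigma, background = background, gain = gain,
         read_noise_sd = read_noise_sd, offset = offset,
         n_frames = as.integer(n_frames), target_snr = target_snr,
         peak_amplitude = peak_amplitude),
    class = "imaging_params"
  )
}

#' Render a synthetic fluorescence time-lapse from tracks
#'
#' For every frame, the noiseless photon image is the uniform background plus
#' one 2-D Gaussian per spot, integrated over each pixel (error-function
#' differences, so integrated spot intensities are exact for stoichiometry
#' work); the recorded pixel value is
#' `gain * Poisson(photons) + Normal(offset, read_noise_sd^2)`, rounded and
#' clipped to the unsigned 16-bit range. Positions are in pixel units with
#' pixel centers at integer coordinates `1 ... field_px` (x = column,
#' y = row).
#'
#' @param ts a [track_set]; all positions must lie inside the field.
#' @param params an [imaging_params]; frames beyond `n_frames - 1` are ignored.
#' @param seed RNG seed for the noise.
#' @return A list of class `synthetic_movie`: `frames` (list of integer
#'   matrices), `params`, `tracks` (the ground truth), `n_spots`,
#'   `density_um2` (spots per square micrometer).
#' @export
render_timelapse <- function(ts, params, seed = NULL) {
  stopifnot(inherits(ts, "track_set"), inherits(params, "imaging_params"))
  df <- ts$tracks[ts$tracks$frame < params$n_frames, , drop = FALSE]
  fp <- params$field_px
  out_of_field <- df$x < 0.5 | df$x > fp + 0.5 | df$y < 0.5 | df$y > fp + 0.5
  if (any(out_of_field)) {
    stopf("track(s) leave the %d px field: %s", fp,
          paste(unique(df$track_id[out_of_field])[1:min(3, sum(out_of_field))],
                collapse = ", "))
  }
  n_spots <- length(unique(df$track_id))
  by_frame <- split(df[, c("x", "y")], df$frame)
  frames <- with_seed(seed, lapply(0:(params$n_frames - 1L), function(f) {
    spots <- by_frame[[as.character(f)]]
    photons <- matrix(params$background, fp, fp)
    if (!is.null(spots) && nrow(spots) > 0) {
      photons <- photons + spot_image(spots$x, spots$y, params)
    }
    counts <- params$gain * rpois(fp * fp, photons) +
      rnorm(fp * fp, mean = params$offset, sd = params$read_noise_sd)
    matrix(as.integer(pmin(pmax(round(counts), 0), 65535L)), fp, fp)
  }))
  structure(
    list(frames = frames, params = params, tracks = ts, n_spots = n_spots,
         density_um2 = density_from_field(n_spots, fp, params$pixel_size_um)),
    class = "synthetic_movie"
  )
}

# Noiseless photon image (above background) of Gaussian spots with peak
# amplitude params$peak_amplitude, pixel-integrated. Matrix is [row = y, col = x].
spot_image <- function(x, y, params) {
  fp <- params$field_px
  s <- params$psf_sigma
  amp_total <- params$peak_amplitude * 2 * pi * s^2  # integrated photons/spot
  w <- ceiling(4 * s) + 1L
  img <- matrix(0, fp, fp)
  for (k in seq_along(x)) {
    cx <- round(x[k]); cy <- round(y[k])
    cols <- max(1L, cx - w):min(fp, cx + w)
    rows <- max(1L, cy - w):min(fp, cy + w)
    mx <- pnorm(cols + 0.5, x[k], s) - pnorm(cols - 0.5, x[k], s)
    my <- pnorm(rows + 0.5, y[k], s) - pnorm(rows - 0.5, y[k], s)
    img[rows, cols] <- img[rows, cols] + amp_total * (my %o% mx)
  }
  img
}

#' @export
print.synthetic_movie <- function(x, ...) {
  cat(sprintf(
    "<synthetic_movie> %d frames of %d x %d px | %d spots, %.3g spots/um^2, target SNR %.3g\n",
    length(x$frames), x$params$field_px, x$params$field_px, x$n_spots,
    x$density_um2, x$params$target_snr
  ))
  invisible(x)
}

#' Measure the realized spot signal-to-noise ratio
#'
#' Re-renders the noiseless photon image of the measured frames, takes per
#' spot the brightest pixel within 1 px of the true center minus the
#' background expectation (in counts), and divides by the empirical standard
#' deviation of background pixels (pixels receiving < 1% of the background in
#' added signal) of the noisy frame. Returns the mean over spots. Pixel
#' integration of the PSF makes the realized peak a few percent below the
#' nominal `peak_amplitude`.
#'
#' @param movie a `synthetic_movie`.
#' @param frames which frames to measure (1-based; default first frame).
#' @return Mean spot SNR.
#' @export
measure_snr <- function(movie, frames = 1L) {
  stopifnot(inherits(movie, "synthetic_movie"))
  p <- movie$params
  fp <- p$field_px
  snrs <- unlist(lapply(frames, function(f) {
    df <- movie$tracks$tracks
    spots <- df[df$frame == f - 1L, , drop = FALSE]
    if (nrow(spots) == 0) return(numeric(0))
    signal <- spot_image(spots$x, spots$y, p)
    noisy <- movie$frames[[f]]
    bg_mask <- signal < 0.01 * p$background
    if (!any(bg_mask)) stopf("no background pixels available for noise estimation")
    bg_sd <- sd(noisy[bg_mask])
    vapply(seq_len(nrow(spots)), function(k) {
      cx <- round(spots$x[k]); cy <- round(spots$y[k])
      rows <- max(1L, cy - 1L):min(fp, cy + 1L)
      cols <- max(1L, cx - 1L):min(fp, cx + 1L)
      p$gain * max(signal[rows, cols]) / bg_sd
    }, numeric(1))
  }))
  if (length(snrs) == 0) stopf("movie contains no spots in the measured frames")
  mean(snrs)
}

#' Spot density of a square field
#'
#' @param n_spots number of spots.
#' @param field_px field edge in pixels.
#' @param pixel_size_um micrometers per pixel.
#' @return Spots per square micrometer: `n_spots / (field_px * pixel_size_um)^2`.
#' @examples
#' density_from_field(1000, 1600, 0.1)  # 0.039
#' density_from_field(1000, 400, 0.1)   # 0.625
#' @export
density_from_field <- function(n_spots, field_px, pixel_size_um) {
  if (field_px <= 0 || pixel_size_um <= 0 || n_spots < 0) {
    stopf("arguments must be positive (n_spots non-negative)")
  }
  n_spots / (field_px * pixel_size_um)^2
}

#' Fraction of a Gaussian PSF's photons within a circular ROI
#'
#' @param radius ROI radius in pixels.
#' @param sigma PSF standard deviation in pixels.
#' @return `1 - exp(-radius^2 / (2 sigma^2))`.
#' @export
psf_mass_fraction <- function(radius, sigma) {
  1 - exp(-radius^2 / (2 * sigma^2))
}

#' Write / read a synthetic movie as multi-page TIFF
#'
#' Frames are stored as 16-bit grayscale. `write_movie` also writes the ground
#' truth track table (`<path>.tracks.csv`) and a JSON sidecar of the imaging
#' parameters (`<path>.params.json`) next to the stack.
#'
#' @param movie a `synthetic_movie`.
#' @param path output TIFF path.
#' @return `read_movie` returns a list of integer matrices.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "synthetic_movie"))
  pages <- lapply(movie$frames, function(fr) fr / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  write_tracks(movie$tracks, paste0(path, ".tracks.csv"))
  jsonlite::write_json(unclass(movie$params), paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) matrix(as.integer(round(p * 65535)), nrow(p), ncol(p)))
}
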