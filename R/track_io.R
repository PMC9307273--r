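#' Construct a track set
#'
#' A track set bundles a table of particle detections with the acquisition
#' metadata needed to convert pixels and frames to physical units. Each row of
#' `tracks` is one detection; a track is the ordered sequence of detections
#' sharing a `track_id`. Trackers fill detection gaps with interpolated
#' ("virtual") positions, so frames within a track must advance by exactly 1.
#'
#' @param tracks data.frame with columns `track_id`, `frame` (0-based integer),
#'   `x`, `y` (pixels); optional `cell_id`, `intensity` (arbitrary units,
#'   default 0) and `is_virtual` (logical, default `FALSE`).
#' @param pixel_size_um pixel size in micrometers per pixel (> 0).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @return An object of class `track_set`: a list with elements `tracks`
#'   (canonicalised data.frame), `pixel_size_um`, `frame_interval_s`.
#' @examples
#' ts <- track_set(data.frame(track_id = 1, frame = 0:5, x = 0:5, y = 0))
#' ts
#' @export
track_set <- function(tracks, pixel_size_um = 0.1, frame_interval_s = 1 / 30) {
  stopifnot(is.data.frame(tracks))
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stopf("`pixel_size_um` must be a positive number")
  }
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    stopf("`frame_interval_s` must be a positive number")
  }
  required <- c("track_id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(tracks))
  if (length(missing_cols) > 0) {
    stopf("track table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!"cell_id" %in% names(tracks)) tracks$cell_id <- rep(NA_character_, nrow(tracks))
  if (!"intensity" %in% names(tracks)) tracks$intensity <- rep(0, nrow(tracks))
  if (!"is_virtual" %in% names(tracks)) tracks$is_virtual <- rep(FALSE, nrow(tracks))
  tracks$is_virtual <- as.logical(tracks$is_virtual)
  tracks$track_id <- as.character(tracks$track_id)
  tracks$cell_id <- as.character(tracks$cell_id)
  tracks$frame <- as.integer(tracks$frame)
  tracks <- tracks[, c("track_id", "cell_id", "frame", "x", "y", "intensity", "is_virtual")]

  n <- nrow(tracks)
  if (n > 0) {
    if (anyNA(tracks$frame) || any(tracks$frame < 0L)) {
      stopf("`frame` must be a non-negative integer")
    }
    if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y))) {
      stopf("`x` and `y` must be finite")
    }
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
    rownames(tracks) <- NULL
    if (n > 1) {
      same <- tracks$track_id[-1] == tracks$track_id[-n]
      dfr <- diff(tracks$frame)
      if (any(same & dfr == 0L)) {
        bad <- tracks$track_id[-1][same & dfr == 0L][1]
        stopf("duplicate (track_id, frame) pair in track '%s'", bad)
      }
      if (any(same & dfr != 1L)) {
        bad <- tracks$track_id[-1][same & dfr != 1L][1]
        stopf("track '%s' has non-consecutive frames (trackers fill gaps with virtual detections)", bad)
      }
    }
  }
  structure(
    list(tracks = tracks, pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  ids <- unique(x$tracks$track_id)
  cat(sprintf(
    "<track_set> %d tracks, %d detections | %.3g um/px, %.4g s/frame\n",
    length(ids), nrow(x$tracks), x$pixel_size_um, x$frame_interval_s
  ))
  invisible(x)
}

#' @export
`==.track_set` <- function(e1, e2) {
  isTRUE(all.equal(e1$tracks, e2$tracks)) &&
    isTRUE(all.equal(e1$pixel_size_um, e2$pixel_size_um)) &&
    isTRUE(all.equal(e1$frame_interval_s, e2$frame_interval_s))
}

#' Read a track table from delimited text
#'
#' Reads the canonical comma-separated track-table format with header
#' `track_id,cell_id,frame,x,y,intensity,is_virtual`. The `cell_id`,
#' `intensity` and `is_virtual` columns may be absent and default to `NA`,
#' 0 and `FALSE` respectively.
#'
#' @param path path to a CSV track table.
#' @inheritParams track_set
#' @return A [track_set].
#' @export
read_tracks <- function(path, pixel_size_um = 0.1, frame_interval_s = 1 / 30) {
  if (!file.exists(path)) stopf("track table not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stopf("%s: missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  for (col in c("frame", "x", "y")) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      stopf("%s: malformed value '%s' in column '%s' at line %d",
            path, v[bad[1]], col, bad[1] + 1L)  # +1 for the header line
    }
    df[[col]] <- num
  }
  if ("is_virtual" %in% names(df)) df$is_virtual <- df$is_virtual %in% c(1, "1", TRUE, "TRUE")
  track_set(df, pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s)
}

#' Write a track set to delimited text
#'
#' Emits the canonical track-table format (see [read_tracks]); numeric fields
#' are written with enough digits that `read_tracks(write_tracks(ts))`
#' reproduces `ts` exactly.
#'
#' @param ts a [track_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  df <- ts$tracks
  out <- data.frame(
    track_id = df$track_id,
    cell_id = ifelse(is.na(df$cell_id), "", df$cell_id),
    frame = df$frame,
    x = formatC(df$x, digits = 17, format = "g"),
    y = formatC(df$y, digits = 17, format = "g"),
    intensity = formatC(df$intensity, digits = 17, format = "g"),
    is_virtual = as.integer(df$is_virtual),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Track-quality filter on virtual detections
#'
#' Tracks whose gaps were heavily interpolated by the tracker are unreliable.
#' A track is excluded when the fraction of virtual detections exceeds
#' `max_fraction`, or when the longest run of successive virtual detections
#' exceeds `max_run`. With `rule = "either"` (default, stricter) failing one
#' criterion excludes the track; `rule = "both"` requires both.
#'
#' @param track a one-track data.frame with an `is_virtual` column, or a
#'   logical vector of virtual flags.
#' @param max_fraction maximum tolerated virtual fraction (default 0.10).
#' @param max_run maximum tolerated run of successive virtual detections
#'   (default 3).
#' @param rule `"either"` or `"both"` — how the two criteria combine.
#' @return `TRUE` to keep the track, `FALSE` to exclude it.
#' @export
filter_virtual <- function(track, max_fraction = 0.10, max_run = 3L,
                           rule = c("either", "both")) {
  rule <- match.arg(rule)
  v <- if (is.data.frame(track)) as.logical(track$is_virtual) else as.logical(track)
  if (length(v) == 0) stopf("empty track")
  if (max_fraction < 0 || max_fraction > 1) stopf("`max_fraction` must be in [0, 1]")
  if (max_run < 1) stopf("`max_run` must be >= 1")
  frac_bad <- mean(v) > max_fraction
  run_bad <- longest_run(v) > max_run
  exclude <- if (rule == "either") frac_bad || run_bad else frac_bad && run_bad
  !exclude
}

longest_run <- function(v) {
  if (!any(v)) return(0L)
  r <- rle(v)
  max(r$lengths[r$values])
}

#' Split a track into fixed-length tracklets
#'
#' Cuts a track of `L` detections into `floor((L - 1) / N)` windows of `N + 1`
#' consecutive positions; tracklet `k` covers detections at offsets
#' `N*k ... N*(k+1)`, so consecutive tracklets share one boundary position.
#' Trailing detections that do not fill a complete window are dropped, and
#' tracks shorter than `N + 1` detections yield no tracklets.
#'
#' @param track a one-track data.frame with columns `frame`, `x`, `y` (rows
#'   ordered by frame).
#' @param N number of increments per tracklet (default 5, i.e. 6 positions).
#' @return A list of tracklets; each is a list with `track_id`, `index_k`
#'   (0-based), `start_frame`, and `positions`, an `(N+1) x 2` matrix.
#' @export
split_track <- function(track, N = 5L) {
  stopifnot(is.data.frame(track))
  if (N < 2) stopf("`N` must be >= 2")
  L <- nrow(track)
  n_tl <- max(0L, (L - 1L) %/% N)
  if (n_tl == 0L) return(list())
  id <- if ("track_id" %in% names(track)) as.character(track$track_id[1]) else NA_character_
  lapply(seq_len(n_tl) - 1L, function(k) {
    idx <- (N * k + 1L):(N * (k + 1L) + 1L)
    list(
      track_id = id,
      index_k = k,
      start_frame = track$frame[idx[1]],
      positions = cbind(x = track$x[idx], y = track$y[idx])
    )
  })
}
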