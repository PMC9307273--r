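collapse_label <- function(label) {
  lab <- as.character(label)
  ifelse(lab %in% c("immobile", "confined"), "restricted", lab)
}

#' Per-track motion-change summary
#'
#' Collapses tracklet labels to \{restricted, brownian, directed\}
#' (restricted = immobile + confined), counts changes of collapsed label
#' between consecutive tracklets, and categorises the track: `all_brownian`,
#' `all_restricted` or `all_directed` when every tracklet shares one collapsed
#' label, `fluctuating` when at least one transition occurs. The number of
#' motion changes along a trajectory estimates the stability of its motion.
#'
#' @param labels ordered motion labels of one track's tracklets.
#' @param track_id optional identifier carried into the result.
#' @return One-row data.frame: `track_id`, `n_tracklets`, `category`,
#'   `n_transitions` (collapsed labels), `n_transitions_raw` (4-level labels),
#'   `transition_rate` (changes per tracklet boundary).
#' @export
summarize_track <- function(labels, track_id = NA_character_) {
  lab <- as.character(labels)
  if (length(lab) < 1) stopf("a track summary needs at least one tracklet")
  coll <- collapse_label(lab)
  n <- length(coll)
  n_trans <- if (n > 1) sum(coll[-1] != coll[-n]) else 0L
  n_trans_raw <- if (n > 1) sum(lab[-1] != lab[-n]) else 0L
  category <- if (n_trans >= 1) "fluctuating" else paste0("all_", coll[1])
  data.frame(
    track_id = track_id,
    n_tracklets = n,
    category = category,
    n_transitions = as.integer(n_trans),
    n_transitions_raw = as.integer(n_trans_raw),
    transition_rate = n_trans / max(1L, n - 1L)
  )
}

#' Summaries for every track of a classification table
#'
#' @param cls classification data.frame from [classify_tracks].
#' @return A data.frame with one [summarize_track] row per track.
#' @export
summarize_tracks <- function(cls) {
  stopifnot(all(c("track_id", "tracklet_index", "label") %in% names(cls)))
  cls <- cls[order(cls$track_id, cls$tracklet_index), , drop = FALSE]
  parts <- split(cls$label, cls$track_id)
  out <- do.call(rbind, lapply(names(parts), function(id) {
    summarize_track(parts[[id]], track_id = id)
  }))
  rownames(out) <- NULL
  out
}

#' Pooled and per-cell motion fractions
#'
#' The global view of receptor dynamics: the fraction of tracklets in each of
#' the four motion labels (and in the restricted collapse), pooled over all
#' tracklets and, when cell identifiers are available, per cell with the mean
#' and standard error of the mean across cells. Track categories from
#' [summarize_tracks] are summarised alongside.
#'
#' @param cls classification data.frame from [classify_tracks].
#' @param by_cell also compute per-cell fractions (requires non-missing
#'   `cell_id`).
#' @return A list of class `population_summary`: `n_tracklets`, `pooled`
#'   (named fractions over the four labels), `restricted_fraction`,
#'   `categories` (track-category fractions), and with `by_cell = TRUE`
#'   `per_cell` (cell x label fraction matrix), `cell_mean`, `cell_sem`.
#' @export
pool_fractions <- function(cls, by_cell = FALSE) {
  if (nrow(cls) == 0) stopf("no classified tracklets to pool")
  labs <- motion_labels()
  counts <- table(factor(cls$label, levels = labs))
  pooled <- as.numeric(counts) / nrow(cls)
  names(pooled) <- labs
  summaries <- summarize_tracks(cls)
  cat_levels <- c("all_restricted", "all_brownian", "all_directed", "fluctuating")
  cats <- table(factor(summaries$category, levels = cat_levels))
  categories <- as.numeric(cats) / nrow(summaries)
  names(categories) <- cat_levels
  out <- list(
    n_tracklets = nrow(cls),
    n_tracks = nrow(summaries),
    pooled = pooled,
    restricted_fraction = unname(pooled["immobile"] + pooled["confined"]),
    categories = categories
  )
  if (by_cell) {
    if (!"cell_id" %in% names(cls) || anyNA(cls$cell_id)) {
      stopf("per-cell fractions require a complete `cell_id` column")
    }
    tab <- table(cls$cell_id, factor(cls$label, levels = labs))
    per_cell <- sweep(unclass(tab), 1, rowSums(tab), "/")
    out$per_cell <- per_cell
    out$cell_mean <- colMeans(per_cell)
    out$cell_sem <- if (nrow(per_cell) > 1) {
      apply(per_cell, 2, sd) / sqrt(nrow(per_cell))
    } else {
      setNames(rep(0, length(labs)), labs)  # single cell: SEM 0 by convention
    }
  }
  structure(out, class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %d tracklets from %d tracks\n",
              x$n_tracklets, x$n_tracks))
  cat("  tracklet fractions:",
      paste(sprintf("%s %.3f", names(x$pooled), x$pooled), collapse = ", "), "\n")
  cat(sprintf("  restricted (immobile + confined): %.3f\n", x$restricted_fraction))
  cat("  track categories:",
      paste(sprintf("%s %.3f", names(x$categories), x$categories), collapse = ", "), "\n")
  invisible(x)
}

#' Restricted-motion fraction over time
#'
#' Bins tracklets by their start time and reports, per bin, the fraction
#' carrying a restricted label (immobile or confined) — the time course of
#' motion arrest, e.g. after a treatment.
#'
#' @param cls classification data.frame from [classify_tracks].
#' @param frame_interval_s seconds per frame.
#' @param window bin width in seconds (> 0).
#' @return data.frame `t_start`, `t_end`, `fraction` (`NA` for empty bins),
#'   `n` (tracklets in bin).
#' @export
restricted_timecourse <- function(cls, frame_interval_s, window) {
  if (window <= 0) stopf("`window` must be positive")
  if (frame_interval_s <= 0) stopf("`frame_interval_s` must be positive")
  if (nrow(cls) == 0) stopf("no classified tracklets")
  t0 <- cls$start_frame * frame_interval_s
  restricted <- collapse_label(cls$label) == "restricted"
  n_bins <- floor(max(t0) / window) + 1L
  bin <- pmin(floor(t0 / window) + 1L, n_bins)
  n <- tabulate(bin, nbins = n_bins)
  hits <- tabulate(bin[restricted], nbins = n_bins)
  data.frame(
    t_start = (seq_len(n_bins) - 1L) * window,
    t_end = seq_len(n_bins) * window,
    fraction = ifelse(n > 0, hits / pmax(n, 1L), NA_real_),
    n = n
  )
}
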