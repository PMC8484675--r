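#' Decibel/linear conversions for volume backscattering
#'
#' Volume backscattering strength in dB re 1 m^-1 relates to the linear
#' coefficient s_v by S_V = 10 log10(s_v), so s_v = 10^(S_V/10). A linear
#' value of 0 (no backscatter) maps to -Inf dB, which downstream averaging
#' handles by working in the linear domain.
#'
#' @param sv_db Backscattering strength in dB.
#' @return Linear backscattering coefficient (m^-1).
#' @export
db_to_linear <- function(sv_db) 10^(sv_db / 10)

#' @param sv_linear Linear backscattering coefficient.
#' @rdname db_to_linear
#' @export
linear_to_db <- function(sv_linear) {
  if (any(sv_linear < 0, na.rm = TRUE)) stop("linear S_V cannot be negative")
  ifelse(sv_linear == 0, -Inf, 10 * log10(sv_linear))
}

#' Construct an echogram
#'
#' A time x depth grid of volume backscattering strength with a validity
#' mask. Cells are invalidated (never deleted) by the bottom dead zone and by
#' instrument/bubble masks.
#'
#' @param time POSIXct (or numeric seconds) ping times, one per row.
#' @param depth Numeric depth-bin centres in metres, increasing downward,
#'   one per column.
#' @param sv_db Matrix of S_V in dB, `length(time)` x `length(depth)`.
#' @param bottom_depth Numeric bottom depth per ping (m).
#' @param valid Optional logical matrix; defaults to all-valid.
#' @return An object of class `echogram`.
#' @export
echogram <- function(time, depth, sv_db, bottom_depth, valid = NULL) {
  sv_db <- as.matrix(sv_db)
  if (nrow(sv_db) != length(time) || ncol(sv_db) != length(depth)) {
    stop("sv_db must be length(time) x length(depth)")
  }
  if (length(bottom_depth) == 1) bottom_depth <- rep(bottom_depth, length(time))
  if (length(bottom_depth) != length(time)) {
    stop("bottom_depth must have one value per ping")
  }
  if (is.null(valid)) valid <- matrix(TRUE, nrow(sv_db), ncol(sv_db))
  structure(
    list(time = time, depth = depth, sv_db = sv_db,
         bottom_depth = bottom_depth, valid = valid,
         thresholded = FALSE, sv_linear = NULL),
    class = "echogram"
  )
}

#' @export
print.echogram <- function(x, ...) {
  cat(sprintf("<echogram> %d pings x %d depth bins, %d/%d cells valid%s\n",
              length(x$time), length(x$depth), sum(x$valid), length(x$valid),
              if (x$thresholded) " [thresholded]" else ""))
  invisible(x)
}

#' Invalidate dead-zone and instrument cells
#'
#' Marks invalid every cell lying deeper than 1 m above the sea bottom (the
#' acoustic dead zone) and any cells covered by the supplied instrument or
#' bubble masks. Masked cells are flagged, not removed, so grid geometry is
#' preserved.
#'
#' @param eg An [echogram()].
#' @param extra_masks Optional list of logical matrices (same shape as the
#'   grid), `TRUE` where the cell must be excluded.
#' @param dead_zone_m Height above bottom excluded together with the bottom
#'   (default 1.0 m).
#' @return The echogram with its validity mask updated; the count of newly
#'   invalidated cells is reported via `message()`.
#' @export
apply_masks <- function(eg, extra_masks = list(), dead_zone_m = 1.0) {
  stopifnot(inherits(eg, "echogram"))
  if (anyNA(eg$bottom_depth)) stop("bottom depth profile required")
  before <- sum(eg$valid)
  dead <- outer(eg$bottom_depth - dead_zone_m, eg$depth,
                function(b, d) d > b)
  eg$valid <- eg$valid & !dead
  for (m in extra_masks) {
    stopifnot(all(dim(m) == dim(eg$valid)))
    eg$valid <- eg$valid & !m
  }
  message(sprintf("apply_masks: invalidated %d cells", before - sum(eg$valid)))
  eg
}

#' Threshold an echogram to suppress background noise
#'
#' Valid cells below the dB threshold are treated as containing no fish:
#' their linear backscatter is set to exactly zero. Cells at or above the
#' threshold keep their value (the boundary is kept). The result carries a
#' linear-domain grid used by [window_mean_sv()].
#'
#' @param eg A masked [echogram()].
#' @param threshold_db Threshold in dB (default -70).
#' @return The echogram with `sv_linear` populated and `thresholded = TRUE`.
#' @export
threshold_echogram <- function(eg, threshold_db = -70) {
  stopifnot(inherits(eg, "echogram"))
  lin <- db_to_linear(eg$sv_db)
  lin[eg$sv_db < threshold_db] <- 0
  eg$sv_linear <- lin
  eg$threshold_db <- threshold_db
  eg$thresholded <- TRUE
  eg
}

#' Mean linear backscatter over a time window
#'
#' Averages linear-domain S_V over all valid cells whose ping time falls in
#' the half-open window `[start, start + duration)`. Zeros produced by
#' thresholding count toward the mean — an empty water column pulls the
#' station mean down, which is why station means can fall below the linear
#' equivalent of the threshold. Averaging is always in the linear domain;
#' averaging decibels would systematically understate patchy backscatter.
#'
#' @param eg A thresholded [echogram()].
#' @param start Window start (same class as `eg$time`).
#' @param duration Window length in seconds (default 600 = 10 min).
#' @param station_id Optional id carried into the summary.
#' @param depth_band Optional `c(min, max)` depth restriction in metres.
#' @return A list of class `echo_summary`: `station_id`, `window`
#'   (start/end), `mean_sv_linear`, `n_cells_used`, `flagged` (TRUE when no
#'   valid cells fall in the window).
#' @export
window_mean_sv <- function(eg, start, duration = 600, station_id = NA,
                           depth_band = NULL) {
  stopifnot(inherits(eg, "echogram"))
  if (!eg$thresholded) stop("threshold_echogram() must be applied first")
  in_win <- as.numeric(eg$time) >= as.numeric(start) &
    as.numeric(eg$time) < as.numeric(start) + duration
  use <- eg$valid & in_win
  if (!is.null(depth_band)) {
    in_band <- eg$depth >= depth_band[1] & eg$depth <= depth_band[2]
    use <- use & rep(in_band, each = nrow(use))
  }
  n <- sum(use)
  structure(
    list(station_id = station_id,
         window = c(start = start, end = start + duration),
         mean_sv_linear = if (n > 0) mean(eg$sv_linear[use]) else NA_real_,
         n_cells_used = n,
         flagged = n == 0),
    class = "echo_summary"
  )
}

#' @export
print.echo_summary <- function(x, ...) {
  cat(sprintf("<echo_summary> station %s: mean s_v %.3g (n = %d)%s\n",
              x$station_id, x$mean_sv_linear, x$n_cells_used,
              if (x$flagged) " [FLAGGED: no valid cells]" else ""))
  invisible(x)
}

#' Per-station echo summaries for a survey
#'
#' Convenience wrapper: masks, thresholds and window-averages one echogram
#' per station, starting each window at the station's eDNA sampling time.
#'
#' @param echograms Named list of [echogram()]s, one per station.
#' @param start_times Named vector of sampling times per station (numeric
#'   seconds or POSIXct); defaults to each echogram's first ping.
#' @param threshold_db,duration,depth_band Passed through.
#' @return Data frame with `station_id`, `mean_sv_linear`, `n_cells_used`.
#' @export
summarise_echograms <- function(echograms, start_times = NULL,
                                threshold_db = -70, duration = 600,
                                depth_band = NULL) {
  rows <- lapply(names(echograms), function(st) {
    eg <- threshold_echogram(
      suppressMessages(apply_masks(echograms[[st]])),
      threshold_db = threshold_db
    )
    t0 <- if (is.null(start_times)) eg$time[1] else start_times[[st]]
    s <- window_mean_sv(eg, start = t0, duration = duration,
                        station_id = st, depth_band = depth_band)
    data.frame(station_id = st, mean_sv_linear = s$mean_sv_linear,
               n_cells_used = s$n_cells_used)
  })
  do.call(rbind, rows)
}
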