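#' Interbeat-interval series
#'
#' Each interval is indexed by the time of its terminating beat.
#' `missing_segments` are disjoint, sorted half-open `[start, end)` time
#' intervals excluded from analysis (set by [flag_and_correct()]).
#'
#' @param times Time of each interval's terminating beat (s), increasing.
#' @param ibi Interval durations (ms), all > 0.
#' @param missing_segments List of `c(start_s, end_s)` half-open intervals.
#' @return An object of class `ibi_series`.
#' @export
ibi_series <- function(times, ibi, missing_segments = list()) {
  stopifnot(length(times) == length(ibi))
  if (length(ibi) && any(ibi <= 0)) stop("ibi values must be positive")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("interval times must be increasing")
  if (length(missing_segments) > 1L) {
    starts <- vapply(missing_segments, `[`, numeric(1L), 1L)
    ends <- vapply(missing_segments, `[`, numeric(1L), 2L)
    ord <- order(starts)
    missing_segments <- missing_segments[ord]
    if (any(starts[ord][-1L] < ends[ord][-length(ends)]))
      stop("missing segments must be disjoint")
  }
  structure(list(times = times, ibi = ibi,
                 missing_segments = missing_segments),
            class = "ibi_series")
}

#' Uniformly sampled 4 Hz IBI signal
#'
#' @param values Samples (ms); sample `k` (0-based) sits at
#'   `start_time + k / rate` seconds.
#' @param valid_mask Per-sample logical; masked samples carry no information
#'   downstream.
#' @param start_time Start of the grid (s).
#' @param rate Samples per second (4 by convention).
#' @return An object of class `uniform_ibi`.
#' @export
uniform_ibi <- function(values, valid_mask = rep(TRUE, length(values)),
                        start_time = 0, rate = 4) {
  stopifnot(length(values) == length(valid_mask), rate > 0)
  structure(list(start_time = start_time, rate = rate,
                 values = values, valid_mask = as.logical(valid_mask)),
            class = "uniform_ibi")
}

#' @export
print.uniform_ibi <- function(x, ...) {
  cat(sprintf("<uniform_ibi: %d samples @ %g Hz, %.1f%% valid>\n",
              length(x$values), x$rate, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Convert beats to interbeat intervals
#'
#' @param beats A [beat_series()] with at least 2 beats.
#' @return An [ibi_series()] with `n_beats - 1` intervals in ms, each stamped
#'   with its terminating beat time.
#' @export
beats_to_ibi <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$times) < 2L)
    stop("unusable record: fewer than 2 beats")
  ibi_series(times = beats$times[-1L], ibi = diff(beats$times) * 1000)
}

#' Flag artifactual intervals and correct or mask them
#'
#' Automated stand-in for manual ECG editing. An interval "needs correcting"
#' when it falls outside physiologic bounds or differs from the preceding
#' accepted interval by more than `jump_fraction` (relative). Each flagged
#' run is sized by the number of beats it implies: one per flagged interval,
#' plus the extra heart periods hidden inside gap-like intervals (an
#' interval spanning k typical periods implies ~k-1 undetected beats). Runs
#' implying 1-2 corrupt beats are repaired by linear interpolation between
#' the adjacent accepted intervals; runs implying 3 or more become missing
#' segments spanning the affected beat-time range and are dropped from the
#' usable record (data needing that much consecutive correction are treated
#' as missing, not analysed).
#'
#' @param ibi An [ibi_series()].
#' @param physio_bounds `c(min_ms, max_ms)` plausible interval range.
#' @param jump_fraction Maximum accepted relative change between successive
#'   intervals.
#' @return An [ibi_series()] with corrected values, flagged long runs removed
#'   and recorded in `missing_segments`.
#' @export
flag_and_correct <- function(ibi, physio_bounds = c(300, 1500),
                             jump_fraction = 0.25) {
  stopifnot(inherits(ibi, "ibi_series"),
            physio_bounds[1L] < physio_bounds[2L])
  x <- ibi$ibi
  times <- ibi$times
  n <- length(x)
  if (n == 0L) return(ibi)
  in_bounds <- x >= physio_bounds[1L] & x <= physio_bounds[2L]
  ref <- stats::median(x[in_bounds])
  if (!length(ref) || is.na(ref)) ref <- stats::median(x)
  flagged <- logical(n)
  for (k in seq_len(n)) {
    bad <- !in_bounds[k] || abs(x[k] - ref) > jump_fraction * ref
    flagged[k] <- bad
    if (!bad) ref <- x[k]
  }
  if (!any(flagged)) return(ibi)

  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  new_segments <- ibi$missing_segments
  keep <- rep(TRUE, n)
  x_fixed <- x
  med0 <- stats::median(x[in_bounds & !flagged])
  if (is.na(med0)) med0 <- stats::median(x)
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    i0 <- starts[r]; i1 <- ends[r]
    # beats needing correction: each flagged interval counts at least one,
    # and a gap spanning k typical heart periods hides ~k-1 missing beats
    implied_beats <- sum(pmax(1, round(x[i0:i1] / med0) - 1))
    if (implied_beats <= 2L) {
      # short run: repair by linear interpolation over time between the
      # nearest accepted neighbours (or carry the single neighbour at edges)
      left <- if (i0 > 1L) i0 - 1L else NA_integer_
      right <- if (i1 < n) i1 + 1L else NA_integer_
      for (k in i0:i1) {
        x_fixed[k] <- if (!is.na(left) && !is.na(right)) {
          x[left] + (x[right] - x[left]) *
            (times[k] - times[left]) / (times[right] - times[left])
        } else if (!is.na(left)) x[left] else if (!is.na(right)) x[right] else ref
      }
    } else {
      # long run: affected time range becomes a missing segment
      seg_start <- if (i0 > 1L) times[i0 - 1L] else times[i0] - x[i0] / 1000
      new_segments[[length(new_segments) + 1L]] <- c(seg_start, times[i1])
      keep[i0:i1] <- FALSE
    }
  }
  new_segments <- merge_segments(new_segments)
  ibi_series(times[keep], x_fixed[keep], new_segments)
}

merge_segments <- function(segments) {
  if (length(segments) <= 1L) return(segments)
  starts <- vapply(segments, `[`, numeric(1L), 1L)
  ord <- order(starts)
  segments <- segments[ord]
  out <- list(segments[[1L]])
  for (s in segments[-1L]) {
    last <- out[[length(out)]]
    if (s[1L] <= last[2L] + 1e-9) {
      out[[length(out)]] <- c(last[1L], max(last[2L], s[2L]))
    } else out[[length(out) + 1L]] <- s
  }
  out
}

#' Interpolate an IBI series onto the uniform 4 Hz grid
#'
#' Cubic-spline interpolation of `(times, ibi)` onto samples at `k / 4`
#' seconds over `[0, task_duration)`. The spline bridges short gaps, but
#' samples inside missing segments of duration >= `max_bridge_s` (10 s by
#' default) are masked invalid: interpolated values spanning that much
#' missing data are not precise enough to keep.
#'
#' @param ibi An [ibi_series()] (typically from [flag_and_correct()]).
#' @param task_duration Task length (s).
#' @param rate Grid rate (samples/s).
#' @param max_bridge_s Missing segments at least this long are masked.
#' @return A [uniform_ibi()].
#' @export
interpolate_4hz <- function(ibi, task_duration, rate = 4, max_bridge_s = 10) {
  stopifnot(inherits(ibi, "ibi_series"), task_duration > 0)
  in_seg <- rep(FALSE, length(ibi$times))
  for (seg in ibi$missing_segments)
    in_seg <- in_seg | (ibi$times >= seg[1L] & ibi$times < seg[2L])
  t_sup <- ibi$times[!in_seg]
  x_sup <- ibi$ibi[!in_seg]
  if (length(t_sup) < 4L)
    stop("unusable record: fewer than 4 usable intervals for spline support")
  sp <- stats::splinefun(t_sup, x_sup, method = "fmm")
  grid <- seq(0, by = 1 / rate, length.out = ceiling(task_duration * rate))
  values <- sp(grid)
  valid <- rep(TRUE, length(grid))
  for (seg in ibi$missing_segments) {
    if (seg[2L] - seg[1L] >= max_bridge_s)
      valid[grid >= seg[1L] & grid < seg[2L]] <- FALSE
  }
  uniform_ibi(values, valid, start_time = 0, rate = rate)
}
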