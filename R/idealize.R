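#' Construct an idealized event list
#'
#' The dwell sequence produced by threshold idealization: contiguous,
#' non-overlapping events, each with a conductance level (0 = closed),
#' start time and duration in seconds, and optionally a measured amplitude
#' in pA.
#'
#' @param level integer conductance level per event.
#' @param start event start times, s.
#' @param duration event durations, s (> 0).
#' @param amplitude measured amplitudes, pA (NA when not measured).
#' @param n_levels maximum conductance level (number of channels).
#' @param dead_time filter dead time, s (NA when unfiltered).
#' @return a data.frame of class `event_list` with attributes `n_levels`
#'   and `dead_time`.
#' @export
event_list <- function(level = integer(), start = numeric(),
                       duration = numeric(), amplitude = NA_real_,
                       n_levels = 1L, dead_time = NA_real_) {
  n <- length(level)
  stopifnot(length(start) == n, length(duration) == n)
  if (n > 0 && any(duration <= 0))
    stop("event durations must be > 0", call. = FALSE)
  df <- data.frame(level = as.integer(level), start = as.numeric(start),
                   duration = as.numeric(duration),
                   amplitude = rep_len(as.numeric(amplitude), n))
  structure(df, n_levels = as.integer(n_levels),
            dead_time = as.numeric(dead_time),
            class = c("event_list", "data.frame"))
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d events, %d level(s), dead time %s ms\n",
              nrow(x), attr(x, "n_levels"),
              format(attr(x, "dead_time") * 1000, digits = 4)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Dead time of a Gaussian low-pass filter
#'
#' The minimum duration of a rectangular current pulse whose Gaussian-filtered
#' peak still reaches 50% of the true amplitude. Found numerically: a unit
#' pulse is rasterized onto the sampling grid with fractional-sample area
#' weighting, convolved with the discrete Gaussian kernel, and the pulse
#' width at which the filtered peak equals 0.5 is located by bisection.
#' Scales as 1/filter_cutoff; at 1 kHz it is 0.179 ms.
#'
#' @param filter_cutoff -3 dB cutoff, Hz.
#' @param sampling_rate digitization rate used for the numeric analysis, Hz.
#' @param tol bisection tolerance on the duration, s.
#' @return dead time in seconds.
#' @examples
#' dead_time(1000) * 1000 # ms: 0.179
#' @export
dead_time <- function(filter_cutoff, sampling_rate = 50 * filter_cutoff,
                      tol = 1e-10) {
  stop_if_not_scalar_pos(filter_cutoff, "filter_cutoff")
  peak <- filtered_pulse_peak_fun(filter_cutoff, sampling_rate)
  lo <- 0.01 / filter_cutoff; hi <- 1 / filter_cutoff
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peak(mid) < 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Returns function(width_s) -> filtered peak amplitude of a unit rectangular
# pulse of that width, computed by discrete convolution. Also used as the
# pulse-response oracle for amplitude-truncation analysis.
filtered_pulse_peak_fun <- function(filter_cutoff, sampling_rate) {
  k <- gaussian_kernel(filter_cutoff, sampling_rate)
  dt <- 1 / sampling_rate
  function(width_s) {
    n <- ceiling(width_s / dt) + 2L * length(k)
    # pulse centered in the window, fractional-sample area weighting
    a <- (n * dt - width_s) / 2; b <- a + width_s
    idx <- seq_len(n)
    hi <- pmin(idx * dt, b); lo <- pmax((idx - 1) * dt, a)
    x <- pmax(hi - lo, 0) / dt
    max(stats::convolve(x, rev(k), type = "open"))
  }
}

#' Relative measured amplitude of a filtered rectangular event
#'
#' Numeric Gaussian pulse-response curve: the filtered peak of a rectangular
#' event, as a fraction of the true amplitude, as a function of duration.
#' Equals 0.5 at one dead time and exceeds 0.99 near four dead times.
#'
#' @param duration event duration(s), s.
#' @param filter_cutoff -3 dB cutoff, Hz.
#' @param sampling_rate digitization rate, Hz.
#' @return fraction(s) in (0, 1].
#' @export
pulse_response <- function(duration, filter_cutoff,
                           sampling_rate = 50 * filter_cutoff) {
  peak <- filtered_pulse_peak_fun(filter_cutoff, sampling_rate)
  vapply(duration, peak, numeric(1L))
}

#' Idealize a current trace by 50% threshold analysis
#'
#' Conductance thresholds are placed midway between adjacent levels, at
#' `closed_level + (k - 1/2) * unit_amplitude` for k = 1..n_channels; each
#' sample is assigned the number of thresholds crossed, the level path is
#' constrained to move by at most one level per sample, and the path is
#' run-length encoded into an event list. The filter dead time is recorded
#' from the trace's filter cutoff.
#'
#' @param trace a `current_trace`.
#' @param closed_level baseline (closed) current, pA.
#' @param unit_amplitude unitary current of one open channel, pA (nonzero;
#'   may be negative).
#' @param n_channels number of channels (maximum level).
#' @return an [event_list()].
#' @export
threshold_idealize <- function(trace, closed_level, unit_amplitude,
                               n_channels = 1L) {
  stopifnot(inherits(trace, "current_trace"))
  if (unit_amplitude == 0) stop("unit_amplitude must be nonzero", call. = FALSE)
  if (n_channels < 1L) stop("n_channels must be >= 1", call. = FALSE)
  if (length(trace$current) < 3L)
    stop("trace must have at least 3 samples", call. = FALSE)
  r <- (trace$current - closed_level) / unit_amplitude
  lev <- pmax(0L, pmin(as.integer(n_channels), as.integer(floor(r + 0.5))))
  # enforce single-threshold-at-a-time transitions
  repeat {
    d <- diff(lev)
    j <- which(abs(d) > 1L)
    if (!length(j)) break
    lev[j + 1L] <- lev[j] + sign(d[j])
  }
  rl <- rle(lev)
  dt <- 1 / trace$sampling_rate
  ends <- cumsum(rl$lengths)
  starts <- c(0L, ends[-length(ends)])
  td <- if (is.null(trace$filter_cutoff)) NA_real_ else
    dead_time(trace$filter_cutoff)
  event_list(level = rl$values,
             start = trace$t0 + starts * dt,
             duration = rl$lengths * dt,
             n_levels = n_channels, dead_time = td)
}

#' Dwell-time statistics per conductance level
#'
#' Mean durations with SEM and counts per level, plus an `open` aggregate
#' over all levels >= 1. The first and last events of the record are
#' censored (their true durations are unobserved) and excluded.
#'
#' @param events an [event_list()] with at least one event.
#' @return data.frame with columns `class` ("closed", "open", "level<k>"),
#'   `mean` (s), `sem` (s, NA when n < 2), `n`.
#' @export
dwell_statistics <- function(events) {
  stopifnot(inherits(events, "event_list"), nrow(events) >= 1L)
  e <- as.data.frame(events)
  if (nrow(e) > 2L) e <- e[2:(nrow(e) - 1L), ] else
    stop("no complete (uncensored) events", call. = FALSE)
  one <- function(d) {
    data.frame(mean = mean(d),
               sem = if (length(d) > 1L) stats::sd(d) / sqrt(length(d))
                     else NA_real_,
               n = length(d))
  }
  groups <- list(closed = e$duration[e$level == 0L],
                 open = e$duration[e$level >= 1L])
  for (k in sort(unique(e$level[e$level >= 1L])))
    groups[[paste0("level", k)]] <- e$duration[e$level == k]
  groups <- groups[vapply(groups, length, 1L) > 0L]
  if (!length(groups)) stop("no complete (uncensored) events", call. = FALSE)
  out <- do.call(rbind, lapply(groups, one))
  data.frame(class = names(groups), out, row.names = NULL)
}

#' NPo and Po from an idealized record
#'
#' \eqn{NPo = \sum_i i P_i}, where \eqn{P_i} is the fraction of total
#' recorded time spent at open level i; \eqn{Po = NPo / N} for N channels.
#'
#' @param events an [event_list()].
#' @param n_channels N; must be >= the maximum observed level. Defaults to
#'   the maximum observed level (the convention when the full opening range
#'   has been observed).
#' @return list with `npo`, `po`, and `p_levels` (named fraction of time per
#'   level, summing to 1).
#' @export
estimate_npo <- function(events, n_channels = NULL) {
  stopifnot(inherits(events, "event_list"))
  total <- sum(events$duration)
  if (!is.finite(total) || total <= 0)
    stop("total event duration is zero", call. = FALSE)
  maxlev <- if (nrow(events)) max(events$level) else 0L
  n_channels <- n_channels %||% max(1L, maxlev)
  if (n_channels < maxlev)
    stop("n_channels must be >= the maximum observed level", call. = FALSE)
  levs <- 0:max(maxlev, n_channels)
  p <- vapply(levs, function(l) sum(events$duration[events$level == l]) / total,
              numeric(1L))
  names(p) <- levs
  npo <- sum(levs * p)
  list(npo = npo, po = npo / n_channels, p_levels = p)
}
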