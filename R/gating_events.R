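#' Detect a sustained hydrogen-bond break in a distance series
#'
#' Finds the first time the distance exceeds `threshold` continuously for at
#' least `persistence`; a break of the D64-Y51 interaction (distance larger
#' than about 0.7 nm) followed by an aspartate flip is the canonical use.
#' Re-arming of the detector (for inspection of later events via
#' `all = TRUE`) requires the distance to drop below
#' `threshold - hysteresis` first.
#'
#' @param series data.frame with `time` (ns, strictly increasing) and
#'   `value` (nm).
#' @param threshold break threshold, nm.
#' @param persistence minimum continuous exceedance, ns.
#' @param hysteresis re-arming margin below the threshold, nm.
#' @param replica_id optional replica identifier carried into the result.
#' @param all return all detected events instead of the first.
#' @return a data.frame of events (`replica_id`, `time`, `direction`,
#'   `sustained`), or `NULL` when none; `direction` is `"break"`.
#' @export
detect_hbond_break <- function(series, threshold = 0.7, persistence = 20,
                               hysteresis = 0.1, replica_id = NA,
                               all = FALSE) {
  check_series(series)
  if (length(series$time) > 1L &&
      persistence < min(diff(series$time)) - 1e-9)
    stop("persistence must be >= the sampling interval", call. = FALSE)
  t <- series$time; v <- series$value
  events <- numeric()
  armed <- TRUE
  i <- 1L; n <- length(t)
  while (i <= n) {
    if (armed && v[i] > threshold) {
      j <- i
      while (j < n && v[j + 1L] > threshold) j <- j + 1L
      if (t[j] - t[i] >= persistence) {
        events <- c(events, t[i])
        armed <- FALSE
        if (!all) break
      }
      i <- j + 1L
    } else {
      if (!armed && v[i] < threshold - hysteresis) armed <- TRUE
      i <- i + 1L
    }
  }
  if (!length(events)) return(NULL)
  data.frame(replica_id = replica_id, time = events, direction = "break",
             sustained = TRUE)
}

check_series <- function(series) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  if (any(!is.finite(series$value)))
    stop("non-finite values in distance series", call. = FALSE)
  if (is.unsorted(series$time, strictly = TRUE))
    stop("series time must be strictly increasing", call. = FALSE)
  invisible(series)
}

#' Estimate the conducting band of a cross-filter distance
#'
#' Baseline mean +/- `k` baseline SDs, estimated from the initial segment of
#' one or more replicas' diagonal CA-CA distance series.
#'
#' @param ... distance series data.frames (`time`, `value`).
#' @param t_max initial segment used for the estimate, ns.
#' @param k band half-width in baseline SDs.
#' @return numeric length-2 vector `c(lo, hi)`, nm.
#' @export
conducting_band <- function(..., t_max = 250, k = 3) {
  vals <- unlist(lapply(list(...), function(s) {
    check_series(s); s$value[s$time <= t_max]
  }))
  if (length(vals) < 2L) stop("not enough baseline samples", call. = FALSE)
  m <- mean(vals); s <- stats::sd(vals)
  c(m - k * s, m + k * s)
}

#' Detect a filter inactivation transition (first passage)
#'
#' Inactivation is scored on the two diagonal cross-filter distance pairs
#' (e.g., G63 CA-CA of oppositely oriented monomers): the first time either
#' pair leaves the conducting band continuously for at least `persistence`.
#' Direction is `dilation` above the band, `constriction` below. The
#' transition is treated as irreversible: at most one event per replica,
#' at the first passage, regardless of later re-entry.
#'
#' @param pair13,pair24 data.frames (`time`, `value`) for the two diagonal
#'   pairs; resampled to `pair13`'s grid by previous-value hold if needed.
#' @param conducting_band numeric `c(lo, hi)`, nm.
#' @param persistence minimum continuous excursion, ns.
#' @param replica_id optional replica identifier.
#' @return one-row data.frame (`replica_id`, `time`, `direction`,
#'   `sustained`, `pair`), or `NULL` when neither pair leaves the band.
#' @export
detect_inactivation <- function(pair13, pair24, conducting_band,
                                persistence = 20, replica_id = NA) {
  check_series(pair13); check_series(pair24)
  if (length(conducting_band) != 2L ||
      conducting_band[1L] >= conducting_band[2L])
    stop("conducting_band must be c(lo, hi) with lo < hi", call. = FALSE)
  grid <- pair13$time
  v24 <- resample_hold(pair24, grid)
  first_excursion <- function(v) {
    out <- ifelse(v > conducting_band[2L], 1L,
                  ifelse(v < conducting_band[1L], -1L, 0L))
    r <- rle(out)
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L) next
      span <- grid[ends[k]] - grid[starts[k]]
      # a run reaching the end of the record is an (ongoing) excursion
      if (span >= persistence)
        return(list(time = grid[starts[k]],
                    direction = if (r$values[k] > 0) "dilation"
                                else "constriction"))
    }
    NULL
  }
  e13 <- first_excursion(pair13$value)
  e24 <- first_excursion(v24)
  cand <- Filter(Negate(is.null), list(pair13 = e13, pair24 = e24))
  if (!length(cand)) return(NULL)
  times <- vapply(cand, `[[`, numeric(1L), "time")
  w <- which.min(times)
  data.frame(replica_id = replica_id, time = cand[[w]]$time,
             direction = cand[[w]]$direction, sustained = TRUE,
             pair = names(cand)[w])
}

# Previous-value-hold resampling of (time, value) onto a new grid; distances
# are never interpolated across gaps.
resample_hold <- function(series, grid) {
  idx <- findInterval(grid, series$time)
  idx[idx < 1L] <- 1L
  series$value[idx]
}

#' Cumulative event-count curve
#'
#' Non-decreasing step curve of the number of replicas that have undergone
#' their (unique, first-passage) transition by each time point.
#'
#' @param events data.frame with `replica_id` and `time` (one row per
#'   replica that transitioned).
#' @param n_replicas total replicas simulated.
#' @param time_grid times (ns) at which to evaluate the curve.
#' @return data.frame: `time`, `cumulative`.
#' @export
cumulative_events <- function(events, n_replicas, time_grid) {
  if (is.null(events) || !nrow(events))
    return(data.frame(time = time_grid, cumulative = 0L))
  if (anyDuplicated(events$replica_id))
    stop("duplicate replica_id: inactivation is first-passage, one event per replica",
         call. = FALSE)
  if (nrow(events) > n_replicas)
    stop("more events than replicas", call. = FALSE)
  if (any(events$time > max(time_grid) | events$time < min(time_grid)))
    stop("event times outside the time grid", call. = FALSE)
  cum <- vapply(time_grid, function(t) sum(events$time <= t), integer(1L))
  data.frame(time = time_grid, cumulative = cum)
}

#' Classify glutamate rotamer orientation per frame
#'
#' The E55 side chain is `vertical` when its carboxylate proton is
#' hydrogen-bonded to the D64 carboxylate (donor-acceptor distance at or
#' below the cutoff; 0.167 nm is the unrestrained-simulation average of the
#' vertical state) and `horizontal` otherwise.
#'
#' @param series data.frame (`time`, `value`): E55 proton to D64 carboxylate
#'   oxygen distance, nm. A list of four such series (one per monomer) gives
#'   a channel-averaged summary.
#' @param vertical_cutoff nm; classification threshold.
#' @return for one series: list with `orientation` (character per frame) and
#'   `frequency` (fraction vertical). For a list: per-monomer frequencies
#'   plus `channel_mean`.
#' @export
classify_rotamer <- function(series, vertical_cutoff = 0.25) {
  stop_if_not_scalar_pos(vertical_cutoff, "vertical_cutoff")
  if (is.data.frame(series)) {
    check_series(series)
    vert <- series$value <= vertical_cutoff
    return(list(orientation = ifelse(vert, "vertical", "horizontal"),
                frequency = mean(vert)))
  }
  freqs <- vapply(series, function(s)
    classify_rotamer(s, vertical_cutoff)$frequency, numeric(1L))
  list(per_monomer = freqs, channel_mean = mean(freqs))
}

#' Event-aligned probability curves
#'
#' Aligns per-replica series at each replica's event time (lag 0) and
#' averages across replicas at each lag; the SEM is across replicas. A
#' replica's series may be a single indicator/value column or one column per
#' monomer, in which case monomers are averaged first so a value of 1 means
#' the event is present in all four monomers simultaneously.
#'
#' @param series_list list of data.frames, one per replica: `time` plus one
#'   or more value columns, all on a common sampling interval.
#' @param event_times numeric, one per replica; `NA` replicas are skipped.
#' @param pre_window,post_window window before/after the event, ns.
#' @return data.frame of class `event_alignment`: `lag`, `mean`, `sem`, `n`.
#' @export
align_on_event <- function(series_list, event_times, pre_window,
                           post_window) {
  stopifnot(length(series_list) == length(event_times))
  stop_if_not_scalar_pos(pre_window, "pre_window")
  stop_if_not_scalar_pos(post_window, "post_window")
  use <- which(!is.na(event_times))
  if (!length(use)) stop("no replicas with events", call. = FALSE)
  dt <- diff(series_list[[use[1L]]]$time[1:2])
  lags <- seq(-pre_window, post_window, by = dt)
  acc <- matrix(NA_real_, length(lags), length(use))
  for (k in seq_along(use)) {
    s <- series_list[[use[k]]]
    vals <- as.matrix(s[, setdiff(names(s), "time"), drop = FALSE])
    v <- rowMeans(vals)
    want <- event_times[use[k]] + lags
    inside <- want >= s$time[1L] - dt / 2 &
      want <= s$time[length(s$time)] + dt / 2
    idx <- pmax(1L, pmin(length(v), round((want - s$time[1L]) / dt) + 1L))
    acc[inside, k] <- v[idx[inside]]
  }
  n <- rowSums(!is.na(acc))
  m <- rowMeans(acc, na.rm = TRUE)
  m[n == 0L] <- NA_real_
  sem <- apply(acc, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_
  })
  out <- data.frame(lag = lags, mean = m, sem = sem, n = n)
  class(out) <- c("event_alignment", "data.frame")
  out
}

#' Count additional water molecules behind the selectivity filter
#'
#' Either subtracts a crystallographic baseline from precomputed per-frame
#' tallies, or counts supplied coordinates inside a per-monomer region
#' (z interval and radial cutoff about the pore axis). "Additional" waters
#' are those beyond the crystallographic complement (2 for WT, 1 for the
#' V55E model).
#'
#' @param tallies matrix or data.frame of per-frame counts (frames x
#'   monomers), or `NULL` when `positions` is given.
#' @param baseline crystallographic water count subtracted per monomer.
#' @param positions optional data.frame (`frame`, `monomer`, `x`, `y`, `z`)
#'   of candidate water positions.
#' @param region list with `zlim` (length 2, nm) and `rcut` (nm) defining
#'   the behind-the-filter volume; required with `positions`.
#' @return matrix of additional-water counts (frames x monomers); negative
#'   adjusted counts are clamped to 0 with a warning.
#' @export
count_water_region <- function(tallies = NULL, baseline = 2,
                               positions = NULL, region = NULL) {
  if (is.null(tallies)) {
    stopifnot(!is.null(positions), !is.null(region))
    stopifnot(all(c("frame", "monomer", "x", "y", "z") %in% names(positions)))
    inside <- positions$z >= region$zlim[1L] & positions$z <= region$zlim[2L] &
      sqrt(positions$x^2 + positions$y^2) <= region$rcut
    p <- positions[inside, ]
    frames <- sort(unique(positions$frame))
    monos <- sort(unique(positions$monomer))
    tallies <- table(factor(p$frame, levels = frames),
                     factor(p$monomer, levels = monos))
    tallies <- matrix(as.integer(tallies), nrow = length(frames),
                      dimnames = list(NULL, monos))
  }
  tallies <- as.matrix(tallies)
  adj <- tallies - baseline
  if (any(adj < 0)) {
    warning("negative adjusted water counts clamped to 0")
    adj[adj < 0] <- 0
  }
  adj
}

#' pKa shift from a deprotonation free energy
#'
#' \eqn{\Delta pKa = \Delta G / (2.303 R T)}. The helper field `pKa` adds
#' the shift to the solution glutamate reference value of 4.
#'
#' @param delta_G deprotonation free-energy difference, kJ/mol.
#' @param temperature temperature, K.
#' @param reference_pKa solution pKa the shift is applied to.
#' @return object of class `delta_pka`: list with `delta_G`, `temperature`,
#'   `delta_pKa`, `pKa`.
#' @examples
#' delta_pka(40)$delta_pKa # about 7.0
#' @export
delta_pka <- function(delta_G, temperature = 298, reference_pKa = 4) {
  stop_if_not_scalar_pos(temperature, "temperature")
  dpka <- delta_G * 1000 / (2.303 * .R_gas * temperature)
  structure(list(delta_G = delta_G, temperature = temperature,
                 delta_pKa = dpka, pKa = reference_pKa + dpka),
            class = "delta_pka")
}

#' @export
print.delta_pka <- function(x, ...) {
  cat(sprintf(
    "dG = %.2f kJ/mol at %g K -> dpKa = %.2f (pKa %.2f from reference 4)\n",
    x$delta_G, x$temperature, x$delta_pKa, x$pKa))
  invisible(x)
}
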