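#' Gating model for synthetic single-channel simulation
#'
#' A continuous-time Markov gating scheme. States carry a conductance class
#' (0 = closed, 1 = open, higher integers allowed for aggregated schemes);
#' transition rates are in 1/ms.
#'
#' @param states character vector of state labels.
#' @param conductance integer vector, conductance class per state.
#' @param rate_matrix square matrix of transition rates (1/ms); diagonal is
#'   recomputed as minus the off-diagonal row sum.
#' @param n_channels number of independent channels.
#' @return an object of class `gating_model`.
#' @examples
#' two_state_model(open_ms = 23.6, closed_ms = 58.2)
#' @export
gating_model <- function(states, conductance, rate_matrix, n_channels = 1L) {
  stopifnot(length(states) == length(conductance),
            is.matrix(rate_matrix),
            nrow(rate_matrix) == length(states),
            ncol(rate_matrix) == length(states))
  if (n_channels < 1L) stop("n_channels must be >= 1", call. = FALSE)
  off <- rate_matrix; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  diag(rate_matrix) <- -rowSums(off)
  if (!any(conductance > 0) || !any(conductance == 0))
    stop("need at least one open and one closed state", call. = FALSE)
  # ergodicity: every state must reach an open state (no absorbing closed set)
  reach <- off > 0
  n <- length(states)
  for (i in seq_len(n)) reach <- reach | (reach %*% reach > 0) # transitive closure
  can_open <- conductance > 0
  ok <- can_open | apply(reach[, can_open, drop = FALSE], 1L, any)
  if (!all(ok))
    stop("rate matrix has an absorbing closed set: state(s) ",
         paste(states[!ok], collapse = ", "),
         " cannot reach an open state", call. = FALSE)
  structure(list(states = states, conductance = as.integer(conductance),
                 rate_matrix = rate_matrix, n_channels = as.integer(n_channels)),
            class = "gating_model")
}

#' Two-state open/closed gating model
#'
#' @param open_ms mean open duration (ms); the open -> closed rate is
#'   1/open_ms.
#' @param closed_ms mean closed duration (ms).
#' @param n_channels number of independent channels.
#' @return a `gating_model` with states `closed`, `open`.
#' @export
two_state_model <- function(open_ms, closed_ms, n_channels = 1L) {
  stop_if_not_scalar_pos(open_ms, "open_ms")
  stop_if_not_scalar_pos(closed_ms, "closed_ms")
  Q <- matrix(c(0, 1 / closed_ms,
                1 / open_ms, 0), 2L, 2L, byrow = TRUE)
  gating_model(c("closed", "open"), c(0L, 1L), Q, n_channels)
}

#' Recording specification for synthetic traces
#'
#' @param sampling_rate digitization rate, Hz.
#' @param filter_cutoff Gaussian low-pass -3 dB cutoff, Hz, or `NULL` for no
#'   filtering.
#' @param noise_sd SD of white Gaussian noise (pA) added before filtering.
#' @param baseline closed-level current, pA.
#' @param open_amplitude unitary current of one open channel, pA.
#' @param duration record duration, s.
#' @param seed RNG seed (required; generators never use global RNG state).
#' @return an object of class `recording_spec`.
#' @export
recording_spec <- function(sampling_rate = 50000, filter_cutoff = 1000,
                           noise_sd = 0.4, baseline = 0,
                           open_amplitude = 14.78, duration = 10,
                           seed) {
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  stop_if_not_scalar_pos(duration, "duration")
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(filter_cutoff) && sampling_rate <= 2 * filter_cutoff)
    stop("sampling_rate must exceed 2 * filter_cutoff", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, filter_cutoff = filter_cutoff,
                 noise_sd = noise_sd, baseline = baseline,
                 open_amplitude = open_amplitude, duration = duration,
                 seed = seed),
            class = "recording_spec")
}

# Gillespie simulation of the gating CTMC for one channel.
# Returns data.frame(state, level, start_ms, duration_ms).
simulate_dwells <- function(model, duration_ms) {
  Q <- model$rate_matrix
  n <- nrow(Q)
  exit <- -diag(Q)
  # stationary distribution of the CTMC for the initial state
  A <- rbind(t(Q), rep(1, n))
  pi0 <- as.numeric(qr.solve(A, c(rep(0, n), 1)))
  pi0 <- pmax(pi0, 0); pi0 <- pi0 / sum(pi0)
  s <- sample.int(n, 1L, prob = pi0)
  cap <- max(16L, ceiling(duration_ms * sum(pi0 * exit)) * 2L + 16L)
  st <- integer(cap); dur <- numeric(cap)
  t <- 0; i <- 0L
  while (t < duration_ms) {
    i <- i + 1L
    if (i > cap) { # grow
      st <- c(st, integer(cap)); dur <- c(dur, numeric(cap)); cap <- 2L * cap
    }
    d <- if (exit[s] > 0) stats::rexp(1L, exit[s]) else duration_ms - t
    st[i] <- s; dur[i] <- min(d, duration_ms - t)
    t <- t + d
    if (t < duration_ms) {
      p <- Q[s, ]; p[s] <- 0
      s <- sample.int(n, 1L, prob = p)
    }
  }
  st <- st[seq_len(i)]; dur <- dur[seq_len(i)]
  data.frame(state = model$states[st],
             level = model$conductance[st],
             start_ms = cumsum(c(0, dur[-i])),
             duration_ms = dur)
}

# Merge consecutive dwells with equal conductance level.
merge_levels <- function(dw) {
  r <- rle(dw$level)
  idx_end <- cumsum(r$lengths)
  idx_start <- c(1L, idx_end[-length(idx_end)] + 1L)
  data.frame(level = r$values,
             start_ms = dw$start_ms[idx_start],
             duration_ms = dw$start_ms[idx_end] + dw$duration_ms[idx_end] -
               dw$start_ms[idx_start])
}

# Rasterize a piecewise-constant level path onto the sampling grid by
# fractional-sample area weighting, so sub-sample events attenuate
# realistically rather than rounding to whole samples.
rasterize_dwells <- function(level, start_ms, duration_ms, n_samples, dt_ms) {
  out <- numeric(n_samples)
  for (k in seq_along(level)) {
    L <- level[k]
    if (L == 0) next
    a <- start_ms[k]; b <- a + duration_ms[k]
    i0 <- floor(a / dt_ms); i1 <- floor((b - 1e-12) / dt_ms)
    i0 <- max(0L, min(i0, n_samples - 1L))
    i1 <- max(0L, min(i1, n_samples - 1L))
    if (i0 == i1) {
      out[i0 + 1L] <- out[i0 + 1L] + L * (b - a) / dt_ms
    } else {
      out[i0 + 1L] <- out[i0 + 1L] + L * ((i0 + 1) * dt_ms - a) / dt_ms
      out[i1 + 1L] <- out[i1 + 1L] + L * (b - i1 * dt_ms) / dt_ms
      if (i1 - i0 > 1L)
        out[(i0 + 2L):i1] <- out[(i0 + 2L):i1] + L
    }
  }
  out
}

#' Simulate a single-channel current trace with known gating ground truth
#'
#' Gillespie-samples the gating scheme (independently per channel), sums the
#' conductance levels, rasterizes onto the sampling grid by fractional-sample
#' area weighting, adds white Gaussian noise, and applies the Gaussian
#' low-pass filter of the recording spec.
#'
#' @param model a `gating_model`.
#' @param spec a `recording_spec`.
#' @return list with `trace` (a `current_trace`) and `events` (the exact
#'   pre-noise, pre-filter dwell sequence as an [event_list()]:
#'   level, start (s), duration (s)).
#' @export
simulate_gating_trace <- function(model, spec) {
  stopifnot(inherits(model, "gating_model"), inherits(spec, "recording_spec"))
  duration_ms <- spec$duration * 1000
  dt_ms <- 1000 / spec$sampling_rate
  n_samples <- round(spec$duration * spec$sampling_rate)
  with_seed(spec$seed, {
    lev_frac <- numeric(n_samples)
    paths <- vector("list", model$n_channels)
    for (ch in seq_len(model$n_channels)) {
      dw <- simulate_dwells(model, duration_ms)
      paths[[ch]] <- dw
      lev_frac <- lev_frac + rasterize_dwells(dw$level, dw$start_ms,
                                              dw$duration_ms, n_samples, dt_ms)
    }
    x <- spec$baseline + spec$open_amplitude * lev_frac
    if (spec$noise_sd > 0) x <- x + stats::rnorm(n_samples, 0, spec$noise_sd)
    if (!is.null(spec$filter_cutoff))
      x <- gaussian_filter(x, spec$filter_cutoff, spec$sampling_rate)
    trace <- current_trace(x, spec$sampling_rate, spec$filter_cutoff)
    # ground truth: summed level path across channels, merged by level
    if (model$n_channels == 1L) {
      gt <- merge_levels(paths[[1L]])
    } else {
      bounds <- sort(unique(c(0, unlist(lapply(paths, function(d)
        d$start_ms)), duration_ms)))
      mid <- (bounds[-1] + bounds[-length(bounds)]) / 2
      lev <- rowSums(vapply(paths, function(d) {
        idx <- findInterval(mid, d$start_ms)
        d$level[idx]
      }, numeric(length(mid))))
      gt <- merge_levels(data.frame(level = lev,
                                    start_ms = bounds[-length(bounds)],
                                    duration_ms = diff(bounds)))
    }
    events <- event_list(level = gt$level, start = gt$start_ms / 1000,
                         duration = gt$duration_ms / 1000,
                         n_levels = model$n_channels,
                         dead_time = if (is.null(spec$filter_cutoff)) NA_real_
                                     else dead_time(spec$filter_cutoff))
    list(trace = trace, events = events)
  })
}

#' Simulate open-probability vs voltage data by binomial sampling
#'
#' Generates per-sweep Po estimates as binomial draws around the Boltzmann
#' open-probability curve
#' \eqn{Po(V) = Pomax / (1 + exp(z\delta (V - V_{1/2}) / k_B T))}.
#'
#' @param params a [boltzmann_params()] object.
#' @param voltages voltages in mV.
#' @param events_per_voltage binomial n per sweep.
#' @param sweeps number of replicate sweeps per voltage.
#' @param seed RNG seed.
#' @return a `pov_data` data.frame with columns `voltage`, `po_mean`,
#'   `po_sem`, `n_replicas`, and the per-sweep matrix in attribute `sweeps`.
#' @export
simulate_po_voltage <- function(params, voltages, events_per_voltage = 1000,
                                sweeps = 5, seed) {
  stopifnot(inherits(params, "boltzmann_params"), length(voltages) >= 1L,
            events_per_voltage >= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  p <- boltzmann_po(voltages, params)
  with_seed(seed, {
    m <- vapply(p, function(pi)
      stats::rbinom(sweeps, events_per_voltage, pi) / events_per_voltage,
      numeric(sweeps))
    m <- matrix(m, nrow = sweeps)
    out <- data.frame(voltage = voltages,
                      po_mean = colMeans(m),
                      po_sem = if (sweeps > 1)
                        apply(m, 2L, stats::sd) / sqrt(sweeps) else NA_real_,
                      n_replicas = sweeps)
    attr(out, "sweeps") <- m
    class(out) <- c("pov_data", "data.frame")
    out
  })
}

#' Discrete-hop model of K+ movement across the selectivity filter
#'
#' Ions hop on a 1-D chain of binding sites (cavity, Scav, S4..S0,
#' extracellular) with per-boundary forward (outward) and backward rates.
#'
#' @param geom an [sf_geometry()] giving site centers; the hop chain uses
#'   its ordered sites.
#' @param forward_rates,backward_rates rates (1/ns) per boundary between
#'   adjacent sites; length = number of sites - 1. Scalars are recycled.
#' @param n_ions number of ions.
#' @param duration trajectory length, ns.
#' @param frame_interval frame spacing, ns.
#' @param jitter_sd Gaussian positional jitter about the site center, nm.
#' @param seed RNG seed.
#' @return an object of class `hop_model`.
#' @export
hop_model <- function(geom = sf_geometry(), forward_rates = 0.5,
                      backward_rates = 0.5, n_ions = 10, duration = 100,
                      frame_interval = 0.1, jitter_sd = 0.03, seed) {
  stopifnot(inherits(geom, "sf_geometry"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  nb <- length(geom$centers) - 1L
  forward_rates <- rep_len(forward_rates, nb)
  backward_rates <- rep_len(backward_rates, nb)
  if (any(forward_rates < 0) || any(backward_rates < 0))
    stop("hop rates must be >= 0", call. = FALSE)
  if (frame_interval > duration)
    stop("frame_interval must not exceed duration", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  structure(list(geom = geom, forward_rates = forward_rates,
                 backward_rates = backward_rates, n_ions = as.integer(n_ions),
                 duration = duration, frame_interval = frame_interval,
                 jitter_sd = jitter_sd, seed = seed),
            class = "hop_model")
}

# Continuous-time hop path of one ion: site index vs time.
hop_path <- function(site0, fr, br, n_sites, duration) {
  t <- 0; s <- site0
  ts <- numeric(64L); ss <- integer(64L); i <- 0L
  while (TRUE) {
    i <- i + 1L
    if (i > length(ss)) { ts <- c(ts, numeric(length(ts))); ss <- c(ss, integer(length(ss))) }
    ts[i] <- t; ss[i] <- s
    up <- if (s < n_sites) fr[s] else 0
    dn <- if (s > 1L) br[s - 1L] else 0
    tot <- up + dn
    if (tot == 0) break
    t <- t + stats::rexp(1L, tot)
    if (t >= duration) break
    s <- if (stats::runif(1L) < up / tot) s + 1L else s - 1L
  }
  list(time = ts[seq_len(i)], site = ss[seq_len(i)])
}

#' Simulate discrete-hop ion trajectories with exact crossing ground truth
#'
#' Each ion performs a continuous-time random walk over the site chain; the
#' trajectory is sampled at the frame interval and the per-frame z is the
#' occupied site center plus Gaussian jitter. Ground-truth outward/inward
#' full-traversal counts are computed from the frame-resolution site path
#' (the path as a frame-based observer sees it).
#'
#' @param model a `hop_model`.
#' @return list with `trajectories` (an `ion_trajectory` data.frame: ion,
#'   time, z, site), `n_outward`, `n_inward` (ground truth), and
#'   `site_path` (matrix of true site indices, frames x ions).
#' @export
simulate_ion_hops <- function(model) {
  stopifnot(inherits(model, "hop_model"))
  g <- model$geom
  n_sites <- length(g$centers)
  times <- seq(0, model$duration, by = model$frame_interval)
  nf <- length(times)
  with_seed(model$seed, {
    start_sites <- sample.int(n_sites, model$n_ions, replace = TRUE)
    site_mat <- matrix(0L, nf, model$n_ions)
    for (j in seq_len(model$n_ions)) {
      p <- hop_path(start_sites[j], model$forward_rates, model$backward_rates,
                    n_sites, model$duration)
      site_mat[, j] <- p$site[findInterval(times, p$time)]
    }
    z <- g$centers[site_mat]
    if (model$jitter_sd > 0)
      z <- z + stats::rnorm(length(z), 0, model$jitter_sd)
    traj <- data.frame(ion = rep(seq_len(model$n_ions), each = nf),
                       time = rep(times, model$n_ions),
                       z = as.numeric(z),
                       site = g$sites[as.integer(site_mat)])
    class(traj) <- c("ion_trajectory", "data.frame")
    # ground truth from the true (jitter-free) frame-resolution site path
    gt <- count_site_traversals(site_mat, n_sites)
    list(trajectories = traj, n_outward = gt$n_outward,
         n_inward = gt$n_inward, site_path = site_mat)
  })
}

# Full-traversal counts on a frames x ions matrix of site indices
# (1 = innermost/cavity, n_sites = outermost/extracellular). An outward
# traversal: ion reaches site n_sites having last entered the interior from
# site 1. Independent of, and structured differently from, count_crossings
# (which works on z and zone geometry).
count_site_traversals <- function(site_mat, n_sites) {
  n_out <- 0L; n_in <- 0L
  for (j in seq_len(ncol(site_mat))) {
    s <- site_mat[, j]
    s <- s[c(TRUE, diff(s) != 0)]
    edge <- s == 1L | s == n_sites
    key <- s[edge]
    if (length(key) > 1L) {
      d <- diff(key)
      n_out <- n_out + sum(d > 0)
      n_in <- n_in + sum(d < 0)
    }
  }
  list(n_outward = n_out, n_inward = n_in)
}

#' Specification for planted-step distance series
#'
#' Mean-reverting (AR(1)-discretized Ornstein-Uhlenbeck) baseline with an
#' optional irreversible step of the mean at `event_time`, emulating
#' hydrogen-bond break or filter-dilation distance traces.
#'
#' @param baseline_mean,baseline_sd stationary mean and SD, nm.
#' @param relaxation_time autocorrelation time of the baseline, ns.
#' @param event_time time of the planted step (ns), or `NA` for no event.
#' @param post_mean mean after the step, nm.
#' @param n_replicas number of replicas.
#' @param duration series length, ns.
#' @param dt sampling interval, ns.
#' @param seed RNG seed.
#' @return an object of class `planted_series_spec`.
#' @export
planted_series_spec <- function(baseline_mean = 0.45, baseline_sd = 0.05,
                                relaxation_time = 5, event_time = NA,
                                post_mean = 1.05, n_replicas = 1,
                                duration = 5000, dt = 1, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (baseline_sd < 0) stop("baseline_sd must be >= 0", call. = FALSE)
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(relaxation_time, "relaxation_time")
  ev <- event_time[!is.na(event_time)]
  if (any(ev < 0 | ev > duration))
    stop("event_time must lie in [0, duration]", call. = FALSE)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 relaxation_time = relaxation_time, event_time = event_time,
                 post_mean = post_mean, n_replicas = as.integer(n_replicas),
                 duration = duration, dt = dt, seed = seed),
            class = "planted_series_spec")
}

#' Generate planted-step distance series
#'
#' @param spec a [planted_series_spec()]. `event_time` may be a vector
#'   (recycled over replicas); `NA` entries produce event-free replicas.
#' @return list with `series` (list of data.frames: time, value, one per
#'   replica) and `ground_truth` (data.frame: replica_id, event_time).
#' @export
plant_flip_series <- function(spec) {
  stopifnot(inherits(spec, "planted_series_spec"))
  times <- seq(0, spec$duration, by = spec$dt)
  n <- length(times)
  phi <- exp(-spec$dt / spec$relaxation_time)
  innov_sd <- spec$baseline_sd * sqrt(1 - phi^2)
  ev <- rep_len(spec$event_time, spec$n_replicas)
  with_seed(spec$seed, {
    series <- vector("list", spec$n_replicas)
    for (r in seq_len(spec$n_replicas)) {
      mu <- rep(spec$baseline_mean, n)
      if (!is.na(ev[r])) mu[times >= ev[r]] <- spec$post_mean
      # AR(1)-discretized OU deviation about the (stepping) mean path, so
      # the planted step of the mean itself is instantaneous
      d <- numeric(n)
      d[1L] <- if (spec$baseline_sd > 0)
        stats::rnorm(1L, 0, spec$baseline_sd) else 0
      if (n > 1L && innov_sd > 0) {
        eps <- stats::rnorm(n - 1L, 0, innov_sd)
        for (i in 2:n) d[i] <- phi * d[i - 1L] + eps[i - 1L]
      }
      series[[r]] <- data.frame(time = times, value = mu + d)
      attr(series[[r]], "replica_id") <- r
    }
    list(series = series,
         ground_truth = data.frame(replica_id = seq_len(spec$n_replicas),
                                   event_time = ev))
  })
}

#' Printed study-condition presets
#'
#' Single-channel gating and amplitude parameters for the MthK wild-type and
#' V55E channels at 200 mV in symmetric 200 mM K+ (mean open/closed dwell
#' times in ms, unitary amplitude in pA), and Boltzmann gating parameters for
#' the Po-voltage curves (V1/2 in mV, e-fold slope in mV, at 295 K).
#'
#' @return nested list of named parameter sets.
#' @export
mthk_presets <- function() {
  temp <- 295
  list(
    wt_200mV = list(open_ms = 23.6, closed_ms = 58.2, amplitude_pA = 14.78),
    v55e_200mV = list(open_ms = 0.41, closed_ms = 9.11, amplitude_pA = 8.98),
    boltzmann_wt_200K = boltzmann_params(
      Pomax = 0.95, z_delta = kT_mV(temp) / 14, V_half = 190,
      temperature = temp),
    boltzmann_wt_5K = boltzmann_params(
      Pomax = 0.95, z_delta = kT_mV(temp) / 14, V_half = 95,
      temperature = temp)
  )
}
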