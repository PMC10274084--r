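# Shared fixture builders; everything is generated in code at test time.

# Noise-free, unfiltered trace from grid-aligned dwells (durations in
# samples), so idealization identities are exact.
grid_trace <- function(levels, n_samples_each, amplitude = 10,
                       sampling_rate = 50000, baseline = 0,
                       filter_cutoff = NULL) {
  x <- baseline + amplitude * rep(levels, n_samples_each)
  tr <- current_trace(x, sampling_rate, filter_cutoff = NULL)
  if (!is.null(filter_cutoff)) tr <- gaussian_filter(tr, filter_cutoff)
  tr
}

expected_event_list <- function(levels, n_samples_each,
                                sampling_rate = 50000) {
  dt <- 1 / sampling_rate
  starts <- cumsum(c(0L, n_samples_each[-length(n_samples_each)])) * dt
  event_list(level = levels, start = starts,
             duration = n_samples_each * dt)
}

# Single filtered rectangular opening with sub-sample placement, returned
# with the surrounding closed baseline.
pulse_trace <- function(width_s, amplitude = 10, sampling_rate = 50000,
                        filter_cutoff = 1000, pad_s = 0.01) {
  dt <- 1 / sampling_rate
  n <- round(2 * pad_s / dt)
  lev <- sfgating:::rasterize_dwells(1, pad_s * 1000, width_s * 1000,
                                     n, dt * 1000)
  tr <- current_trace(amplitude * lev, sampling_rate)
  gaussian_filter(tr, filter_cutoff)
}

# analytic peak response of a Gaussian filter (continuous-time oracle,
# independent of the package's discrete-convolution path)
analytic_pulse_peak <- function(width_s, filter_cutoff) {
  sigma <- 0.1325 / filter_cutoff
  2 * stats::pnorm(width_s / (2 * sigma)) - 1
}

make_series <- function(value, dt = 1) {
  data.frame(time = seq(0, by = dt, length.out = length(value)),
             value = value)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
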