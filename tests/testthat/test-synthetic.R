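test_that("gating model validates rates and rejects absorbing closed sets", {
  expect_s3_class(two_state_model(23.6, 58.2), "gating_model")
  # closed states 1,2 only exchange with each other: absorbing closed set
  Q <- matrix(c(0, 1, 0,
                1, 0, 0,
                0, 1, 0), 3, 3, byrow = TRUE)
  expect_error(gating_model(c("c1", "c2", "o"), c(0L, 0L, 1L), Q),
               "absorbing closed set")
  Qneg <- matrix(c(0, -1, 1, 0), 2, 2, byrow = TRUE)
  expect_error(gating_model(c("c", "o"), c(0L, 1L), Qneg), "rates")
})

test_that("identical seed gives bit-identical simulated outputs", {
  m <- two_state_model(5, 10)
  sp <- recording_spec(duration = 0.5, seed = 7)
  a <- simulate_gating_trace(m, sp)
  b <- simulate_gating_trace(m, sp)
  expect_identical(a$trace$current, b$trace$current)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  h1 <- simulate_ion_hops(hop_model(n_ions = 3, duration = 20, seed = 5))
  h2 <- simulate_ion_hops(hop_model(n_ions = 3, duration = 20, seed = 5))
  expect_identical(h1$trajectories$z, h2$trajectories$z)
})

test_that("noise-free unfiltered trace reproduces the dwell path sample-for-sample", {
  m <- two_state_model(4, 6)
  sp <- recording_spec(filter_cutoff = NULL, noise_sd = 0, baseline = -1,
                       open_amplitude = 8, duration = 1, seed = 3)
  sim <- simulate_gating_trace(m, sp)
  ev <- sim$events
  lev <- sfgating:::rasterize_dwells(ev$level, ev$start * 1000,
                                     ev$duration * 1000,
                                     length(sim$trace$current),
                                     1000 / sp$sampling_rate)
  expect_equal(sim$trace$current, -1 + 8 * lev, tolerance = 1e-8)
  # away from dwell boundaries the trace is exactly at the two levels
  expect_true(all(abs(sim$trace$current - (-1)) < 1e-9 |
                    abs(sim$trace$current - 7) < 1e-9 |
                    (sim$trace$current > -1 & sim$trace$current < 7)))
})

test_that("two-state occupancy matches the stationary distribution", {
  # open fraction 23.6/(23.6+58.2) = 0.2885
  m <- two_state_model(23.6, 58.2)
  sp <- recording_spec(filter_cutoff = NULL, noise_sd = 0, duration = 60,
                       seed = 11)
  sim <- simulate_gating_trace(m, sp)
  ev <- sim$events
  frac_open <- sum(ev$duration[ev$level == 1]) / sum(ev$duration)
  expect_equal(frac_open, 23.6 / (23.6 + 58.2), tolerance = 0.02 / 0.2885)
})

test_that("empirical dwell means sit within 3 SE of the model rates", {
  m <- two_state_model(5, 2)
  sp <- recording_spec(filter_cutoff = NULL, noise_sd = 0, duration = 30,
                       seed = 13)
  ev <- simulate_gating_trace(m, sp)$events
  for (lv in 0:1) {
    d <- ev$duration[ev$level == lv] * 1000
    truth <- if (lv == 1) 5 else 2
    se <- truth / sqrt(length(d)) # exponential: sd = mean
    expect_lt(abs(mean(d) - truth), 3 * se)
  }
})

test_that("an opening lasting one dead time is filtered to half amplitude", {
  td <- dead_time(1000)
  tr <- pulse_trace(td, amplitude = 10, filter_cutoff = 1000)
  expect_equal(max(tr$current), 5, tolerance = 0.01)
})

test_that("Gaussian filtering commutes with amplitude scaling", {
  m <- two_state_model(3, 7)
  sp <- recording_spec(filter_cutoff = NULL, noise_sd = 0, duration = 1,
                       open_amplitude = 1, seed = 17)
  x <- simulate_gating_trace(m, sp)$trace$current
  f1 <- gaussian_filter(5.5 * x, 1000, 50000)
  f2 <- 5.5 * gaussian_filter(x, 1000, 50000)
  expect_lt(max(abs(f1 - f2)) / max(abs(f2)), 1e-9)
})

test_that("simulated Po-voltage sweeps are binomial around the Boltzmann curve", {
  p <- boltzmann_params(Pomax = 0.9, z_delta = 1.8, V_half = 190)
  v <- c(150, 190, 230)
  d <- simulate_po_voltage(p, v, events_per_voltage = 1e5, sweeps = 4,
                           seed = 19)
  truth <- boltzmann_po(v, p)
  se <- sqrt(truth * (1 - truth) / (4 * 1e5))
  expect_true(all(abs(d$po_mean - truth) < 3 * se))
  # zero valence gives a flat curve at Pomax/2
  flat <- boltzmann_po(seq(-200, 200, 50),
                       boltzmann_params(0.9, 0, 100))
  expect_equal(flat, rep(0.45, 9))
  expect_error(simulate_po_voltage(p, v, 1000, 5), "seed")
})

test_that("hop simulator ground truth matches a monotone outward walk", {
  g <- sf_geometry()
  m <- hop_model(g, forward_rates = 2, backward_rates = 0, n_ions = 1,
                 duration = 100, frame_interval = 0.05, jitter_sd = 0,
                 seed = 23)
  h <- simulate_ion_hops(m)
  # start site is random; a cavity start gives exactly one outward crossing
  if (h$site_path[1, 1] == 1L) {
    expect_identical(h$n_outward, 1L)
  } else {
    expect_lte(h$n_outward, 1L)
  }
  expect_identical(h$n_inward, 0L)
  # jitter-free z round-trips to the exact site labels
  lab <- assign_sites(h$trajectories[, c("ion", "time", "z")], g)
  expect_identical(lab$site, h$trajectories$site)
})

test_that("hop ground truth conserves side attribution exactly", {
  # outward - inward = net change in ions attributed above the filter
  for (s in 1:20) {
    h <- simulate_ion_hops(hop_model(n_ions = 6, duration = 60,
                                     frame_interval = 0.1, seed = 100 + s))
    sp <- h$site_path
    n_sites <- 8L
    side <- function(col) { # per-ion attributed side at first/last frame
      first <- col[col %in% c(1L, n_sites)]
      if (length(first))
        c(first[1L] == n_sites, first[length(first)] == n_sites)
      else c(NA, NA)
    }
    sides <- apply(sp, 2L, side)
    known <- !is.na(sides[1L, ])
    delta <- sum(sides[2L, known]) - sum(sides[1L, known])
    expect_identical(h$n_outward - h$n_inward, as.integer(delta))
  }
})

test_that("symmetric hop rates give no systematic net flux", {
  h <- simulate_ion_hops(hop_model(n_ions = 50, duration = 200,
                                   frame_interval = 0.1, seed = 29))
  tot <- h$n_outward + h$n_inward
  expect_lte(abs(h$n_outward - h$n_inward), max(3 * sqrt(tot), 3))
})

test_that("planted series are exact when noiseless and bookkeeping is right", {
  sp <- planted_series_spec(baseline_mean = 0.45, baseline_sd = 0,
                            event_time = 2000, post_mean = 1.05,
                            duration = 4000, dt = 1, seed = 31)
  out <- plant_flip_series(sp)
  s <- out$series[[1]]
  expect_true(all(s$value[s$time < 2000] == 0.45))
  expect_true(all(s$value[s$time >= 2000] == 1.05))
  # 20 replicas, 19 with events
  sp2 <- planted_series_spec(event_time = c(NA, rep(1000, 19)),
                             n_replicas = 20, duration = 2000, seed = 33)
  gt <- plant_flip_series(sp2)$ground_truth
  expect_identical(sum(!is.na(gt$event_time)), 19L)
  expect_identical(nrow(gt), 20L)
})

test_that("planted series have the requested stationary moments", {
  sp <- planted_series_spec(baseline_mean = 0.5, baseline_sd = 0.05,
                            relaxation_time = 2, event_time = NA,
                            duration = 20000, dt = 1, seed = 37)
  v <- plant_flip_series(sp)$series[[1]]$value
  expect_equal(mean(v), 0.5, tolerance = 0.01)
  expect_equal(sd(v), 0.05, tolerance = 0.15)
})
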