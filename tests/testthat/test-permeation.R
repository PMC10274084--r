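test_that("site assignment uses half-open intervals with the stated convention", {
  g <- sf_geometry()
  mid_S2 <- g$centers[g$sites == "S2"]
  d <- data.frame(ion = 1L, time = 1:3,
                  z = c(mid_S2, g$boundaries[1], g$boundaries[7]))
  lab <- assign_sites(d, g)
  expect_identical(lab$site, c("S2", "Scav", "ext"))
  # exactly on an interior boundary: lower interval is left behind ([lo, hi))
  d2 <- assign_sites(data.frame(z = g$boundaries[2]), g)
  expect_identical(d2$site, "S4")
  # outside the filter: labeled by side
  d3 <- assign_sites(data.frame(z = c(-5, 5)), g)
  expect_identical(d3$site, c("cavity", "ext"))
})

test_that("crossing counter scores full traversals only", {
  g <- sf_geometry()
  below <- g$entry_plane - 0.3
  inside <- mean(c(g$entry_plane, g$exit_plane))
  above <- g$exit_plane + 0.3
  mk <- function(z) data.frame(ion = 1L, time = seq_along(z), z = z)
  # monotone passage
  r <- count_crossings(mk(c(below, inside, above)), g)
  expect_identical(c(r$n_outward, r$n_inward), c(1L, 0L))
  # partial entry with retreat
  r2 <- count_crossings(mk(c(below, inside, below, inside, below)), g)
  expect_identical(c(r2$n_outward, r2$n_inward), c(0L, 0L))
  # round trip counts one each way
  r3 <- count_crossings(mk(c(below, inside, above, inside, below)), g)
  expect_identical(c(r3$n_outward, r3$n_inward), c(1L, 1L))
  # flicker at the top without re-entering from below adds nothing
  r4 <- count_crossings(mk(c(below, inside, above, inside, above)), g)
  expect_identical(c(r4$n_outward, r4$n_inward), c(1L, 0L))
  expect_error(count_crossings(mk(c(below, NaN, above)), g), "non-finite")
})

test_that("periodic-boundary wraps do not create phantom crossings", {
  g <- sf_geometry()
  Lz <- 10
  # ion exits above, wraps to the bottom of the box, re-enters from below
  z <- c(g$entry_plane - 0.2, 0.7, g$exit_plane + 0.2,
         g$exit_plane + 0.2 - Lz + 0.5, g$entry_plane - 0.2)
  r <- count_crossings(data.frame(ion = 1L, time = 1:5, z = z), g, Lz = Lz)
  expect_identical(r$n_outward, 1L)
  expect_identical(r$n_inward, 0L) # the wrap is not an inward passage
})

test_that("counter equals hop-simulator ground truth over 200 seeded sets", {
  g <- sf_geometry()
  mismatches <- 0L
  for (s in 1:200) {
    h <- simulate_ion_hops(hop_model(g, forward_rates = 0.6,
                                     backward_rates = 0.4, n_ions = 5,
                                     duration = 40, frame_interval = 0.2,
                                     jitter_sd = 0.03, seed = 5000 + s))
    r <- count_crossings(h$trajectories, g)
    if (r$n_outward != h$n_outward || r$n_inward != h$n_inward)
      mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("time reversal swaps outward and inward counts", {
  g <- sf_geometry()
  h <- simulate_ion_hops(hop_model(g, n_ions = 10, duration = 80,
                                   seed = 61))
  fw <- count_crossings(h$trajectories, g)
  rev_traj <- h$trajectories
  rev_traj$time <- -rev_traj$time
  bw <- count_crossings(rev_traj, g)
  expect_identical(bw$n_outward, fw$n_inward)
  expect_identical(bw$n_inward, fw$n_outward)
})

test_that("current conversion is exact and linear", {
  expect_equal(current_from_counts(0, 0, 100), 0)
  expect_equal(current_from_counts(10, 0, 100), 16.02177, tolerance = 1e-6)
  expect_equal(current_from_counts(20, 0, 100),
               2 * current_from_counts(10, 0, 100))
  expect_equal(current_from_counts(10, 0, 200),
               current_from_counts(10, 0, 100) / 2)
  expect_equal(current_from_counts(7, 3, 50), current_from_counts(4, 0, 50))
})

test_that("site occupancy is a presence probability", {
  g <- sf_geometry()
  zS2 <- g$centers[g$sites == "S2"]
  zS3 <- g$centers[g$sites == "S3"]
  # one ion parked in S2
  d <- assign_sites(data.frame(ion = 1L, time = 1:100, z = rep(zS2, 100)), g)
  occ <- site_occupancy(d, g)
  expect_equal(occ$presence[occ$site == "S2"], 1)
  expect_true(all(occ$presence[occ$site != "S2"] == 0))
  # alternating S2/S3
  d2 <- assign_sites(data.frame(ion = 1L, time = 1:100,
                                z = rep(c(zS2, zS3), 50)), g)
  occ2 <- site_occupancy(d2, g)
  expect_equal(occ2$presence[occ2$site %in% c("S2", "S3")], c(0.5, 0.5))
  # two ions in one site count once for presence, twice for mean count
  d3 <- assign_sites(data.frame(ion = rep(1:2, each = 10),
                                time = rep(1:10, 2),
                                z = rep(zS2, 20)), g)
  occ3 <- site_occupancy(d3, g)
  expect_equal(occ3$presence[occ3$site == "S2"], 1)
  expect_equal(occ3$mean_count[occ3$site == "S2"], 2)
})

test_that("hop-model occupancy matches the analytic stationary distribution", {
  # detailed balance on a birth-death chain: pi_{j+1}/pi_j = f/b
  f <- 0.6; b <- 0.4
  g <- sf_geometry()
  h <- simulate_ion_hops(hop_model(g, forward_rates = f, backward_rates = b,
                                   n_ions = 40, duration = 400,
                                   frame_interval = 0.5, jitter_sd = 0,
                                   seed = 67))
  ratio <- (f / b)^(0:7)
  pi_stat <- ratio / sum(ratio)
  emp <- prop.table(table(factor(h$trajectories$site, levels = g$sites)))
  # compare the interior sites with 3 SE binomial slack (frames correlated;
  # use the number of ions as the effective sample unit per frame block)
  n_eff <- 40 * 10
  for (k in 2:7) {
    se <- sqrt(pi_stat[k] * (1 - pi_stat[k]) / n_eff)
    expect_lt(abs(emp[[g$sites[k]]] - pi_stat[k]), 5 * se + 0.02)
  }
})

test_that("free-energy profiles are flat for uniform density and shift-invariant", {
  set.seed(71)
  g <- sf_geometry()
  z <- runif(1e5, g$centers[1], g$centers[8])
  prof <- free_energy_profile(z, bins = 40, geom = g)
  expect_lt(max(abs(prof$G[!prof$masked])), 0.15)
  expect_equal(min(prof$G[!prof$masked]), 0)
  # shift invariance
  prof2 <- free_energy_profile(z + 3, bins = 40,
                               range = c(g$centers[1], g$centers[8]) + 3)
  expect_equal(prof2$G, prof$G, tolerance = 1e-12)
  expect_error(free_energy_profile(numeric(0)), "at least one")
  expect_error(free_energy_profile(100, range = c(0, 1), bins = 10),
               "empty")
})

test_that("a planted double-well profile is recovered by Boltzmann inversion", {
  # G(z) with two wells and a central barrier, amplitude ~3 kT
  zgrid <- seq(0, 1.55, length.out = 2000)
  G_true <- 3 * (cos(2 * pi * (zgrid - 0.2) / 1.35) + 1) / 2
  G_true <- G_true - min(G_true)
  dens <- exp(-G_true); dens <- dens / sum(dens)
  set.seed(73)
  n <- 2e5
  idx <- sample.int(length(zgrid), n, replace = TRUE, prob = dens)
  dz <- zgrid[2] - zgrid[1]
  z <- zgrid[idx] + runif(n, -dz / 2, dz / 2)
  prof <- free_energy_profile(z, bins = 60, range = c(0, 1.55))
  G_ref <- approx(zgrid, G_true, xout = prof$z)$y
  G_ref <- G_ref - min(G_ref[!prof$masked])
  rms <- sqrt(mean((prof$G[!prof$masked] - G_ref[!prof$masked])^2))
  expect_lt(rms, 0.2)
  # doubling the sample size shrinks the error
  idx2 <- sample.int(length(zgrid), 4 * n, replace = TRUE, prob = dens)
  z2 <- zgrid[idx2] + runif(4 * n, -dz / 2, dz / 2)
  prof2 <- free_energy_profile(z2, bins = 60, range = c(0, 1.55))
  rms2 <- sqrt(mean((prof2$G[!prof2$masked] - G_ref[!prof2$masked])^2))
  expect_lt(rms2, rms + 0.02)
})

test_that("voltage from field is the field-box product in mV", {
  expect_equal(voltage_from_field(0, 15), 0)
  expect_equal(voltage_from_field(0.02, 15), 300)
  expect_equal(voltage_from_field(0.04, 15), 2 * voltage_from_field(0.02, 15))
})

test_that("binned responses report bootstrap CIs with near-nominal coverage", {
  # constant y: zero-width CI
  r <- binned_response(runif(50), rep(2.5, 50), c(0, 1), seed = 79)
  expect_equal(r$ci_lo, 2.5)
  expect_equal(r$ci_hi, 2.5)
  # single point in a bin: degenerate flag
  r2 <- binned_response(c(0.5, 1.5), c(1, 2), c(0, 1, 2), seed = 81)
  expect_true(all(r2$degenerate))
  expect_equal(r2$mean, c(1, 2))
  # empty bin masked
  r3 <- binned_response(c(0.5), c(1), c(0, 1, 2), seed = 83)
  expect_identical(r3$n[2], 0L)
  expect_true(is.na(r3$mean[2]))
  # coverage across 200 seeded repetitions
  hit <- logical(200)
  for (s in 1:200) {
    y <- with_seed_test(s, rnorm(60, 5, 2))
    r <- binned_response(rep(0.5, 60), y, c(0, 1), n_bootstrap = 400,
                         seed = 100 + s)
    hit[s] <- r$ci_lo <= 5 && r$ci_hi >= 5
  }
  expect_gte(mean(hit), 0.88)
  expect_lte(mean(hit), 0.99)
})
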