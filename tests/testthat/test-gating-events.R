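test_that("hydrogen-bond break detection honors threshold and persistence", {
  # constant below threshold: nothing
  s <- make_series(rep(0.4, 500), dt = 2)
  expect_null(detect_hbond_break(s, threshold = 0.7, persistence = 20))
  # brief excursion shorter than the persistence window: nothing
  v <- rep(0.4, 500); v[100:104] <- 1.0 # 10 ns at dt = 2
  expect_null(detect_hbond_break(make_series(v, 2), 0.7, 50))
  # sustained break detected at its onset
  v2 <- rep(0.45, 2500); v2[1001:2500] <- 1.2 # step at t = 2000 ns
  ev <- detect_hbond_break(make_series(v2, 2), 0.7, 50, replica_id = 3)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$time, 2000, tolerance = 4)
  expect_identical(ev$direction, "break")
  expect_identical(ev$replica_id, 3)
  expect_error(detect_hbond_break(make_series(c(0.4, NA, 0.4)), 0.7, 1),
               "non-finite")
})

test_that("planted steps are detected at the right time on noisy baselines", {
  # +0.6 nm step on a 0.05 nm SD baseline; persistence 20 ns = 10
  # relaxation times; recovery within 2 persistence windows in >= 95/100
  hits <- 0L
  for (s in 1:100) {
    out <- plant_flip_series(planted_series_spec(
      baseline_mean = 0.45, baseline_sd = 0.05, relaxation_time = 2,
      event_time = 1500, post_mean = 1.05, duration = 3000, dt = 1,
      seed = 4000 + s))
    ev <- detect_hbond_break(out$series[[1]], threshold = 0.7,
                             persistence = 20)
    if (!is.null(ev) && abs(ev$time - 1500) <= 40) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("detector sensitivity and false-positive rates meet the design point", {
  det <- 0L; fp <- 0L
  for (s in 1:100) {
    with_ev <- plant_flip_series(planted_series_spec(
      baseline_mean = 0.45, baseline_sd = 0.05, relaxation_time = 2,
      event_time = 1000, post_mean = 0.45 + 4 * 0.05 + 0.45,
      duration = 2000, dt = 1, seed = 6000 + s))
    if (!is.null(detect_hbond_break(with_ev$series[[1]], 0.7, 20)))
      det <- det + 1L
    no_ev <- plant_flip_series(planted_series_spec(
      baseline_mean = 0.45, baseline_sd = 0.05, relaxation_time = 2,
      event_time = NA, duration = 2000, dt = 1, seed = 6500 + s))
    if (!is.null(detect_hbond_break(no_ev$series[[1]], 0.7, 20)))
      fp <- fp + 1L
  }
  expect_gte(det / 100, 0.95)
  expect_lte(fp / 100, 0.05)
})

test_that("inactivation detection is first-passage and direction-aware", {
  band <- c(0.7, 1.0)
  quiet <- make_series(rep(0.85, 3000), dt = 2)
  expect_null(detect_inactivation(quiet, quiet, band, persistence = 20))
  # dilation on one pair at 3500 ns
  v <- rep(0.85, 3000); v[1751:3000] <- 1.3
  ev <- detect_inactivation(make_series(v, 2), quiet, band, persistence = 20,
                            replica_id = 1)
  expect_identical(ev$direction, "dilation")
  expect_equal(ev$time, 3500, tolerance = 4)
  expect_identical(ev$pair, "pair13")
  # constriction below the band
  v2 <- rep(0.85, 3000); v2[2001:3000] <- 0.4
  ev2 <- detect_inactivation(quiet, make_series(v2, 2), band, 20)
  expect_identical(ev2$direction, "constriction")
  # leaving then re-entering still yields exactly the first passage
  v3 <- rep(0.85, 3000)
  v3[501:600] <- 1.3   # first sustained excursion at t = 1000
  v3[2001:3000] <- 1.3
  ev3 <- detect_inactivation(make_series(v3, 2), quiet, band, 20)
  expect_identical(nrow(ev3), 1L)
  expect_equal(ev3$time, 1000, tolerance = 4)
  expect_error(detect_inactivation(quiet, quiet, c(1, 0.5), 20), "band")
})

test_that("conducting band estimation brackets the baseline", {
  set.seed(87)
  s1 <- make_series(rnorm(1000, 0.85, 0.03), dt = 1)
  s2 <- make_series(rnorm(1000, 0.85, 0.03), dt = 1)
  band <- conducting_band(s1, s2, t_max = 250)
  expect_lt(band[1], 0.8)
  expect_gt(band[2], 0.9)
  expect_equal(mean(band), 0.85, tolerance = 0.01)
})

test_that("cumulative event curves are monotone step functions", {
  grid <- seq(0, 5000, 100)
  expect_true(all(cumulative_events(NULL, 20, grid)$cumulative == 0L))
  ev <- data.frame(replica_id = 1:19,
                   time = seq(200, 4700, length.out = 19))
  cum <- cumulative_events(ev, 20, grid)
  expect_identical(cum$cumulative[length(grid)], 19L)
  expect_true(all(diff(cum$cumulative) >= 0L))
  # all events at t = 0 start the curve at n_events
  ev0 <- data.frame(replica_id = 1:5, time = rep(0, 5))
  expect_identical(cumulative_events(ev0, 10, grid)$cumulative[1], 5L)
  # duplicate replica ids violate the first-passage contract
  dup <- data.frame(replica_id = c(1, 1), time = c(10, 20))
  expect_error(cumulative_events(dup, 10, grid), "first-passage")
})

test_that("rotamer classification thresholds the hydrogen-bond distance", {
  vert <- make_series(rep(0.167, 100))
  expect_equal(classify_rotamer(vert)$frequency, 1)
  expect_true(all(classify_rotamer(vert)$orientation == "vertical"))
  horiz <- make_series(rep(0.8, 100))
  expect_equal(classify_rotamer(horiz)$frequency, 0)
  mixed <- make_series(rep(c(0.17, 0.8), 50))
  expect_equal(classify_rotamer(mixed)$frequency, 0.5)
  ch <- classify_rotamer(list(vert, horiz, vert, horiz))
  expect_equal(ch$channel_mean, 0.5)
  expect_equal(ch$per_monomer, c(1, 0, 1, 0))
})

test_that("event alignment centers replicas at lag zero and averages monomers", {
  # planted indicator stepping 0 -> 1 at each replica's event
  mk_ind <- function(event_t) {
    t <- seq(0, 1000, 2)
    data.frame(time = t, value = as.numeric(t >= event_t))
  }
  evs <- c(300, 500, 700)
  al <- align_on_event(lapply(evs, mk_ind), evs, pre_window = 100,
                       post_window = 100)
  expect_equal(al$mean[al$lag < 0], rep(0, sum(al$lag < 0)))
  expect_equal(al$mean[al$lag >= 0], rep(1, sum(al$lag >= 0)))
  expect_true(all(al$n == 3L))
  expect_true(all(al$mean >= 0 & al$mean <= 1, na.rm = TRUE))
  # single replica: the aligned curve is its own window
  one <- align_on_event(list(mk_ind(400)), 400, 50, 50)
  expect_equal(one$mean, as.numeric(one$lag >= 0))
  # indicator on in exactly 1 of 4 monomers everywhere: 0.25 at all lags
  t <- seq(0, 1000, 2)
  four <- data.frame(time = t, m1 = 1, m2 = 0, m3 = 0, m4 = 0)
  al4 <- align_on_event(list(four), 500, 100, 100)
  expect_equal(al4$mean, rep(0.25, nrow(al4)))
  expect_error(align_on_event(list(mk_ind(1)), NA, 10, 10), "no replicas")
})

test_that("alignment means stay within the contributing values", {
  set.seed(91)
  series <- lapply(1:6, function(r)
    make_series(runif(500), dt = 2))
  evs <- runif(6, 200, 800)
  al <- align_on_event(series, evs, 150, 150)
  expect_true(all(al$n <= 6L))
  expect_true(all(al$mean[al$n > 0] >= 0 & al$mean[al$n > 0] <= 1))
})

test_that("additional-water counting subtracts the crystallographic baseline", {
  tal <- matrix(2, nrow = 10, ncol = 4)
  expect_true(all(count_water_region(tal, baseline = 2) == 0))
  tal[3, 2] <- 3
  adj <- count_water_region(tal, baseline = 2)
  expect_identical(adj[3, 2], 1)
  expect_identical(sum(adj), 1)
  # clamping with a warning
  tal2 <- matrix(0, 2, 4)
  expect_warning(out <- count_water_region(tal2, baseline = 1), "clamped")
  expect_true(all(out == 0))
  # geometric membership: planted points are counted exactly
  pos <- data.frame(frame = rep(1:5, each = 3),
                    monomer = rep(1, 15),
                    x = rep(c(0.1, 0.2, 2), 5),
                    y = 0,
                    z = rep(c(0.5, 0.6, 0.5), 5))
  reg <- list(zlim = c(0, 1), rcut = 1)
  cnt <- count_water_region(positions = pos, region = reg, baseline = 0)
  expect_true(all(cnt == 2)) # the x = 2 point is outside the radial cutoff
})

test_that("pKa shifts follow the free-energy conversion exactly", {
  expect_equal(delta_pka(0)$delta_pKa, 0)
  expect_equal(delta_pka(40, 298)$delta_pKa, 7.01, tolerance = 0.001)
  expect_equal(delta_pka(40, 298)$pKa, 11.01, tolerance = 0.001)
  # linear in dG, inverse-linear in T
  expect_equal(delta_pka(80, 298)$delta_pKa, 2 * delta_pka(40, 298)$delta_pKa)
  expect_equal(delta_pka(40, 596)$delta_pKa, delta_pka(40, 298)$delta_pKa / 2)
  # the 40-45.6 kJ/mol range maps onto seven-to-eight pKa units
  expect_true(all(vapply(c(41, 43, 45.5), function(dg)
    delta_pka(dg, 298)$delta_pKa, numeric(1)) > 7))
  expect_lt(delta_pka(45.6, 298)$delta_pKa, 8.01)
})
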