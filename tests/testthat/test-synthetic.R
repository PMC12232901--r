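test_that("simulated datasets are byte-identical given the seed", {
  sc <- kinetic_scheme(); gm <- filament_geometry()
  sd1 <- acquisition_schedule(n_cycles = 40)
  a <- simulate_events(sc, gm, sd1, n_events = 500, seed = 123)
  b <- simulate_events(sc, gm, sd1, n_events = 500, seed = 123)
  expect_identical(a$truth_events, b$truth_events)
  expect_identical(a$observed_events, b$observed_events)
  expect_identical(a$zdisk_truth, b$zdisk_truth)
  c2 <- simulate_events(sc, gm, sd1, n_events = 500, seed = 124)
  expect_false(identical(a$observed_events, c2$observed_events))
})

test_that("constructor invariants are enforced", {
  expect_error(kinetic_scheme(lifetime_drx = 0.5), "nonspecific < DRX < SRX")
  expect_error(kinetic_scheme(srx_fraction_by_zone = c(P = 1.2, C = 0, D = 0)),
               "0, 1")
  expect_error(filament_geometry(zone_bounds = c(5, 100, 200, 300)), "start at 0")
  expect_error(acquisition_schedule(n_cycles = 0), "no frames")
  expect_error(continuous_schedule(0), "no frames")
  expect_error(simulate_events(kinetic_scheme(), filament_geometry(),
                               acquisition_schedule(n_cycles = 5),
                               noise = c(x = -1, y = 0), n_events = 10),
               "negative noise")
})

test_that("empirical mean dwell per state matches directly drawn exponentials", {
  # event-level 50/50 SRX/DRX split so every state gets ~n/3 events
  f_half <- RATES["drx"] / (RATES["drx"] + RATES["srx"])
  sc <- kinetic_scheme(fraction_nonspecific_of_events = 1 / 3,
                       srx_fraction_by_zone = c(P = f_half, C = f_half, D = f_half))
  sim <- sim_ideal(15000, seed = 31, scheme = sc)
  tr <- sim$truth_events
  for (st in c("ns", "drx", "srx")) {
    d <- tr$true_duration_s[tr$state == st]
    expect_gt(length(d), 4000)
    expect_equal(mean(d), LIFETIMES[[st]], tolerance = 0.05)
  }
})

test_that("axial placement is uniform over the zone spans", {
  gm <- filament_geometry()
  sim <- sim_ideal(10000, seed = 17)
  z <- table(sim$truth_events$zone)
  widths <- diff(gm$zone_bounds)
  p <- widths / sum(widths)
  # binomial 99% bounds per zone
  for (i in seq_along(p)) {
    zone <- c("P", "C", "D")[i]
    lo <- qbinom(0.005, 10000, p[i]); hi <- qbinom(0.995, 10000, p[i])
    expect_gte(z[[zone]], lo)
    expect_lte(z[[zone]], hi)
  }
})

test_that("zero SRX fractions produce no SRX events", {
  sc <- kinetic_scheme(srx_fraction_by_zone = c(P = 0, C = 0, D = 0))
  sim <- sim_ideal(2000, seed = 2, scheme = sc)
  expect_false(any(sim$truth_events$state == "srx"))
})

test_that("event-level SRX share reflects rate-weighted molecule fractions", {
  sc <- kinetic_scheme(fraction_nonspecific_of_events = 0)
  sim <- sim_ideal(40000, seed = 23, scheme = sc)
  tr <- sim$truth_events
  for (z in c("P", "C", "D")) {
    f <- sc$srx_fraction_by_zone[[z]]
    p_expect <- f * RATES[["srx"]] / (f * RATES[["srx"]] + (1 - f) * RATES[["drx"]])
    n_z <- sum(tr$zone == z)
    p_obs <- mean(tr$state[tr$zone == z] == "srx")
    expect_lt(abs(p_obs - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / n_z))
  }
})

test_that("noiseless observed durations equal schedule-discretised truth", {
  sc <- kinetic_scheme()
  sched <- acquisition_schedule(n_cycles = 30)
  sim <- simulate_events(sc, filament_geometry(), sched,
                         noise = c(x = 0, y = 0), n_events = 300, seed = 6)
  nuc <- sched[sched$channel == "nucleotide", ]
  tr <- sim$truth_events
  obs <- sim$observed_events
  # independent brute-force censoring oracle, event by event
  for (i in seq_len(nrow(tr))) {
    t0 <- tr$t_start_s[i]; t1 <- t0 + tr$true_duration_s[i]
    hit <- which(nuc$timestamp < t1 & (nuc$timestamp + nuc$exposure) > t0)
    row <- obs[obs$event_id == tr$event_id[i], ]
    if (length(hit) == 0L) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_equal(nrow(row), 1L)
      expect_equal(row$duration_s,
                   nuc$timestamp[max(hit)] - nuc$timestamp[min(hit)] +
                     nuc$exposure[max(hit)])
    }
  }
  # every observed event maps to exactly one truth event
  expect_true(all(obs$event_id %in% tr$event_id))
  expect_false(any(duplicated(obs$event_id)))
})

test_that("positions mirror on both sides of the M-line with correct zones", {
  sim <- sim_ideal(4000, seed = 13)
  tr <- sim$truth_events
  expect_setequal(unique(tr$side), c(-1, 1))
  # reconstruct axial distance from x and the sarcomere M-line
  gm <- filament_geometry()
  mline_x <- (tr$sarcomere - 0.5) * gm$sarcomere_length
  expect_equal(abs(tr$x_nm - mline_x), tr$axial_nm, tolerance = 1e-9)
  expect_equal(tr$y_nm, rep(0, nrow(tr)))
})

test_that("event tables round-trip through the CSV format", {
  sim <- sim_ideal(200, seed = 3)
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  write_events_csv(sim$observed_events, p)
  back <- read_events_csv(p)
  expect_equal(back$duration_s, sim$observed_events$duration_s)
  expect_equal(back$x_nm, sim$observed_events$x_nm, tolerance = 1e-9)
  expect_equal(back$truth_zone, sim$observed_events$truth_zone)
})
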