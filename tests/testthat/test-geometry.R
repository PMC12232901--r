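zd <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(x_nm = m[, 1], y_nm = m[, 2])
}

test_that("M-line is the midpoint and length the Z-disk distance", {
  s <- build_sarcomeres(zd(0, 0, 1820, 0))
  expect_equal(nrow(s), 1L)
  expect_equal(s$length_nm, 1820)
  # in tilt-corrected coordinates the M-line is centred between Z-disks
  expect_equal(s$mline_x, (s$za_x + s$zb_x) / 2)
  expect_equal(s$zb_x - s$za_x, 1820)
})

test_that("sarcomere geometry is invariant under rotation", {
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- as.matrix(zd(0, 0, 1820, 0)) %*% t(R)
  s <- build_sarcomeres(data.frame(x_nm = pts[, 1], y_nm = pts[, 2]))
  expect_equal(s$length_nm, 1820)
  expect_equal(s$za_y, s$zb_y, tolerance = 1e-9)  # axis horizontal after tilt correction
})

test_that("collinear Z-disks chain into consecutive sarcomeres", {
  s <- build_sarcomeres(zd(0, 0, 1800, 0, 3600, 0, 5400, 0, 7200, 0))
  expect_equal(nrow(s), 4L)
  expect_equal(s$length_nm, rep(1800, 4))
  expect_equal(build_sarcomeres(zd(0, 0)) |> nrow(), 0L)
})

test_that("short sarcomeres are filtered at the 1.7 um threshold", {
  s <- build_sarcomeres(zd(0, 0, 1600, 0, 3350, 0, 5170, 0))
  expect_equal(s$length_nm, c(1600, 1750, 1820))
  expect_message(kept <- filter_sarcomeres(s), "rejected")
  expect_equal(kept$length_nm, c(1750, 1820))
  expect_warning(filter_sarcomeres(s, min_length = 5000), "all sarcomeres")
  expect_equal(filter_sarcomeres(s, min_length = 0)$length_nm, s$length_nm)
})

test_that("length statistics match closed-form sample moments", {
  s <- build_sarcomeres(zd(0, 0, 1700, 0, 3600, 0))
  st <- sarcomere_length_stats(s)
  expect_equal(st$mean_nm, 1800)
  expect_equal(st$sd_nm, sd(c(1700, 1900)))
  expect_equal(round(st$sd_nm, 1), 141.4)

  s2 <- build_sarcomeres(zd(0, 0, 1820, 0, 3640, 0))
  expect_equal(sarcomere_length_stats(s2)$sd_nm, 0)
  expect_error(sarcomere_length_stats(build_sarcomeres(zd(0, 0, 100, 0))[0, ]),
               "at least 2")
})

test_that("simulated Z-disk localizations recover the true sarcomere length", {
  gm <- filament_geometry(n_sarcomeres = 600L)
  sc <- kinetic_scheme()
  sched <- acquisition_schedule(n_cycles = 12)
  sim <- simulate_events(sc, gm, sched, n_events = 10, seed = 44)
  # average the per-frame localizations of each fiducial
  agg <- aggregate(sim$zdisk_truth[, c("x_nm", "y_nm")],
                   list(id = sim$zdisk_truth$zdisk_id), mean)
  s <- build_sarcomeres(agg[, c("x_nm", "y_nm")])
  st <- sarcomere_length_stats(s)
  expect_equal(st$mean_nm, 1820, tolerance = 0.01)
})

test_that("axial distances bin into half-open P/C/D zones", {
  s <- build_sarcomeres(zd(0, 0, 1820, 0))
  ev <- data.frame(x_nm = 910 + c(100, 300, 600, 900, 0, -100, -300),
                   y_nm = 0, duration_s = 1)
  z <- assign_zones(ev, s)
  expect_equal(z$zone, c("P", "C", "D", "excluded", "P", "P", "C"))
  expect_equal(z$axial_distance_nm[1:4], c(100, 300, 600, 900))
  # event exactly at the M-line
  expect_equal(z$zone[5], "P")
  expect_equal(z$axial_distance_nm[5], 0)
  # boundary cuts at 159.5 / 500.5 / 800.5 nm
  b <- assign_zones(data.frame(x_nm = 910 + c(159.4, 159.5, 500.4, 500.5, 800.4, 800.5),
                               y_nm = 0, duration_s = 1), s)
  expect_equal(b$zone, c("P", "C", "C", "D", "D", "excluded"))
})

test_that("zone assignment is symmetric under folding about the M-line", {
  s <- build_sarcomeres(zd(0, 0, 1820, 0))
  off <- runif(50, 0, 900)
  a <- assign_zones(data.frame(x_nm = 910 + off, y_nm = 0, duration_s = 1), s)
  b <- assign_zones(data.frame(x_nm = 910 - off, y_nm = 0, duration_s = 1), s)
  expect_equal(a$zone, b$zone)
  expect_equal(a$axial_distance_nm, b$axial_distance_nm)
})

test_that("off-axis and unsegmented events are excluded with reasons", {
  s <- build_sarcomeres(zd(0, 0, 1820, 0))
  z <- assign_zones(data.frame(x_nm = c(910, 910, 5000),
                               y_nm = c(0, 700, 0), duration_s = 1), s)
  expect_equal(z$zone, c("P", "excluded", "excluded"))
  expect_equal(z$exclude_reason[2], "off-axis")
  expect_equal(z$exclude_reason[3], "outside segmented myofibril")
  # partition: each assigned event has exactly one zone
  expect_true(all(z$zone %in% c("P", "C", "D", "excluded")))
})

test_that("noiseless zone assignment matches simulation truth exactly", {
  gm <- filament_geometry(n_sarcomeres = 6L, axis_angle = 25)
  sim <- sim_ideal(2000, seed = 12, geom = gm)
  # true fiducial positions, rotated like the simulator's
  th <- 25 * pi / 180
  zs <- (0:6) * gm$sarcomere_length
  zpos <- data.frame(x_nm = zs * cos(th), y_nm = zs * sin(th))
  s <- build_sarcomeres(zpos)
  z <- assign_zones(sim$observed_events, s)
  expect_equal(z$zone, sim$observed_events$truth_zone)
})

test_that("crossed fiducials are rejected", {
  expect_error(build_sarcomeres(zd(0, 0, 0, 1e-12, 1800, 0)), "crossed")
})
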