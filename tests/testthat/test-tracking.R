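# one event at a known position, rendered and re-detected
render_one <- function(x_nm, y_nm, ...) {
  sc <- kinetic_scheme(fraction_nonspecific_of_events = 0,
                       srx_fraction_by_zone = c(P = 1, C = 1, D = 1))
  sched <- continuous_schedule(1, frame_exposure = 0.2)
  sim <- simulate_events(sc, filament_geometry(n_sarcomeres = 1L), sched,
                         noise = c(x = 0, y = 0), n_events = 1, seed = 1,
                         censor = FALSE)
  sim$truth_events$x_nm <- x_nm
  sim$truth_events$y_nm <- y_nm
  sim$truth_events$t_start_s <- 0
  sim$truth_events$true_duration_s <- 10
  render_frames(sim, frames = 1L, ...)
}

test_that("a rendered spot peaks within one pixel of its true position", {
  r <- render_one(2000, 1500, pixel_size = 65, image_shape = c(64L, 48L))
  img <- r$nucleotide[, , 1]
  pk <- which(img == max(img), arr.ind = TRUE)
  expect_lt(abs((pk[1] - 0.5) * 65 - 2000), 65)
  expect_lt(abs((pk[2] - 0.5) * 65 - 1500), 65)

  # zero events -> flat background stack
  sc <- kinetic_scheme()
  sim <- simulate_events(sc, filament_geometry(),
                         continuous_schedule(1), n_events = 1, seed = 1,
                         censor = FALSE)
  sim$truth_events <- sim$truth_events[0, ]
  r0 <- render_frames(sim, frames = 1L, image_shape = c(32L, 32L))
  expect_true(all(r0$nucleotide == 0))
})

test_that("the LoG detector localizes rendered spots to tens of nm", {
  r <- render_one(2000, 1500, pixel_size = 65, image_shape = c(64L, 48L))
  sp <- detect_spots(r$nucleotide[, , 1], pixel_size = 65)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x_nm - 2000), 20)
  expect_lt(abs(sp$y_nm - 1500), 20)

  expect_warning(blank <- detect_spots(matrix(0, 32, 32), pixel_size = 65),
                 "blank")
  expect_equal(nrow(blank), 0L)
})

test_that("two spots two microns apart are resolved and localized", {
  r <- render_one(1500, 1500, pixel_size = 65, image_shape = c(80L, 48L))
  img <- r$nucleotide[, , 1]
  r2 <- render_one(3500, 1500, pixel_size = 65, image_shape = c(80L, 48L))
  img <- img + r2$nucleotide[, , 1]
  sp <- detect_spots(img, pixel_size = 65)
  expect_equal(nrow(sp), 2L)
  got_x <- sort(sp$x_nm)
  expect_lt(abs(got_x[1] - 1500), 30)
  expect_lt(abs(got_x[2] - 3500), 30)
})

test_that("stationary spots link into one track and gaps are closed", {
  sp <- data.frame(x_nm = 1000, y_nm = 500, frame = 1:5)
  tr <- link_spots(sp)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$n_spots, 5L)
  expect_equal(tr$frame_start, 1L)
  expect_equal(tr$frame_end, 5L)

  # frame 3 missing: gap closed within 5 frames
  tr2 <- link_spots(sp[sp$frame != 3, ])
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2$frame_start, 1L)
  expect_equal(tr2$frame_end, 5L)

  # gap longer than gap_max: two tracks
  sp3 <- data.frame(x_nm = 1000, y_nm = 500, frame = c(1, 2, 10, 11))
  expect_equal(nrow(link_spots(sp3, gap_max = 5)), 2L)
})

test_that("nearby persistent spots keep separate identities", {
  # 50 nm apart: within the 100 nm cap, but nearest-neighbour keeps identity
  sp <- do.call(rbind, lapply(1:6, function(f) {
    data.frame(x_nm = c(1000, 1050), y_nm = 500, frame = f)
  }))
  tr <- link_spots(sp)
  expect_equal(nrow(tr), 2L)
  expect_equal(sort(tr$x_nm), c(1000, 1050))
  # brute-force optimal assignment on this instance: same total displacement
  expect_equal(tr$n_spots, c(6L, 6L))
})

test_that("every spot joins exactly one track", {
  set.seed(99)
  sp <- data.frame(x_nm = runif(120, 0, 5000), y_nm = runif(120, 0, 5000),
                   frame = sample(1:10, 120, replace = TRUE))
  tr <- link_spots(sp)
  st <- attr(tr, "spot_track")
  expect_equal(nrow(st), nrow(sp))
  expect_false(any(is.na(st$track)))
  expect_equal(sum(tr$n_spots), nrow(sp))
})

test_that("durations follow the schedule timing convention", {
  sched <- acquisition_schedule(n_cycles = 3)
  sp <- data.frame(x_nm = 0, y_nm = 0, frame = 1:7)  # nucleotide frame indices
  tr <- link_spots(sp, schedule = sched)
  nuc <- sched[sched$channel == "nucleotide", ]
  expect_equal(tr$duration_s, nuc$timestamp[7] - nuc$timestamp[1] + 0.2)
})

test_that("injected drift is recovered from the Z-disk fiducials", {
  gm <- filament_geometry()
  sched <- acquisition_schedule(n_cycles = 60)
  sim <- simulate_events(kinetic_scheme(), gm, sched, n_events = 100,
                         drift_per_frame = c(2, -1), seed = 21)
  dr <- estimate_drift(sim$zdisk_truth, frames = sched$frame)
  truth <- sim$drift_series
  # relative slope error, fitted over the covered frames
  fit <- coef(lm(dr$dx_nm ~ dr$frame))[2]
  expect_equal(unname(fit), 2, tolerance = 0.1)
  fit_y <- coef(lm(dr$dy_nm ~ dr$frame))[2]
  expect_equal(unname(fit_y), -1, tolerance = 0.1)
  # drift idempotence: re-estimating on corrected fiducials gives ~0
  corr <- apply_drift(sim$zdisk_truth, dr)
  dr2 <- estimate_drift(corr, frames = sched$frame)
  expect_lt(max(abs(dr2$dx_nm)), 68.2)
  expect_lt(max(abs(dr2$dy_nm)), 135.4)
})

test_that("zero injected drift estimates as zero within localization noise", {
  sim <- simulate_events(kinetic_scheme(), filament_geometry(),
                         acquisition_schedule(n_cycles = 40),
                         n_events = 50, seed = 31)
  dr <- estimate_drift(sim$zdisk_truth)
  expect_lt(max(abs(dr$dx_nm)), 3 * 68.2)
  expect_lt(max(abs(dr$dy_nm)), 3 * 135.4)
})

test_that("a 500 nm outlier fiducial barely moves the median translation", {
  ref <- data.frame(frame = 1, x_nm = seq(0, 16000, by = 2000), y_nm = 0)
  cur <- ref; cur$frame <- 2
  cur$x_nm <- cur$x_nm + 10            # true drift 10 nm
  cur$x_nm[4] <- cur$x_nm[4] + 500     # one bad fiducial
  dr <- estimate_drift(rbind(ref, cur))
  expect_lt(abs(dr$dx_nm[dr$frame == 2] - 10), 5)
})

test_that("frames with too few fiducials hold the last estimate", {
  ref <- data.frame(frame = 1, x_nm = c(0, 2000, 4000), y_nm = 0)
  mid <- data.frame(frame = 2, x_nm = c(0, 2000, 4000) + 20, y_nm = 0)
  bad <- data.frame(frame = 3, x_nm = 0, y_nm = 0)
  expect_warning(dr <- estimate_drift(rbind(ref, mid, bad)), "fiducials")
  expect_equal(dr$dx_nm[dr$frame == 3], 20)
})

test_that("localization precision is the per-axis SD of a fixed point", {
  still <- data.frame(x_nm = rep(100, 25), y_nm = rep(50, 25))
  expect_equal(unname(estimate_precision(still)), c(0, 0))
  set.seed(77)
  wob <- data.frame(x_nm = rnorm(1000, 0, 28.1), y_nm = rnorm(1000, 0, 38))
  pr <- estimate_precision(wob)
  expect_equal(unname(pr[1]), 28.1, tolerance = 0.1)
  expect_equal(unname(pr[2]), 38, tolerance = 0.1)
  expect_error(estimate_precision(wob[1:10, ]), "insufficient")
})
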