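#' Simulate a ground-truthed single-molecule ATP-turnover experiment
#'
#' Generates fluorescent-nucleotide binding events on an idealised
#' myofibril with known kinetics, geometry and acquisition structure, so
#' the full analysis pipeline can be validated against truth. Molecules are
#' the sampling unit: a molecule in state \eqn{i} produces binding events
#' at a rate proportional to its turnover rate \eqn{k_i}, so over a fixed
#' observation window the simulator draws the *event-level* state of each
#' specific event with probability proportional to (molecule fraction
#' \eqn{\times k_i}). This is exactly the observation bias that
#' [corrected_srx_percent()] undoes downstream.
#'
#' Each event receives a uniform axial position along the half thick
#' filament (mirrored on either side of its sarcomere's M-line), an
#' exponential true dwell time for its state, an optional photobleach
#' truncation accruing only over illuminated time, and is then censored to
#' the acquisition schedule: an event is observed only if its span covers
#' at least one nucleotide frame, and its observed duration is
#' (last frame timestamp − first frame timestamp) + exposure. With
#' `censor = FALSE` true durations are reported directly (idealised
#' continuous observation), which isolates dwell-time statistics from
#' acquisition effects.
#'
#' @param scheme a [kinetic_scheme()].
#' @param geom a [filament_geometry()].
#' @param sched an [acquisition_schedule()] or [continuous_schedule()].
#' @param noise named vector `c(x=, y=)` of localization SDs in nm for
#'   nucleotide events (defaults 28.1 / 38).
#' @param zdisk_noise localization SDs in nm for Z-disk fiducials
#'   (defaults 68.2 / 135.4).
#' @param n_events number of truth events generated (observed events are
#'   fewer after censoring). Default 3638.
#' @param drift_per_frame `c(dx, dy)` nm of linear stage drift per frame.
#' @param censor censor durations and positions to the schedule
#'   (default `TRUE`).
#' @param seed integer seed; the dataset is reproducible given the seed.
#' @return An object of class `"srx_sim"` with elements `truth_events`,
#'   `observed_events`, `zdisk_truth`, `drift_series`, `scheme`, `geom`,
#'   `sched`, `seed`.
#' @export
simulate_events <- function(scheme, geom, sched,
                            noise = c(x = 28.1, y = 38),
                            zdisk_noise = c(x = 68.2, y = 135.4),
                            n_events = 3638L,
                            drift_per_frame = c(0, 0),
                            censor = TRUE,
                            seed = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(geom, "filament_geometry"),
            inherits(sched, "acq_schedule"))
  if (nrow(sched) == 0L) stop("no frames")
  if (any(noise < 0) || any(zdisk_noise < 0)) stop("negative noise SD")
  if (n_events < 1L) stop("n_events must be positive")

  k <- c(ns = 1 / scheme$lifetime_nonspecific,
         drx = 1 / scheme$lifetime_drx,
         srx = 1 / scheme$lifetime_srx)
  zones <- names(scheme$srx_fraction_by_zone)
  bounds <- geom$zone_bounds
  outer_bound <- bounds[length(bounds)]
  t_end <- max(sched$timestamp) + sched$exposure[nrow(sched)]
  nuc <- sched[sched$channel == "nucleotide", , drop = FALSE]
  if (nrow(nuc) == 0L) stop("schedule has no nucleotide frames")
  duty <- schedule_duty_cycle(sched, "nucleotide")

  sim <- .with_seed(seed, {
    # geometry of the myofibril in image coordinates
    th <- geom$axis_angle * pi / 180
    u_axis <- c(cos(th), sin(th))
    zdisk_s <- (0:geom$n_sarcomeres) * geom$sarcomere_length  # along axis
    mline_s <- (zdisk_s[-1] + zdisk_s[-length(zdisk_s)]) / 2

    # truth events
    sarc <- sample.int(geom$n_sarcomeres, n_events, replace = TRUE)
    side <- sample(c(-1, 1), n_events, replace = TRUE)
    axial <- stats::runif(n_events, 0, outer_bound)
    zone <- zones[findInterval(axial, bounds, rightmost.closed = FALSE)]
    is_ns <- stats::runif(n_events) < scheme$fraction_nonspecific_of_events
    f <- scheme$srx_fraction_by_zone[zone]
    p_srx_event <- f * k["srx"] / (f * k["srx"] + (1 - f) * k["drx"])
    is_srx <- !is_ns & stats::runif(n_events) < p_srx_event
    state <- ifelse(is_ns, "ns", ifelse(is_srx, "srx", "drx"))
    true_dur <- stats::rexp(n_events, k[state])
    t_start <- stats::runif(n_events, 0, t_end)

    s_pos <- mline_s[sarc] + side * axial        # along-axis coordinate
    x0 <- geom$myofibril_origin[1] + s_pos * u_axis[1]
    y0 <- geom$myofibril_origin[2] + s_pos * u_axis[2]

    truth <- data.frame(
      event_id = seq_len(n_events), x_nm = x0, y_nm = y0,
      sarcomere = sarc, side = side, axial_nm = axial,
      zone = zone, state = state,
      t_start_s = t_start, true_duration_s = true_dur,
      stringsAsFactors = FALSE
    )

    # photobleach truncation: bleach clock runs only while illuminated
    end_t <- t_start + true_dur
    if (scheme$bleach_rate > 0) {
      bleach_wall <- stats::rexp(n_events, scheme$bleach_rate * duty)
      end_t <- pmin(end_t, t_start + bleach_wall)
    }

    drift <- data.frame(
      frame = sched$frame,
      dx_nm = drift_per_frame[1] * (sched$frame - 1L),
      dy_nm = drift_per_frame[2] * (sched$frame - 1L)
    )

    if (censor) {
      # first/last nucleotide frame overlapped by [t_start, end_t)
      i_first <- findInterval(t_start, nuc$timestamp + nuc$exposure) + 1L
      i_last <- findInterval(end_t, nuc$timestamp,
                             left.open = TRUE)
      ok <- i_first <= i_last & i_first <= nrow(nuc)
      obs_dur <- rep(NA_real_, n_events)
      obs_dur[ok] <- nuc$timestamp[i_last[ok]] - nuc$timestamp[i_first[ok]] +
        nuc$exposure[i_last[ok]]
      frame_start <- ifelse(ok, nuc$frame[pmin(i_first, nrow(nuc))], NA_integer_)
      frame_end <- ifelse(ok, nuc$frame[pmax(i_last, 1L)], NA_integer_)
      t_obs_start <- ifelse(ok, nuc$timestamp[pmin(i_first, nrow(nuc))], NA_real_)
      # mean drift over the frames the event is visible in
      mid_frame <- round((frame_start + frame_end) / 2)
      ddx <- drift$dx_nm[match(mid_frame, drift$frame)]
      ddy <- drift$dy_nm[match(mid_frame, drift$frame)]
    } else {
      ok <- rep(TRUE, n_events)
      obs_dur <- end_t - t_start
      frame_start <- findInterval(t_start, nuc$timestamp)
      frame_end <- findInterval(end_t, nuc$timestamp)
      t_obs_start <- t_start
      ddx <- ddy <- rep(0, n_events)
    }

    obs <- data.frame(
      event_id = truth$event_id[ok],
      x_nm = x0[ok] + ddx[ok] + stats::rnorm(sum(ok), 0, noise[["x"]]),
      y_nm = y0[ok] + ddy[ok] + stats::rnorm(sum(ok), 0, noise[["y"]]),
      frame_start = frame_start[ok], frame_end = frame_end[ok],
      t_start_s = t_obs_start[ok], duration_s = obs_dur[ok],
      channel = "nucleotide",
      truth_state = state[ok], truth_zone = zone[ok],
      stringsAsFactors = FALSE
    )
    obs <- obs[obs$duration_s > 0, , drop = FALSE]

    # Z-disk fiducials per Z-disk frame, with drift and localization noise
    zx <- geom$myofibril_origin[1] + zdisk_s * u_axis[1]
    zy <- geom$myofibril_origin[2] + zdisk_s * u_axis[2]
    zframes <- sched$frame[sched$channel == "zdisk"]
    if (length(zframes) > 0L) {
      nz <- length(zdisk_s)
      zd <- data.frame(
        frame = rep(zframes, each = nz),
        zdisk_id = rep(seq_len(nz), times = length(zframes)),
        x_nm = rep(zx, times = length(zframes)) +
          drift$dx_nm[match(rep(zframes, each = nz), drift$frame)] +
          stats::rnorm(nz * length(zframes), 0, zdisk_noise[["x"]]),
        y_nm = rep(zy, times = length(zframes)) +
          drift$dy_nm[match(rep(zframes, each = nz), drift$frame)] +
          stats::rnorm(nz * length(zframes), 0, zdisk_noise[["y"]])
      )
    } else {
      zd <- data.frame(frame = integer(0), zdisk_id = integer(0),
                       x_nm = numeric(0), y_nm = numeric(0))
    }

    list(truth_events = truth, observed_events = obs,
         zdisk_truth = zd, drift_series = drift)
  })

  structure(
    c(sim, list(scheme = scheme, geom = geom, sched = sched, seed = seed)),
    class = "srx_sim"
  )
}

#' @export
print.srx_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic ATP-turnover dataset: %d truth events, %d observed after censoring\n",
    nrow(x$truth_events), nrow(x$observed_events)))
  print(table(truth_state = x$observed_events$truth_state,
              truth_zone = x$observed_events$truth_zone))
  invisible(x)
}

#' Write/read the package event-table CSV
#'
#' The shared on-disk event format: one row per observed event with
#' columns `event_id, x_nm, y_nm, frame_start, frame_end, t_start_s,
#' duration_s, channel, truth_state, truth_zone` (the truth columns are
#' `NA` for real data).
#'
#' @param events an event data frame (e.g. `sim$observed_events`).
#' @param path CSV file path.
#' @return `path` invisibly, or for the reader the event data frame.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("event_id", "x_nm", "y_nm", "frame_start", "frame_end",
            "t_start_s", "duration_s", "channel")
  stopifnot(all(cols %in% names(events)))
  for (cc in c("truth_state", "truth_zone")) {
    if (!cc %in% names(events)) events[[cc]] <- NA_character_
  }
  utils::write.csv(events[, c(cols, "truth_state", "truth_zone")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Render a synthetic dataset as two-channel image stacks
#'
#' Draws each event visible in a frame as a 2-D Gaussian of width
#' `psf_sigma` at its drifted true position, and each Z-disk as a
#' Gaussian-blurred line perpendicular to the myofibril axis on the
#' Z-disk-channel frames. Optional Poisson background noise is added per
#' pixel. Intended for end-to-end validation of the spot detector and
#' tracker, not for camera-realistic simulation.
#'
#' @param dataset an `"srx_sim"` object.
#' @param psf_sigma Gaussian PSF sigma in nm (default 138, matching a
#'   390-nm detection diameter).
#' @param pixel_size nm per pixel (default 65).
#' @param image_shape `c(nx, ny)` in pixels.
#' @param amplitude peak signal counts per spot (default 100).
#' @param background Poisson background mean per pixel (default 0).
#' @param zdisk_halfwidth half-length of the rendered Z-disk line in nm.
#' @param frames optional subset of frame indices to render.
#' @param seed seed for the background noise.
#' @return list with `nucleotide` and `zdisk` arrays (nx x ny x n_frames),
#'   `pixel_size`, and the frame indices rendered per channel.
#' @export
render_frames <- function(dataset, psf_sigma = 138, pixel_size = 65,
                          image_shape = c(128L, 64L), amplitude = 100,
                          background = 0, zdisk_halfwidth = 400,
                          frames = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "srx_sim"), psf_sigma > 0, pixel_size > 0)
  sched <- dataset$sched
  if (is.null(frames)) frames <- sched$frame
  drift <- dataset$drift_series

  nx <- image_shape[1]; ny <- image_shape[2]
  sig_px <- psf_sigma / pixel_size
  half <- max(3L, ceiling(4 * sig_px))

  add_spot <- function(img, xpx, ypx, amp) {
    if (xpx < -half || xpx > nx + half || ypx < -half || ypx > ny + half) {
      warning("spot outside image bounds; rendered clipped")
    }
    ix <- max(1L, floor(xpx) - half):min(nx, ceiling(xpx) + half)
    iy <- max(1L, floor(ypx) - half):min(ny, ceiling(ypx) + half)
    if (length(ix) == 0L || length(iy) == 0L) return(img)
    gx <- exp(-((ix - xpx)^2) / (2 * sig_px^2))
    gy <- exp(-((iy - ypx)^2) / (2 * sig_px^2))
    img[ix, iy] <- img[ix, iy] + amp * outer(gx, gy)
    img
  }

  th <- dataset$geom$axis_angle * pi / 180
  perp <- c(-sin(th), cos(th))
  # true Z-disk centres (no localization noise)
  zdisk_s <- (0:dataset$geom$n_sarcomeres) * dataset$geom$sarcomere_length
  zx <- dataset$geom$myofibril_origin[1] + zdisk_s * cos(th)
  zy <- dataset$geom$myofibril_origin[2] + zdisk_s * sin(th)

  tr <- dataset$truth_events
  ev_end <- tr$t_start_s + tr$true_duration_s

  nuc_frames <- frames[frames %in% sched$frame[sched$channel == "nucleotide"]]
  zd_frames <- frames[frames %in% sched$frame[sched$channel == "zdisk"]]

  out <- .with_seed(seed, {
    nuc_stack <- array(0, c(nx, ny, length(nuc_frames)))
    for (j in seq_along(nuc_frames)) {
      fr <- nuc_frames[j]
      t0 <- sched$timestamp[sched$frame == fr]
      t1 <- t0 + sched$exposure[sched$frame == fr]
      act <- which(tr$t_start_s < t1 & ev_end > t0)
      img <- matrix(0, nx, ny)
      dx <- drift$dx_nm[drift$frame == fr]; dy <- drift$dy_nm[drift$frame == fr]
      for (i in act) {
        img <- add_spot(img, (tr$x_nm[i] + dx) / pixel_size + 0.5,
                        (tr$y_nm[i] + dy) / pixel_size + 0.5, amplitude)
      }
      if (background > 0) {
        img <- img + stats::rpois(nx * ny, background)
      }
      nuc_stack[, , j] <- img
    }
    zd_stack <- array(0, c(nx, ny, length(zd_frames)))
    line_step <- pixel_size / 2
    offs <- seq(-zdisk_halfwidth, zdisk_halfwidth, by = line_step)
    for (j in seq_along(zd_frames)) {
      fr <- zd_frames[j]
      img <- matrix(0, nx, ny)
      dx <- drift$dx_nm[drift$frame == fr]; dy <- drift$dy_nm[drift$frame == fr]
      for (i in seq_along(zx)) {
        for (o in offs) {
          img <- add_spot(img,
                          (zx[i] + o * perp[1] + dx) / pixel_size + 0.5,
                          (zy[i] + o * perp[2] + dy) / pixel_size + 0.5,
                          amplitude / 4)
        }
      }
      if (background > 0) img <- img + stats::rpois(nx * ny, background)
      zd_stack[, , j] <- img
    }
    list(nucleotide = nuc_stack, zdisk = zd_stack)
  })
  out$pixel_size <- pixel_size
  out$nucleotide_frames <- nuc_frames
  out$zdisk_frames <- zd_frames
  out
}

#' Write rendered stacks as multi-page TIFF with a JSON schedule sidecar
#'
#' @param rendered result of [render_frames()].
#' @param sched the acquisition schedule used.
#' @param dir output directory (created if needed).
#' @param basename file stem for the two TIFFs and the JSON sidecar.
#' @return named vector of file paths, invisibly.
#' @export
write_image_stacks <- function(rendered, sched, dir, basename = "stack") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing TIFF stacks requires the 'tiff' package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm <- function(a) {
    m <- max(a, 1e-9)
    lapply(seq_len(dim(a)[3]), function(i) t(a[, , i]) / m)
  }
  p1 <- file.path(dir, paste0(basename, "_nucleotide.tif"))
  p2 <- file.path(dir, paste0(basename, "_zdisk.tif"))
  tiff::writeTIFF(norm(rendered$nucleotide), p1)
  tiff::writeTIFF(norm(rendered$zdisk), p2)
  p3 <- file.path(dir, paste0(basename, "_schedule.json"))
  jsonlite::write_json(
    list(frame = sched$frame, timestamp = sched$timestamp,
         exposure = sched$exposure, channel = sched$channel,
         pixel_size_nm = rendered$pixel_size),
    p3, auto_unbox = FALSE, digits = NA
  )
  invisible(c(nucleotide = p1, zdisk = p2, schedule = p3))
}
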