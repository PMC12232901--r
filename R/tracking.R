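#' Detect fluorescent spots in a single frame
#'
#' Laplacian-of-Gaussian (LoG) blob detection at a scale matched to the
#' expected object diameter, followed by local-maximum selection and
#' sub-pixel refinement (2-D Gaussian fit on a 7x7 window, falling back to
#' quadratic interpolation if the fit fails). The default quality
#' threshold is chosen by Otsu's method on the LoG response, since an
#' absolute threshold depends on camera gain.
#'
#' @param img numeric matrix (x by y) of pixel intensities.
#' @param pixel_size nm per pixel.
#' @param object_diameter expected spot diameter in nm (default 390).
#' @param quality_threshold minimum LoG response at a maximum; `NULL`
#'   (default) uses Otsu's threshold on the response image.
#' @return data frame with columns `x_nm`, `y_nm`, `quality` (LoG
#'   response); empty (with a warning) for blank or saturated frames.
#' @export
detect_spots <- function(img, pixel_size, object_diameter = 390,
                         quality_threshold = NULL) {
  stopifnot(is.matrix(img), pixel_size > 0)
  sigma_px <- object_diameter / (2 * sqrt(2)) / pixel_size
  if (object_diameter / pixel_size <= 2) {
    stop("object_diameter must exceed 2 pixels")
  }
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      quality = numeric(0))
  if (max(img) <= min(img)) {
    warning("blank or saturated frame; no spots detected")
    return(empty)
  }
  resp <- -.log_filter(img, sigma_px)   # bright blobs -> positive response
  thr <- if (is.null(quality_threshold)) .otsu(resp) else quality_threshold
  mx <- .local_maxima(resp)
  sel <- which(mx & resp > thr & resp > 0, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(empty)
  out <- lapply(seq_len(nrow(sel)), function(i) {
    cx <- sel[i, 1]; cy <- sel[i, 2]
    sub <- .subpixel(img, cx, cy, sigma_px)
    data.frame(x_nm = (sub[1] - 0.5) * pixel_size,
               y_nm = (sub[2] - 0.5) * pixel_size,
               quality = resp[cx, cy])
  })
  out <- do.call(rbind, out)
  out[order(-out$quality), , drop = FALSE]
}

# LoG response via separable Gaussian smoothing and a discrete Laplacian,
# scale-normalised by sigma^2.
.log_filter <- function(img, sigma_px) {
  sm <- .gauss_blur(img, sigma_px)
  n1 <- dim(sm)[1]; n2 <- dim(sm)[2]
  pad <- function(m) m[c(1, seq_len(n1), n1), c(1, seq_len(n2), n2)]
  p <- pad(sm)
  lap <- p[2:(n1 + 1), 2:(n2 + 1)] * -4 +
    p[1:n1, 2:(n2 + 1)] + p[3:(n1 + 2), 2:(n2 + 1)] +
    p[2:(n1 + 1), 1:n2] + p[2:(n1 + 1), 3:(n2 + 2)]
  lap * sigma_px^2
}

.gauss_blur <- function(img, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  kern <- stats::dnorm(-half:half, sd = sigma_px)
  kern <- kern / sum(kern)
  # separable convolution with edge replication
  conv1 <- function(m, k) {
    n <- nrow(m); h <- (length(k) - 1L) / 2L
    idx <- pmin(pmax(outer(seq_len(n), -h:h, "+"), 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img, kern)), kern))
}

.local_maxima <- function(resp) {
  n1 <- nrow(resp); n2 <- ncol(resp)
  p <- resp[c(1, seq_len(n1), n1), c(1, seq_len(n2), n2)]
  ge <- function(di, dj) resp >= p[2:(n1 + 1) + di, 2:(n2 + 1) + dj]
  ge(-1, -1) & ge(-1, 0) & ge(-1, 1) & ge(0, -1) & ge(0, 1) &
    ge(1, -1) & ge(1, 0) & ge(1, 1)
}

.otsu <- function(x) {
  v <- as.vector(x)
  br <- seq(min(v), max(v), length.out = 257)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  w <- h$counts / sum(h$counts); mids <- h$mids
  cw <- cumsum(w); cm <- cumsum(w * mids); mt <- cm[length(cm)]
  between <- (mt * cw - cm)^2 / (cw * (1 - cw))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# sub-pixel centre by 2-D Gaussian least squares on a 7x7 window; falls
# back to quadratic (parabolic) interpolation of the peak
.subpixel <- function(img, cx, cy, sigma_px) {
  half <- 3L
  ix <- max(1L, cx - half):min(nrow(img), cx + half)
  iy <- max(1L, cy - half):min(ncol(img), cy + half)
  w <- img[ix, iy, drop = FALSE]
  fit <- tryCatch({
    df <- data.frame(x = rep(ix, times = length(iy)),
                     y = rep(iy, each = length(ix)),
                     z = as.vector(w))
    f <- suppressWarnings(stats::nls(z ~ b + a * exp(-((x - mx)^2 + (y - my)^2) / (2 * s2)),
                    data = df,
                    start = list(b = min(w), a = max(w) - min(w),
                                 mx = cx, my = cy,
                                 s2 = max(sigma_px^2, 0.5)),
                    control = stats::nls.control(warnOnly = TRUE, maxiter = 100)))
    cf <- stats::coef(f)
    if (abs(cf["mx"] - cx) > half || abs(cf["my"] - cy) > half) stop("ran away")
    c(cf[["mx"]], cf[["my"]])
  }, error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  qa <- function(m1, m2, m3) {
    d <- (m1 - 2 * m2 + m3)
    if (d == 0) 0 else 0.5 * (m1 - m3) / d
  }
  dx <- if (cx > 1 && cx < nrow(img)) {
    qa(img[cx - 1, cy], img[cx, cy], img[cx + 1, cy])
  } else 0
  dy <- if (cy > 1 && cy < ncol(img)) {
    qa(img[cx, cy - 1], img[cx, cy], img[cx, cy + 1])
  } else 0
  c(cx + dx, cy + dy)
}

#' Link spots across frames into tracked events
#'
#' Greedy nearest-neighbour frame-to-frame linking with a distance cap and
#' gap closing: a track whose spot disappears may be continued up to
#' `gap_max` missed frames later within the same distance cap. Each spot
#' joins at most one track; equidistant candidates are resolved toward the
#' lower spot index. Durations are computed from the acquisition schedule
#' as (last frame timestamp - first frame timestamp) + exposure; without a
#' schedule, frames are assumed `frame_interval_s` apart.
#'
#' @param spots data frame with columns `x_nm`, `y_nm`, `frame` (indices
#'   into the nucleotide-frame sequence, need not be consecutive).
#' @param max_link_dist linking and gap-closing distance cap in nm
#'   (default 100).
#' @param gap_max maximum number of missed frames bridged (default 5).
#' @param schedule optional `"acq_schedule"`; its nucleotide frames define
#'   the timestamps for `spots$frame` values.
#' @param frame_interval_s fallback frame spacing in seconds (default 1).
#' @return data frame of class `"tracked_events"`: `event_id`, `x_nm`,
#'   `y_nm` (mean spot position), `frame_start`, `frame_end`, `n_spots`,
#'   `t_start_s`, `duration_s`; per-spot assignments in
#'   `attr(, "spot_track")`.
#' @export
link_spots <- function(spots, max_link_dist = 100, gap_max = 5L,
                       schedule = NULL, frame_interval_s = 1) {
  stopifnot(is.data.frame(spots),
            all(c("x_nm", "y_nm", "frame") %in% names(spots)))
  if (nrow(spots) == 0L) {
    out <- data.frame(event_id = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), frame_start = integer(0),
                      frame_end = integer(0), n_spots = integer(0),
                      t_start_s = numeric(0), duration_s = numeric(0))
    class(out) <- c("tracked_events", "data.frame")
    return(out)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  spots$.row <- seq_len(nrow(spots))
  track_of <- rep(NA_integer_, nrow(spots))
  # active track state: id, last x/y, last frame
  tr_id <- integer(0); tr_x <- numeric(0); tr_y <- numeric(0)
  tr_last <- integer(0)
  next_id <- 1L
  for (fr in sort(unique(spots$frame))) {
    idx <- spots$.row[spots$frame == fr]
    live <- which(tr_last >= fr - gap_max - 1L & tr_last < fr)
    if (length(live) > 0L && length(idx) > 0L) {
      d <- outer(seq_along(live), seq_along(idx), function(i, j) {
        sqrt((tr_x[live[i]] - spots$x_nm[idx[j]])^2 +
               (tr_y[live[i]] - spots$y_nm[idx[j]])^2)
      })
      repeat {
        if (all(!is.finite(d)) || min(d, na.rm = TRUE) > max_link_dist) break
        best <- which(d == min(d), arr.ind = TRUE)
        # ties resolved by lower spot index then lower track index
        best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
        ti <- live[best[1]]; sj <- idx[best[2]]
        track_of[sj] <- tr_id[ti]
        tr_x[ti] <- spots$x_nm[sj]; tr_y[ti] <- spots$y_nm[sj]
        tr_last[ti] <- fr
        d[best[1], ] <- Inf; d[, best[2]] <- Inf
      }
    }
    for (sj in idx[is.na(track_of[idx])]) {
      tr_id <- c(tr_id, next_id)
      tr_x <- c(tr_x, spots$x_nm[sj]); tr_y <- c(tr_y, spots$y_nm[sj])
      tr_last <- c(tr_last, fr)
      track_of[sj] <- next_id
      next_id <- next_id + 1L
    }
  }

  nuc_ts <- NULL
  exposure <- frame_interval_s
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "acq_schedule"))
    nuc <- schedule[schedule$channel == "nucleotide", , drop = FALSE]
    nuc_ts <- nuc$timestamp
    exposure <- nuc$exposure[1]
  }
  t_of <- function(fr) {
    if (is.null(nuc_ts)) (fr - 1) * frame_interval_s else nuc_ts[fr]
  }
  rows <- lapply(sort(unique(track_of)), function(id) {
    s <- spots[track_of == id, , drop = FALSE]
    f0 <- min(s$frame); f1 <- max(s$frame)
    data.frame(event_id = id,
               x_nm = mean(s$x_nm), y_nm = mean(s$y_nm),
               frame_start = f0, frame_end = f1, n_spots = nrow(s),
               t_start_s = t_of(f0),
               duration_s = t_of(f1) - t_of(f0) + exposure)
  })
  out <- do.call(rbind, rows)
  attr(out, "spot_track") <- data.frame(spot = spots$.row, track = track_of,
                                        frame = spots$frame)
  class(out) <- c("tracked_events", "data.frame")
  out
}

#' Estimate stage drift from Z-disk fiducials
#'
#' For each Z-disk frame, matches the fiducial constellation to the
#' reference frame by nearest neighbour and takes the median displacement
#' vector (robust to single mismatched fiducials). Translations are then
#' linearly interpolated to every frame of the schedule. Frames with fewer
#' than 3 fiducials inherit the last valid estimate, with a warning.
#'
#' @param zdisk_spots data frame with columns `frame`, `x_nm`, `y_nm`.
#' @param reference_frame frame whose constellation defines zero drift
#'   (default: first Z-disk frame).
#' @param frames integer vector of all frames to cover (default: range of
#'   observed Z-disk frames).
#' @return data frame of class `"drift_series"` with columns `frame`,
#'   `dx_nm`, `dy_nm`, zero at the reference frame.
#' @export
estimate_drift <- function(zdisk_spots, reference_frame = NULL,
                           frames = NULL) {
  stopifnot(is.data.frame(zdisk_spots),
            all(c("frame", "x_nm", "y_nm") %in% names(zdisk_spots)))
  zf <- sort(unique(zdisk_spots$frame))
  if (length(zf) == 0L) stop("no Z-disk spots supplied")
  if (is.null(reference_frame)) reference_frame <- zf[1]
  ref <- zdisk_spots[zdisk_spots$frame == reference_frame, , drop = FALSE]
  if (nrow(ref) < 3L) stop("reference frame needs at least 3 fiducials")
  dx <- dy <- numeric(length(zf))
  last <- c(0, 0)
  for (i in seq_along(zf)) {
    cur <- zdisk_spots[zdisk_spots$frame == zf[i], , drop = FALSE]
    if (nrow(cur) < 3L) {
      warning("frame ", zf[i], " has <3 fiducials; holding last drift estimate")
      dx[i] <- last[1]; dy[i] <- last[2]
      next
    }
    # match each current fiducial to its nearest reference fiducial
    nn <- vapply(seq_len(nrow(cur)), function(j) {
      which.min((ref$x_nm - cur$x_nm[j])^2 + (ref$y_nm - cur$y_nm[j])^2)
    }, integer(1))
    dx[i] <- stats::median(cur$x_nm - ref$x_nm[nn])
    dy[i] <- stats::median(cur$y_nm - ref$y_nm[nn])
    last <- c(dx[i], dy[i])
  }
  if (is.null(frames)) frames <- seq(min(zf), max(zf))
  out <- data.frame(
    frame = frames,
    dx_nm = stats::approx(zf, dx, xout = frames, rule = 2)$y,
    dy_nm = stats::approx(zf, dy, xout = frames, rule = 2)$y
  )
  class(out) <- c("drift_series", "data.frame")
  out
}

#' Remove estimated drift from spot or event coordinates
#'
#' @param spots data frame with `x_nm`, `y_nm` and a frame column
#'   (`frame` or `frame_start`).
#' @param drift a `"drift_series"` from [estimate_drift()].
#' @return `spots` with drift subtracted from the coordinates.
#' @export
apply_drift <- function(spots, drift) {
  stopifnot(inherits(drift, "drift_series"))
  fcol <- if ("frame" %in% names(spots)) "frame" else "frame_start"
  i <- match(spots[[fcol]], drift$frame)
  i[is.na(i)] <- which.min(abs(drift$frame - stats::median(spots[[fcol]])))
  spots$x_nm <- spots$x_nm - drift$dx_nm[i]
  spots$y_nm <- spots$y_nm - drift$dy_nm[i]
  spots
}

#' Localization precision from a stationary object
#'
#' Sample SD per axis of repeated localizations of a fixed point, the
#' standard empirical measure of super-localization precision.
#'
#' @param positions data frame with columns `x_nm`, `y_nm`, at least 20
#'   rows.
#' @return named vector `c(sd_x, sd_y)` in nm.
#' @export
estimate_precision <- function(positions) {
  stopifnot(is.data.frame(positions),
            all(c("x_nm", "y_nm") %in% names(positions)))
  if (nrow(positions) < 20L) stop("insufficient localizations (need >= 20)")
  c(sd_x = stats::sd(positions$x_nm), sd_y = stats::sd(positions$y_nm))
}
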