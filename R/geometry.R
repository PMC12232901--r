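# rotate row-wise (x, y) coordinates counterclockwise by phi radians
.rot2 <- function(xy, phi) {
  cbind(xy[, 1] * cos(phi) - xy[, 2] * sin(phi),
        xy[, 1] * sin(phi) + xy[, 2] * cos(phi))
}

#' Build sarcomere models from Z-disk positions
#'
#' Fits the myofibril axis as the principal axis of the Z-disk coordinates,
#' rotates all coordinates about their centroid so that axis is horizontal
#' (tilt correction), orders the Z-disks along the axis, and pairs
#' consecutive Z-disks into sarcomeres. The M-line of each sarcomere is the
#' midpoint between its two Z-disks.
#'
#' @param zdisks data frame with columns `x_nm`, `y_nm`, one row per
#'   Z-disk (time-averaged, drift-corrected positions).
#' @return An object of class `"sarcomere_set"`: a data frame with one row
#'   per sarcomere (`sarcomere_id`, Z-disk endpoints `za_x`..`zb_y` in
#'   tilt-corrected coordinates, `length_nm`, `mline_x`, `mline_y`) and
#'   attributes `rotation` (radians applied) and `center` used to map
#'   event coordinates into the same frame. Empty if fewer than 2 Z-disks.
#' @export
build_sarcomeres <- function(zdisks) {
  stopifnot(is.data.frame(zdisks), all(c("x_nm", "y_nm") %in% names(zdisks)))
  empty <- data.frame(sarcomere_id = integer(0), za_x = numeric(0),
                      za_y = numeric(0), zb_x = numeric(0), zb_y = numeric(0),
                      length_nm = numeric(0), mline_x = numeric(0),
                      mline_y = numeric(0))
  if (nrow(zdisks) < 2L) {
    attr(empty, "rotation") <- 0; attr(empty, "center") <- c(0, 0)
    class(empty) <- c("sarcomere_set", "data.frame")
    return(empty)
  }
  xy <- as.matrix(zdisks[, c("x_nm", "y_nm")])
  ctr <- colMeans(xy)
  xyc <- sweep(xy, 2, ctr)
  # principal axis; for exactly 2 points this is the connecting line
  sv <- svd(xyc)
  v1 <- sv$v[, 1]
  ang <- atan2(v1[2], v1[1])
  xyr <- .rot2(xyc, -ang)
  ord <- order(xyr[, 1])
  xr <- xyr[ord, 1]
  if (any(diff(xr) <= 0)) stop("crossed fiducials: Z-disks do not order along the axis")
  xyr <- xyr[ord, , drop = FALSE]
  n <- nrow(xyr) - 1L
  a <- xyr[seq_len(n), , drop = FALSE]
  b <- xyr[seq_len(n) + 1L, , drop = FALSE]
  out <- data.frame(
    sarcomere_id = seq_len(n),
    za_x = a[, 1], za_y = a[, 2], zb_x = b[, 1], zb_y = b[, 2],
    length_nm = sqrt(rowSums((b - a)^2)),
    mline_x = (a[, 1] + b[, 1]) / 2,
    mline_y = (a[, 2] + b[, 2]) / 2
  )
  attr(out, "rotation") <- -ang
  attr(out, "center") <- ctr
  class(out) <- c("sarcomere_set", "data.frame")
  out
}

#' Filter sarcomeres by minimum length
#'
#' Only clearly relaxed sarcomeres are analysed; shorter ones are dropped.
#'
#' @param models a `"sarcomere_set"`.
#' @param min_length minimum sarcomere length in nm (default 1700).
#' @return the retained subset, same class.
#' @export
filter_sarcomeres <- function(models, min_length = 1700) {
  stopifnot(inherits(models, "sarcomere_set"))
  keep <- models$length_nm > min_length
  n_rej <- sum(!keep)
  if (n_rej > 0L) {
    message(n_rej, " sarcomere(s) below ", min_length, " nm rejected")
  }
  if (all(!keep) && nrow(models) > 0L) {
    warning("all sarcomeres below the length threshold")
  }
  out <- models[keep, , drop = FALSE]
  attr(out, "rotation") <- attr(models, "rotation")
  attr(out, "center") <- attr(models, "center")
  class(out) <- class(models)
  out
}

#' Sarcomere length statistics
#'
#' Sample mean and SD of sarcomere lengths plus a Gaussian fit to the
#' binned length histogram (as conventionally reported for sarcomere-length
#' distributions).
#'
#' @param models a `"sarcomere_set"` with at least 2 sarcomeres.
#' @param binwidth histogram bin width in nm (default 20).
#' @return list with `mean_nm`, `sd_nm`, `n`, `histogram` (a
#'   [graphics::hist()] object, not plotted), and `gauss_fit`
#'   (`c(mean, sd)` from a least-squares Gaussian fit to the bin counts,
#'   `NA` if the fit fails).
#' @export
sarcomere_length_stats <- function(models, binwidth = 20) {
  stopifnot(inherits(models, "sarcomere_set"))
  len <- models$length_nm
  if (length(len) < 2L) stop("need at least 2 sarcomeres")
  h <- graphics::hist(len, breaks = seq(min(len) - binwidth, max(len) + binwidth,
                                        by = binwidth), plot = FALSE)
  gfit <- tryCatch({
    df <- data.frame(x = h$mids, y = h$counts)
    fit <- stats::nls(y ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                      start = list(a = max(h$counts), mu = mean(len),
                                   s = stats::sd(len)))
    cf <- stats::coef(fit)
    c(mean = unname(cf["mu"]), sd = abs(unname(cf["s"])))
  }, error = function(e) c(mean = NA_real_, sd = NA_real_))
  list(mean_nm = mean(len), sd_nm = stats::sd(len), n = length(len),
       histogram = h, gauss_fit = gfit)
}

#' Assign events to subsarcomeric zones
#'
#' Maps each (drift-corrected) event into the tilt-corrected frame of a
#' [build_sarcomeres()] model, finds the sarcomere whose axial interval
#' contains the event (ties at a shared Z-disk go to the lower-index
#' sarcomere), folds both halves of the sarcomere onto one axis by taking
#' the absolute axial distance from the M-line, and bins that distance into
#' the P-, C- or D-zone. Events beyond the outer zone boundary, farther
#' than `lateral_max` from the axis, or outside every sarcomere are marked
#' `excluded` with a reason.
#'
#' @param events data frame with columns `x_nm`, `y_nm` and `duration_s`
#'   (other columns are carried through).
#' @param sarcomeres a `"sarcomere_set"`.
#' @param zone_bounds 4 increasing boundaries in nm from the M-line
#'   (default `c(0, 159.5, 500.5, 800.5)`), delimiting zones P, C, D.
#' @param lateral_max maximum perpendicular distance from the myofibril
#'   axis in nm (default 500); farther events are excluded as off-axis.
#' @return the events data frame with added columns `sarcomere_id`,
#'   `axial_distance_nm`, `zone` (`"P"/"C"/"D"/"excluded"`) and
#'   `exclude_reason`.
#' @export
assign_zones <- function(events, sarcomeres,
                         zone_bounds = c(0, 159.5, 500.5, 800.5),
                         lateral_max = 500) {
  stopifnot(is.data.frame(events), inherits(sarcomeres, "sarcomere_set"),
            all(c("x_nm", "y_nm") %in% names(events)))
  if (length(zone_bounds) != 4L || is.unsorted(zone_bounds, strictly = TRUE) ||
      zone_bounds[1] != 0) {
    stop("zone_bounds must be 4 strictly increasing boundaries starting at 0")
  }
  n <- nrow(events)
  events$sarcomere_id <- NA_integer_
  events$axial_distance_nm <- NA_real_
  events$zone <- rep("excluded", n)
  events$exclude_reason <- rep("outside segmented myofibril", n)
  if (n == 0L || nrow(sarcomeres) == 0L) return(events)

  ang <- attr(sarcomeres, "rotation")
  ctr <- attr(sarcomeres, "center")
  xy <- .rot2(sweep(as.matrix(events[, c("x_nm", "y_nm")]), 2, ctr), ang)

  zone_names <- c("P", "C", "D")
  for (i in seq_len(n)) {
    xi <- xy[i, 1]
    # interval membership along the axis; ties toward lower index
    hit <- which(xi >= sarcomeres$za_x & xi <= sarcomeres$zb_x)
    if (length(hit) == 0L) next
    s <- hit[1]
    events$sarcomere_id[i] <- sarcomeres$sarcomere_id[s]
    lateral <- abs(xy[i, 2] - sarcomeres$mline_y[s])
    if (lateral > lateral_max) {
      events$exclude_reason[i] <- "off-axis"
      next
    }
    ax <- abs(xi - sarcomeres$mline_x[s])
    events$axial_distance_nm[i] <- ax
    idx <- findInterval(ax, zone_bounds, rightmost.closed = FALSE)
    if (idx >= 1L && idx <= 3L) {
      events$zone[i] <- zone_names[idx]
      events$exclude_reason[i] <- ""
    } else {
      events$exclude_reason[i] <- "beyond outer zone boundary"
    }
  }
  events
}

#' Assign a single event to a zone of one sarcomere
#'
#' Scalar convenience wrapper: folds the event's axial position about the
#' sarcomere M-line and bins the absolute distance.
#'
#' @param event list or one-row data frame with `x_nm`, `y_nm`.
#' @param sarcomere one row of a `"sarcomere_set"` (in whose tilt-corrected
#'   frame the event coordinates are expressed).
#' @param zone_bounds as in [assign_zones()].
#' @return list with `axial_distance_nm` and `zone`.
#' @export
assign_zone <- function(event, sarcomere,
                        zone_bounds = c(0, 159.5, 500.5, 800.5)) {
  ax <- abs(event$x_nm - sarcomere$mline_x)
  idx <- findInterval(ax, zone_bounds, rightmost.closed = FALSE)
  zone <- if (idx >= 1 && idx <= 3) c("P", "C", "D")[idx] else "excluded"
  list(axial_distance_nm = ax, zone = zone)
}
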