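#' Kinetic scheme of fluorescent-ATP binding events
#'
#' Container for the three-population dwell-time model: fast nonspecific
#' nucleotide association, DRX myosin ATP turnover, and SRX turnover, plus
#' the molecule-level SRX fraction per subsarcomeric zone and an optional
#' photobleach rate. Defaults are the untreated porcine ventricular values
#' used throughout the package: lifetimes 1.4 / 11.9 / 284.3 s and
#' molecule-level SRX fractions P 56.7%, C 53.7%, D 44.1%.
#'
#' @param lifetime_nonspecific,lifetime_drx,lifetime_srx state lifetimes in
#'   seconds; must be positive and strictly increasing in this order.
#' @param fraction_nonspecific_of_events fraction of generated events that
#'   are nonspecific surface binding, in \[0, 1\].
#' @param srx_fraction_by_zone named numeric vector (zones P, C, D) of the
#'   fraction of specific *molecules* in the SRX state, each in \[0, 1\].
#' @param bleach_rate photobleach rate per second of illuminated time.
#' @return An object of class `"kinetic_scheme"`.
#' @export
kinetic_scheme <- function(lifetime_nonspecific = 1.4,
                           lifetime_drx = 11.9,
                           lifetime_srx = 284.3,
                           fraction_nonspecific_of_events = 0.5,
                           srx_fraction_by_zone = c(P = 0.567, C = 0.537, D = 0.441),
                           bleach_rate = 0) {
  lt <- c(lifetime_nonspecific, lifetime_drx, lifetime_srx)
  if (any(lt <= 0)) stop("all lifetimes must be positive")
  if (!(lifetime_nonspecific < lifetime_drx && lifetime_drx < lifetime_srx)) {
    stop("lifetimes must satisfy nonspecific < DRX < SRX")
  }
  if (fraction_nonspecific_of_events < 0 || fraction_nonspecific_of_events > 1) {
    stop("fraction_nonspecific_of_events must be in [0, 1]")
  }
  if (is.null(names(srx_fraction_by_zone)) ||
      !all(nzchar(names(srx_fraction_by_zone)))) {
    stop("srx_fraction_by_zone must be a named vector (zone -> fraction)")
  }
  if (any(srx_fraction_by_zone < 0 | srx_fraction_by_zone > 1)) {
    stop("every srx_fraction_by_zone value must be in [0, 1]")
  }
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  structure(
    list(lifetime_nonspecific = lifetime_nonspecific,
         lifetime_drx = lifetime_drx,
         lifetime_srx = lifetime_srx,
         fraction_nonspecific_of_events = fraction_nonspecific_of_events,
         srx_fraction_by_zone = srx_fraction_by_zone,
         bleach_rate = bleach_rate),
    class = "kinetic_scheme"
  )
}

#' Thick-filament / myofibril geometry for simulation
#'
#' Describes an idealised myofibril: `n_sarcomeres` sarcomeres of equal
#' length laid end to end along an axis at `axis_angle` degrees from the
#' image X-axis, with subsarcomeric zone boundaries measured axially from
#' each M-line. The default boundaries realise the P-zone (0-159 nm),
#' C-zone (160-500 nm) and D-zone (501-800 nm) as half-open intervals with
#' cuts at 159.5 and 500.5 nm, so the printed integer bounds leave no
#' nanometre-scale gap.
#'
#' @param sarcomere_length sarcomere length in nm (Z-disk to Z-disk).
#' @param n_sarcomeres number of sarcomeres in the myofibril.
#' @param axis_angle myofibril axis angle, degrees from the image X-axis.
#' @param zone_bounds numeric vector of 4 increasing boundaries (nm from
#'   the M-line) delimiting the three zones; must start at 0.
#' @param myofibril_origin (x, y) position in nm of the first Z-disk.
#' @return An object of class `"filament_geometry"`.
#' @export
filament_geometry <- function(sarcomere_length = 1820,
                              n_sarcomeres = 8L,
                              axis_angle = 0,
                              zone_bounds = c(0, 159.5, 500.5, 800.5),
                              myofibril_origin = c(0, 0)) {
  if (sarcomere_length <= 0) stop("sarcomere_length must be positive")
  if (n_sarcomeres < 1L) stop("need at least one sarcomere")
  if (length(zone_bounds) != 4L || is.unsorted(zone_bounds, strictly = TRUE)) {
    stop("zone_bounds must be 4 strictly increasing boundaries")
  }
  if (zone_bounds[1] != 0) stop("zone_bounds must start at 0 (the M-line)")
  structure(
    list(sarcomere_length = sarcomere_length,
         n_sarcomeres = as.integer(n_sarcomeres),
         axis_angle = axis_angle,
         zone_bounds = zone_bounds,
         myofibril_origin = myofibril_origin),
    class = "filament_geometry"
  )
}

#' Stroboscopic acquisition schedule
#'
#' Builds the frame timetable of the experiment. The default emulates the
#' stroboscopic six-frame cycle: five sequential 200-ms nucleotide-channel
#' frames at the start of each cycle, followed by one 200-ms Z-disk-channel
#' frame during the dark period, repeating every `cycle_period` seconds.
#' The printed acquisition description (1,000 frames, 30 min) is not
#' consistent with a literal back-to-back cycle, so the default cycle
#' period spreads 166 cycles over 30 minutes.
#'
#' @param n_cycles number of six-frame cycles (default 166).
#' @param frame_exposure exposure per frame in seconds (default 0.2).
#' @param cycle_period wall-clock seconds per cycle (default 1800/166).
#' @param nucleotide_per_cycle nucleotide frames per cycle (default 5).
#' @return An object of class `"acq_schedule"`: a data frame with columns
#'   `frame`, `timestamp`, `exposure`, `channel`.
#' @seealso [continuous_schedule()] for idealised uninterrupted observation.
#' @export
acquisition_schedule <- function(n_cycles = 166L, frame_exposure = 0.2,
                                 cycle_period = 1800 / 166,
                                 nucleotide_per_cycle = 5L) {
  if (n_cycles < 1L) stop("no frames")
  if (frame_exposure <= 0) stop("exposure must be positive")
  if (cycle_period < (nucleotide_per_cycle + 1L) * frame_exposure) {
    stop("cycle_period too short for the frames it must contain")
  }
  offs_nuc <- (seq_len(nucleotide_per_cycle) - 1L) * frame_exposure
  offs <- c(offs_nuc, nucleotide_per_cycle * frame_exposure)
  chan <- c(rep("nucleotide", nucleotide_per_cycle), "zdisk")
  ts <- as.vector(outer(offs, cycle_period * (seq_len(n_cycles) - 1L), "+"))
  channel <- rep(chan, times = n_cycles)
  out <- data.frame(frame = seq_along(ts), timestamp = ts,
                    exposure = frame_exposure, channel = channel,
                    stringsAsFactors = FALSE)
  .as_schedule(out)
}

#' Idealised continuous acquisition schedule
#'
#' Back-to-back nucleotide frames with no dark period, used when dwell
#' times should be observed with only frame-rate discretisation (or, with
#' `censor = FALSE` downstream, essentially exactly). No Z-disk frames are
#' included; geometry for such runs comes from the simulator's truth table.
#'
#' @param duration_s total observation time in seconds.
#' @param frame_exposure exposure per frame in seconds (default 0.2).
#' @return An `"acq_schedule"` object.
#' @export
continuous_schedule <- function(duration_s, frame_exposure = 0.2) {
  if (duration_s <= 0 || frame_exposure <= 0) stop("no frames")
  n <- floor(duration_s / frame_exposure)
  if (n < 1L) stop("no frames")
  out <- data.frame(frame = seq_len(n),
                    timestamp = (seq_len(n) - 1L) * frame_exposure,
                    exposure = frame_exposure,
                    channel = "nucleotide", stringsAsFactors = FALSE)
  .as_schedule(out)
}

.as_schedule <- function(df) {
  if (nrow(df) == 0L) stop("no frames")
  if (is.unsorted(df$timestamp, strictly = TRUE)) {
    stop("frame timestamps must be strictly increasing")
  }
  class(df) <- c("acq_schedule", "data.frame")
  df
}

#' Illuminated duty cycle of an acquisition schedule
#'
#' Fraction of total wall-clock time during which the given channel is
#' illuminated; used to scale the photobleach rate in
#' [photobleach_correct()].
#'
#' @param sched an `"acq_schedule"`.
#' @param channel channel name (default `"nucleotide"`).
#' @return a fraction in (0, 1\].
#' @export
schedule_duty_cycle <- function(sched, channel = "nucleotide") {
  stopifnot(inherits(sched, "acq_schedule"))
  span <- max(sched$timestamp) + sched$exposure[nrow(sched)] - min(sched$timestamp)
  sum(sched$exposure[sched$channel == channel]) / span
}
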