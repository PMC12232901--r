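#' Read TrackMate track exports
#'
#' Ingests TrackMate (ImageJ) results for one channel, from either the
#' full XML model file or the spots-table CSV export, and converts them to
#' the package's tracked-event representation. Positions are converted to
#' nm using the file's spatial units where present; files in pixel units
#' require an explicit `pixel_size`. Per-track frame spans and durations
#' are recomputed under the package's timing convention
#' ((last - first frame timestamp) + exposure), so XML and CSV dialects of
#' the same tracks yield identical events.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"xml"`, or `"csv"`.
#' @param pixel_size nm per pixel; required when the file's units are
#'   pixels, ignored when the file is already calibrated in nm or um.
#' @param schedule optional `"acq_schedule"` supplying nucleotide-frame
#'   timestamps; otherwise `frame_interval_s` spacing is assumed.
#' @param frame_interval_s fallback frame spacing in seconds (default 1).
#' @return a `"tracked_events"` data frame (see [link_spots()]).
#' @export
read_trackmate <- function(path, dialect = c("auto", "xml", "csv"),
                           pixel_size = NULL, schedule = NULL,
                           frame_interval_s = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "csv"
  }
  spots <- switch(dialect,
                  xml = .tm_read_xml(path, pixel_size),
                  csv = .tm_read_csv(path, pixel_size))
  # rebuild events track by track under the package timing convention
  nuc_ts <- NULL; exposure <- frame_interval_s
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "acq_schedule"))
    nuc <- schedule[schedule$channel == "nucleotide", , drop = FALSE]
    nuc_ts <- nuc$timestamp; exposure <- nuc$exposure[1]
  }
  t_of <- function(fr) {
    if (is.null(nuc_ts)) (fr - 1) * frame_interval_s else nuc_ts[fr]
  }
  rows <- lapply(split(spots, spots$track), function(s) {
    s <- s[order(s$frame), , drop = FALSE]
    data.frame(event_id = s$track[1],
               x_nm = mean(s$x_nm), y_nm = mean(s$y_nm),
               frame_start = min(s$frame), frame_end = max(s$frame),
               n_spots = nrow(s),
               t_start_s = t_of(min(s$frame)),
               duration_s = t_of(max(s$frame)) - t_of(min(s$frame)) + exposure)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tracked_events", "data.frame")
  out
}

.tm_scale <- function(units, pixel_size) {
  u <- tolower(units)
  if (u %in% c("nm", "nanometer", "nanometre")) return(1)
  if (u %in% c("um", "micron", "micrometer", "µm", "micrometre")) {
    return(1000)
  }
  if (u %in% c("pixel", "pixels", "px")) {
    if (is.null(pixel_size)) {
      stop("file is in pixel units; supply pixel_size (nm per pixel)")
    }
    return(pixel_size)
  }
  stop("unknown spatial units '", units, "'; supply calibrated data")
}

.tm_read_xml <- function(path, pixel_size) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed TrackMate XML: ", conditionMessage(e))
  })
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing")) stop("no <Model> element in file")
  units <- xml2::xml_attr(model, "spatialunits")
  if (is.na(units)) stop("missing unit metadata; supply calibrated XML")
  scale <- .tm_scale(units, pixel_size)
  sp <- xml2::xml_find_all(doc, ".//AllSpots//Spot")
  if (length(sp) == 0L) stop("no spots in file")
  spot_id <- xml2::xml_attr(sp, "ID")
  spots <- data.frame(
    id = spot_id,
    x_nm = as.numeric(xml2::xml_attr(sp, "POSITION_X")) * scale,
    y_nm = as.numeric(xml2::xml_attr(sp, "POSITION_Y")) * scale,
    frame = as.integer(xml2::xml_attr(sp, "FRAME")) + 1L,
    stringsAsFactors = FALSE
  )
  tracks <- xml2::xml_find_all(doc, ".//AllTracks/Track")
  if (length(tracks) == 0L) stop("no tracks in file")
  edges <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    e <- xml2::xml_find_all(tracks[[i]], ".//Edge")
    if (length(e) == 0L) return(NULL)
    data.frame(
      track = as.integer(xml2::xml_attr(tracks[[i]], "TRACK_ID")),
      src = xml2::xml_attr(e, "SPOT_SOURCE_ID"),
      tgt = xml2::xml_attr(e, "SPOT_TARGET_ID"),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(edges)) stop("no edges in any track")
  member <- unique(rbind(
    data.frame(track = edges$track, id = edges$src, stringsAsFactors = FALSE),
    data.frame(track = edges$track, id = edges$tgt, stringsAsFactors = FALSE)
  ))
  spots <- merge(spots, member, by = "id")
  spots[order(spots$track, spots$frame), c("track", "x_nm", "y_nm", "frame")]
}

.tm_read_csv <- function(path, pixel_size) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "POSITION_X", "POSITION_Y", "FRAME")
  if (!all(need %in% names(raw))) {
    stop("CSV lacks required TrackMate columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  # TrackMate v7 spot CSVs carry extra header rows (labels/units) before data
  numeric_rows <- !is.na(suppressWarnings(as.numeric(raw$FRAME)))
  raw <- raw[numeric_rows, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no spot rows in CSV")
  # spot-table CSVs carry no machine-readable unit metadata; positions are
  # in pixels, so an explicit calibration is mandatory
  if (is.null(pixel_size)) {
    stop("CSV dialect carries no unit metadata; supply pixel_size (nm per pixel)")
  }
  scale <- pixel_size
  data.frame(
    track = as.integer(raw$TRACK_ID),
    x_nm = as.numeric(raw$POSITION_X) * scale,
    y_nm = as.numeric(raw$POSITION_Y) * scale,
    frame = as.integer(raw$FRAME) + 1L
  )
}
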