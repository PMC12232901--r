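# shared fixtures for the test suite; everything is generated in code

# canonical three-population kinetics used across tests
LIFETIMES <- c(ns = 1.4, drx = 11.9, srx = 284.3)
RATES <- 1 / LIFETIMES

draw_mixture <- function(n, A, k, seed) {
  set.seed(seed)
  comp <- sample(seq_along(A), n, replace = TRUE, prob = A)
  stats::rexp(n, k[comp])
}

# dense noiseless cumulative curve as a crth object (for oracle fits)
noiseless_crth <- function(A, k, t_min = 0.2, t_max = 1500, m = 200) {
  t <- exp(seq(log(t_min), log(t_max), length.out = m))
  y <- drop(exp(-outer(t, k)) %*% A)
  out <- data.frame(t = t, count = y)
  attr(out, "n_events") <- m
  attr(out, "normalized") <- TRUE
  class(out) <- c("crth", "data.frame")
  out
}

# minimal TrackMate-style XML for a list of track data frames
# each track: data.frame(x, y, frame) with frame 0-based, positions in
# `units` (e.g. "pixel" or "um")
write_trackmate_xml <- function(path, tracks, units = "um") {
  spot_id <- 0L
  spot_lines <- character(0)
  edge_lines <- list()
  frames_all <- sort(unique(unlist(lapply(tracks, `[[`, "frame"))))
  spots_by_frame <- setNames(vector("list", length(frames_all)),
                             as.character(frames_all))
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    ids <- integer(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      ids[i] <- spot_id
      spots_by_frame[[as.character(tr$frame[i])]] <- c(
        spots_by_frame[[as.character(tr$frame[i])]],
        sprintf('<Spot ID="%d" POSITION_X="%g" POSITION_Y="%g" FRAME="%d" QUALITY="1"/>',
                spot_id, tr$x[i], tr$y[i], tr$frame[i]))
      spot_id <- spot_id + 1L
    }
    edge_lines[[ti]] <- if (length(ids) > 1L) {
      sprintf('<Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d"/>',
              ids[-length(ids)], ids[-1])
    } else {
      # synthetic fixture convention for single-spot tracks
      sprintf('<Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d"/>', ids, ids)
    }
  }
  frame_blocks <- vapply(names(spots_by_frame), function(f) {
    paste0('<SpotsInFrame frame="', f, '">\n',
           paste(spots_by_frame[[f]], collapse = "\n"),
           "\n</SpotsInFrame>")
  }, character(1))
  track_blocks <- vapply(seq_along(tracks), function(ti) {
    paste0('<Track TRACK_ID="', ti - 1L, '" NUMBER_SPOTS="',
           nrow(tracks[[ti]]), '">\n',
           paste(edge_lines[[ti]], collapse = "\n"), "\n</Track>")
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<TrackMate version="7.0.0">\n',
    '<Model spatialunits="', units, '" timeunits="s">\n',
    "<AllSpots>\n", paste(frame_blocks, collapse = "\n"), "\n</AllSpots>\n",
    "<AllTracks>\n", paste(track_blocks, collapse = "\n"), "\n</AllTracks>\n",
    "</Model>\n</TrackMate>\n")
  writeLines(xml, path)
  invisible(path)
}

write_trackmate_csv <- function(path, tracks) {
  rows <- do.call(rbind, lapply(seq_along(tracks), function(ti) {
    data.frame(LABEL = paste0("ID", seq_len(nrow(tracks[[ti]]))),
               TRACK_ID = ti - 1L,
               POSITION_X = tracks[[ti]]$x, POSITION_Y = tracks[[ti]]$y,
               FRAME = tracks[[ti]]$frame)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# small simulation in idealised observation mode (exact durations)
sim_ideal <- function(n_events, seed, scheme = kinetic_scheme(),
                      geom = filament_geometry(),
                      noise = c(x = 0, y = 0)) {
  simulate_events(scheme, geom, continuous_schedule(3600),
                  noise = noise, n_events = n_events,
                  censor = FALSE, seed = seed)
}
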