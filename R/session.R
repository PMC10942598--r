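#' Construct and validate a session object
#'
#' A session bundles everything recorded in one behavioral session: spike
#' trains, tracking, the behavioral event log (Tree-Maze only), tetrode
#' depths and optional waveform sets. All validation errors name the
#' offending component.
#'
#' @param subject_id,session_id identifiers
#' @param task "treemaze" or "openfield"
#' @param spike_trains named list of numeric vectors (spike times, s,
#'   ascending)
#' @param tracking data.frame with columns t, x, y, theta, speed
#' @param events data.frame with columns t, kind, payload (Tree-Maze), or
#'   NULL
#' @param units optional data.frame (unit_id, tetrode, unit_class); built
#'   from `spike_trains` names if omitted
#' @param tetrode_depths named numeric (um per tetrode)
#' @param zones a `zone_map`; defaults to [treemaze_zones()]
#' @param waveforms optional waveform set (see [simulate_waveform_sets()])
#' @return object of class `session_data`
#' @export
session_data <- function(subject_id, session_id, task, spike_trains,
                         tracking, events = NULL, units = NULL,
                         tetrode_depths = NULL, zones = treemaze_zones(),
                         waveforms = NULL) {
  task <- match.arg(task, c("treemaze", "openfield"))
  if (is.null(names(spike_trains)) || anyDuplicated(names(spike_trains))) {
    stop("session_data: spike_trains must be a uniquely named list")
  }
  stopifnot(is.data.frame(tracking),
            all(c("t", "x", "y", "theta", "speed") %in% names(tracking)))
  t0 <- tracking$t[1]
  t1 <- tracking$t[nrow(tracking)]
  for (u in names(spike_trains)) {
    st <- spike_trains[[u]]
    if (is.unsorted(st, strictly = FALSE)) {
      stop(sprintf("session_data: spike times of unit %s are not sorted", u))
    }
    if (length(st) && (st[1] < t0 - 1e-9 || st[length(st)] > t1 + 1e-9)) {
      stop(sprintf("session_data: unit %s has spikes outside session bounds", u))
    }
  }
  if (any(tracking$speed < -1e-9, na.rm = TRUE)) {
    stop("session_data: negative speeds in tracking")
  }
  if (!is.null(events)) {
    stopifnot(all(c("t", "kind", "payload") %in% names(events)))
    if (is.unsorted(events$t)) stop("session_data: event log not time-ordered")
  }
  if (is.null(units)) {
    units <- data.frame(unit_id = names(spike_trains),
                        tetrode = 1L,
                        unit_class = "isolated",
                        stringsAsFactors = FALSE)
  }
  structure(list(subject_id = subject_id, session_id = session_id,
                 task = task, spike_trains = spike_trains,
                 tracking = tracking, events = events, units = units,
                 tetrode_depths = tetrode_depths, zones = zones,
                 waveforms = waveforms),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> %s / %s (%s): %d units, %.1f s, %d events\n",
              x$subject_id, x$session_id, x$task, length(x$spike_trains),
              diff(range(x$tracking$t)),
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Save a session bundle to a directory
#'
#' Writes the inspectable plain-text session dialect: `manifest.json`
#' (subject, session, task, unit table, tetrode depths), `spikes.csv`
#' (unit_id, t), `tracking.csv`, `events.csv` (Tree-Maze only) and
#' `zones.json`.
#'
#' @param session a `session_data`
#' @param path directory (created if missing)
#' @return `path`, invisibly
#' @export
save_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(subject_id = session$subject_id,
                   session_id = session$session_id,
                   task = session$task,
                   units = session$units,
                   tetrode_depths = as.list(session$tetrode_depths))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  sp <- data.frame(
    unit_id = rep(names(session$spike_trains),
                  vapply(session$spike_trains, length, 1L)),
    t = unlist(session$spike_trains, use.names = FALSE)
  )
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$tracking, file.path(path, "tracking.csv"),
                   row.names = FALSE)
  if (!is.null(session$events)) {
    utils::write.csv(session$events, file.path(path, "events.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(zones = session$zones$zones,
                            adjacency = session$zones$adjacency,
                            bounds = session$zones$bounds),
                       file.path(path, "zones.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a session bundle from a directory
#'
#' Inverse of [save_session()]; all `session_data` invariants are
#' re-validated on load.
#'
#' @param path directory containing the bundle
#' @return a `session_data`
#' @export
load_session <- function(path) {
  need <- c("manifest.json", "spikes.csv", "tracking.csv", "zones.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("load_session: missing file %s in %s", f, path))
    }
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  sp <- utils::read.csv(file.path(path, "spikes.csv"),
                        stringsAsFactors = FALSE)
  tracking <- utils::read.csv(file.path(path, "tracking.csv"))
  ev_path <- file.path(path, "events.csv")
  events <- if (file.exists(ev_path)) {
    utils::read.csv(ev_path, stringsAsFactors = FALSE)
  } else NULL
  zj <- jsonlite::read_json(file.path(path, "zones.json"),
                            simplifyVector = TRUE)
  zones <- structure(list(zones = zj$zones,
                          adjacency = lapply(zj$adjacency, as.integer),
                          bounds = zj$bounds),
                     class = "zone_map")
  unit_ids <- as.character(manifest$units$unit_id)
  # not re-sorted here: session_data() rejects unsorted trains, which is the
  # wanted behavior for hand-edited bundles
  spike_trains <- stats::setNames(
    lapply(unit_ids, function(u) sp$t[sp$unit_id == u]), unit_ids)
  depths <- unlist(manifest$tetrode_depths)
  session_data(subject_id = manifest$subject_id,
               session_id = manifest$session_id,
               task = manifest$task,
               spike_trains = spike_trains,
               tracking = tracking,
               events = events,
               units = manifest$units,
               tetrode_depths = depths,
               zones = zones)
}
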