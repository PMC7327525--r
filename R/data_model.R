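#' Construct a centriole track
#'
#' A `centriole_track` holds one centriole's background-subtracted fluorescence
#' time series (nominally sampled every 30 s), optional xy positions, a fate
#' label and any observed duplication-event times. Times are in seconds on the
#' embryo clock; per-cycle analyses rebase them so that centrosome separation
#' (CS, the start of S-phase) is t = 0.
#'
#' @param track_id,embryo_id identifiers (coerced to character).
#' @param times numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @param intensity fluorescence in arbitrary units, same length as `times`.
#'   Negative values (possible after background subtraction) are retained.
#' @param xy optional two-column matrix of pixel positions per time point.
#' @param fate one of `"fertile"`, `"sterile"`, `"ambiguous"`, `"unknown"`.
#' @param duplication_times sorted numeric vector of duplication-event times in
#'   seconds, all within `range(times)`; may be empty.
#' @return an object of class `centriole_track`.
#' @export
centriole_track <- function(track_id, embryo_id = "e1", times, intensity,
                            xy = NULL, fate = "unknown",
                            duplication_times = numeric(0)) {
  fate <- match.arg(fate, c("fertile", "sterile", "ambiguous", "unknown"))
  times <- as.numeric(times); intensity <- as.numeric(intensity)
  if (length(times) != length(intensity))
    stop_validation("track ", track_id, ": times and intensity lengths differ")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_validation("track ", track_id, ": times are not strictly increasing")
  duplication_times <- sort(as.numeric(duplication_times))
  if (length(duplication_times) &&
      (min(duplication_times) < min(times) || max(duplication_times) > max(times)))
    stop_validation("track ", track_id,
                    ": duplication_times outside the track's time range")
  if (!is.null(xy)) {
    xy <- as.matrix(xy)
    stopifnot(ncol(xy) == 2L, nrow(xy) == length(times))
  }
  structure(list(track_id = as.character(track_id),
                 embryo_id = as.character(embryo_id),
                 times = times, intensity = intensity, xy = xy, fate = fate,
                 duplication_times = duplication_times),
            class = "centriole_track")
}

#' Construct a cell-cycle annotation
#'
#' Marks one nuclear cycle: `cs_time` is centrosome separation (taken as the
#' start of S-phase and the local time origin) and `neb_time` is nuclear
#' envelope breakdown (mitotic entry).
#'
#' @param cycle_index integer cycle number (syncytial fly embryos: 10-14).
#' @param cs_time,neb_time,next_cs_time seconds; `cs_time < neb_time` and, when
#'   given, `neb_time < next_cs_time`.
#' @return an object of class `cycle_annotation`.
#' @export
cycle_annotation <- function(cycle_index, cs_time, neb_time, next_cs_time = NA_real_) {
  if (cs_time >= neb_time)
    stop_validation("cycle ", cycle_index, ": cs_time must precede neb_time")
  if (!is.na(next_cs_time) && neb_time >= next_cs_time)
    stop_validation("cycle ", cycle_index, ": neb_time must precede next_cs_time")
  structure(list(cycle_index = as.integer(cycle_index), cs_time = cs_time,
                 neb_time = neb_time, next_cs_time = next_cs_time),
            class = "cycle_annotation")
}

#' Construct an embryo dataset
#'
#' @param embryo_id identifier.
#' @param condition free-text condition label (e.g. "WT").
#' @param tracks list of [centriole_track] objects.
#' @param annotations list of [cycle_annotation] objects.
#' @param observation_window length-2 numeric `[t_start, t_end]` in seconds;
#'   defaults to the range spanned by the tracks. All track times must fall
#'   inside it.
#' @return an object of class `embryo_dataset`.
#' @export
embryo_dataset <- function(embryo_id, tracks, annotations = list(),
                           condition = "WT", observation_window = NULL) {
  stopifnot(is.list(tracks), all(vapply(tracks, inherits, TRUE, "centriole_track")))
  if (is.null(observation_window)) {
    rng <- range(unlist(lapply(tracks, `[[`, "times")))
    observation_window <- rng
  }
  for (tr in tracks)
    if (min(tr$times) < observation_window[1] || max(tr$times) > observation_window[2])
      stop_validation("track ", tr$track_id, " falls outside observation_window")
  structure(list(embryo_id = as.character(embryo_id), condition = condition,
                 tracks = tracks, annotations = annotations,
                 observation_window = as.numeric(observation_window)),
            class = "embryo_dataset")
}

#' @export
print.embryo_dataset <- function(x, ...) {
  cat("<embryo_dataset> ", x$embryo_id, " (", x$condition, "): ",
      length(x$tracks), " tracks, ", length(x$annotations), " annotated cycles, ",
      "window [", x$observation_window[1], ", ", x$observation_window[2], "] s\n",
      sep = "")
  invisible(x)
}

track_table_columns <- c("track_id", "embryo_id", "time_s", "intensity",
                         "x_px", "y_px", "fate", "event")

#' Read a long-form centriole track table
#'
#' The interchange format is a long CSV with one row per (track, time point):
#' columns `track_id`, `time_s`, `intensity` are required; `embryo_id`, `x_px`,
#' `y_px`, `fate` and `event` are optional. Duplication events are encoded as
#' extra rows with `event == "duplication"` (their `intensity` may be NA).
#'
#' @param path CSV file path.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(time_s = "t")`.
#' @param condition condition label stored on the dataset.
#' @return an [embryo_dataset] (cycle annotations are supplied separately).
#' @seealso [write_track_table()]
#' @export
read_track_table <- function(path, dialect = NULL, condition = "WT") {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect))
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  required <- c("track_id", "time_s", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_validation("track table lacks required column(s): ",
                    paste(missing, collapse = ", "))
  if (is.null(df$embryo_id)) df$embryo_id <- "e1"
  if (is.null(df$fate)) df$fate <- "unknown"
  if (is.null(df$event)) df$event <- ""
  df$event[is.na(df$event)] <- ""
  tracks <- lapply(split(df, df$track_id), function(d) {
    dup <- d$time_s[d$event == "duplication"]
    d <- d[d$event != "duplication", , drop = FALSE]
    d <- d[order(d$time_s), , drop = FALSE]
    if (any(diff(d$time_s) <= 0))
      stop_validation("track ", d$track_id[1], ": non-monotone time values")
    xy <- if (!is.null(d$x_px) && !all(is.na(d$x_px)))
      cbind(d$x_px, d$y_px) else NULL
    centriole_track(d$track_id[1], d$embryo_id[1], d$time_s, d$intensity,
                    xy = xy, fate = d$fate[1], duplication_times = dup)
  })
  tracks <- tracks[order(names(tracks))]
  embryo_dataset(tracks[[1]]$embryo_id, unname(tracks), condition = condition)
}

#' Write a dataset as a long-form track table
#'
#' Inverse of [read_track_table()]: numeric fields round-trip exactly (written
#' with full precision).
#'
#' @param dataset an [embryo_dataset].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(dataset, path) {
  rows <- lapply(dataset$tracks, function(tr) {
    n <- length(tr$times)
    base <- data.frame(track_id = tr$track_id, embryo_id = tr$embryo_id,
                       time_s = tr$times, intensity = tr$intensity,
                       x_px = if (is.null(tr$xy)) NA_real_ else tr$xy[, 1],
                       y_px = if (is.null(tr$xy)) NA_real_ else tr$xy[, 2],
                       fate = tr$fate, event = "",
                       stringsAsFactors = FALSE)
    if (length(tr$duplication_times)) {
      ev <- data.frame(track_id = tr$track_id, embryo_id = tr$embryo_id,
                       time_s = tr$duplication_times, intensity = NA_real_,
                       x_px = NA_real_, y_px = NA_real_, fate = tr$fate,
                       event = "duplication", stringsAsFactors = FALSE)
      base <- rbind(base, ev)
    }
    base
  })
  out <- do.call(rbind, rows)
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Segment tracks into one cycle and aggregate across centrioles
#'
#' Restricts all tracks to one annotated nuclear cycle, rebases time so that
#' centrosome separation is t = 0, snaps samples to the common acquisition grid
#' (30 s by default; off-grid samples are snapped to the nearest grid point
#' with a warning) and returns the cross-track mean +/- SD signal.
#'
#' @param dataset an [embryo_dataset] with a [cycle_annotation] for `cycle`.
#' @param cycle integer cycle index to extract.
#' @param dt acquisition grid spacing in seconds.
#' @return an object of class `pulse_segment` with fields `cycle_index`,
#'   `rel_times` (starting at 0), `mean_intensity`, `sd_intensity` (0 where a
#'   single track contributes), `n_tracks` and `neb_rel`.
#' @export
segment_and_aggregate <- function(dataset, cycle, dt = 30) {
  ann <- Filter(function(a) a$cycle_index == cycle, dataset$annotations)
  if (!length(ann)) stop_validation("no annotation for cycle ", cycle)
  ann <- ann[[1]]
  t_end <- if (!is.na(ann$next_cs_time)) ann$next_cs_time else ann$neb_time
  grid <- seq(0, t_end - ann$cs_time, by = dt)
  mat <- matrix(NA_real_, nrow = length(grid), ncol = length(dataset$tracks))
  for (j in seq_along(dataset$tracks)) {
    tr <- dataset$tracks[[j]]
    keep <- tr$times >= ann$cs_time - dt / 2 & tr$times <= t_end + dt / 2
    if (!any(keep)) next
    rel <- tr$times[keep] - ann$cs_time
    idx <- round(rel / dt) + 1L
    if (any(abs(rel - (idx - 1L) * dt) > 1e-6))
      warning("track ", tr$track_id, ": off-grid samples snapped to ", dt, " s grid")
    ok <- idx >= 1L & idx <= length(grid)
    mat[idx[ok], j] <- tr$intensity[keep][ok]
  }
  used <- colSums(!is.na(mat)) > 0
  if (!any(used)) stop_validation("no tracks overlap cycle ", cycle)
  mat <- mat[, used, drop = FALSE]
  covered <- rowSums(!is.na(mat)) > 0
  m <- apply(mat, 1, function(r) mean(r, na.rm = TRUE))
  s <- apply(mat, 1, function(r) {
    v <- r[!is.na(r)]
    if (length(v) < 2) 0 else stats::sd(v)
  })
  structure(list(cycle_index = as.integer(cycle),
                 rel_times = grid[covered],
                 mean_intensity = m[covered],
                 sd_intensity = s[covered],
                 n_tracks = sum(used),
                 neb_rel = ann$neb_time - ann$cs_time),
            class = "pulse_segment")
}

#' Construct a pulse segment directly
#'
#' Convenience constructor for analyses that start from an already aggregated
#' per-cycle signal.
#'
#' @param rel_times seconds, rebased so CS = 0 (first element must be 0).
#' @param mean_intensity,sd_intensity a.u. vectors matching `rel_times`.
#' @param neb_rel NEB time on the rebased axis, seconds.
#' @param cycle_index integer cycle label.
#' @param n_tracks number of contributing tracks.
#' @return a `pulse_segment`.
#' @export
pulse_segment <- function(rel_times, mean_intensity,
                          sd_intensity = rep(0, length(rel_times)),
                          neb_rel = max(rel_times), cycle_index = 1L,
                          n_tracks = 1L) {
  if (rel_times[1] != 0) stop_validation("rel_times must start at 0 (CS origin)")
  if (any(sd_intensity < 0)) stop_validation("sd_intensity must be >= 0")
  stopifnot(length(rel_times) == length(mean_intensity))
  structure(list(cycle_index = as.integer(cycle_index), rel_times = rel_times,
                 mean_intensity = mean_intensity, sd_intensity = sd_intensity,
                 n_tracks = as.integer(n_tracks), neb_rel = neb_rel),
            class = "pulse_segment")
}

#' Normalise pulse segments so each channel peaks at 1
#'
#' Within each channel (fluorescent tag), divides all segments by the global
#' maximum of the mean signal, so the highest mean value per channel becomes 1
#' while relative scaling across cycles is preserved. Channels are normalised
#' independently. Idempotent, and invariant to multiplying a channel by any
#' positive constant.
#'
#' @param segments either a list of `pulse_segment`s (one channel) or a named
#'   list of such lists (one entry per channel).
#' @return same shape as the input, rescaled.
#' @export
normalize_and_scale <- function(segments) {
  one_channel <- function(segs) {
    mx <- max(unlist(lapply(segs, `[[`, "mean_intensity")))
    if (!is.finite(mx) || mx <= 0)
      stop_validation("channel has no positive mean intensity; cannot normalise")
    lapply(segs, function(s) {
      s$mean_intensity <- s$mean_intensity / mx
      s$sd_intensity <- s$sd_intensity / mx
      s
    })
  }
  if (length(segments) && inherits(segments[[1]], "pulse_segment"))
    one_channel(segments)
  else
    lapply(segments, one_channel)
}
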