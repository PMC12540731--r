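#' @importFrom rlang .data
NULL

TRACK_COLUMNS <- c("cell_id", "track_kind", "track_id", "frame_index",
                   "time_min", "x_um", "y_um", "sister", "centriole_count")
EVENT_COLUMNS <- c("cell_id", "t_nebd", "t_bipolarization",
                   "t_anaphase_onset")
INTENSITY_COLUMNS <- c("cell_id", "roi_id", "channel", "roi_kind",
                       "mean_signal", "background_mean", "reference_mean",
                       "n_z_planes", "location_class",
                       "dist_to_nearest_pole", "dist_to_plane")

# fixed 6-significant-digit numeric formatting so identical runs give
# byte-identical files
round_cols <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

#' Write tracks of a cohort to CSV
#'
#' Serializes pole and pair tracks of one or more cells into the long
#' track table schema: `cell_id`, `track_kind` (`pair`/`pole`),
#' `track_id`, `frame_index` (0-based), `time_min`, `x_um`, `y_um`,
#' `sister` (1/2 for pairs, empty for poles) and `centriole_count`
#' (poles only). Numeric values are written with 6 significant digits.
#'
#' @param cells A list of [cell_record()] objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(cells, path) {
  if (inherits(cells, "cell_record")) cells <- list(cells)
  rows <- lapply(cells, function(cell) {
    poles <- tibble::tibble(
      cell_id = cell$cell_id,
      track_kind = "pole",
      track_id = cell$pole_tracks$pole_id,
      frame_index = cell$pole_tracks$frame_index,
      time_min = cell$pole_tracks$time_min,
      x_um = cell$pole_tracks$x_um,
      y_um = cell$pole_tracks$y_um,
      sister = NA_integer_,
      centriole_count = cell$pole_tracks$centriole_count
    )
    pt <- cell$pair_tracks
    pairs <- dplyr::bind_rows(
      tibble::tibble(cell_id = cell$cell_id, track_kind = "pair",
                     track_id = pt$pair_id, frame_index = pt$frame_index,
                     time_min = pt$time_min, x_um = pt$x1_um,
                     y_um = pt$y1_um, sister = 1L,
                     centriole_count = NA_integer_),
      tibble::tibble(cell_id = cell$cell_id, track_kind = "pair",
                     track_id = pt$pair_id, frame_index = pt$frame_index,
                     time_min = pt$time_min, x_um = pt$x2_um,
                     y_um = pt$y2_um, sister = 2L,
                     centriole_count = NA_integer_)
    )
    dplyr::bind_rows(poles, pairs)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$cell_id,
                        .data$track_kind, .data$track_id, .data$sister,
                        .data$frame_index)
  readr::write_csv(round_cols(out), path, na = "")
  invisible(path)
}

stop_schema <- function(path, ...) {
  stop("schema error in '", path, "': ", ..., call. = FALSE)
}

#' Read a track table CSV
#'
#' Reads and validates the long track table written by [write_tracks()]:
#' required columns, 0-based frame indices, unique
#' `(cell_id, track_kind, track_id, frame_index, sister)` keys and a
#' strictly increasing, constantly spaced time base per track. Schema
#' violations are hard errors naming the offending rows.
#'
#' @param path CSV path.
#' @return A named list (one entry per cell) of partial records, each a
#'   list with `pole_tracks` and `pair_tracks` tibbles, pending event
#'   annotations (see [assemble_cells()]).
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(TRACK_COLUMNS, names(df))
  if (length(miss)) {
    stop_schema(path, "missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) stop_schema(path, "no data rows")
  if (!all(df$track_kind %in% c("pair", "pole"))) {
    stop_schema(path, "track_kind must be 'pair' or 'pole'")
  }
  if (any(is.na(df$frame_index)) || any(df$frame_index < 0) ||
      any(df$frame_index != floor(df$frame_index))) {
    stop_schema(path, "frame_index must be a non-negative integer")
  }
  if (min(df$frame_index) >= 1) {
    stop_schema(path, "frame indices start at ", min(df$frame_index),
                "; the track schema is 0-based (first frame has ",
                "frame_index 0)")
  }
  key <- paste(df$cell_id, df$track_kind, df$track_id, df$frame_index,
               df$sister, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop_schema(path, "duplicated (cell_id, track_kind, track_id, ",
                "frame_index, sister) keys at data row(s) ",
                paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(df$track_kind == "pair" & !(df$sister %in% c(1L, 2L)))) {
    stop_schema(path, "pair rows must have sister 1 or 2")
  }

  tid <- paste(df$cell_id, df$track_kind, df$track_id, df$sister,
               sep = "\r")
  for (g in split(seq_len(nrow(df)), tid)) {
    o <- g[order(df$frame_index[g])]
    tt <- df$time_min[o]
    if (length(tt) >= 2) {
      dtt <- diff(tt)
      if (any(dtt <= 0)) {
        stop_schema(path, "time_min not strictly increasing for track '",
                    df$track_id[o[1]], "' of cell '", df$cell_id[o[1]], "'")
      }
      step <- dtt / diff(df$frame_index[o])
      if (max(step) - min(step) > 1e-6 * max(step)) {
        stop_schema(path, "non-constant frame interval for track '",
                    df$track_id[o[1]], "' of cell '", df$cell_id[o[1]], "'")
      }
    }
  }

  lapply(split(df, df$cell_id), function(d) {
    poles <- d[d$track_kind == "pole", ]
    pole_tracks <- tibble::tibble(
      pole_id = poles$track_id,
      centriole_count = as.integer(poles$centriole_count),
      frame_index = as.integer(poles$frame_index),
      time_min = poles$time_min,
      x_um = poles$x_um, y_um = poles$y_um
    )
    pole_tracks <- dplyr::arrange(pole_tracks, .data$pole_id,
                                  .data$frame_index)
    pr <- d[d$track_kind == "pair", ]
    s1 <- pr[pr$sister == 1L, ]
    s2 <- pr[pr$sister == 2L, ]
    merged <- dplyr::full_join(
      tibble::tibble(pair_id = s1$track_id, frame_index = s1$frame_index,
                     time_min = s1$time_min, x1_um = s1$x_um,
                     y1_um = s1$y_um),
      tibble::tibble(pair_id = s2$track_id, frame_index = s2$frame_index,
                     time_min = s2$time_min, x2_um = s2$x_um,
                     y2_um = s2$y_um),
      by = c("pair_id", "frame_index", "time_min")
    )
    merged$frame_index <- as.integer(merged$frame_index)
    pair_tracks <- dplyr::arrange(merged, .data$pair_id, .data$frame_index)
    list(cell_id = d$cell_id[1], pole_tracks = pole_tracks,
         pair_tracks = pair_tracks)
  })
}

#' Write / read per-cell event annotations
#'
#' Events are supplied separately from tracks because they are manual
#' annotations: one row per cell with `cell_id`, `t_nebd`,
#' `t_bipolarization` and `t_anaphase_onset` (empty when the cell never
#' entered anaphase).
#'
#' @param cells List of [cell_record()] objects.
#' @param path CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_events <- function(cells, path) {
  if (inherits(cells, "cell_record")) cells <- list(cells)
  out <- dplyr::bind_rows(lapply(cells, function(cell) {
    tibble::tibble(cell_id = cell$cell_id,
                   t_nebd = cell$t_nebd,
                   t_bipolarization = cell$t_bipolarization,
                   t_anaphase_onset = cell$t_anaphase_onset)
  }))
  readr::write_csv(round_cols(out), path, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path,
                               call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(EVENT_COLUMNS, names(df))
  if (length(miss)) {
    stop_schema(path, "missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- !is.na(df$t_anaphase_onset) &
    !(df$t_nebd <= df$t_bipolarization &
        df$t_bipolarization <= df$t_anaphase_onset)
  if (any(bad)) {
    stop_schema(path, "event times must satisfy nebd <= bipolarization ",
                "<= anaphase for cell(s) ",
                paste(df$cell_id[bad], collapse = ", "))
  }
  df
}

#' Assemble full cell records from tracks and events
#'
#' @param tracks Output of [read_tracks()].
#' @param events Tibble from [read_events()].
#' @param condition_label Condition label applied to all cells (or a
#'   per-cell named vector).
#' @return List of [cell_record()] objects.
#' @export
assemble_cells <- function(tracks, events, condition_label = "unknown") {
  lapply(tracks, function(tr) {
    ev <- events[events$cell_id == tr$cell_id, ]
    if (nrow(ev) != 1) {
      stop("no (or duplicated) event annotation for cell ", tr$cell_id,
           call. = FALSE)
    }
    lab <- if (length(condition_label) > 1) condition_label[[tr$cell_id]]
    else condition_label
    cell_record(
      cell_id = tr$cell_id, condition_label = lab,
      pole_tracks = tr$pole_tracks, pair_tracks = tr$pair_tracks,
      t_nebd = ev$t_nebd, t_bipolarization = ev$t_bipolarization,
      t_anaphase_onset = ev$t_anaphase_onset
    )
  })
}

#' Write / read intensity sample tables
#'
#' @param samples Intensity sample tibble (schema of
#'   [simulate_intensities()]).
#' @param path CSV path.
#' @return `path` invisibly (write); a validated tibble (read).
#' @export
write_intensities <- function(samples, path) {
  readr::write_csv(round_cols(samples[INTENSITY_COLUMNS]), path, na = "")
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  if (!file.exists(path)) stop("intensity file not found: ", path,
                               call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(INTENSITY_COLUMNS, names(df))
  if (length(miss)) {
    stop_schema(path, "missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(df$mean_signal < 0 | df$background_mean < 0, na.rm = TRUE)) {
    stop_schema(path, "negative signal or background intensities")
  }
  if (any(df$n_z_planes < 1, na.rm = TRUE)) {
    stop_schema(path, "n_z_planes must be >= 1")
  }
  ok_kind <- df$roi_kind %in% c("kinetochore_pair", "pole")
  if (!all(ok_kind)) {
    stop_schema(path, "roi_kind must be 'kinetochore_pair' or 'pole'")
  }
  df
}

#' Write a simulated cohort to a directory
#'
#' Writes `tracks.csv`, `events.csv`, `intensities.csv` (when present),
#' `ground_truth.csv` and `manifest.json` for a cohort from
#' [simulate_experiment()].
#'
#' @param cohort A `spindle_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "spindle_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tracks(cohort$cells, file.path(dir, "tracks.csv"))
  write_events(cohort$cells, file.path(dir, "events.csv"))
  if (!is.null(cohort$intensities)) {
    write_intensities(cohort$intensities, file.path(dir, "intensities.csv"))
  }
  truth <- cohort$truth
  truth$t_initiation[is.infinite(truth$t_initiation)] <- NA_real_
  readr::write_csv(round_cols(truth), file.path(dir, "ground_truth.csv"),
                   na = "")
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
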