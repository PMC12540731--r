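#' Analysis configuration
#'
#' Bundles the thresholds used throughout track classification and
#' kinematics. Defaults are the operational definitions used for the live
#' and fixed-cell readouts: a kinetochore pair is aligned once either
#' sister lies within `aligned_dist_threshold` of the equatorial plane (or
#' the pair midpoint is at least as close to the spindle centre as to a
#' pole); an alignment event fires when the pair midpoint first comes
#' within `alignment_cross_threshold` of the plane; congression velocity
#' is the net midpoint displacement over the last `velocity_window`
#' minutes before that crossing; polar chromosomes are counted
#' `count_delay_after_bipolarization` minutes after spindle
#' bipolarization; kinetochore intensity samples within
#' `pole_exclusion_radius` of a pole are discarded.
#'
#' @param aligned_dist_threshold µm, default 3.
#' @param alignment_cross_threshold µm, default 2.
#' @param velocity_window minutes, default 6.
#' @param count_delay_after_bipolarization minutes, default 5.
#' @param pole_exclusion_radius µm, default 1.
#' @param min_velocity_window minutes, default 3; shorter pre-crossing
#'   coverage leaves the velocity undefined.
#' @param max_gap_frames_interpolated integer, default 2; missing-frame
#'   gaps up to this length are linearly interpolated per sister, longer
#'   gaps split the usable window.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(aligned_dist_threshold = 3,
                            alignment_cross_threshold = 2,
                            velocity_window = 6,
                            count_delay_after_bipolarization = 5,
                            pole_exclusion_radius = 1,
                            min_velocity_window = 3,
                            max_gap_frames_interpolated = 2L) {
  cfg <- list(
    aligned_dist_threshold = aligned_dist_threshold,
    alignment_cross_threshold = alignment_cross_threshold,
    velocity_window = velocity_window,
    count_delay_after_bipolarization = count_delay_after_bipolarization,
    pole_exclusion_radius = pole_exclusion_radius,
    min_velocity_window = min_velocity_window,
    max_gap_frames_interpolated = as.integer(max_gap_frames_interpolated)
  )
  num <- vapply(cfg[1:6], is.numeric, logical(1))
  pos <- setdiff(names(cfg)[1:6], "pole_exclusion_radius")
  if (!all(num) || any(unlist(cfg[pos]) <= 0) || pole_exclusion_radius < 0) {
    stop("analysis thresholds must be positive numbers (the pole ",
         "exclusion radius may be 0)", call. = FALSE)
  }
  if (alignment_cross_threshold > aligned_dist_threshold) {
    stop("alignment_cross_threshold must not exceed aligned_dist_threshold",
         call. = FALSE)
  }
  structure(cfg, class = "analysis_config")
}

#' Construct a cell record
#'
#' Container for all tracks of one mitotic cell plus its annotated event
#' times. Pole and pair tracks share one time base (constant frame
#' interval).
#'
#' @param cell_id Cell identifier.
#' @param condition_label Free-text condition (e.g. `"cenpe_inhibited"`).
#' @param pole_tracks Tibble with columns `pole_id`, `centriole_count`
#'   (0, 1 or 2, constant per pole), `frame_index`, `time_min`, `x_um`,
#'   `y_um`; exactly two pole ids.
#' @param pair_tracks Tibble with columns `pair_id`, `frame_index`,
#'   `time_min`, `x1_um`, `y1_um`, `x2_um`, `y2_um` (NA where a sister
#'   could not be tracked in a frame).
#' @param t_nebd,t_bipolarization Minutes; nuclear envelope breakdown and
#'   completion of spindle bipolarization.
#' @param t_anaphase_onset Minutes, or `NA` if the cell never entered
#'   anaphase within the imaging window.
#'
#' @return A list of class `cell_record`.
#' @export
cell_record <- function(cell_id, condition_label, pole_tracks, pair_tracks,
                        t_nebd, t_bipolarization, t_anaphase_onset = NA_real_) {
  pole_ids <- unique(pole_tracks$pole_id)
  if (length(pole_ids) != 2) {
    stop("cell ", cell_id, ": expected exactly 2 pole tracks, got ",
         length(pole_ids), call. = FALSE)
  }
  cc <- dplyr::distinct(pole_tracks, .data$pole_id, .data$centriole_count)
  if (nrow(cc) != 2 || !all(cc$centriole_count %in% 0:2)) {
    stop("cell ", cell_id,
         ": centriole_count must be constant per pole and in {0, 1, 2}",
         call. = FALSE)
  }
  if (!is.na(t_anaphase_onset) &&
      !(t_nebd <= t_bipolarization && t_bipolarization <= t_anaphase_onset)) {
    stop("cell ", cell_id,
         ": event times must satisfy nebd <= bipolarization <= anaphase",
         call. = FALSE)
  }
  structure(
    list(
      cell_id = cell_id,
      condition_label = condition_label,
      pole_tracks = pole_tracks,
      pair_tracks = pair_tracks,
      t_nebd = t_nebd,
      t_bipolarization = t_bipolarization,
      t_anaphase_onset = t_anaphase_onset
    ),
    class = "cell_record"
  )
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf(
    "<cell_record %s> %s | %d pairs, poles %s | nebd %.3g bipolar %.3g anaphase %s\n",
    x$cell_id, x$condition_label,
    length(unique(x$pair_tracks$pair_id)),
    paste(sprintf("%s(%d)", unique(x$pole_tracks$pole_id),
                  dplyr::distinct(x$pole_tracks, .data$pole_id,
                                  .data$centriole_count)$centriole_count),
          collapse = "/"),
    x$t_nebd, x$t_bipolarization,
    if (is.na(x$t_anaphase_onset)) "-" else format(x$t_anaphase_onset)
  ))
  invisible(x)
}

frame_interval <- function(cell) {
  t <- sort(unique(cell$pole_tracks$time_min))
  if (length(t) < 2) return(NA_real_)
  min(diff(t))
}

cell_time_span <- function(cell) {
  range(cell$pole_tracks$time_min)
}

# Linear interpolation of interior NA runs no longer than max_gap.
fill_gaps <- function(v, max_gap) {
  if (!anyNA(v) || all(is.na(v))) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- seq_along(v)
  known <- which(!is.na(v))
  for (k in which(r$values)) {
    if (r$lengths[k] > max_gap) next
    if (starts[k] == 1 || ends[k] == length(v)) next # edge gaps stay missing
    seg <- starts[k]:ends[k]
    v[seg] <- stats::approx(idx[known], v[known], xout = seg)$y
  }
  v
}

# Per-frame geometry table for one pair within a cell: joins pole and pair
# tracks on frame_index, interpolates short gaps, computes the spindle
# frame geometry. Rows where geometry cannot be computed keep NA.
pair_frame_table <- function(cell, pair_id,
                             cfg = analysis_config()) {
  poles <- cell$pole_tracks
  pole_ids <- sort(unique(poles$pole_id))
  pa <- poles[poles$pole_id == pole_ids[1], ]
  pb <- poles[poles$pole_id == pole_ids[2], ]
  pa <- pa[order(pa$frame_index), ]
  pb <- pb[order(pb$frame_index), ]

  tr <- cell$pair_tracks[cell$pair_tracks$pair_id == pair_id, ]
  if (nrow(tr) == 0) {
    stop("cell ", cell$cell_id, ": no track for pair ", pair_id,
         call. = FALSE)
  }
  tr <- tr[order(tr$frame_index), ]

  ib <- match(pa$frame_index, pb$frame_index)
  it <- match(pa$frame_index, tr$frame_index)
  mg <- cfg$max_gap_frames_interpolated
  s1x <- fill_gaps(tr$x1_um[it], mg)
  s1y <- fill_gaps(tr$y1_um[it], mg)
  s2x <- fill_gaps(tr$x2_um[it], mg)
  s2y <- fill_gaps(tr$y2_um[it], mg)

  g <- pair_geometry_frames(pa$x_um, pa$y_um, pb$x_um[ib],
                            pb$y_um[ib], s1x, s1y, s2x, s2y)
  g$nearest_pole_id <- ifelse(is.na(g$nearest_pole_id), NA_character_,
                              ifelse(g$nearest_pole_id == "A",
                                     pole_ids[1], pole_ids[2]))
  g$frame_index <- pa$frame_index
  g$time_min <- pa$time_min
  g$pair_id <- pair_id
  g
}

# Geometry of every pair of a cell at one frame time, vectorized across
# pairs. Pairs without a (non-interpolatable) position at that frame get
# NA geometry. Short gaps are interpolated from the surrounding
# max_gap + 1 frames of the pair track.
all_pairs_frame_geometry <- function(cell, t_used, cfg) {
  poles <- cell$pole_tracks
  pole_ids <- sort(unique(poles$pole_id))
  pa <- poles[poles$pole_id == pole_ids[1], ]
  pb <- poles[poles$pole_id == pole_ids[2], ]
  f <- pa$frame_index[which(abs(pa$time_min - t_used) < 1e-9)][1]

  tr <- cell$pair_tracks
  pair_ids <- unique(tr$pair_id)
  mg <- cfg$max_gap_frames_interpolated

  pick <- function(pid) {
    d <- tr[tr$pair_id == pid, ]
    i <- match(f, d$frame_index)
    row <- if (!is.na(i)) d[i, ] else NULL
    if (!is.null(row) && !anyNA(row[c("x1_um", "y1_um", "x2_um", "y2_um")])) {
      return(c(row$x1_um, row$y1_um, row$x2_um, row$y2_um))
    }
    # gap at the requested frame: interpolate within the allowed window
    w <- d[d$frame_index >= f - (mg + 1L) & d$frame_index <= f + (mg + 1L), ]
    if (nrow(w) < 2 || !any(w$frame_index < f) || !any(w$frame_index > f)) {
      return(rep(NA_real_, 4))
    }
    vapply(c("x1_um", "y1_um", "x2_um", "y2_um"), function(col) {
      v <- w[[col]]
      ok <- !is.na(v)
      if (sum(ok) < 2 || !any(w$frame_index[ok] < f) ||
          !any(w$frame_index[ok] > f)) return(NA_real_)
      lo <- max(w$frame_index[ok & w$frame_index < f])
      hi <- min(w$frame_index[ok & w$frame_index > f])
      if (hi - lo - 1L > mg) return(NA_real_)
      stats::approx(w$frame_index[ok], v[ok], xout = f)$y
    }, numeric(1))
  }

  pos <- vapply(pair_ids, pick, numeric(4))
  ia <- which(pa$frame_index == f)
  ib <- which(pb$frame_index == f)
  n <- length(pair_ids)
  g <- pair_geometry_frames(rep(pa$x_um[ia], n), rep(pa$y_um[ia], n),
                            rep(pb$x_um[ib], n), rep(pb$y_um[ib], n),
                            pos[1, ], pos[2, ], pos[3, ], pos[4, ])
  g$nearest_pole_id <- ifelse(is.na(g$nearest_pole_id), NA_character_,
                              ifelse(g$nearest_pole_id == "A",
                                     pole_ids[1], pole_ids[2]))
  g$pair_id <- pair_ids
  g$time_min <- t_used
  g
}

#' Classify kinetochore pairs as polar or aligned
#'
#' A pair is aligned if at least one sister lies within
#' `aligned_dist_threshold` (3 µm) of the equatorial plane, or if the pair
#' midpoint is at least as close to the spindle centre as to the nearest
#' pole; otherwise it is polar. The two aligned rules are combined as a
#' union, so each pair is exactly one of the two classes.
#'
#' @param geom A `pair_geometry` object or a geometry table (as produced
#'   internally per frame) with columns `sister_dist_plane_min`,
#'   `dist_pole_near`, `dist_center`.
#' @param cfg An [analysis_config()].
#' @return Character vector, `"polar"` or `"aligned"` (NA where the pair
#'   has no position in the frame).
#' @export
classify_pair <- function(geom, cfg = analysis_config()) {
  if (inherits(geom, "pair_geometry")) geom <- tibble::as_tibble(geom[
    c("sister_dist_plane_min", "dist_pole_near", "dist_center")])
  aligned <- geom$sister_dist_plane_min <= cfg$aligned_dist_threshold |
    geom$dist_pole_near >= geom$dist_center
  ifelse(is.na(aligned), NA_character_,
         ifelse(aligned, "aligned", "polar"))
}

#' Detect the alignment event of a kinetochore pair
#'
#' Alignment is the moment the pair midpoint first crosses within
#' `alignment_cross_threshold` (2 µm) of the equatorial plane. Pairs that
#' never cross within the track are censored, with the reason `"anaphase"`
#' when the cell entered anaphase and `"end_of_track"` otherwise.
#'
#' @param geom_tbl Per-frame geometry table for the pair (internal form;
#'   obtained from a [cell_record()] via [analyze_cell()]).
#' @param cfg An [analysis_config()].
#' @param t_anaphase_onset Minutes or NA, used only to label censoring.
#' @return A list with `t_alignment` (minutes or NA), `censored` (logical)
#'   and `censor_reason` (NA, `"anaphase"` or `"end_of_track"`).
#' @export
detect_alignment <- function(geom_tbl, cfg = analysis_config(),
                             t_anaphase_onset = NA_real_) {
  ok <- !is.na(geom_tbl$dist_plane)
  if (!any(ok)) {
    stop("pair track does not overlap the spindle frame series", call. = FALSE)
  }
  hit <- ok & geom_tbl$dist_plane <= cfg$alignment_cross_threshold
  if (any(hit)) {
    list(t_alignment = geom_tbl$time_min[which(hit)[1]],
         censored = FALSE, censor_reason = NA_character_)
  } else {
    list(t_alignment = NA_real_, censored = TRUE,
         censor_reason = if (!is.na(t_anaphase_onset)) "anaphase"
         else "end_of_track")
  }
}

#' Congression velocity of a pair
#'
#' Net displacement of the pair midpoint over the last `velocity_window`
#' (6) minutes before the alignment crossing, divided by the window. If
#' the tracked coverage before the crossing is shorter than the window but
#' at least `min_velocity_window` (3) minutes, the available window is
#' used and flagged; shorter coverage leaves the velocity undefined.
#'
#' @inheritParams detect_alignment
#' @param t_alignment Minutes, from [detect_alignment()].
#' @return A list with `velocity` (µm/min or NA), `window_used` (minutes)
#'   and `partial_window` (logical).
#' @export
congression_velocity <- function(geom_tbl, t_alignment,
                                 cfg = analysis_config()) {
  if (is.na(t_alignment)) {
    return(list(velocity = NA_real_, window_used = NA_real_,
                partial_window = FALSE))
  }
  ok <- !is.na(geom_tbl$mx)
  tt <- geom_tbl$time_min
  i_end <- which(ok & abs(tt - t_alignment) < 1e-9)
  if (length(i_end) == 0) {
    return(list(velocity = NA_real_, window_used = NA_real_,
                partial_window = FALSE))
  }
  i_end <- i_end[1]
  t0_target <- t_alignment - cfg$velocity_window
  cand <- which(ok & tt >= t0_target - 1e-9 & tt < t_alignment)
  # contiguity: use the earliest valid frame of the run ending at i_end
  if (length(cand) == 0) {
    return(list(velocity = NA_real_, window_used = NA_real_,
                partial_window = FALSE))
  }
  i0 <- min(cand)
  window_used <- t_alignment - tt[i0]
  if (window_used < cfg$min_velocity_window - 1e-9) {
    return(list(velocity = NA_real_, window_used = window_used,
                partial_window = TRUE))
  }
  disp <- sqrt((geom_tbl$mx[i_end] - geom_tbl$mx[i0])^2 +
                 (geom_tbl$my[i_end] - geom_tbl$my[i0])^2)
  list(velocity = disp / window_used,
       window_used = window_used,
       partial_window = window_used < cfg$velocity_window - 1e-9)
}

#' Residence time of a polar chromosome at the spindle pole
#'
#' Time from spindle bipolarization until the pair aligned, or until
#' anaphase onset (censored) for pairs that never aligned; when the cell
#' never entered anaphase the last tracked time is used and the value is
#' censored.
#'
#' @param t_bipolarization Minutes.
#' @param t_alignment Minutes or NA.
#' @param t_anaphase_onset Minutes or NA.
#' @param t_end Minutes, end of the track (fallback censoring time).
#' @return List with `time` (minutes, >= 0) and `censored`.
#' @export
residence_time <- function(t_bipolarization, t_alignment = NA_real_,
                           t_anaphase_onset = NA_real_, t_end = NA_real_) {
  if (!is.na(t_alignment)) {
    rt <- t_alignment - t_bipolarization
    if (rt < 0) {
      warning("alignment precedes bipolarization; residence time clamped to 0")
      rt <- 0
    }
    return(list(time = rt, censored = FALSE))
  }
  stop_t <- if (!is.na(t_anaphase_onset)) t_anaphase_onset else t_end
  if (is.na(stop_t)) {
    stop("censored residence time needs an anaphase or end-of-track time",
         call. = FALSE)
  }
  list(time = max(0, stop_t - t_bipolarization), censored = TRUE)
}

#' Number of polar chromosomes at a given time
#'
#' Classifies every tracked pair at the frame nearest to `t` and counts
#' the polar ones, in total and split by nearest pole (the per-pole counts
#' support readouts that compare centriolar and acentriolar poles of the
#' same spindle). Pairs with no usable position at that frame are not
#' counted.
#'
#' @param cell A [cell_record()].
#' @param t Minutes; must lie within the imaged span.
#' @param cfg An [analysis_config()].
#' @return List with `t_used` (the frame time), `n_polar`, `per_pole`
#'   (tibble `pole_id`, `centriole_count`, `n_polar`) and `n_unclassified`.
#' @export
polar_count <- function(cell, t, cfg = analysis_config()) {
  span <- cell_time_span(cell)
  if (t < span[1] - 1e-9 || t > span[2] + 1e-9) {
    stop("cell ", cell$cell_id, ": time ", t,
         " is outside the imaged span [", span[1], ", ", span[2], "]",
         call. = FALSE)
  }
  times <- sort(unique(cell$pole_tracks$time_min))
  t_used <- times[which.min(abs(times - t))]

  g <- all_pairs_frame_geometry(cell, t_used, cfg)
  cls <- classify_pair(g, cfg)
  polar <- !is.na(cls) & cls == "polar"

  cc <- dplyr::distinct(cell$pole_tracks, .data$pole_id,
                        .data$centriole_count)
  per_pole <- dplyr::count(
    tibble::tibble(pole_id = g$nearest_pole_id[polar]),
    .data$pole_id, name = "n_polar"
  )
  per_pole <- dplyr::left_join(cc, per_pole, by = "pole_id")
  per_pole$n_polar[is.na(per_pole$n_polar)] <- 0L

  list(t_used = t_used, n_polar = sum(polar), per_pole = per_pole,
       n_unclassified = sum(is.na(cls)))
}

#' Duration of mitosis
#'
#' Time from nuclear envelope breakdown to one frame before the onset of
#' anaphase. Cells that never entered anaphase are censored at the last
#' imaged frame.
#'
#' @param cell A [cell_record()].
#' @return List with `duration` (minutes) and `censored`.
#' @export
mitosis_duration <- function(cell) {
  dt <- frame_interval(cell)
  if (is.na(cell$t_anaphase_onset)) {
    list(duration = cell_time_span(cell)[2] - cell$t_nebd, censored = TRUE)
  } else {
    list(duration = (cell$t_anaphase_onset - dt) - cell$t_nebd,
         censored = FALSE)
  }
}

#' Per-pair congression analysis of one cell
#'
#' Runs classification, alignment detection, residence time and velocity
#' for every pair of a cell. The reference classification time is
#' `t_bipolarization + count_delay_after_bipolarization`.
#'
#' @param cell A [cell_record()].
#' @param cfg An [analysis_config()].
#' @return A tibble with one row per pair: `cell_id`, `pair_id`,
#'   `classification` (at the reference time), `t_alignment`, `censored`,
#'   `censor_reason`, `residence_time`, `residence_censored`,
#'   `congression_velocity`, `velocity_window_used`, `partial_window`,
#'   `initial_dist_pole` (distance to the nearest centrosome at the first
#'   tracked frame), `nearest_pole_id` (at the first tracked frame),
#'   `t_first_tracked` and `mean_interkinetochore_distance`.
#' @export
analyze_cell <- function(cell, cfg = analysis_config()) {
  t_ref <- cell$t_bipolarization + cfg$count_delay_after_bipolarization
  span <- cell_time_span(cell)
  t_ref <- min(max(t_ref, span[1]), span[2])
  t_end <- span[2]

  pair_ids <- unique(cell$pair_tracks$pair_id)
  rows <- lapply(pair_ids, function(pid) {
    g <- pair_frame_table(cell, pid, cfg)
    ok <- !is.na(g$dist_plane)
    first <- which(ok)[1]
    ev <- detect_alignment(g, cfg, cell$t_anaphase_onset)
    vel <- congression_velocity(g, ev$t_alignment, cfg)
    # residence is defined from bipolarization: pairs already at the plate
    # then have residence 0, not a negative value
    t_al_res <- if (!is.na(ev$t_alignment)) {
      max(ev$t_alignment, cell$t_bipolarization)
    } else {
      NA_real_
    }
    res <- residence_time(cell$t_bipolarization, t_al_res,
                          cell$t_anaphase_onset, t_end)
    i_ref <- which(ok & abs(g$time_min - t_ref) < 1e-9)
    cls_ref <- if (length(i_ref)) classify_pair(g[i_ref[1], ], cfg)
    else NA_character_
    cls_first <- classify_pair(g[first, ], cfg)
    list(
      cell_id = cell$cell_id,
      pair_id = pid,
      classification = cls_ref,
      initial_classification = cls_first,
      t_alignment = ev$t_alignment,
      censored = ev$censored,
      censor_reason = ev$censor_reason,
      residence_time = res$time,
      residence_censored = res$censored,
      congression_velocity = vel$velocity,
      velocity_window_used = vel$window_used,
      partial_window = vel$partial_window,
      initial_dist_pole = g$dist_pole_near[first],
      nearest_pole_id = g$nearest_pole_id[first],
      t_first_tracked = g$time_min[first],
      mean_interkinetochore_distance =
        mean(g$interkinetochore_distance, na.rm = TRUE)
    )
  })
  col <- function(f, mode) vapply(rows, `[[`, mode, f)
  tibble::new_tibble(list(
    cell_id = col("cell_id", character(1)),
    pair_id = col("pair_id", character(1)),
    classification = col("classification", character(1)),
    initial_classification = col("initial_classification", character(1)),
    t_alignment = col("t_alignment", numeric(1)),
    censored = col("censored", logical(1)),
    censor_reason = col("censor_reason", character(1)),
    residence_time = col("residence_time", numeric(1)),
    residence_censored = col("residence_censored", logical(1)),
    congression_velocity = col("congression_velocity", numeric(1)),
    velocity_window_used = col("velocity_window_used", numeric(1)),
    partial_window = col("partial_window", logical(1)),
    initial_dist_pole = col("initial_dist_pole", numeric(1)),
    nearest_pole_id = col("nearest_pole_id", character(1)),
    t_first_tracked = col("t_first_tracked", numeric(1)),
    mean_interkinetochore_distance =
      col("mean_interkinetochore_distance", numeric(1))
  ), nrow = length(rows))
}

#' Congression analysis of a cohort of cells
#'
#' @param cells List of [cell_record()] objects.
#' @param cfg An [analysis_config()].
#' @return List with `pairs` (row-bound [analyze_cell()] tables) and
#'   `cells` (per-cell tibble: polar counts at the reference time, per
#'   pole and total, and mitosis duration).
#' @export
analyze_cohort <- function(cells, cfg = analysis_config()) {
  pairs <- dplyr::bind_rows(lapply(cells, analyze_cell, cfg = cfg))
  per_cell <- dplyr::bind_rows(lapply(cells, function(cell) {
    t_ref <- cell$t_bipolarization + cfg$count_delay_after_bipolarization
    span <- cell_time_span(cell)
    t_ref <- min(max(t_ref, span[1]), span[2])
    pc <- polar_count(cell, t_ref, cfg)
    md <- mitosis_duration(cell)
    tibble::tibble(
      cell_id = cell$cell_id,
      condition_label = cell$condition_label,
      t_count = pc$t_used,
      n_polar = pc$n_polar,
      n_polar_pole_1 = pc$per_pole$n_polar[1],
      n_polar_pole_2 = pc$per_pole$n_polar[2],
      pole_id_1 = pc$per_pole$pole_id[1],
      pole_id_2 = pc$per_pole$pole_id[2],
      centrioles_pole_1 = pc$per_pole$centriole_count[1],
      centrioles_pole_2 = pc$per_pole$centriole_count[2],
      mitosis_duration = md$duration,
      mitosis_censored = md$censored
    )
  }))
  list(pairs = pairs, cells = per_cell)
}

#' Congression-initiation likelihood versus distance from the centrosome
#'
#' For every pair of a cohort, tabulates the initial distance to the
#' nearest centrosome (at the first tracked frame) against the duration of
#' congression (time from the first tracked frame to the alignment
#' crossing), a proxy for the likelihood of initiation. An OLS fit of
#' duration on distance is returned; censored pairs appear in the table
#' but are excluded from the fit.
#'
#' Only pairs that were polar at their first tracked frame enter the
#' analysis: congression duration is not meaningful for pairs that were
#' already at the plate.
#'
#' @param cells List of [cell_record()] objects.
#' @param cfg An [analysis_config()].
#' @return List with `table` (tibble: `cell_id`, `pair_id`,
#'   `initial_dist_pole`, `duration`, `censored`) and `fit` (an
#'   [ols_slope_test()] result, or NULL when every pair is censored).
#' @export
initiation_vs_distance <- function(cells, cfg = analysis_config()) {
  pairs <- dplyr::bind_rows(lapply(cells, analyze_cell, cfg = cfg))
  pairs <- pairs[!is.na(pairs$initial_classification) &
                   pairs$initial_classification == "polar", ]
  tab <- tibble::tibble(
    cell_id = pairs$cell_id,
    pair_id = pairs$pair_id,
    initial_dist_pole = pairs$initial_dist_pole,
    duration = pairs$t_alignment - pairs$t_first_tracked,
    censored = pairs$censored
  )
  unc <- tab[!tab$censored & !is.na(tab$duration), ]
  if (nrow(unc) == 0) {
    return(list(table = tab, fit = NULL))
  }
  if (nrow(unc) == 1) {
    stop("fit unavailable: a single uncensored pair cannot constrain a slope",
         call. = FALSE)
  }
  fit <- ols_slope_test(unc$initial_dist_pole, unc$duration)
  list(table = tab, fit = fit)
}
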