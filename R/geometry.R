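#' Build the spindle coordinate frame for one time frame
#'
#' The spindle frame is defined by the two pole positions: the spindle axis
#' is the unit vector from pole A to pole B, and the equatorial (metaphase)
#' plane is the line through the midpoint of the pole-to-pole segment,
#' perpendicular to that axis. All downstream distances (to the plane, to
#' the nearest pole, to the spindle centre) are measured in this frame.
#'
#' @param pole_a,pole_b Numeric length-2 vectors, pole positions in µm.
#' @param frame_index Integer frame index (0-based), carried through for
#'   error messages and joins.
#'
#' @return An object of class `spindle_frame`: a list with elements
#'   `frame_index`, `pole_a`, `pole_b`, `midpoint`, `axis_unit` (unit
#'   vector from `pole_a` to `pole_b`) and `spindle_length` (µm).
#'
#' @details Coincident poles leave the axis, and hence the equatorial
#'   plane, undefined; this is reported as an error naming the frame.
#'
#' @examples
#' fr <- spindle_frame(c(0, 0), c(6, 8), frame_index = 0)
#' fr$midpoint       # (3, 4)
#' fr$spindle_length # 10
#' @export
spindle_frame <- function(pole_a, pole_b, frame_index = 0L) {
  pole_a <- as_point2(pole_a, "pole_a")
  pole_b <- as_point2(pole_b, "pole_b")
  d <- pole_b - pole_a
  len <- sqrt(sum(d^2))
  if (len == 0) {
    stop("degenerate spindle frame at frame_index ", frame_index,
         ": poles coincide, the spindle axis is undefined", call. = FALSE)
  }
  structure(
    list(
      frame_index = as.integer(frame_index),
      pole_a = pole_a,
      pole_b = pole_b,
      midpoint = (pole_a + pole_b) / 2,
      axis_unit = d / len,
      spindle_length = len
    ),
    class = "spindle_frame"
  )
}

#' @export
print.spindle_frame <- function(x, ...) {
  cat(sprintf(
    "<spindle_frame #%d>  poles (%.3g, %.3g)--(%.3g, %.3g)  length %.4g um\n",
    x$frame_index, x$pole_a[1], x$pole_a[2], x$pole_b[1], x$pole_b[2],
    x$spindle_length
  ))
  invisible(x)
}

as_point2 <- function(p, what) {
  p <- as.numeric(p)
  if (length(p) != 2 || anyNA(p)) {
    stop(what, " must be a length-2 numeric point without NA", call. = FALSE)
  }
  p
}

#' Per-frame geometry of a sister kinetochore pair in the spindle frame
#'
#' Computes the distances and the angle used by the polar/aligned
#' classification and the kinematic metrics: the pair midpoint's distance
#' to the equatorial plane, to the nearest pole and to the spindle centre,
#' the per-sister minimum distance to the plane, the interkinetochore
#' distance, and the angle at the nearest pole between the pole-to-pole
#' axis and the pole-to-pair line.
#'
#' @param frame A [spindle_frame()].
#' @param sister1,sister2 Numeric length-2 sister kinetochore positions (µm).
#'
#' @return A list of class `pair_geometry` with elements `midpoint`,
#'   `dist_plane`, `dist_pole_near`, `dist_center`, `sister_dist_plane_min`,
#'   `interkinetochore_distance`, `angle_to_axis` (degrees in \[0, 180\])
#'   and `nearest_pole_id` (`"A"` or `"B"`; exact ties resolve to `"A"`).
#'
#' @details Distance to the plane is the absolute projection of the
#'   midpoint offset onto the spindle axis,
#'   `|(m - frame$midpoint) . axis_unit|`; because the plane passes through
#'   the spindle midpoint this never exceeds the Euclidean distance to the
#'   midpoint itself.
#' @export
pair_geometry <- function(frame, sister1, sister2) {
  stopifnot(inherits(frame, "spindle_frame"))
  s1 <- as_point2(sister1, "sister1")
  s2 <- as_point2(sister2, "sister2")
  m <- (s1 + s2) / 2

  off <- m - frame$midpoint
  dist_plane <- abs(sum(off * frame$axis_unit))
  dist_center <- sqrt(sum(off^2))

  da <- sqrt(sum((m - frame$pole_a)^2))
  db <- sqrt(sum((m - frame$pole_b)^2))
  # ties resolve toward pole A (lexicographically smaller id)
  nearest <- if (da <= db) "A" else "B"
  near_pole <- if (nearest == "A") frame$pole_a else frame$pole_b
  far_pole <- if (nearest == "A") frame$pole_b else frame$pole_a
  dist_pole_near <- min(da, db)

  sd1 <- abs(sum((s1 - frame$midpoint) * frame$axis_unit))
  sd2 <- abs(sum((s2 - frame$midpoint) * frame$axis_unit))

  u <- far_pole - near_pole
  v <- m - near_pole
  nv <- sqrt(sum(v^2))
  angle <- if (nv == 0) {
    0 # pair midpoint on the pole: angle undefined, reported as 0
  } else {
    cosang <- sum(u * v) / (sqrt(sum(u^2)) * nv)
    acos(min(1, max(-1, cosang))) * 180 / pi
  }

  structure(
    list(
      midpoint = m,
      dist_plane = dist_plane,
      dist_pole_near = dist_pole_near,
      dist_center = dist_center,
      sister_dist_plane_min = min(sd1, sd2),
      interkinetochore_distance = sqrt(sum((s1 - s2)^2)),
      angle_to_axis = angle,
      nearest_pole_id = nearest
    ),
    class = "pair_geometry"
  )
}

# Vectorized geometry for a whole track against per-frame pole positions.
# All inputs are equal-length numeric vectors (one element per frame);
# returns a tibble with one row per frame. NA sister positions propagate.
pair_geometry_frames <- function(ax, ay, bx, by, s1x, s1y, s2x, s2y) {
  dx <- bx - ax
  dy <- by - ay
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0, na.rm = TRUE)) {
    bad <- which(len == 0)[1]
    stop("degenerate spindle frame (coincident poles) at row ", bad,
         call. = FALSE)
  }
  ux <- dx / len
  uy <- dy / len
  cx <- (ax + bx) / 2
  cy <- (ay + by) / 2

  mx <- (s1x + s2x) / 2
  my <- (s1y + s2y) / 2

  dist_plane <- abs((mx - cx) * ux + (my - cy) * uy)
  dist_center <- sqrt((mx - cx)^2 + (my - cy)^2)
  da <- sqrt((mx - ax)^2 + (my - ay)^2)
  db <- sqrt((mx - bx)^2 + (my - by)^2)
  dist_pole_near <- pmin(da, db)
  nearest_pole <- ifelse(da <= db, "A", "B")

  sd1 <- abs((s1x - cx) * ux + (s1y - cy) * uy)
  sd2 <- abs((s2x - cx) * ux + (s2y - cy) * uy)

  npx <- ifelse(nearest_pole == "A", ax, bx)
  npy <- ifelse(nearest_pole == "A", ay, by)
  fpx <- ifelse(nearest_pole == "A", bx, ax)
  fpy <- ifelse(nearest_pole == "A", by, ay)
  vx <- mx - npx
  vy <- my - npy
  wx <- fpx - npx
  wy <- fpy - npy
  nv <- sqrt(vx^2 + vy^2)
  cosang <- (vx * wx + vy * wy) / (nv * sqrt(wx^2 + wy^2))
  angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  angle[!is.na(nv) & nv == 0] <- 0

  tibble::new_tibble(list(
    mx = mx, my = my,
    dist_plane = dist_plane,
    dist_pole_near = dist_pole_near,
    dist_center = dist_center,
    sister_dist_plane_min = pmin(sd1, sd2),
    interkinetochore_distance = sqrt((s1x - s2x)^2 + (s1y - s2y)^2),
    angle_to_axis = angle,
    nearest_pole_id = nearest_pole,
    spindle_length = len
  ), nrow = length(mx))
}
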