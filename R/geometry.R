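#' @keywords internal
as_point <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 2L) p <- c(p, 0)
  if (length(p) != 3L || any(!is.finite(p)))
    stop("a point must be 2 or 3 finite coordinates (um)", call. = FALSE)
  p
}

#' Midpoint of a sister-kinetochore pair
#'
#' The pair center is the arithmetic midpoint of the two sister positions.
#' All per-pair kinematics (distance to the equatorial plane, distance to
#' the nearest pole, positional angle) are computed on this center.
#'
#' @param p1,p2 Numeric vectors of length 2 or 3, positions in um. A length-2
#'   vector is treated as a projected-2D point with z = 0.
#' @return Numeric length-3 position in um.
#' @export
#' @examples
#' pair_center(c(0, 0, 0), c(2, 0, 0))
pair_center <- function(p1, p2) {
  (as_point(p1) + as_point(p2)) / 2
}

#' Interkinetochore distance
#'
#' Euclidean distance between the two sister-kinetochore centers, the
#' standard proxy for attachment tension: laterally attached pairs sit near
#' their rest distance and biorientation stretches them.
#'
#' @inheritParams pair_center
#' @return Distance in um.
#' @export
interkinetochore_distance <- function(p1, p2) {
  sqrt(sum((as_point(p1) - as_point(p2))^2))
}

#' Reconstruct the spindle reference frame from pole trajectories
#'
#' For each frame where both poles are available (after filling short
#' tracking gaps by linear interpolation) the spindle frame is the pole
#' midpoint `m`, the unit pole-to-pole axis `u` and the pole separation `L`.
#' The equatorial (metaphase) plane is the plane through `m` perpendicular
#' to `u`; in projected-2D data it degenerates to the perpendicular line
#' through `m`, with the same formula.
#'
#' Frames where the poles come closer than `eps_pole` are kept in the table
#' but marked undefined rather than yielding a near-degenerate axis.
#'
#' @param pole_a,pole_b Data frames with columns `frame`, `t_min`, `x_um`,
#'   `y_um` and optionally `z_um` (missing z is read as 0). Frames must be
#'   strictly increasing; missing frames are gaps.
#' @param eps_pole Minimum pole separation (um) below which the frame is
#'   undefined. Default 1 um.
#' @param max_gap Longest run of missing frames (per pole) filled by linear
#'   interpolation; longer gaps stay undefined. Default 2.
#' @return A tibble with one row per frame of the joint support: pole
#'   positions (`pax`..`pbz`), midpoint (`mx`,`my`,`mz`), unit axis
#'   (`ux`,`uy`,`uz`), separation `L` and a logical `defined`.
#' @export
spindle_frames <- function(pole_a, pole_b, eps_pole = 1, max_gap = 2) {
  a <- fill_trajectory_gaps(pole_a, max_gap = max_gap)
  b <- fill_trajectory_gaps(pole_b, max_gap = max_gap)
  common <- intersect(a$frame[a$defined], b$frame[b$defined])
  if (length(common) == 0L)
    stop("pole trajectories share no defined frames", call. = FALSE)
  a <- a[match(common, a$frame), ]
  b <- b[match(common, b$frame), ]
  dx <- b$x_um - a$x_um; dy <- b$y_um - a$y_um; dz <- b$z_um - a$z_um
  L <- sqrt(dx^2 + dy^2 + dz^2)
  ok <- L > eps_pole
  if (!any(ok))
    stop("degenerate spindle: pole separation <= eps_pole on every frame",
         call. = FALSE)
  ux <- ifelse(ok, dx / L, NA_real_)
  uy <- ifelse(ok, dy / L, NA_real_)
  uz <- ifelse(ok, dz / L, NA_real_)
  tibble::tibble(
    frame = a$frame, t_min = a$t_min,
    pax = a$x_um, pay = a$y_um, paz = a$z_um,
    pbx = b$x_um, pby = b$y_um, pbz = b$z_um,
    mx = (a$x_um + b$x_um) / 2, my = (a$y_um + b$y_um) / 2,
    mz = (a$z_um + b$z_um) / 2,
    ux = ux, uy = uy, uz = uz, L = L, defined = ok)
}

#' @keywords internal
frame_row <- function(frames, frame) {
  i <- match(frame, frames$frame)
  if (is.na(i) || !frames$defined[i])
    stop("spindle frame undefined at frame ", frame, call. = FALSE)
  frames[i, ]
}

#' Distance from a point to the equatorial plane
#'
#' The nearest distance from a position to the plane through the spindle
#' midpoint perpendicular to the pole-to-pole axis: `|(p - m) . u|`.
#'
#' @param p Position (um), length 2 or 3.
#' @param frame A single-row spindle frame (a row of [spindle_frames()]
#'   output, or the full table plus `at` giving the frame index).
#' @param at Optional frame index to pick from a multi-row `frame` table.
#' @return Distance in um (non-negative).
#' @export
plane_distance <- function(p, frame, at = NULL) {
  fr <- if (!is.null(at)) frame_row(frame, at) else check_one_frame(frame)
  p <- as_point(p)
  abs((p[1] - fr$mx) * fr$ux + (p[2] - fr$my) * fr$uy + (p[3] - fr$mz) * fr$uz)
}

#' @keywords internal
check_one_frame <- function(frame) {
  if (nrow(frame) != 1L) stop("expected a single spindle frame", call. = FALSE)
  if (!isTRUE(frame$defined))
    stop("spindle frame undefined", call. = FALSE)
  frame
}

#' Distance to the nearest spindle pole
#'
#' Distance from a position to the closer of the two poles. An exact tie is
#' resolved to pole A so the result is deterministic.
#'
#' @inheritParams plane_distance
#' @return A list with `distance` (um) and `pole` (`"A"` or `"B"`).
#' @export
nearest_pole_distance <- function(p, frame, at = NULL) {
  fr <- if (!is.null(at)) frame_row(frame, at) else check_one_frame(frame)
  p <- as_point(p)
  da <- sqrt((p[1] - fr$pax)^2 + (p[2] - fr$pay)^2 + (p[3] - fr$paz)^2)
  db <- sqrt((p[1] - fr$pbx)^2 + (p[2] - fr$pby)^2 + (p[3] - fr$pbz)^2)
  if (da <= db) list(distance = da, pole = "A") else list(distance = db, pole = "B")
}

#' @keywords internal
acute_angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  ct <- abs(sum(v1 * v2)) / (n1 * n2)
  acos(min(1, max(0, ct))) * 180 / pi
}

#' Positional angle of a kinetochore pair
#'
#' Acute angle between the pole-to-pole axis and the line joining the pair
#' center to its nearest spindle pole. Both are treated as lines, so the
#' angle lies in \[0, 90\] degrees.
#'
#' @param p Pair-center position (um).
#' @inheritParams plane_distance
#' @return Angle in degrees.
#' @export
positional_angle <- function(p, frame, at = NULL) {
  fr <- if (!is.null(at)) frame_row(frame, at) else check_one_frame(frame)
  p <- as_point(p)
  np <- nearest_pole_distance(p, fr)
  pole <- if (np$pole == "A") c(fr$pax, fr$pay, fr$paz) else c(fr$pbx, fr$pby, fr$pbz)
  v <- p - pole
  if (sqrt(sum(v^2)) < 1e-12)
    stop("pair center coincides with its nearest pole: angle undefined",
         call. = FALSE)
  acute_angle_deg(v, c(fr$ux, fr$uy, fr$uz))
}

#' Orientation angle of the sister-kinetochore axis
#'
#' Acute angle between the sister-to-sister axis and the spindle axis.
#' Bioriented pairs reorient this axis toward the spindle axis (angle near
#' 0); laterally attached polar pairs sit at larger angles.
#'
#' @inheritParams pair_center
#' @inheritParams plane_distance
#' @return Angle in degrees in \[0, 90\].
#' @export
pair_orientation_angle <- function(p1, p2, frame, at = NULL) {
  fr <- if (!is.null(at)) frame_row(frame, at) else check_one_frame(frame)
  v <- as_point(p2) - as_point(p1)
  if (sqrt(sum(v^2)) < 1e-12)
    stop("coincident sisters: orientation angle undefined", call. = FALSE)
  acute_angle_deg(v, c(fr$ux, fr$uy, fr$uz))
}

#' Fill short gaps in a trajectory by linear interpolation
#'
#' Tracking is routinely interrupted by neighbouring kinetochores, so
#' missing frames are first-class. Runs of up to `max_gap` missing frames
#' are filled by linear interpolation on the frame index; longer runs are
#' kept as rows flagged undefined.
#'
#' @param traj Data frame with `frame`, `t_min`, `x_um`, `y_um` and optional
#'   `z_um`.
#' @param max_gap Longest interpolated run (frames). Default 2.
#' @return The trajectory over the full frame range with a logical
#'   `defined` column; interpolated frames are defined, long-gap frames are
#'   not (their coordinates are NA).
#' @export
fill_trajectory_gaps <- function(traj, max_gap = 2) {
  traj <- as.data.frame(traj)
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  if (is.null(traj$z_um)) traj$z_um <- 0
  if (any(duplicated(traj$frame)) || is.unsorted(traj$frame, strictly = TRUE))
    stop("trajectory frames must be strictly increasing", call. = FALSE)
  fr <- seq(min(traj$frame), max(traj$frame))
  have <- fr %in% traj$frame
  if (all(have)) {     # gap-free: nothing to interpolate
    return(tibble::new_tibble(
      list(frame = fr, t_min = traj$t_min, x_um = traj$x_um,
           y_um = traj$y_um, z_um = traj$z_um,
           defined = rep(TRUE, length(fr))), nrow = length(fr)))
  }
  out <- list(frame = fr)
  for (col in c("t_min", "x_um", "y_um", "z_um")) {
    out[[col]] <- if (nrow(traj) == 1L) traj[[col]] else
      stats::approx(traj$frame, traj[[col]], xout = fr)$y
  }
  defined <- have
  if (!all(have)) {
    r <- rle(have)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (!r$values[k] && r$lengths[k] <= max_gap)
        defined[starts[k]:ends[k]] <- TRUE
    }
  }
  for (col in c("t_min", "x_um", "y_um", "z_um"))
    out[[col]][!defined] <- NA_real_
  out$defined <- defined
  tibble::new_tibble(out, nrow = length(fr))
}

#' Per-frame kinematics of one sister-kinetochore pair
#'
#' Joins the two sister trajectories (after gap filling) with the spindle
#' frame series and computes, per frame: pair center, distance to the
#' equatorial plane, distance to and identity of the nearest pole,
#' interkinetochore distance, positional angle and sister-axis orientation
#' angle.
#'
#' @param sister1,sister2 Sister trajectories (see [fill_trajectory_gaps()]
#'   for the expected columns).
#' @param frames Spindle frame series from [spindle_frames()].
#' @param max_gap Gap-filling policy shared by both sisters.
#' @return A tibble with one row per frame where both sisters and the
#'   spindle frame are defined: `frame`, `t_min`, `cx`,`cy`,`cz`, `d_plane`,
#'   `d_pole`, `nearest_pole`, `d_kt`, `theta_pos`, `theta_orient` (um,
#'   minutes, degrees).
#' @export
pair_kinematics <- function(sister1, sister2, frames, max_gap = 2) {
  s1 <- fill_trajectory_gaps(sister1, max_gap = max_gap)
  s2 <- fill_trajectory_gaps(sister2, max_gap = max_gap)
  common <- Reduce(intersect, list(s1$frame[s1$defined], s2$frame[s2$defined],
                                   frames$frame[frames$defined]))
  if (length(common) == 0L)
    stop("pair and spindle frames share no defined frames", call. = FALSE)
  i1 <- match(common, s1$frame); i2 <- match(common, s2$frame)
  s1 <- lapply(s1[c("x_um", "y_um", "z_um")], `[`, i1)
  s2 <- lapply(s2[c("x_um", "y_um", "z_um")], `[`, i2)
  fi <- match(common, frames$frame)
  fr <- lapply(frames[c("t_min", "pax", "pay", "paz", "pbx", "pby", "pbz",
                        "mx", "my", "mz", "ux", "uy", "uz")], `[`, fi)
  cx <- (s1$x_um + s2$x_um) / 2
  cy <- (s1$y_um + s2$y_um) / 2
  cz <- (s1$z_um + s2$z_um) / 2
  d_plane <- abs((cx - fr$mx) * fr$ux + (cy - fr$my) * fr$uy +
                 (cz - fr$mz) * fr$uz)
  da <- sqrt((cx - fr$pax)^2 + (cy - fr$pay)^2 + (cz - fr$paz)^2)
  db <- sqrt((cx - fr$pbx)^2 + (cy - fr$pby)^2 + (cz - fr$pbz)^2)
  nearest <- ifelse(da <= db, "A", "B")
  d_pole <- pmin(da, db)
  dkx <- s2$x_um - s1$x_um; dky <- s2$y_um - s1$y_um; dkz <- s2$z_um - s1$z_um
  d_kt <- sqrt(dkx^2 + dky^2 + dkz^2)
  # vector from nearest pole to center
  vx <- ifelse(nearest == "A", cx - fr$pax, cx - fr$pbx)
  vy <- ifelse(nearest == "A", cy - fr$pay, cy - fr$pby)
  vz <- ifelse(nearest == "A", cz - fr$paz, cz - fr$pbz)
  vn <- sqrt(vx^2 + vy^2 + vz^2)
  dotp <- abs(vx * fr$ux + vy * fr$uy + vz * fr$uz)
  theta_pos <- ifelse(vn < 1e-12, NA_real_,
                      acos(pmin(1, pmax(0, dotp / vn))) * 180 / pi)
  kn <- d_kt
  dotk <- abs(dkx * fr$ux + dky * fr$uy + dkz * fr$uz)
  theta_orient <- ifelse(kn < 1e-12, NA_real_,
                         acos(pmin(1, pmax(0, dotk / kn))) * 180 / pi)
  tibble::new_tibble(
    list(frame = common, t_min = fr$t_min,
         cx = cx, cy = cy, cz = cz,
         d_plane = d_plane, d_pole = d_pole, nearest_pole = nearest,
         d_kt = d_kt, theta_pos = theta_pos, theta_orient = theta_orient),
    nrow = length(common))
}
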