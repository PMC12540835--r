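#' Thresholds for alignment classification and congression events
#'
#' Bundles the decision thresholds used throughout the event module. The
#' defaults are the values used for RPE-1 cells: a pair is ever-aligned if
#' it comes within 3 um of the equatorial plane, a plate crossing is the
#' first time the pair center passes below 2 um, congression velocity is
#' measured over the last 6 min before that crossing (4 min is the usual
#' choice for U2OS, see `u2os_thresholds()`), alignment success is scored
#' over a 30-min window, and polar pairs are counted from 12 min after
#' mitosis onset and every 6 min thereafter.
#'
#' @param d_align_ever um; ever-aligned rule (inclusive boundary).
#' @param d_success um; plate-crossing rule (strict boundary).
#' @param success_window minutes; window for scoring alignment success.
#' @param velocity_window minutes; window before the crossing over which
#'   congression velocity is computed.
#' @param count_start,count_step minutes; polar-count schedule.
#' @param min_dwell minutes; optional persistence required below
#'   `d_success` for a crossing to count (0 = first touch counts).
#' @param plate_fraction fraction of pairs within `d_align_ever` of the
#'   plane for the metaphase plate to count as formed.
#' @return A list of class `congression_thresholds`.
#' @export
congression_thresholds <- function(d_align_ever = 3, d_success = 2,
                                   success_window = 30, velocity_window = 6,
                                   count_start = 12, count_step = 6,
                                   min_dwell = 0, plate_fraction = 0.75) {
  vals <- c(d_align_ever = d_align_ever, d_success = d_success,
            success_window = success_window,
            velocity_window = velocity_window,
            count_start = count_start, count_step = count_step)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be finite and strictly positive", call. = FALSE)
  if (d_success > d_align_ever)
    stop("d_success must not exceed d_align_ever", call. = FALSE)
  structure(list(d_align_ever = d_align_ever, d_success = d_success,
                 success_window = success_window,
                 velocity_window = velocity_window,
                 count_start = count_start, count_step = count_step,
                 min_dwell = min_dwell, plate_fraction = plate_fraction),
            class = "congression_thresholds")
}

#' @rdname congression_thresholds
#' @export
u2os_thresholds <- function() congression_thresholds(velocity_window = 4)

#' @keywords internal
kin_at_time <- function(kin, t, dt = NULL) {
  # nearest defined kinematics row within one nominal frame interval of t
  if (is.null(dt)) dt <- nominal_dt(kin)
  i <- which.min(abs(kin$t_min - t))
  if (length(i) == 0L || abs(kin$t_min[i] - t) > dt + 1e-9) return(NULL)
  list(t_min = kin$t_min[i], d_plane = kin$d_plane[i],
       d_pole = kin$d_pole[i])
}

#' @keywords internal
nominal_dt <- function(kin) {
  if (nrow(kin) < 2L) return(Inf)
  stats::median(diff(kin$t_min))
}

#' Is a pair polar at a given frame?
#'
#' A kinetochore pair is polar when its center is strictly closer to one of
#' the spindle poles than to the equatorial plane. Equidistant pairs are
#' not polar.
#'
#' @param kin Pair kinematics from [pair_kinematics()].
#' @param frame Frame index at which to classify.
#' @return Logical.
#' @export
is_polar <- function(kin, frame) {
  i <- match(frame, kin$frame)
  if (is.na(i)) stop("kinematics undefined at frame ", frame, call. = FALSE)
  kin$d_pole[i] < kin$d_plane[i]
}

#' Was a pair ever aligned?
#'
#' True when the pair center came within `d_align_ever` (default 3 um,
#' inclusive) of the equatorial plane at any defined frame.
#'
#' @inheritParams is_polar
#' @param thresholds A [congression_thresholds()] object.
#' @return Logical.
#' @export
is_aligned_ever <- function(kin, thresholds = congression_thresholds()) {
  if (nrow(kin) == 0L) stop("empty kinematics", call. = FALSE)
  min(kin$d_plane, na.rm = TRUE) <= thresholds$d_align_ever
}

#' Detect the metaphase-plate crossing of a pair
#'
#' The crossing time is the first defined frame at which the distance of
#' the pair center to the equatorial plane drops strictly below
#' `d_success` (default 2 um). With `min_dwell > 0` the pair must stay
#' below the threshold for that long for the crossing to count.
#'
#' @inheritParams is_aligned_ever
#' @return Crossing time in minutes, or `NA` if the pair never crosses.
#' @export
detect_plate_crossing <- function(kin, thresholds = congression_thresholds()) {
  if (nrow(kin) == 0L) stop("empty kinematics", call. = FALSE)
  below <- which(kin$d_plane < thresholds$d_success)
  if (thresholds$min_dwell > 0) {
    keep <- vapply(below, function(i) {
      upto <- kin$t_min <= kin$t_min[i] + thresholds$min_dwell &
        kin$t_min >= kin$t_min[i]
      all(kin$d_plane[upto] < thresholds$d_success)
    }, logical(1))
    below <- below[keep]
  }
  if (length(below) == 0L) return(NA_real_)
  kin$t_min[below[1]]
}

#' Congression velocity of a pair
#'
#' Signed velocity of approach to the metaphase plate over the last
#' `velocity_window` minutes (default 6) before the plate crossing:
#' `(d_plane(t_cross - w) - d_plane(t_cross)) / w`. Positive values are
#' movement toward the plate, negative values movement away from it. When
#' the track starts less than a full window before the crossing, the
#' velocity is computed over the available span provided at least half the
#' window is covered; the span actually used is returned as `window_used`.
#'
#' @inheritParams is_aligned_ever
#' @param t_cross Crossing time from [detect_plate_crossing()].
#' @return List with `velocity` (um/min) and `window_used` (minutes).
#' @export
congression_velocity <- function(kin, t_cross,
                                 thresholds = congression_thresholds()) {
  if (is.na(t_cross)) stop("t_cross is undefined", call. = FALSE)
  w <- thresholds$velocity_window
  ic <- which(abs(kin$t_min - t_cross) < 1e-9)
  if (length(ic) != 1L)
    stop("no kinematics row at the crossing time", call. = FALSE)
  in_win <- which(kin$t_min >= t_cross - w - 1e-9 & kin$t_min < t_cross)
  if (length(in_win) == 0L)
    stop("no defined frames in the velocity window before the crossing",
         call. = FALSE)
  i0 <- in_win[1]
  w_eff <- t_cross - kin$t_min[i0]
  if (w_eff < w / 2)
    stop("velocity window coverage ", w_eff, " min is less than half of ",
         w, " min", call. = FALSE)
  list(velocity = (kin$d_plane[i0] - kin$d_plane[ic]) / w_eff,
       window_used = w_eff)
}

#' Mean speed of approach to the plate over an interval
#'
#' `(d_plane(t0) - d_plane(t0 + duration)) / duration`, evaluated at the
#' nearest defined frames within one nominal frame interval of each
#' endpoint. Same sign convention as [congression_velocity()].
#'
#' @inheritParams is_aligned_ever
#' @param t0 Interval start (minutes).
#' @param duration Interval length (minutes).
#' @return Speed in um/min.
#' @export
mean_speed_over_interval <- function(kin, t0, duration) {
  dt <- nominal_dt(kin)
  a <- kin_at_time(kin, t0, dt)
  b <- kin_at_time(kin, t0 + duration, dt)
  if (is.null(a) || is.null(b))
    stop("no defined frames near the interval endpoints", call. = FALSE)
  (a$d_plane - b$d_plane) / duration
}

#' Fraction of initially polar pairs that align within a window
#'
#' A pair counts as initially polar if it is polar at the reference time
#' `t_ref` (nearest defined frame within one frame interval). Alignment is
#' successful if the pair center comes within `d_success` of the
#' equatorial plane at any frame in `(t_ref, t_ref + success_window]`;
#' pairs lost before the window ends without crossing count as failures.
#'
#' @param kin_list List of pair kinematics tibbles (one per pair).
#' @inheritParams is_aligned_ever
#' @param t_ref Reference time (minutes): recording start, drug washout or
#'   spindle elongation, depending on the assay. Default 0.
#' @return Percentage in \[0, 100\].
#' @export
alignment_success_fraction <- function(kin_list,
                                       thresholds = congression_thresholds(),
                                       t_ref = 0) {
  polar0 <- vapply(kin_list, function(kin) {
    row <- kin_at_time(kin, t_ref)
    !is.null(row) && row$d_pole < row$d_plane
  }, logical(1))
  if (!any(polar0))
    stop("no pairs are polar at the reference time", call. = FALSE)
  w <- thresholds$success_window
  success <- vapply(kin_list[polar0], function(kin) {
    sel <- kin$t_min > t_ref & kin$t_min <= t_ref + w
    any(kin$d_plane[sel] <= thresholds$d_success)
  }, logical(1))
  100 * mean(success)
}

#' Number of polar pairs over time
#'
#' Counts pairs classified polar at `count_start` minutes (default 12)
#' after mitosis onset and every `count_step` minutes (default 6)
#' thereafter, up to `t_end`. Pairs without a defined frame near a time
#' point do not contribute to its count.
#'
#' @inheritParams alignment_success_fraction
#' @param t_end Last time point (minutes), e.g. anaphase onset.
#' @return Tibble with `t_min` and `n_polar`.
#' @export
polar_counts_timeline <- function(kin_list,
                                  thresholds = congression_thresholds(),
                                  t_end) {
  times <- seq(thresholds$count_start, t_end, by = thresholds$count_step)
  if (length(times) == 0L) return(tibble::tibble(t_min = numeric(),
                                                 n_polar = integer()))
  counts <- vapply(times, function(tt) {
    sum(vapply(kin_list, function(kin) {
      row <- kin_at_time(kin, tt)
      !is.null(row) && row$d_pole < row$d_plane
    }, logical(1)))
  }, integer(1))
  tibble::tibble(t_min = times, n_polar = counts)
}

#' Misalignment category of a cell at one frame
#'
#' The metaphase plate counts as formed when at least `plate_fraction` of
#' the pairs lie within `d_align_ever` of the equatorial plane. Given a
#' formed plate, the cell is classified by the number of pairs outside it:
#' none -> `"tight"`, one to four -> `"low"`, five or more -> `"high"`.
#' Without a formed plate the category is `"no_plate"`.
#'
#' @param d_plane Distances of all pair centers to the equatorial plane at
#'   one frame (um).
#' @inheritParams is_aligned_ever
#' @return One of `"tight"`, `"low"`, `"high"`, `"no_plate"`.
#' @export
misalignment_category <- function(d_plane,
                                  thresholds = congression_thresholds()) {
  d_plane <- d_plane[!is.na(d_plane)]
  if (length(d_plane) == 0L)
    stop("no pairs defined at this frame", call. = FALSE)
  outside <- sum(d_plane > thresholds$d_align_ever)
  if ((length(d_plane) - outside) / length(d_plane) < thresholds$plate_fraction)
    return("no_plate")
  if (outside == 0) "tight" else if (outside < 5) "low" else "high"
}

#' Maximum chromosome spread
#'
#' Largest pairwise distance between the centers of any two kinetochore
#' pairs in a cell at one frame.
#'
#' @param centers Numeric matrix of pair centers, one row per pair, 2 or 3
#'   columns (um).
#' @return Distance in um.
#' @export
max_chromosome_spread <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2L)
    stop("at least two pair centers are required", call. = FALSE)
  max(stats::dist(centers))
}

#' Re-index a kinematics series around an event
#'
#' Shifts the time axis so the event maps to 0 and keeps samples in
#' `[-pre, post]`, e.g. to average distance-to-plate trajectories around
#' the moment of successful alignment.
#'
#' @inheritParams is_aligned_ever
#' @param event_time Event time (minutes); must be defined.
#' @param pre,post Minutes kept before and after the event.
#' @return The kinematics tibble with a `t_rel` column, truncated.
#' @export
register_to_event <- function(kin, event_time, pre, post) {
  if (is.na(event_time)) stop("event time is undefined", call. = FALSE)
  out <- kin
  out$t_rel <- out$t_min - event_time
  out[out$t_rel >= -pre - 1e-9 & out$t_rel <= post + 1e-9, ]
}

#' Per-pair congression event table
#'
#' Applies the classification and event rules to every pair of a cell and
#' returns one row per pair: initial polar status, ever-aligned flag,
#' plate-crossing time, windowed congression velocity and 30-min success.
#'
#' @inheritParams alignment_success_fraction
#' @param pair_ids Identifiers, one per element of `kin_list`.
#' @return Tibble with columns `pair_id`, `polar_initial`, `aligned_ever`,
#'   `t_cross_min`, `v_congress_um_per_min`, `window_used_min`,
#'   `success_30min`.
#' @export
pair_event_table <- function(kin_list, pair_ids = seq_along(kin_list),
                             thresholds = congression_thresholds(),
                             t_ref = 0) {
  rows <- lapply(seq_along(kin_list), function(i) {
    kin <- kin_list[[i]]
    row0 <- kin_at_time(kin, t_ref)
    polar0 <- !is.null(row0) && row0$d_pole < row0$d_plane
    t_cross <- detect_plate_crossing(kin, thresholds)
    v <- NA_real_; w <- NA_real_
    if (!is.na(t_cross)) {
      cv <- tryCatch(congression_velocity(kin, t_cross, thresholds),
                     error = function(e) NULL)
      if (!is.null(cv)) { v <- cv$velocity; w <- cv$window_used }
    }
    sel <- kin$t_min > t_ref & kin$t_min <= t_ref + thresholds$success_window
    tibble::tibble(pair_id = pair_ids[i],
                   polar_initial = polar0,
                   aligned_ever = is_aligned_ever(kin, thresholds),
                   t_cross_min = t_cross,
                   v_congress_um_per_min = v,
                   window_used_min = w,
                   success_30min = any(kin$d_plane[sel] <= thresholds$d_success))
  })
  do.call(rbind, rows)
}
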