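#' Construct a tracked three-point time series
#'
#' A `track_series` holds, per video frame, the coordinates of the three
#' labelled leaf points used to quantify the sealing movement: point 1 near
#' the leaf base, point 2 close to the injury (the hinge), and point 3 at the
#' leaf tip.  Frame 0 is the pre-injury reference image.
#'
#' @param time_s numeric vector of frame times in seconds, strictly
#'   increasing, first frame the pre-injury reference.
#' @param p1,p2,p3 two-column matrices (or data frames) of x,y coordinates,
#'   one row per frame.
#' @param units `"mm"` or `"px"`; purely descriptive (all angle computations
#'   are scale invariant).
#' @param convention `"y-up"` for mathematical axes or `"y-down"` for image
#'   coordinates.  Image-convention series are mirrored on ingestion by
#'   [track_angles()] so that wound closure keeps a positive sign.
#' @param leaf_id,condition optional labels carried through to outputs.
#' @return a data frame of class `track_series` with columns
#'   `time_s, x1, y1, x2, y2, x3, y3`.
#' @export
#' @examples
#' ts <- track_series(c(0, 30), p1 = rbind(c(-1, 0), c(-1, 0)),
#'                    p2 = rbind(c(0, 0), c(0, 0)),
#'                    p3 = rbind(c(1, 0), c(1, 0.2)))
#' track_angles(ts)
track_series <- function(time_s, p1, p2, p3, units = c("mm", "px"),
                         convention = c("y-up", "y-down"),
                         leaf_id = NA_character_, condition = NA_character_) {
  units <- match.arg(units)
  convention <- match.arg(convention)
  p1 <- as.matrix(p1); p2 <- as.matrix(p2); p3 <- as.matrix(p3)
  n <- length(time_s)
  if (!all(c(nrow(p1), nrow(p2), nrow(p3)) == n) ||
      !all(c(ncol(p1), ncol(p2), ncol(p3)) == 2L))
    stopf("p1, p2, p3 must each be n x 2 with n = length(time_s)")
  check_finite(time_s, "time_s")
  check_finite(c(p1, p2, p3), "coordinates")
  if (n > 1 && any(diff(time_s) <= 0))
    stopf("frame times must be strictly increasing")
  same12 <- rowSums((p1 - p2)^2) == 0
  same32 <- rowSums((p3 - p2)^2) == 0
  if (any(same12 | same32))
    stopf("degenerate geometry: point coincides with hinge point 2 in frame(s) %s",
          paste(which(same12 | same32) - 1L, collapse = ", "))
  out <- fast_df(time_s = unname(time_s),
                 x1 = unname(p1[, 1]), y1 = unname(p1[, 2]),
                 x2 = unname(p2[, 1]), y2 = unname(p2[, 2]),
                 x3 = unname(p3[, 1]), y3 = unname(p3[, 2]))
  structure(out, units = units, convention = convention,
            leaf_id = leaf_id, condition = condition,
            class = c("track_series", "data.frame"))
}

#' Base and tip line angles of a single frame
#'
#' With the hinge (point 2) taken as the coordinate origin, `alpha` is the
#' orientation of the straight line through points 2 and 1 relative to the
#' horizontal, and `beta` the orientation of the line through points 2 and 3.
#' Lines are undirected, so both angles are reported on (-90, 90] degrees.
#'
#' @param p1,p2,p3 numeric length-2 vectors, the x,y coordinates of the base,
#'   hinge and tip point of one frame.
#' @return named numeric vector `c(alpha = , beta = )`, degrees.
#' @export
#' @examples
#' frame_angles(c(-1, 0), c(0, 0), c(cos(pi / 18), sin(pi / 18)))  # beta = 10
frame_angles <- function(p1, p2, p3) {
  check_finite(c(p1, p2, p3), "coordinates")
  if (all(p1 == p2) || all(p3 == p2))
    stopf("degenerate geometry: a tracked point coincides with hinge point 2")
  a <- wrap_line_angle(atan2(p1[2] - p2[2], p1[1] - p2[1]) * 180 / pi)
  b <- wrap_line_angle(atan2(p3[2] - p2[2], p3[1] - p2[1]) * 180 / pi)
  c(alpha = a, beta = b)
}

#' Actual bending angle
#'
#' The angle between tip line and base line, `delta = beta - alpha`, wrapped
#' onto (-90, 90].  Subtracting the base angle removes rigid motion of the
#' leaf base, so `delta` captures the actual closing movement and is invariant
#' under rigid motion of the whole configuration (for bending below 90
#' degrees).
#'
#' @param alpha,beta line angles in degrees from the same frame.
#' @return `delta` in degrees on (-90, 90].
#' @export
actual_bending <- function(alpha, beta) {
  check_finite(alpha, "alpha"); check_finite(beta, "beta")
  wrap_line_angle(beta - alpha)
}

#' Relative bending angle series
#'
#' Subtracts the pre-injury bending angle: `gamma_n = delta_n - delta_0`.
#' `gamma` is exactly zero in the reference frame; positive values mean the
#' lesion is closing, negative values that it is opening.
#'
#' @param delta numeric vector of actual bending angles (degrees), first
#'   element the pre-injury frame.
#' @return numeric vector of `gamma` values, same length.
#' @export
relative_bending <- function(delta) {
  check_finite(delta, "delta")
  if (length(delta) < 1L)
    stopf("missing pre-injury reference frame: 'delta' is empty")
  gamma <- delta - delta[1]
  gamma[1] <- 0
  gamma
}

#' Full angle series of a tracked leaf
#'
#' Computes `alpha`, `beta`, `delta` and `gamma` for every frame of a
#' [track_series()].  Image-convention (`y-down`) input is mirrored to the
#' mathematical frame first.  A continuity check rejects series whose bending
#' angle jumps by 90 degrees or more between consecutive frames, since line
#' angles are only defined modulo 180 degrees.
#'
#' @param track a [track_series()].
#' @param flip_sign logical; negate `delta` and `gamma` (for wounds on the
#'   other leaf flank, where closure would otherwise score negative).
#' @return data frame of class `angle_series` with columns `frame`, `time_s`,
#'   `alpha_deg`, `beta_deg`, `delta_deg`, `gamma_deg`.
#' @export
track_angles <- function(track, flip_sign = FALSE) {
  if (!inherits(track, "track_series"))
    stopf("'track' must be a track_series")
  y1 <- track$y1; y2 <- track$y2; y3 <- track$y3
  if (identical(attr(track, "convention"), "y-down")) {
    y1 <- -y1; y2 <- -y2; y3 <- -y3
  }
  alpha <- wrap_line_angle(atan2(y1 - y2, track$x1 - track$x2) * 180 / pi)
  beta  <- wrap_line_angle(atan2(y3 - y2, track$x3 - track$x2) * 180 / pi)
  delta <- wrap_line_angle(beta - alpha)
  if (length(delta) > 1 && any(abs(diff(delta)) >= 90))
    stopf("bending angle jumps by >= 90 degrees between frames %s; line-angle wrapping is ambiguous",
          paste(which(abs(diff(delta)) >= 90)[1] - 1L, "->",
                which(abs(diff(delta)) >= 90)[1]))
  if (flip_sign) delta <- -delta
  gamma <- relative_bending(delta)
  out <- fast_df(frame = seq_along(delta) - 1L, time_s = track$time_s,
                 alpha_deg = alpha, beta_deg = beta,
                 delta_deg = delta, gamma_deg = gamma)
  structure(out, leaf_id = attr(track, "leaf_id"),
            condition = attr(track, "condition"),
            class = c("angle_series", "data.frame"))
}

#' Sample the relative bending angle at evaluation times
#'
#' Returns the nearest-frame `gamma` at each requested time (minutes); when a
#' requested time falls exactly midway between two frames the earlier frame is
#' used.  The chosen frame and its true time are reported alongside so the
#' mapping onto the frame grid stays auditable.
#'
#' @param angles an `angle_series` from [track_angles()].
#' @param times_min numeric vector of evaluation times in minutes
#'   (default `c(1, 5, 10, 20, 40, 55)`).
#' @return data frame with columns `requested_min`, `frame`, `frame_time_s`,
#'   `gamma_deg`.
#' @export
sample_at_times <- function(angles, times_min = c(1, 5, 10, 20, 40, 55)) {
  if (!inherits(angles, "angle_series"))
    stopf("'angles' must be an angle_series")
  check_finite(times_min, "times_min")
  ft <- angles$time_s
  half <- if (length(ft) > 1) stats::median(diff(ft)) / 2 else 0
  idx <- vapply(times_min * 60, function(t) {
    d <- abs(ft - t)
    if (min(d) > half + 1e-9)
      stopf("requested time %.3g min is outside series coverage (nearest frame %.3g s away)",
            t / 60, min(d))
    # nearest frame, ties toward the earlier frame
    order(round(d, 9), ft)[1]
  }, integer(1))
  fast_df(requested_min = times_min,
          frame = angles$frame[idx],
          frame_time_s = ft[idx],
          gamma_deg = angles$gamma_deg[idx])
}
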