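# Per-frame eye/mouth geometry and windowed blink/yawn frequencies.
#
# Landmark conventions: the eye is 6 points with p1/p6 the corners and
# (p2,p3), (p4,p5) the vertical lid pairs; the mouth is 8 points with M1/M5
# the corners and (M2,M8), (M3,M7), (M4,M6) the vertical lip pairs, M3/M7
# being the mid-lip pair.

#' Eye calibration constants
#'
#' @param a_max Maximum canthus (corner-to-corner) distance in pixels.
#' @param b_max Maximum eyelid-pair distance in pixels.
#' @param baseline_open Fully-open lid distance used by the per-frame
#'   closure rule (defaults to `b_max`).
#' @return A list of class `"eye_calibration"`.
#' @export
eye_calibration <- function(a_max, b_max, baseline_open = b_max) {
  check_scalar_number(a_max, "a_max", positive = TRUE)
  check_scalar_number(b_max, "b_max", positive = TRUE)
  check_scalar_number(baseline_open, "baseline_open", positive = TRUE)
  structure(list(a_max = a_max, b_max = b_max, baseline_open = baseline_open),
            class = "eye_calibration")
}

#' Calibrate eye geometry from a landmark stream
#'
#' Takes the observed maxima of the canthus and mean lid distances as the
#' fully-open reference values.
#'
#' @param landmarks Landmark data frame (see [read_landmarks()]).
#' @return An [eye_calibration()].
#' @export
calibrate_eyes <- function(landmarks) {
  g <- eye_geometry(landmarks)
  eye_calibration(a_max = max(g$width), b_max = max(g$lid))
}

# vectorized eye distances from a landmark data frame
eye_geometry <- function(df) {
  width <- sqrt((df$eye_p6_x - df$eye_p1_x)^2 + (df$eye_p6_y - df$eye_p1_y)^2)
  d23 <- sqrt((df$eye_p2_x - df$eye_p3_x)^2 + (df$eye_p2_y - df$eye_p3_y)^2)
  d45 <- sqrt((df$eye_p4_x - df$eye_p5_x)^2 + (df$eye_p4_y - df$eye_p5_y)^2)
  list(width = width, d23 = d23, d45 = d45, lid = (d23 + d45) / 2)
}

#' Eye aspect vector
#'
#' The two vertical lid-pair distances normalized by the canthus distance:
#' `(||p5 - p4|| / ||p6 - p1||, ||p2 - p3|| / ||p6 - p1||)`.
#'
#' @param eye_pts 6 x 2 matrix of eye landmarks in canonical order.
#' @return Numeric length-2 vector.
#' @examples
#' pts <- rbind(c(0, 0), c(1, 1), c(1, -1), c(3, 1), c(3, -1), c(4, 0))
#' eav(pts)  # c(0.5, 0.5)
#' @export
eav <- function(eye_pts) {
  p <- as_point_matrix(eye_pts, 6L, "eye_pts")
  w <- vnorm(p[6, ] - p[1, ])
  if (w <= 0) stop_invalid("degenerate eye geometry: coincident eye corners")
  c(vnorm(p[5, ] - p[4, ]) / w, vnorm(p[2, ] - p[3, ]) / w)
}

# perpendicular distance of point q to the infinite line through a and b
perp_dist <- function(q, a, b) {
  ab <- b - a
  abs(ab[1] * (q[2] - a[2]) - ab[2] * (q[1] - a[1])) / vnorm(ab)
}

opening_angle <- function(q, a, b, what) {
  if (vnorm(b - a) <= 0)
    stop_invalid("degenerate ", what, " geometry: coincident corners")
  h <- vnorm(q - a)
  if (h <= 0)
    stop_invalid("degenerate ", what, " geometry: lid/lip point coincides with corner")
  asin(min(1, perp_dist(q, a, b) / h))
}

#' Eye opening angle
#'
#' `arcsin(d / h)` where `d` is the perpendicular distance of the upper-lid
#' point `p2` to the corner line p1-p6 and `h = ||p2 - p1||`. Always in
#' `[0, pi/2]`.
#'
#' @inheritParams eav
#' @param lid_point Index of the lid landmark used (default 2).
#' @return Angle in radians.
#' @export
eoa <- function(eye_pts, lid_point = 2L) {
  p <- as_point_matrix(eye_pts, 6L, "eye_pts")
  opening_angle(p[lid_point, ], p[1, ], p[6, ], "eye")
}

#' Eye closure area ratio
#'
#' Ratio of the instantaneous fitted-ellipse axis product to the calibrated
#' maximum: `a' b' / (a_max b_max)`, where `a'` is the current canthus
#' distance and `b'` the current mean lid-pair distance (the ellipse
#' constant pi cancels).
#'
#' @inheritParams eav
#' @param calib An [eye_calibration()].
#' @return Dimensionless ratio (>= 0, ~1 when fully open).
#' @export
s_ar <- function(eye_pts, calib) {
  if (!inherits(calib, "eye_calibration"))
    stop_invalid("`calib` must be created by eye_calibration()")
  p <- as_point_matrix(eye_pts, 6L, "eye_pts")
  a_cur <- vnorm(p[6, ] - p[1, ])
  b_cur <- (vnorm(p[2, ] - p[3, ]) + vnorm(p[4, ] - p[5, ])) / 2
  (a_cur * b_cur) / (calib$a_max * calib$b_max)
}

#' Mouth aspect vector
#'
#' The three vertical lip-pair distances normalized by the mouth-corner
#' distance: `(||M4 - M6||, ||M3 - M7||, ||M2 - M8||) / ||M5 - M1||`.
#'
#' @param mouth_pts 8 x 2 matrix of mouth landmarks in canonical order.
#' @return Numeric length-3 vector; the middle component is the mid-lip pair.
#' @export
mav <- function(mouth_pts) {
  m <- as_point_matrix(mouth_pts, 8L, "mouth_pts")
  w <- vnorm(m[5, ] - m[1, ])
  if (w <= 0) stop_invalid("degenerate mouth geometry: coincident mouth corners")
  c(vnorm(m[4, ] - m[6, ]), vnorm(m[3, ] - m[7, ]), vnorm(m[2, ] - m[8, ])) / w
}

#' Mouth opening angle
#'
#' Defined analogously to [eoa()]: arcsin of the perpendicular distance of
#' the mid-upper-lip point `M3` to the corner line M1-M5 over `||M3 - M1||`.
#'
#' @inheritParams mav
#' @return Angle in radians, in `[0, pi/2]`.
#' @export
moa <- function(mouth_pts) {
  m <- as_point_matrix(mouth_pts, 8L, "mouth_pts")
  opening_angle(m[3, ], m[1, ], m[5, ], "mouth")
}

#' Mouth opening area proxy
#'
#' The product of absolute coordinate differences
#' `|x_M8 - x_M1| * |y_M7 - y_M3|` (pixels squared).
#'
#' @inheritParams mav
#' @return Non-negative area proxy.
#' @export
s_mp <- function(mouth_pts) {
  m <- as_point_matrix(mouth_pts, 8L, "mouth_pts")
  unname(abs(m[8, 1] - m[1, 1]) * abs(m[7, 2] - m[3, 2]))
}

#' Per-frame eye closure rule
#'
#' An eye counts as closed when the mean lid-pair distance falls below a
#' fraction of the calibrated fully-open distance (default 20%, the P80
#' convention from the PERCLOS literature).
#'
#' @param lid Current mean lid-pair distance(s), pixels (vectorized).
#' @param calib An [eye_calibration()] with positive `baseline_open`.
#' @param threshold Closure fraction of `baseline_open` (default 0.2).
#' @return Logical vector.
#' @export
is_eye_closed <- function(lid, calib, threshold = 0.2) {
  if (!inherits(calib, "eye_calibration"))
    stop_invalid("`calib` must be created by eye_calibration()")
  check_prob(threshold, "threshold")
  if (!is.numeric(lid) || any(!is.finite(lid)))
    stop_invalid("`lid` must be finite numeric")
  lid < threshold * calib$baseline_open
}

#' Blink frequency over a window
#'
#' Fraction of closed-eye frames: the number of frames with closed eyes
#' divided by the total number of frames in the window.
#'
#' @param closed_flags Logical vector of per-frame closure flags (length >= 1).
#' @return Fraction in \[0, 1\].
#' @examples
#' blink_frequency(c(TRUE, FALSE, TRUE, FALSE, FALSE))
#' @export
blink_frequency <- function(closed_flags) {
  if (length(closed_flags) < 1L) stop_invalid("empty window")
  if (!is.logical(closed_flags) || anyNA(closed_flags))
    stop_invalid("`closed_flags` must be logical without NA")
  mean(closed_flags)
}

#' Yawn frequency over a window
#'
#' A frame counts as yawning when it lies in a contiguous run where the
#' middle mouth-aspect component exceeds `threshold` for at least
#' `min_duration` seconds; the duration gate separates ~4 s yawns from
#' short speech bursts. The frequency is yawning frames over total frames.
#'
#' @param mav_mid Numeric vector of per-frame middle mouth-aspect values
#'   (the `||M3 - M7||` ratio), length >= 1.
#' @param fps Frames per second (> 0).
#' @param threshold Opening gate on the middle aspect (default 0.6).
#' @param min_duration Minimum run length in seconds (default 3).
#' @return Fraction in \[0, 1\].
#' @export
yawn_frequency <- function(mav_mid, fps, threshold = 0.6, min_duration = 3) {
  if (length(mav_mid) < 1L) stop_invalid("empty window")
  if (!is.numeric(mav_mid) || any(!is.finite(mav_mid)))
    stop_invalid("`mav_mid` must be finite numeric")
  check_scalar_number(fps, "fps", positive = TRUE)
  mean(yawn_flags(mav_mid, fps, threshold, min_duration))
}

# per-frame yawning indicator after the duration gate
yawn_flags <- function(mav_mid, fps, threshold = 0.6, min_duration = 3) {
  open <- mav_mid > threshold
  r <- rle(open)
  keep <- r$values & (r$lengths >= min_duration * fps)
  inverse.rle(list(lengths = r$lengths, values = keep))
}

#' Scalarize a feature frame to the 11-feature vector
#'
#' Fixed order: EAV, MAV, S_ar, S_mp, Pitch, Yaw, Roll, EOA, MOA, F_blink,
#' F_yawn. The two EAV components and three MAV components enter as their
#' means.
#'
#' @param frame A list/one-row data frame with fields `eav` (length 2 or
#'   scalar), `mav` (length 3 or scalar), `s_ar`, `s_mp`, `pitch`, `yaw`,
#'   `roll`, `eoa`, `moa`.
#' @param window A list with `f_blink` and `f_yawn` fractions.
#' @return Named numeric vector of length 11.
#' @export
scalarize <- function(frame, window) {
  v <- c(eav = mean(unlist(frame[["eav"]])),
         mav = mean(unlist(frame[["mav"]])),
         s_ar = frame[["s_ar"]], s_mp = frame[["s_mp"]],
         pitch = frame[["pitch"]], yaw = frame[["yaw"]], roll = frame[["roll"]],
         eoa = frame[["eoa"]], moa = frame[["moa"]],
         f_blink = window[["f_blink"]], f_yawn = window[["f_yawn"]])
  if (length(v) != 11L || any(!is.finite(v)))
    stop_invalid("feature frame has missing or non-finite components")
  v
}

feature_order <- c("eav", "mav", "s_ar", "s_mp", "pitch", "yaw", "roll",
                   "eoa", "moa", "f_blink", "f_yawn")

# trailing rolling mean of a 0/1 vector over up to `w` frames
rolling_fraction <- function(flags, w) {
  n <- length(flags)
  w <- min(w, n)
  cs <- cumsum(as.numeric(flags))
  full <- seq_len(n) >= w
  out <- numeric(n)
  out[!full] <- cs[!full] / seq_len(n)[!full]
  idx <- which(full)
  out[idx] <- (cs[idx] - c(0, cs)[idx - w + 1]) / w
  out
}

#' Extract the per-frame feature table from a landmark stream
#'
#' Computes the scalarized 11-feature vector for every frame: eye/mouth
#' aspect means, opening angles, closure-area ratio, mouth-area proxy,
#' head-pose Euler angles recovered by [solve_pose()] (warm-started from the
#' previous frame), and trailing-window blink and yawn frequencies.
#'
#' @param landmarks A `fatigue_session`, landmark data frame, or path to a
#'   landmark CSV.
#' @param calib Optional [eye_calibration()]; computed by [calibrate_eyes()]
#'   when `NULL`.
#' @param cam [camera_intrinsics()] for the pose solve.
#' @param model 5 x 3 face model (mm).
#' @param freq_window Trailing window (frames) for the blink/yawn
#'   frequencies (default 900, i.e. 60 s at 15 fps).
#' @param fps Frame rate; taken from the session or inferred from
#'   timestamps when `NULL`.
#' @param closure_threshold,yawn_threshold,yawn_min_duration Gates for the
#'   closure rule and yawn run-length rule.
#' @return Data frame with columns `t`, `eav`, `eoa`, `s_ar`, `mav`, `moa`,
#'   `s_mp`, `pitch`, `yaw`, `roll`, `f_blink`, `f_yawn`, `label` (0 =
#'   non-fatigue, 1 = fatigue, NA = excluded KSS), with the calibration
#'   attached as attribute `"calibration"`.
#' @export
extract_features <- function(landmarks, calib = NULL,
                             cam = camera_intrinsics(),
                             model = default_face_model(),
                             freq_window = 900, fps = NULL,
                             closure_threshold = 0.2,
                             yawn_threshold = 0.6, yawn_min_duration = 3) {
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  if (inherits(landmarks, "fatigue_session")) {
    if (is.null(fps)) fps <- landmarks$fps
    landmarks <- landmarks$frames
  }
  df <- landmarks
  n <- nrow(df)
  if (n < 1L) stop_invalid("no frames in landmark input")
  if (is.null(fps)) {
    dt <- diff(df$t)
    if (length(dt) == 0L || any(dt <= 0))
      stop_invalid("cannot infer fps: need strictly increasing timestamps")
    fps <- 1 / stats::median(dt)
  }
  if (is.null(calib)) calib <- calibrate_eyes(df)

  g <- eye_geometry(df)
  if (any(g$width <= 0)) stop_invalid("degenerate eye geometry: zero canthus distance")
  eav_mean <- (g$d45 / g$width + g$d23 / g$width) / 2
  s_ar_v <- (g$width * g$lid) / (calib$a_max * calib$b_max)

  # vectorized opening angles
  ang <- function(qx, qy, ax, ay, bx, by) {
    abx <- bx - ax; aby <- by - ay
    d <- abs(abx * (qy - ay) - aby * (qx - ax)) / sqrt(abx^2 + aby^2)
    h <- sqrt((qx - ax)^2 + (qy - ay)^2)
    asin(pmin(1, d / pmax(h, .Machine$double.eps)))
  }
  eoa_v <- ang(df$eye_p2_x, df$eye_p2_y, df$eye_p1_x, df$eye_p1_y,
               df$eye_p6_x, df$eye_p6_y)
  moa_v <- ang(df$m3_x, df$m3_y, df$m1_x, df$m1_y, df$m5_x, df$m5_y)

  mouth_w <- sqrt((df$m5_x - df$m1_x)^2 + (df$m5_y - df$m1_y)^2)
  mav1 <- sqrt((df$m4_x - df$m6_x)^2 + (df$m4_y - df$m6_y)^2) / mouth_w
  mav2 <- sqrt((df$m3_x - df$m7_x)^2 + (df$m3_y - df$m7_y)^2) / mouth_w
  mav3 <- sqrt((df$m2_x - df$m8_x)^2 + (df$m2_y - df$m8_y)^2) / mouth_w
  mav_mean <- (mav1 + mav2 + mav3) / 3
  s_mp_v <- abs(df$m8_x - df$m1_x) * abs(df$m7_y - df$m3_y)

  euler <- solve_pose_series(df, cam, model)

  closed <- is_eye_closed(g$lid, calib, closure_threshold)
  f_blink <- rolling_fraction(closed, freq_window)
  yflags <- yawn_flags(mav2, fps, yawn_threshold, yawn_min_duration)
  f_yawn <- rolling_fraction(yflags, freq_window)

  label <- rep(NA_integer_, n)
  if (!is.null(df$kss)) {
    b <- binarize_kss(df$kss)
    label <- ifelse(b == "non_fatigue", 0L, ifelse(b == "fatigue", 1L, NA_integer_))
  } else if (!is.null(df$state)) {
    label <- as.integer(df$state == "fatigued")
  }

  out <- data.frame(t = df$t, eav = eav_mean, eoa = eoa_v, s_ar = s_ar_v,
                    mav = mav_mean, moa = moa_v, s_mp = s_mp_v,
                    pitch = euler[, 1], yaw = euler[, 2], roll = euler[, 3],
                    f_blink = f_blink, f_yawn = f_yawn, label = label)
  attr(out, "calibration") <- calib
  attr(out, "fps") <- fps
  out
}

# per-frame pose solves, warm-started from the previous frame's solution
solve_pose_series <- function(df, cam, model) {
  n <- nrow(df)
  out <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("pitch", "yaw", "roll")))
  px <- cbind(df$pose1_x, df$pose2_x, df$pose3_x, df$pose4_x, df$pose5_x)
  py <- cbind(df$pose1_y, df$pose2_y, df$pose3_y, df$pose4_y, df$pose5_y)
  rot <- NULL; tv <- NULL
  for (i in seq_len(n)) {
    p2d <- cbind(px[i, ], py[i, ])
    fit <- NULL
    if (!is.null(rot))
      fit <- gn_refine(p2d, model, cam, rot, tv, max_iter = 8L, tol = 1e-8)
    if (is.null(fit) || fit$rms > 5) {   # cold start (first frame or lost track)
      init <- tryCatch(pose_init_pos(p2d, model, cam), error = function(e) NULL)
      if (!is.null(init))
        fit <- gn_refine(p2d, model, cam, init$rotation,
                         as.numeric(init$translation), max_iter = 50L,
                         tol = 1e-8)
    }
    if (is.null(fit)) {
      out[i, ] <- if (i > 1) out[i - 1, ] else c(0, 0, 0)
      rot <- NULL
    } else {
      out[i, ] <- rotation_to_euler(fit$rot)
      rot <- fit$rot; tv <- fit$tv
    }
  }
  out
}
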