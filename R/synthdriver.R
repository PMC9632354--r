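# Synthetic facial-landmark stream simulator.
#
# Emulates the statistical structure the identification pipeline assumes:
# state-dependent blink durations (0.2-0.3 s awake, > 1 s fatigued), ~4 s
# yawns, short speech episodes, head nods/tilts, and isotropic Gaussian
# landmark jitter, with per-frame KSS labels. Events are drawn from renewal
# schedules whose long-run rates equal the profile rates.

#' Subject behaviour profile for the landmark simulator
#'
#' Rates are events per minute; durations are seconds. Blink durations are
#' sampled uniformly from the given ranges; the fatigued range must lie
#' entirely above the awake range (slow, heavy-lidded blinks are the fatigue
#' signature). Under the default profile the closed-eye frame fraction rises
#' from about 4% awake to about 15% fatigued.
#'
#' @param blink_rate_awake,blink_rate_fatigued Blink events per minute.
#' @param blink_dur_awake,blink_dur_fatigued Length-2 duration ranges (s).
#' @param yawn_rate_fatigued Yawns per minute in the fatigued state (awake
#'   sessions never yawn).
#' @param yawn_dur Yawn duration in seconds (default 4).
#' @param speech_rate Speech bursts per minute (both states).
#' @param nod_rate_fatigued Head nod/tilt events per minute when fatigued.
#' @param landmark_noise_sd Isotropic Gaussian jitter per coordinate (px).
#' @param eye_width,mouth_width Corner-to-corner widths (px).
#' @return A list of class `"subject_profile"`.
#' @examples
#' subject_profile()
#' @export
subject_profile <- function(blink_rate_awake = 15,
                            blink_rate_fatigued = 10,
                            blink_dur_awake = c(0.2, 0.3),
                            blink_dur_fatigued = c(1.0, 2.0),
                            yawn_rate_fatigued = 2,
                            yawn_dur = 4,
                            speech_rate = 2,
                            nod_rate_fatigued = 3,
                            landmark_noise_sd = 0.5,
                            eye_width = 60,
                            mouth_width = 80) {
  for (nm in c("blink_rate_awake", "blink_rate_fatigued", "yawn_rate_fatigued",
               "speech_rate", "nod_rate_fatigued")) {
    v <- get(nm)
    check_scalar_number(v, nm)
    if (v < 0) stop_invalid("`", nm, "` must be >= 0")
  }
  check_scalar_number(yawn_dur, "yawn_dur", positive = TRUE)
  check_scalar_number(landmark_noise_sd, "landmark_noise_sd")
  if (landmark_noise_sd < 0) stop_invalid("`landmark_noise_sd` must be >= 0")
  check_scalar_number(eye_width, "eye_width", positive = TRUE)
  check_scalar_number(mouth_width, "mouth_width", positive = TRUE)
  if (length(blink_dur_awake) != 2L || length(blink_dur_fatigued) != 2L ||
      any(!is.finite(c(blink_dur_awake, blink_dur_fatigued))) ||
      any(c(blink_dur_awake, blink_dur_fatigued) <= 0) ||
      diff(blink_dur_awake) < 0 || diff(blink_dur_fatigued) < 0)
    stop_invalid("blink duration ranges must be ordered positive length-2 vectors")
  if (blink_dur_fatigued[1] <= blink_dur_awake[2])
    stop_invalid("fatigued blink durations must exceed awake durations ",
                 "(lower bound ", blink_dur_fatigued[1], " must be > ",
                 blink_dur_awake[2], ")")
  structure(list(blink_rate_awake = blink_rate_awake,
                 blink_rate_fatigued = blink_rate_fatigued,
                 blink_dur_awake = blink_dur_awake,
                 blink_dur_fatigued = blink_dur_fatigued,
                 yawn_rate_fatigued = yawn_rate_fatigued,
                 yawn_dur = yawn_dur,
                 speech_rate = speech_rate,
                 nod_rate_fatigued = nod_rate_fatigued,
                 landmark_noise_sd = landmark_noise_sd,
                 eye_width = eye_width,
                 mouth_width = mouth_width),
            class = "subject_profile")
}

#' Binarize a Karolinska Sleepiness Scale score
#'
#' KSS below 3 is non-fatigue, above 4 is fatigue; the uncovered scores 3
#' and 4 are excluded rather than forced into either class.
#'
#' @param kss Integer vector with values in 1..9.
#' @return Factor with levels `non_fatigue`, `fatigue`, `excluded`.
#' @examples
#' binarize_kss(c(2, 3, 7))
#' @export
binarize_kss <- function(kss) {
  if (!is.numeric(kss) || any(!is.finite(kss)) ||
      any(kss != round(kss)) || any(kss < 1) || any(kss > 9))
    stop_invalid("`kss` must contain integers in 1..9")
  out <- ifelse(kss < 3, "non_fatigue", ifelse(kss > 4, "fatigue", "excluded"))
  factor(out, levels = c("non_fatigue", "fatigue", "excluded"))
}

# Renewal schedule: event starts separated by the event duration plus an
# exponential gap whose mean makes the long-run start rate equal
# `rate_per_min`. Returns data.frame(start, end) clipped to [0, duration].
schedule_events <- function(rate_per_min, dur_sampler, duration) {
  if (rate_per_min <= 0) return(data.frame(start = numeric(0), end = numeric(0)))
  rate <- rate_per_min / 60
  starts <- numeric(0); ends <- numeric(0)
  t <- stats::rexp(1, rate)  # delay to first event
  while (t < duration) {
    d <- dur_sampler()
    starts <- c(starts, t); ends <- c(ends, min(t + d, duration))
    gap_mean <- max(1 / rate - d, 0.05 / rate)
    t <- t + d + stats::rexp(1, 1 / gap_mean)
  }
  data.frame(start = starts, end = ends)
}

# cosine close/hold/open envelope: 1 at the edges, `floor_val` in the hold
blink_envelope <- function(u, floor_val = 0.02) {
  e <- rep(floor_val, length(u))
  cl <- u < 0.25
  op <- u > 0.75
  e[cl] <- 1 - (1 - floor_val) * (1 - cos(pi * u[cl] / 0.25)) / 2
  e[op] <- floor_val + (1 - floor_val) * (1 - cos(pi * (u[op] - 0.75) / 0.25)) / 2
  e
}

# ramp-hold-ramp envelope in [0, 1] with `ramp` seconds on each side
hold_envelope <- function(trel, dur, ramp = 0.5) {
  ramp <- min(ramp, dur / 4)
  e <- rep(1, length(trel))
  up <- trel < ramp
  dn <- trel > dur - ramp
  e[up] <- (1 - cos(pi * trel[up] / ramp)) / 2
  e[dn] <- (1 - cos(pi * (dur - trel[dn]) / ramp)) / 2
  pmax(e, 0)
}

apply_events <- function(t, events, fun) {
  out <- rep(0, length(t))
  if (nrow(events) == 0L) return(out)
  for (i in seq_len(nrow(events))) {
    idx <- which(t >= events$start[i] & t < events$end[i])
    if (length(idx) == 0L) next
    out[idx] <- pmax(out[idx], fun(t[idx], events$start[i], events$end[i], i))
  }
  out
}

#' Simulate a synthetic landmark session
#'
#' Generates a seed-reproducible stream of timestamped facial landmarks for
#' a driver in a fixed state. Blinks shrink the eyelid-pair distances to
#' below 5% of the open baseline through a cosine close/hold/open envelope;
#' yawns open the middle lip pair to 85% of the mouth width for
#' `yawn_dur` seconds; speech bursts open the mouth briefly and modestly;
#' nods and tilts are smooth pitch/roll excursions of 20-40 degrees lasting
#' 1-3 s. Pose landmarks are the projection of [default_face_model()] under
#' the per-frame head rotation, and every coordinate receives isotropic
#' Gaussian jitter.
#'
#' @param profile A [subject_profile()].
#' @param state `"awake"` or `"fatigued"`.
#' @param duration Session length in seconds (> 0).
#' @param fps Frame rate (default 15, so a 900-frame window spans 60 s).
#' @param seed Integer seed; identical inputs reproduce the session exactly.
#' @param cam [camera_intrinsics()] used to project the pose landmarks.
#' @return A list of class `"fatigue_session"` with elements `frames` (one
#'   row per frame: `t`, `kss`, `state`, then eye/mouth/pose coordinate
#'   columns), `fps`, `seed`, `state`, `profile`, and `ground_truth_events`
#'   (`type`, `start`, `end`).
#' @examples
#' s <- simulate_session(subject_profile(), "awake", duration = 10, seed = 1)
#' nrow(s$frames)
#' @export
simulate_session <- function(profile = subject_profile(),
                             state = c("awake", "fatigued"),
                             duration = 60, fps = 15, seed = 1,
                             cam = camera_intrinsics()) {
  state <- match.arg(state)
  if (!inherits(profile, "subject_profile"))
    stop_invalid("`profile` must be created by subject_profile()")
  check_scalar_number(duration, "duration", positive = TRUE)
  check_scalar_number(fps, "fps", positive = TRUE)
  with_seed(seed, {
    n <- round(fps * duration)
    t <- (seq_len(n) - 1) / fps
    fatigued <- state == "fatigued"

    kss <- if (fatigued) sample(5:9, 1) else sample(1:2, 1)

    blink_rate <- if (fatigued) profile$blink_rate_fatigued else profile$blink_rate_awake
    blink_rng <- if (fatigued) profile$blink_dur_fatigued else profile$blink_dur_awake
    blinks <- schedule_events(blink_rate,
                              function() stats::runif(1, blink_rng[1], blink_rng[2]),
                              duration)
    yawns <- if (fatigued)
      schedule_events(profile$yawn_rate_fatigued, function() profile$yawn_dur, duration)
    else data.frame(start = numeric(0), end = numeric(0))
    speech <- schedule_events(profile$speech_rate,
                              function() stats::runif(1, 0.5, 1.5), duration)
    nods <- if (fatigued)
      schedule_events(profile$nod_rate_fatigued,
                      function() stats::runif(1, 1, 3), duration)
    else data.frame(start = numeric(0), end = numeric(0))
    # suppress speech that collides with a yawn
    if (nrow(speech) > 0L && nrow(yawns) > 0L) {
      clash <- vapply(seq_len(nrow(speech)), function(i)
        any(speech$start[i] < yawns$end & speech$end[i] > yawns$start), logical(1))
      speech <- speech[!clash, , drop = FALSE]
    }

    ew <- profile$eye_width
    lid_open <- 0.35 * ew
    closure <- 1 - apply_events(t, blinks, function(tt, s, e, i)
      1 - blink_envelope((tt - s) / (e - s)))
    lid <- lid_open * closure

    mw <- profile$mouth_width
    yawn_open <- 0.85 * mw * apply_events(t, yawns, function(tt, s, e, i)
      hold_envelope(tt - s, e - s, ramp = 0.5))
    speech_open <- apply_events(t, speech, function(tt, s, e, i)
      0.28 * mw * hold_envelope(tt - s, e - s, ramp = 0.15) *
        (0.6 + 0.4 * sin(2 * pi * 6 * (tt - s))))
    lip_mid <- 2 + pmax(yawn_open, speech_open)   # 2 px resting lip gap
    lip_outer <- 1 + 0.6 * pmax(yawn_open, speech_open)

    # head attitude: slow wander plus nod (pitch) / tilt (roll) excursions
    ph <- stats::runif(6, 0, 2 * pi)
    wander <- function(a1, f1, p1, a2, f2, p2)
      a1 * sin(2 * pi * f1 * t + p1) + a2 * sin(2 * pi * f2 * t + p2)
    pitch <- wander(1.5, 0.02, ph[1], 0.5, 0.11, ph[2])
    yaw   <- wander(2.0, 0.017, ph[3], 0.5, 0.09, ph[4])
    roll  <- wander(1.0, 0.023, ph[5], 0.4, 0.13, ph[6])
    nod_type <- if (nrow(nods) > 0L)
      sample(c("nod", "tilt"), nrow(nods), replace = TRUE) else character(0)
    nod_amp <- stats::runif(nrow(nods), 20, 40) *
      sample(c(-1, 1), max(nrow(nods), 1), replace = TRUE)[seq_len(nrow(nods))]
    if (nrow(nods) > 0L) {
      for (i in seq_len(nrow(nods))) {
        idx <- which(t >= nods$start[i] & t < nods$end[i])
        if (length(idx) == 0L) next
        bump <- nod_amp[i] *
          (1 - cos(2 * pi * (t[idx] - nods$start[i]) /
                     (nods$end[i] - nods$start[i]))) / 2
        if (nod_type[i] == "nod") pitch[idx] <- pitch[idx] + bump
        else roll[idx] <- roll[idx] + bump
      }
    }

    # eye landmarks (image-plane template, px): p1/p6 corners,
    # (p2,p3) and (p4,p5) upper/lower lid pairs at 25% / 75% of the width
    e0 <- c(290, 210)
    eye <- list(
      p1 = cbind(e0[1], e0[2]),
      p2 = cbind(e0[1] + 0.25 * ew, e0[2] - lid / 2),
      p3 = cbind(e0[1] + 0.25 * ew, e0[2] + lid / 2),
      p4 = cbind(e0[1] + 0.75 * ew, e0[2] - lid / 2),
      p5 = cbind(e0[1] + 0.75 * ew, e0[2] + lid / 2),
      p6 = cbind(e0[1] + ew, e0[2])
    )
    # mouth landmarks: M1/M5 corners, pairs (M2,M8), (M3,M7), (M4,M6)
    m0 <- c(280, 330)
    mouth <- list(
      m1 = cbind(m0[1], m0[2]),
      m2 = cbind(m0[1] + 0.25 * mw, m0[2] - lip_outer / 2),
      m3 = cbind(m0[1] + 0.50 * mw, m0[2] - lip_mid / 2),
      m4 = cbind(m0[1] + 0.75 * mw, m0[2] - lip_outer / 2),
      m5 = cbind(m0[1] + mw, m0[2]),
      m6 = cbind(m0[1] + 0.75 * mw, m0[2] + lip_outer / 2),
      m7 = cbind(m0[1] + 0.50 * mw, m0[2] + lip_mid / 2),
      m8 = cbind(m0[1] + 0.25 * mw, m0[2] + lip_outer / 2)
    )

    pose_pts <- project_face_series(pitch, yaw, roll, cam)

    df <- data.frame(t = t, kss = kss, state = state)
    for (k in 1:6) {
      df[[paste0("eye_p", k, "_x")]] <- rep_len(eye[[k]][, 1], n)
      df[[paste0("eye_p", k, "_y")]] <- rep_len(eye[[k]][, 2], n)
    }
    for (k in 1:8) {
      df[[paste0("m", k, "_x")]] <- rep_len(mouth[[k]][, 1], n)
      df[[paste0("m", k, "_y")]] <- rep_len(mouth[[k]][, 2], n)
    }
    for (k in 1:5) {
      df[[paste0("pose", k, "_x")]] <- pose_pts[[k]][, 1]
      df[[paste0("pose", k, "_y")]] <- pose_pts[[k]][, 2]
    }
    coord_cols <- setdiff(names(df), c("t", "kss", "state"))
    if (profile$landmark_noise_sd > 0) {
      noise <- matrix(stats::rnorm(n * length(coord_cols),
                                   sd = profile$landmark_noise_sd),
                      nrow = n)
      df[coord_cols] <- df[coord_cols] + noise
    }

    ev <- rbind(
      if (nrow(blinks)) cbind(type = "blink", blinks),
      if (nrow(yawns)) cbind(type = "yawn", yawns),
      if (nrow(speech)) cbind(type = "speech", speech),
      if (nrow(nods)) cbind(type = nod_type, nods)
    )
    if (is.null(ev)) ev <- data.frame(type = character(0), start = numeric(0),
                                      end = numeric(0))
    ev <- ev[order(ev$start), , drop = FALSE]
    rownames(ev) <- NULL

    structure(list(frames = df, fps = fps, seed = seed, state = state,
                   profile = profile, ground_truth_events = ev,
                   true_angles = data.frame(pitch = pitch, yaw = yaw, roll = roll)),
              class = "fatigue_session")
  })
}

# vectorized projection of the 5-point face model over per-frame Euler angles
project_face_series <- function(pitch, yaw, roll, cam,
                                model = default_face_model(),
                                translation = c(0, 0, 600)) {
  p <- pitch * pi / 180; y <- yaw * pi / 180; r <- roll * pi / 180
  cp <- cos(p); sp <- sin(p); cy <- cos(y); sy <- sin(y)
  cr <- cos(r); sr <- sin(r)
  # rows of R = Rx(p) %*% Ry(y) %*% Rz(r), each entry a per-frame vector
  r11 <- cy * cr;                 r12 <- -cy * sr;                r13 <- sy
  r21 <- cp * sr + sp * sy * cr;  r22 <- cp * cr - sp * sy * sr;  r23 <- -sp * cy
  r31 <- sp * sr - cp * sy * cr;  r32 <- sp * cr + cp * sy * sr;  r33 <- cp * cy
  lapply(seq_len(nrow(model)), function(i) {
    x <- model[i, 1]; yy <- model[i, 2]; z <- model[i, 3]
    xc <- r11 * x + r12 * yy + r13 * z + translation[1]
    yc <- r21 * x + r22 * yy + r23 * z + translation[2]
    zc <- r31 * x + r32 * yy + r33 * z + translation[3]
    cbind(cam$fx * xc / zc + cam$cx, cam$fy * yc / zc + cam$cy)
  })
}

#' @export
print.fatigue_session <- function(x, ...) {
  cat("<fatigue_session> state:", x$state, "| frames:", nrow(x$frames),
      "| fps:", x$fps, "| seed:", x$seed, "\n")
  cat("events:", nrow(x$ground_truth_events), "(",
      paste(names(table(x$ground_truth_events$type)),
            table(x$ground_truth_events$type), collapse = ", "), ")\n")
  invisible(x)
}

#' Write a landmark session to CSV
#'
#' One row per frame; columns `t, kss, state`, then the eye, mouth and pose
#' coordinate columns. UTF-8, '.' decimal separator, header mandatory.
#'
#' @param session A `fatigue_session` or a landmark data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(session, path) {
  df <- if (inherits(session, "fatigue_session")) session$frames else session
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a landmark CSV
#'
#' @param path File written by [write_landmarks()] (or matching its layout).
#' @return A landmark data frame.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop_invalid("landmark file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("t", sprintf("eye_p%d_%s", rep(1:6, each = 2), c("x", "y")),
            sprintf("m%d_%s", rep(1:8, each = 2), c("x", "y")),
            sprintf("pose%d_%s", rep(1:5, each = 2), c("x", "y")))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_invalid("landmark CSV is missing columns: ",
                 paste(missing, collapse = ", "))
  df
}
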