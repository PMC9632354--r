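# Head-pose recovery from five 2D face landmarks under a pinhole camera.
#
# The driver's head is treated as a rigid body: a generic 3D face model is
# fitted to the observed 2D points by minimizing squared reprojection error.
# Initialization is a scaled-orthographic (POS) estimate, refined by
# Gauss-Newton steps on the rotation (left-multiplied axis-angle increments)
# and translation.

#' Pinhole camera intrinsics
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @return A list of class `"camera_intrinsics"`.
#' @examples
#' camera_intrinsics()
#' @export
camera_intrinsics <- function(fx = 600, fy = 600, cx = 320, cy = 240) {
  check_scalar_number(fx, "fx", positive = TRUE)
  check_scalar_number(fy, "fy", positive = TRUE)
  check_scalar_number(cx, "cx")
  check_scalar_number(cy, "cy")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' Generic synthetic 3D face model
#'
#' Five model-centred 3D points in millimetres (left eye, right eye, nose
#' tip, left and right mouth corner) for a face looking along the negative
#' z axis of the camera frame (x right, y down, z away from the camera).
#' This is a synthetic generic model, not measured from any subject.
#'
#' @return A 5 x 3 numeric matrix with row names.
#' @examples
#' default_face_model()
#' @export
default_face_model <- function() {
  m <- rbind(
    left_eye    = c(-35, -35, -12),
    right_eye   = c( 35, -35, -12),
    nose_tip    = c(  0,   0, -35),
    mouth_left  = c(-25,  30, -18),
    mouth_right = c( 25,  30, -18)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

check_face_model <- function(model) {
  model <- as.matrix(model)
  if (!is.numeric(model) || nrow(model) != 5L || ncol(model) != 3L ||
      !all(is.finite(model)))
    stop_invalid("`model` must be a finite 5 x 3 matrix of 3D points (mm)")
  centred <- sweep(model, 2, colMeans(model))
  if (qr(centred)$rank < 2L)
    stop_invalid("degenerate face model: points are collinear")
  model
}

# project camera-frame 3D points (rows) to pixels
project_points <- function(pts_cam, cam) {
  z <- pts_cam[, 3]
  cbind(cam$fx * pts_cam[, 1] / z + cam$cx,
        cam$fy * pts_cam[, 2] / z + cam$cy)
}

#' Project a 3D face model to image points
#'
#' @param model 5 x 3 matrix of model points (mm), see [default_face_model()].
#' @param rotation 3 x 3 rotation matrix (model to camera frame).
#' @param translation Length-3 translation in mm; `translation[3] > 0`
#'   places the head in front of the camera.
#' @param cam [camera_intrinsics()].
#' @return A 5 x 2 matrix of pixel coordinates.
#' @export
project_face <- function(model, rotation, translation,
                         cam = camera_intrinsics()) {
  model <- check_face_model(model)
  pts_cam <- model %*% t(rotation) +
    matrix(translation, nrow(model), 3, byrow = TRUE)
  if (any(pts_cam[, 3] <= 0))
    stop_invalid("projection places model points behind the camera")
  project_points(pts_cam, cam)
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# Rodrigues exponential map
rotation_exp <- function(w) {
  th <- vnorm(w)
  if (th < 1e-12) return(diag(3) + skew(w))
  k <- skew(w / th)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# scaled-orthographic (POS) initial pose estimate
pose_init_pos <- function(points2d, model, cam) {
  xn <- (points2d[, 1] - cam$cx) / cam$fx
  yn <- (points2d[, 2] - cam$cy) / cam$fy
  x0 <- colMeans(model)
  a <- sweep(model, 2, x0)
  ap <- solve(crossprod(a) + 1e-12 * diag(3), t(a))
  iv <- ap %*% (xn - mean(xn))
  jv <- ap %*% (yn - mean(yn))
  s <- (vnorm(iv) + vnorm(jv)) / 2
  if (s < 1e-12) stop_invalid("degenerate correspondences: zero image spread")
  r1 <- iv / vnorm(iv); r2 <- jv / vnorm(jv)
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  rt <- rbind(c(r1), c(r2), c(r3))
  sv <- svd(rt)
  rot <- sv$u %*% t(sv$v)
  if (det(rot) < 0) rot <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  tz <- 1 / s
  # translation maps the uncentred model: t = t_centroid - R x0
  tv <- c(mean(xn) * tz, mean(yn) * tz, tz) - as.numeric(rot %*% x0)
  list(rotation = rot, translation = tv)
}

#' Recover head pose from five 2D-3D correspondences
#'
#' Minimizes the mean squared pixel reprojection error of the model under a
#' pinhole camera by damped Gauss-Newton iterations, initialized from a
#' scaled-orthographic estimate (or a caller-supplied pose).
#'
#' @param points2d 5 x 2 matrix of observed pixel coordinates, rows in the
#'   order of `model`.
#' @param model 5 x 3 matrix of model points (mm).
#' @param cam [camera_intrinsics()].
#' @param init Optional list with elements `rotation` and `translation`
#'   used as the starting pose (e.g. the previous video frame's solution).
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param tol Convergence tolerance on the parameter update norm.
#' @param max_residual Root-mean-square reprojection error (pixels) above
#'   which the solve is declared non-convergent.
#' @return A list of class `"head_pose"`: `rotation` (3 x 3), `translation`
#'   (length 3, mm), `euler` ([rotation_to_euler()] angles in degrees),
#'   `residual` (RMS reprojection error, pixels), `iterations`, `converged`.
#' @examples
#' m <- default_face_model()
#' p2d <- project_face(m, diag(3), c(0, 0, 600))
#' solve_pose(p2d, m)$euler
#' @export
solve_pose <- function(points2d, model = default_face_model(),
                       cam = camera_intrinsics(), init = NULL,
                       max_iter = 50L, tol = 1e-10, max_residual = 50) {
  points2d <- as_point_matrix(points2d, 5L, "points2d")
  model <- check_face_model(model)
  if (is.null(init)) init <- pose_init_pos(points2d, model, cam)
  fit <- gn_refine(points2d, model, cam, init$rotation,
                   as.numeric(init$translation), max_iter, tol)
  if (is.null(fit)) stop_invalid("initial pose places points behind the camera")
  if (fit$rms > max_residual)
    stop_invalid("pose solver did not converge: RMS reprojection error ",
                 format(fit$rms, digits = 4), " px exceeds ", max_residual, " px")
  structure(list(rotation = fit$rot, translation = fit$tv,
                 euler = rotation_to_euler(fit$rot),
                 residual = fit$rms, iterations = fit$iter,
                 converged = fit$rms <= max_residual),
            class = "head_pose")
}

# damped Gauss-Newton core; returns NULL when the start pose is behind the
# camera. No input validation: callers guarantee shapes.
gn_refine <- function(points2d, model, cam, rot, tv, max_iter, tol) {
  if (tv[3] <= 0) tv[3] <- abs(tv[3]) + 1e-3
  n <- nrow(model)
  obs <- c(points2d[, 1], points2d[, 2])
  resid_state <- function(rot, tv) {
    pc <- model %*% rot                      # rot passed transposed below
    pc[, 1] <- pc[, 1] + tv[1]; pc[, 2] <- pc[, 2] + tv[2]
    pc[, 3] <- pc[, 3] + tv[3]
    if (any(pc[, 3] <= 1e-9)) return(NULL)
    r <- c(cam$fx * pc[, 1] / pc[, 3] + cam$cx,
           cam$fy * pc[, 2] / pc[, 3] + cam$cy) - obs
    list(r = r, pc = pc)
  }
  st <- resid_state(t(rot), tv)
  if (is.null(st)) return(NULL)
  err <- sum(st$r^2)
  lambda <- 1e-6
  iter <- 0L
  jac <- matrix(0, 2 * n, 6)
  for (iter in seq_len(max_iter)) {
    pc <- st$pc
    # rotation acts on the rotated model point (camera point minus t):
    # d(camera point)/d(axis-angle increment) = -[y - t]_x ; d/dt = I
    x <- pc[, 1]; y <- pc[, 2]; z <- pc[, 3]
    rx <- x - tv[1]; ry <- y - tv[2]; rz <- z - tv[3]
    iz <- 1 / z; iz2 <- iz * iz
    # dXc/dw = (0, rz, -ry; -rz, 0, rx; ry, -rx, 0), dXc/dt = I (rowwise)
    ui <- seq_len(n); vi <- n + ui
    jac[ui, 1] <- cam$fx * (0 * z - x * ry) * iz2
    jac[ui, 2] <- cam$fx * (rz * z + x * rx) * iz2
    jac[ui, 3] <- cam$fx * (-ry * z) * iz2
    jac[ui, 4] <- cam$fx * iz
    jac[ui, 5] <- 0
    jac[ui, 6] <- -cam$fx * x * iz2
    jac[vi, 1] <- cam$fy * (-rz * z - y * ry) * iz2
    jac[vi, 2] <- cam$fy * (0 * z + y * rx) * iz2
    jac[vi, 3] <- cam$fy * (rx * z) * iz2
    jac[vi, 4] <- 0
    jac[vi, 5] <- cam$fy * iz
    jac[vi, 6] <- -cam$fy * y * iz2
    h <- crossprod(jac)
    g <- crossprod(jac, st$r)
    repeat {
      delta <- tryCatch(solve(h + lambda * diag(6), -g), error = function(e) NULL)
      if (!is.null(delta)) {
        rot_new <- rotation_exp(delta[1:3]) %*% rot
        tv_new <- tv + delta[4:6]
        st_new <- resid_state(t(rot_new), tv_new)
        if (!is.null(st_new) && sum(st_new$r^2) <= err) break
      }
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
    if (lambda > 1e8) break
    improved <- err - sum(st_new$r^2)
    rot <- rot_new; tv <- tv_new; st <- st_new; err <- sum(st$r^2)
    lambda <- max(lambda / 10, 1e-9)
    if (vnorm(delta) < tol || improved < tol * (err + tol)) break
  }
  list(rot = rot, tv = tv, rms = sqrt(err / (2 * n)), iter = iter)
}

#' Convert a rotation matrix to head-pose Euler angles
#'
#' Uses the intrinsic pitch-yaw-roll (x-y-z) decomposition
#' `R = Rx(pitch) %*% Ry(yaw) %*% Rz(roll)`, returning degrees. At the
#' gimbal-lock singularity (|yaw| = 90 deg) the roll is set to 0 and the
#' pitch absorbs the remaining rotation.
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1,
#'   checked to tolerance 1e-6).
#' @return Named numeric vector `c(pitch, yaw, roll)` in degrees.
#' @examples
#' rotation_to_euler(diag(3))
#' @export
rotation_to_euler <- function(rotation) {
  r <- as.matrix(rotation)
  if (!is.numeric(r) || !identical(dim(r), c(3L, 3L)) || !all(is.finite(r)))
    stop_invalid("`rotation` must be a finite 3 x 3 matrix")
  if (max(abs(crossprod(r) - diag(3))) > 1e-6 || abs(det(r) - 1) > 1e-6)
    stop_invalid("`rotation` is not a rotation matrix (orthonormality/det check failed)")
  sy <- max(-1, min(1, r[1, 3]))
  yaw <- asin(sy)
  if (abs(sy) > 1 - 1e-9) {
    roll <- 0
    pitch <- atan2(r[3, 2], r[2, 2])
  } else {
    pitch <- atan2(-r[2, 3], r[3, 3])
    roll <- atan2(-r[1, 2], r[1, 1])
  }
  c(pitch = pitch, yaw = yaw, roll = roll) * 180 / pi
}

#' Build a rotation matrix from head-pose Euler angles
#'
#' Inverse of [rotation_to_euler()]: intrinsic pitch-yaw-roll (x-y-z),
#' angles in degrees.
#'
#' @param pitch,yaw,roll Angles in degrees.
#' @return A 3 x 3 rotation matrix.
#' @examples
#' euler_to_rotation(0, 30, 0)
#' @export
euler_to_rotation <- function(pitch, yaw, roll) {
  p <- pitch * pi / 180; y <- yaw * pi / 180; r <- roll * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(p), sin(p), 0, -sin(p), cos(p)), 3, 3)
  ry <- matrix(c(cos(y), 0, -sin(y), 0, 1, 0, sin(y), 0, cos(y)), 3, 3)
  rz <- matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
  rx %*% ry %*% rz
}

#' Flag abnormal head posture
#'
#' Nods are pitch excursions and tilts roll excursions beyond a threshold.
#'
#' @param euler Named vector or matrix/data frame with `pitch` and `roll`
#'   in degrees.
#' @param threshold Degrees beyond which posture is abnormal (default 20).
#' @return Logical (vector): `TRUE` where |pitch| or |roll| exceeds the
#'   threshold.
#' @export
abnormal_posture <- function(euler, threshold = 20) {
  check_scalar_number(threshold, "threshold", positive = TRUE)
  if (is.matrix(euler) || is.data.frame(euler)) {
    abs(euler[, "pitch"]) > threshold | abs(euler[, "roll"]) > threshold
  } else {
    abs(euler[["pitch"]]) > threshold | abs(euler[["roll"]]) > threshold
  }
}
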