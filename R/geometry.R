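#' Camera model
#'
#' Ideal pinhole camera with square pixels and a single focal length. The
#' focal length may be given directly in pixels or derived from a horizontal
#' field of view via `f = (width / 2) / tan(fov / 2)`.
#'
#' @param width,height Image size in pixels.
#' @param focal_length Focal length in pixels. Exactly one of `focal_length`
#'   and `fov_horizontal` must be supplied.
#' @param principal_point Numeric length-2, principal point `(x, y)` in
#'   pixels. Defaults to the image centre.
#' @param fov_horizontal Horizontal field of view in degrees.
#' @return An object of class `camera_model` with fields `width`, `height`,
#'   `focal_length`, `principal_point`, `fov_horizontal`.
#' @examples
#' cam <- camera_model(1088, 1080, fov_horizontal = 82)
#' cam$focal_length
#' @export
camera_model <- function(width, height, focal_length = NULL,
                         principal_point = NULL, fov_horizontal = NULL) {
  stopifnot(is.numeric(width), width > 0, is.numeric(height), height > 0)
  if (is.null(focal_length) && is.null(fov_horizontal)) {
    stop("supply either `focal_length` (pixels) or `fov_horizontal` (degrees)")
  }
  if (is.null(focal_length)) {
    stopifnot(fov_horizontal > 0, fov_horizontal < 180)
    focal_length <- (width / 2) / tan(fov_horizontal / 2 * pi / 180)
  } else if (is.null(fov_horizontal)) {
    fov_horizontal <- 2 * atan((width / 2) / focal_length) * 180 / pi
  } else {
    f_implied <- (width / 2) / tan(fov_horizontal / 2 * pi / 180)
    if (abs(f_implied - focal_length) > 1e-6 * focal_length) {
      stop("`focal_length` and `fov_horizontal` are inconsistent: ",
           "f implied by the fov is ", format(f_implied))
    }
  }
  if (focal_length <= 0) stop("focal_length must be > 0")
  if (is.null(principal_point)) principal_point <- c(width / 2, height / 2)
  stopifnot(length(principal_point) == 2)
  if (principal_point[1] < 0 || principal_point[1] > width ||
      principal_point[2] < 0 || principal_point[2] > height) {
    stop("principal point must lie inside the image bounds")
  }
  structure(
    list(width = width, height = height, focal_length = focal_length,
         principal_point = as.numeric(principal_point),
         fov_horizontal = fov_horizontal),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %g x %g px, f = %.2f px, fov_h = %.1f deg, pp = (%.1f, %.1f)\n",
              x$width, x$height, x$focal_length, x$fov_horizontal,
              x$principal_point[1], x$principal_point[2]))
  invisible(x)
}

#' Scene camera of the wearable eye tracker
#'
#' Convenience constructor matching the eye-tracking glasses used by the
#' measurement setup: 1088 x 1080 pixels, 82 degree horizontal field of view.
#' @return A [camera_model()].
#' @export
scene_camera <- function() camera_model(1088, 1080, fov_horizontal = 82)

#' Ceiling camera looking down at the head marker
#'
#' Convenience constructor for the downward-looking head-tracking camera:
#' 1152 x 986 pixels. The focal length in pixels depends on the lens and
#' pixel binning; the default of 3000 px (about a 21 degree horizontal
#' field of view,
#' consistent with a telephoto machine-vision lens) renders a 10-cm marker at
#' 1 m distance with an image area of roughly 90,000 px^2, matching the
#' reported regime in which marker pose is reliable.
#' @param focal_length Focal length in pixels.
#' @return A [camera_model()].
#' @export
ceiling_camera <- function(focal_length = 3000) {
  camera_model(1152, 986, focal_length = focal_length)
}

#' Square fiducial marker model
#'
#' The marker is a square of known physical size lying in the plane z = 0 of
#' its own frame. Corners are ordered top-left, top-right, bottom-right,
#' bottom-left, with x to the right and y downward (image-like axes), so an
#' identity pose projects the corners in the same order on screen.
#'
#' @param side_length Side length in meters.
#' @return An object of class `marker_model` with a `corners` matrix (4 x 3).
#' @export
marker_model <- function(side_length = 0.1) {
  stopifnot(is.numeric(side_length), side_length > 0)
  h <- side_length / 2
  corners <- rbind(c(-h, -h, 0), c(h, -h, 0), c(h, h, 0), c(-h, h, 0))
  rownames(corners) <- c("tl", "tr", "br", "bl")
  structure(list(side_length = side_length, corners = corners),
            class = "marker_model")
}

#' Marker observation: four corner pixels at one timestamp
#'
#' @param corners 4 x 2 matrix of corner pixel coordinates in the fixed
#'   order top-left, top-right, bottom-right, bottom-left.
#' @param timestamp Time in seconds.
#' @param valid Logical validity flag.
#' @return An object of class `marker_observation`.
#' @export
marker_observation <- function(corners, timestamp = NA_real_, valid = TRUE) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 4, ncol(corners) == 2)
  structure(list(timestamp = timestamp, corners = corners, valid = valid),
            class = "marker_observation")
}

#' Pose of the marker in the camera frame
#'
#' @param rotation 3 x 3 orthonormal rotation matrix (marker frame to camera
#'   frame, det = +1).
#' @param translation Length-3 numeric, marker origin in the camera frame,
#'   meters; the z component must be positive (marker in front of camera).
#' @param low_confidence Logical, set when the homography used to estimate
#'   the pose was ill-conditioned.
#' @return An object of class `pose_estimate`; `$rotation_vector` exposes the
#'   axis-angle form.
#' @export
pose_estimate <- function(rotation, translation, low_confidence = FALSE) {
  rotation <- as.matrix(rotation)
  assert_rotation(rotation)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  structure(list(rotation = rotation, translation = translation,
                 rotation_vector = matrix_to_rotvec(rotation),
                 low_confidence = low_confidence),
            class = "pose_estimate")
}

assert_rotation <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("rotation must be a 3x3 orthonormal matrix with determinant +1")
  }
  invisible(R)
}

# elementary rotations (right-handed, angles in radians)
rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

#' Euler angles (intrinsic Z-Y-X) to rotation matrix and back
#'
#' The Z axis is the camera optical axis; for the downward-looking ceiling
#' camera it coincides with the vertical axis the head rotates about, so the
#' Z (yaw) angle is the head angle H. `matrix_to_euler` inverts
#' `euler_to_matrix` away from gimbal lock (|pitch| < 89 degrees).
#'
#' @param yaw,pitch,roll Angles in degrees.
#' @return `euler_to_matrix`: a 3 x 3 rotation matrix.
#'   `matrix_to_euler`: named numeric `c(yaw, pitch, roll)` in degrees.
#' @export
euler_to_matrix <- function(yaw, pitch = 0, roll = 0) {
  d <- pi / 180
  rot_z(yaw * d) %*% rot_y(pitch * d) %*% rot_x(roll * d)
}

#' @rdname euler_to_matrix
#' @param R 3 x 3 rotation matrix.
#' @export
matrix_to_euler <- function(R) {
  assert_rotation(R)
  pitch <- -asin(max(-1, min(1, R[3, 1])))
  if (abs(cos(pitch)) < 1e-8) {
    stop("gimbal lock: |pitch| is 90 degrees, yaw and roll are not separable")
  }
  yaw <- atan2(R[2, 1], R[1, 1])
  roll <- atan2(R[3, 2], R[3, 3])
  c(yaw = yaw, pitch = pitch, roll = roll) * 180 / pi
}

#' Rodrigues rotation vector to matrix, and inverse
#'
#' The rotation vector is the axis-angle representation: direction = rotation
#' axis, norm = rotation angle in radians. `matrix_to_rotvec` inverts
#' `rotvec_to_matrix` for rotation angles in (0, pi); the zero vector maps to
#' the identity matrix.
#'
#' @param v Numeric length-3 rotation vector.
#' @return A 3 x 3 rotation matrix, or a length-3 rotation vector.
#' @examples
#' rotvec_to_matrix(c(0, 0, pi / 2)) %*% c(1, 0, 0)  # -> (0, 1, 0)
#' @export
rotvec_to_matrix <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 3, all(is.finite(v)))
  th <- sqrt(sum(v^2))
  if (th < 1e-14) return(diag(3))
  k <- v / th
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rotvec_to_matrix
#' @param R 3 x 3 rotation matrix.
#' @export
matrix_to_rotvec <- function(R) {
  assert_rotation(R)
  tr <- sum(diag(R))
  th <- acos(max(-1, min(1, (tr - 1) / 2)))
  if (th < 1e-12) return(c(0, 0, 0))
  if (pi - th < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    S <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(S), 0))
    i <- which.max(k)
    if (k[i] > 0) k <- S[, i] / k[i]
    k <- k / sqrt(sum(k^2))
    # fix sign using the skew part where it is nonzero
    w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sum(w * k) < 0) k <- -k
    return(th * k)
  }
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  th * w / (2 * sin(th))
}

#' Project marker corners through an ideal pinhole camera
#'
#' Forward model used both by the simulator and as the brute-force oracle for
#' pose recovery: each marker corner is rotated and translated into the
#' camera frame and perspective-divided onto the image plane. No lens
#' distortion is modelled; corner input to [estimate_planar_pose()] is
#' assumed pre-undistorted if a real lens deviates from the pinhole model.
#'
#' @param pose A [pose_estimate()].
#' @param marker A [marker_model()].
#' @param camera A [camera_model()].
#' @param timestamp Optional time in seconds carried into the observation.
#' @return A [marker_observation()]; invalid (with a `reason` attribute) if
#'   any corner lies behind the camera.
#' @export
project_marker <- function(pose, marker, camera, timestamp = NA_real_) {
  stopifnot(inherits(pose, "pose_estimate"), inherits(marker, "marker_model"),
            inherits(camera, "camera_model"))
  pc <- pose$rotation %*% t(marker$corners) + pose$translation  # 3 x 4
  if (any(pc[3, ] <= 0)) {
    obs <- marker_observation(matrix(NA_real_, 4, 2), timestamp, valid = FALSE)
    attr(obs, "reason") <- "corner behind camera"
    return(obs)
  }
  f <- camera$focal_length
  pp <- camera$principal_point
  px <- cbind(f * pc[1, ] / pc[3, ] + pp[1],
              f * pc[2, ] / pc[3, ] + pp[2])
  marker_observation(px, timestamp, valid = TRUE)
}

# area of the quadrilateral spanned by 4 corners (shoelace), px^2
quad_area <- function(corners) {
  x <- corners[, 1]; y <- corners[, 2]
  i2 <- c(2, 3, 4, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

# TRUE when any 3 of the 4 corners are (nearly) collinear
corners_degenerate <- function(corners, tol = 1e-9) {
  for (idx in utils::combn(4, 3, simplify = FALSE)) {
    p <- corners[idx, , drop = FALSE]
    cr <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
          (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])
    scale <- max(abs(p)) + 1
    if (abs(cr) <= tol * scale^2) return(TRUE)
  }
  FALSE
}

#' Estimate planar marker pose from one observation
#'
#' Planar perspective-n-point via direct linear transform: the homography
#' mapping marker-plane coordinates to intrinsics-normalized image
#' coordinates is solved from the 4 corner correspondences, then decomposed
#' into rotation and translation. The first two rotation columns come from
#' the scaled homography columns, the third from their cross product, and the
#' result is re-orthonormalized by projection onto the nearest rotation
#' (SVD). Translation is metric because the marker model is metric. No
#' iterative reprojection refinement is applied; at the marker image sizes
#' this setup produces (area above ~80,000 px^2) the direct solution is
#' accurate to well below 0.1 degree.
#'
#' @param obs A [marker_observation()].
#' @param marker A [marker_model()].
#' @param camera A [camera_model()].
#' @param condition_threshold Condition number of the DLT system above which
#'   the pose is flagged low-confidence (not dropped).
#' @return A [pose_estimate()].
#' @export
estimate_planar_pose <- function(obs, marker, camera,
                                 condition_threshold = 1e8) {
  stopifnot(inherits(obs, "marker_observation"),
            inherits(marker, "marker_model"),
            inherits(camera, "camera_model"))
  if (!isTRUE(obs$valid)) stop("cannot estimate pose from an invalid observation")
  if (corners_degenerate(obs$corners)) {
    stop("degenerate marker observation: corners are collinear")
  }
  f <- camera$focal_length
  pp <- camera$principal_point
  xn <- (obs$corners[, 1] - pp[1]) / f
  yn <- (obs$corners[, 2] - pp[2]) / f
  X <- marker$corners[, 1]
  Y <- marker$corners[, 2]
  # DLT with h33 = 1: rows [X Y 1 0 0 0 -x X -x Y] h = x, and the y analogue
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    A[2 * i - 1, ] <- c(X[i], Y[i], 1, 0, 0, 0, -xn[i] * X[i], -xn[i] * Y[i])
    A[2 * i, ]     <- c(0, 0, 0, X[i], Y[i], 1, -yn[i] * X[i], -yn[i] * Y[i])
    b[2 * i - 1] <- xn[i]
    b[2 * i]     <- yn[i]
  }
  kap <- kappa(A, exact = FALSE)
  h <- tryCatch(solve(A, b), error = function(e) {
    stop("ill-conditioned marker observation: ", conditionMessage(e))
  })
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  h1 <- H[, 1]; h2 <- H[, 2]; h3 <- H[, 3]
  lam <- 2 / (sqrt(sum(h1^2)) + sqrt(sum(h2^2)))
  if (lam * h3[3] < 0) lam <- -lam  # marker must be in front of the camera
  r1 <- lam * h1; r2 <- lam * h2
  Rapprox <- cbind(r1, r2, c(r1[2] * r2[3] - r1[3] * r2[2],
                             r1[3] * r2[1] - r1[1] * r2[3],
                             r1[1] * r2[2] - r1[2] * r2[1]))
  sv <- svd(Rapprox)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  pose_estimate(R, lam * h3, low_confidence = kap > condition_threshold)
}

#' Wrap angles to (-180, 180] degrees
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Head yaw from a marker pose
#'
#' Extracts the Z (optical axis) angle of the intrinsic Z-Y-X Euler
#' decomposition of the pose rotation and subtracts the reference yaw
#' measured while the participant fixates the room-corner zero target, giving
#' the head angle H in degrees wrapped to (-180, 180]. Positive H is a head
#' rotation toward the participant's left (counterclockwise seen from above,
#' with the camera and marker mounted as in the described setup).
#'
#' @param pose A [pose_estimate()].
#' @param reference_yaw Yaw (degrees) measured at the zero fixation.
#' @return Head yaw H in degrees.
#' @export
pose_to_head_yaw <- function(pose, reference_yaw = 0) {
  stopifnot(inherits(pose, "pose_estimate"))
  eul <- matrix_to_euler(pose$rotation)
  if (abs(eul["pitch"]) > 85) {
    stop("marker pitch is near gimbal lock (|pitch| > 85 deg); ",
         "yaw about the optical axis is unreliable - check the marker mounting")
  }
  unname(wrap_angle(eul["yaw"] - reference_yaw))
}

#' Estimate head yaw for a table of marker observations
#'
#' Vectorized convenience wrapper: runs [estimate_planar_pose()] and
#' [pose_to_head_yaw()] over a marker observation table (as read by
#' [read_marker_csv()]) and returns a pose table. Invalid observations yield
#' invalid rows rather than errors.
#'
#' @param markers Data frame with columns `timestamp`, `x0,y0,...,x3,y3`,
#'   `valid`.
#' @param marker A [marker_model()].
#' @param camera A [camera_model()].
#' @param reference_yaw Reference yaw in degrees subtracted from every frame;
#'   use [estimate_reference_yaw()] to obtain it from a zero-fixation episode.
#' @param min_area_px2 Marker image area (px^2) below which a frame's pose is
#'   flagged invalid (low confidence); pose error grows quickly for small
#'   marker images, and reliability is documented down to roughly 1500 px^2.
#' @return Data frame `timestamp, yaw_deg, pitch_deg, roll_deg, tx_m, ty_m,
#'   tz_m, valid` (yaw relative to `reference_yaw`).
#' @export
estimate_head_pose_series <- function(markers, marker, camera,
                                      reference_yaw = 0,
                                      min_area_px2 = 1500) {
  n <- nrow(markers)
  xs <- as.matrix(markers[, c("x0", "x1", "x2", "x3")])
  ys <- as.matrix(markers[, c("y0", "y1", "y2", "y3")])
  ok <- as.logical(markers$valid) &
    rowSums(!is.finite(xs) | !is.finite(ys)) == 0
  # image area (shoelace), vectorized: small markers give unreliable poses
  j <- c(2, 3, 4, 1)
  area <- abs(rowSums(xs * ys[, j] - xs[, j] * ys)) / 2
  f <- camera$focal_length
  pp <- camera$principal_point
  X <- marker$corners[, 1]
  Y <- marker$corners[, 2]
  A <- matrix(0, 8, 8)
  A[cbind(1:4 * 2 - 1, 1)] <- X; A[cbind(1:4 * 2 - 1, 2)] <- Y
  A[cbind(1:4 * 2 - 1, 3)] <- 1
  A[cbind(1:4 * 2, 4)] <- X; A[cbind(1:4 * 2, 5)] <- Y
  A[cbind(1:4 * 2, 6)] <- 1
  yaw <- pitch <- roll <- tx <- ty <- tz <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in which(ok)) {
    xn <- (xs[i, ] - pp[1]) / f
    yn <- (ys[i, ] - pp[2]) / f
    A[cbind(1:4 * 2 - 1, 7)] <- -xn * X; A[cbind(1:4 * 2 - 1, 8)] <- -xn * Y
    A[cbind(1:4 * 2, 7)] <- -yn * X; A[cbind(1:4 * 2, 8)] <- -yn * Y
    b <- as.numeric(rbind(xn, yn))
    h <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(h)) next
    H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
    lam <- 2 / (sqrt(sum(H[, 1]^2)) + sqrt(sum(H[, 2]^2)))
    if (lam * H[3, 3] < 0) lam <- -lam
    r1 <- lam * H[, 1]; r2 <- lam * H[, 2]
    Rapprox <- cbind(r1, r2, c(r1[2] * r2[3] - r1[3] * r2[2],
                               r1[3] * r2[1] - r1[1] * r2[3],
                               r1[1] * r2[2] - r1[2] * r2[1]))
    sv <- La.svd(Rapprox)
    R <- sv$u %*% diag(c(1, 1, det(sv$u) * det(t(sv$vt)))) %*% sv$vt
    p <- -asin(max(-1, min(1, R[3, 1])))
    if (abs(cos(p)) < 1e-8) next
    yaw[i] <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    pitch[i] <- p * 180 / pi
    roll[i] <- atan2(R[3, 2], R[3, 3]) * 180 / pi
    tx[i] <- lam * H[1, 3]; ty[i] <- lam * H[2, 3]; tz[i] <- lam * H[3, 3]
    valid[i] <- area[i] >= min_area_px2
  }
  data.frame(timestamp = markers$timestamp,
             yaw_deg = wrap_angle(yaw - reference_yaw), pitch_deg = pitch,
             roll_deg = roll, tx_m = tx, ty_m = ty, tz_m = tz,
             valid = valid)
}

#' Reference yaw from a zero-fixation episode
#'
#' Median raw marker yaw over a time window during which the participant
#' fixates the room-corner zero target; subtracting it zeroes the head
#' orientation signal.
#'
#' @param pose_series Pose table from [estimate_head_pose_series()] computed
#'   with `reference_yaw = 0`.
#' @param window Length-2 numeric, time window in seconds.
#' @return Reference yaw in degrees.
#' @export
estimate_reference_yaw <- function(pose_series, window) {
  sel <- pose_series$valid & pose_series$timestamp >= window[1] &
    pose_series$timestamp <= window[2]
  if (!any(sel)) stop("no valid poses inside the reference window")
  stats::median(pose_series$yaw_deg[sel])
}
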