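#' Rigid-body transforms
#'
#' A rigid transform is a distance-preserving map of 3-space, stored as a
#' 3x3 rotation matrix (orthonormal, determinant +1) and a translation
#' 3-vector in millimetres.  It models a change of head pose without
#' deformation: the head at time \code{t} occupies
#' \code{R p + t} for every point \code{p} of the head at reference time.
#'
#' @param rotation 3x3 numeric rotation matrix (dimensionless).
#' @param translation numeric 3-vector, millimetres.
#' @return An object of class \code{"rigid_transform"} with elements
#'   \code{R} (rotation) and \code{t} (translation).
#' @examples
#' rigid_transform(diag(3), c(1, 0, 0))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("non-finite entries in rigid transform")
  assert_rotation(rotation)
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

# Orthonormality / determinant check used on every constructed transform.
# Tolerance 1e-9 on ||R'R - I|| (max abs) and |det(R) - 1|.
assert_rotation <- function(R, tol = 1e-9) {
  dev <- max(abs(crossprod(R) - diag(3)))
  if (dev > tol || abs(det(R) - 1) > tol)
    stop(sprintf("matrix is not a rotation (orthonormality deviation %.3g)",
                 dev))
  invisible(dev)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  translation (mm):",
      paste(formatC(x$t, digits = 6, format = "fg"), collapse = ", "), "\n")
  p <- motion_params(x)
  cat("  rotation (deg, z-y-x Tait-Bryan): rx =",
      formatC(p$r_x, digits = 6, format = "fg"),
      " ry =", formatC(p$r_y, digits = 6, format = "fg"),
      " rz =", formatC(p$r_z, digits = 6, format = "fg"), "\n")
  invisible(x)
}

#' Elementary transforms
#'
#' Constructors for the identity, pure translations, and rotations about
#' single RAS axes (angles in degrees).
#'
#' @param x,y,z translation components in mm.
#' @param angle_deg rotation angle in degrees (right-handed about the axis).
#' @return A \code{rigid_transform}.
#' @name elementary-transforms
NULL

#' @rdname elementary-transforms
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @rdname elementary-transforms
#' @export
rt_translate <- function(x, y, z) rigid_transform(diag(3), c(x, y, z))

#' @rdname elementary-transforms
#' @export
rt_rot_x <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rigid_transform(matrix(c(1, 0, 0,
                           0, cos(a), -sin(a),
                           0, sin(a), cos(a)), 3, 3, byrow = TRUE))
}

#' @rdname elementary-transforms
#' @export
rt_rot_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rigid_transform(matrix(c(cos(a), 0, sin(a),
                           0, 1, 0,
                           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE))
}

#' @rdname elementary-transforms
#' @export
rt_rot_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rigid_transform(matrix(c(cos(a), -sin(a), 0,
                           sin(a), cos(a), 0,
                           0, 0, 1), 3, 3, byrow = TRUE))
}

#' Compose two rigid transforms
#'
#' Returns the transform that applies \code{B} first and then \code{A}
#' (matrix convention \code{A \%*\% B}).  If floating-point drift pushes the
#' composed rotation's orthonormality deviation above 1e-9 it is projected
#' back onto the nearest rotation.
#'
#' @param A,B rigid transforms.
#' @return A \code{rigid_transform}.
#' @export
rt_compose <- function(A, B) {
  stopifnot(inherits(A, "rigid_transform"), inherits(B, "rigid_transform"))
  R <- A$R %*% B$R
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    R <- nearest_rotation(R)
  rigid_transform(R, as.numeric(A$R %*% B$t) + A$t)
}

#' Invert a rigid transform
#' @param T a rigid transform.
#' @return The inverse \code{rigid_transform}.
#' @export
rt_invert <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  Rt <- t(T$R)
  rigid_transform(Rt, as.numeric(-Rt %*% T$t))
}

#' Apply a rigid transform to a point
#'
#' Computes \code{R p + t}, the image of the point under the head's pose
#' change.
#'
#' @param T a rigid transform.
#' @param p numeric 3-vector (mm).
#' @return Numeric 3-vector (mm).
#' @export
rt_apply <- function(T, p) {
  stopifnot(inherits(T, "rigid_transform"))
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p)))
    stop("point must be a finite 3-vector")
  as.numeric(T$R %*% p) + T$t
}

#' Project a near-rotation matrix onto the nearest rotation
#'
#' Orthogonal Procrustes projection via SVD; the determinant is forced to
#' +1 so reflections are never returned.
#'
#' @param M a 3x3 matrix close to a rotation.
#' @return A 3x3 rotation matrix.
#' @export
nearest_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Decompose a rigid transform into six motion parameters
#'
#' The translation is reported verbatim in mm.  Angles are the Tait-Bryan
#' angles of the factorization \code{R = Rz(r_z) Ry(r_y) Rx(r_x)}, in
#' degrees, each in (-180, 180].  Near gimbal lock (|r_y| -> 90 deg) the
#' canonical solution with \code{r_x = 0} is returned and flagged via the
#' \code{gimbal_lock} field.
#'
#' @param x a \code{rigid_transform} (or a \code{pose_trace}; see
#'   \code{\link{motion_params.pose_trace}}).
#' @param ... passed to methods.
#' @return For a single transform, a one-row data frame with columns
#'   \code{t_x, t_y, t_z} (mm), \code{r_x, r_y, r_z} (deg) and
#'   \code{gimbal_lock} (logical).
#' @examples
#' motion_params(rt_rot_x(2))
#' @export
motion_params <- function(x, ...) UseMethod("motion_params")

#' @export
motion_params.rigid_transform <- function(x, ...) {
  ang <- rotmat_to_zyx_angles(x$R)
  data.frame(t_x = x$t[1], t_y = x$t[2], t_z = x$t[3],
             r_x = ang[1], r_y = ang[2], r_z = ang[3],
             gimbal_lock = attr(ang, "gimbal_lock"))
}

# ZYX (Tait-Bryan) extraction for a single rotation matrix, degrees.
# R = Rz Ry Rx  =>  R[3,1] = -sin(ry), R[3,2] = cos(ry) sin(rx),
# R[3,3] = cos(ry) cos(rx), R[2,1] = sin(rz) cos(ry), R[1,1] = cos(rz) cos(ry)
rotmat_to_zyx_angles <- function(R, lock_tol = 1e-9) {
  sy <- -R[3, 1]
  sy <- min(1, max(-1, sy))
  if (1 - abs(sy) < lock_tol) {
    # gimbal lock: only rz +/- rx identifiable; absorb into rz, set rx = 0
    ry <- 90 * sign(sy)
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2]) * 180 / pi
    lock <- TRUE
  } else {
    ry <- asin(sy) * 180 / pi
    rx <- atan2(R[3, 2], R[3, 3]) * 180 / pi
    rz <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    lock <- FALSE
  }
  structure(canonical_angle(c(rx, ry, rz)), gimbal_lock = lock)
}

# map angles into (-180, 180]
canonical_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' Rebuild a rigid transform from six motion parameters
#'
#' Inverse of \code{\link{motion_params}}: the rotation is
#' \code{Rz(r_z) Ry(r_y) Rx(r_x)} (angles in degrees), the translation is
#' taken verbatim.  Round-tripping through \code{motion_params} reproduces
#' the transform to 1e-9.
#'
#' @param t_x,t_y,t_z translation components, mm.
#' @param r_x,r_y,r_z Tait-Bryan angles, degrees.
#' @return A \code{rigid_transform}.
#' @export
rt_from_params <- function(t_x = 0, t_y = 0, t_z = 0,
                           r_x = 0, r_y = 0, r_z = 0) {
  R <- rt_rot_z(r_z)$R %*% rt_rot_y(r_y)$R %*% rt_rot_x(r_x)$R
  rigid_transform(R, c(t_x, t_y, t_z))
}

## ---- quaternion helpers (scalar-first, unit) --------------------------
## Used at the I/O boundary (pose logs store unit quaternions so rigidity
## is enforceable at parse time) and by the simulator.  All are vectorized
## over rows of an n x 4 matrix.

quat_normalize <- function(q) q / sqrt(rowSums(q^2))

quat_multiply <- function(a, b) {
  # Hamilton product, row-wise; a, b are n x 4 (w, x, y, z)
  cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
        a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
        a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
        a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

quat_rotate <- function(q, v) {
  # rotate row-vectors v (n x 3) by unit quaternions q (n x 4)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 q_vec x v ; v' = v + w t + q_vec x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(vx + w * tx + y * tz - z * ty,
        vy + w * ty + z * tx - x * tz,
        vz + w * tz + x * ty - y * tx)
}

quat_to_rotarray <- function(q) {
  # n x 4 unit quaternions -> 3 x 3 x n rotation array
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  n <- nrow(q)
  A <- array(0, c(3, 3, n))
  A[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  A[1, 2, ] <- 2 * (x * y - w * z)
  A[1, 3, ] <- 2 * (x * z + w * y)
  A[2, 1, ] <- 2 * (x * y + w * z)
  A[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  A[2, 3, ] <- 2 * (y * z - w * x)
  A[3, 1, ] <- 2 * (x * z - w * y)
  A[3, 2, ] <- 2 * (y * z + w * x)
  A[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  A
}

rotmat_to_quat <- function(R) {
  # Shepperd's method, single matrix -> (w, x, y, z) with w >= 0
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# axis-angle quaternions for a single fixed axis, vectorized over angles (rad)
quat_about_axis <- function(axis, angle_rad) {
  h <- angle_rad / 2
  u <- axis / sqrt(sum(axis^2))
  cbind(cos(h), sin(h) * u[1], sin(h) * u[2], sin(h) * u[3])
}

## ---- vectorized rotation-array utilities ------------------------------

rotarray_multiply_fixed <- function(A, M, side = c("right", "left")) {
  # A: 3x3xn, M: 3x3 fixed.  right: A[,,i] %*% M ; left: M %*% A[,,i]
  side <- match.arg(side)
  out <- array(0, dim(A))
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:3) {
      acc <- acc + if (side == "right") A[i, k, ] * M[k, j]
                   else                 M[i, k] * A[k, j, ]
    }
    out[i, j, ] <- acc
  }
  out
}

rotarray_apply <- function(A, tr, p) {
  # positions of fixed point p under each sample: A[,,i] %*% p + tr[i, ]
  cbind(A[1, 1, ] * p[1] + A[1, 2, ] * p[2] + A[1, 3, ] * p[3] + tr[, 1],
        A[2, 1, ] * p[1] + A[2, 2, ] * p[2] + A[2, 3, ] * p[3] + tr[, 2],
        A[3, 1, ] * p[1] + A[3, 2, ] * p[2] + A[3, 3, ] * p[3] + tr[, 3])
}

rotarray_to_zyx_angles <- function(A, lock_tol = 1e-9) {
  # vectorized ZYX extraction; returns n x 3 (deg) + gimbal_lock attr
  sy <- pmin(1, pmax(-1, -A[3, 1, ]))
  lock <- (1 - abs(sy)) < lock_tol
  rx <- atan2(A[3, 2, ], A[3, 3, ]) * 180 / pi
  ry <- asin(sy) * 180 / pi
  rz <- atan2(A[2, 1, ], A[1, 1, ]) * 180 / pi
  if (any(lock)) {
    rx[lock] <- 0
    ry[lock] <- 90 * sign(sy[lock])
    rz[lock] <- atan2(-A[1, 2, lock], A[2, 2, lock]) * 180 / pi
  }
  structure(cbind(r_x = canonical_angle(rx),
                  r_y = canonical_angle(ry),
                  r_z = canonical_angle(rz)),
            gimbal_lock = lock)
}
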