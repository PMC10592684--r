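# Rigid-body transforms, Kabsch superposition, Euler decomposition and the
# 6-D transform hash used for pose clustering.

#' Construct a rigid-body transform
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) followed by a translation in Angstroms. Applied to a
#' row-vector coordinate matrix `X` it computes `X %*% t(R) + t`.
#'
#' @param R 3x3 rotation matrix.
#' @param t translation vector of length 3 (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- unname(as.matrix(R))
  t <- unname(as.numeric(t))
  if (!all(dim(R) == c(3L, 3L)) || length(t) != 3L) {
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  }
  if (!is_rotation_matrix(R)) {
    stop("rotation matrix is not orthonormal with determinant +1")
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

is_rotation_matrix <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  R:\n")
  print(round(x$R, 6))
  cat("  t:", paste(sprintf("%.4f", x$t), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param tf `rigid_transform`.
#' @return Transformed n x 3 matrix.
#' @export
transform_points <- function(xyz, tf) {
  xyz <- as.matrix(xyz)
  out <- xyz %*% t(tf$R)
  out[, 1] <- out[, 1] + tf$t[1]
  out[, 2] <- out[, 2] + tf$t[2]
  out[, 3] <- out[, 3] + tf$t[3]
  out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first and then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tf `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$R)
  rigid_transform(Rt, as.numeric(-Rt %*% tf$t))
}

#' Rotation about an arbitrary axis
#'
#' @param axis length-3 axis (need not be normalized).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rot_z <- function(deg) rotation_about_axis(c(0, 0, 1), deg)

# Rotation taking the +z axis onto `axis` (shortest arc).
align_z_to <- function(axis) {
  u <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2],
         z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(z * u)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about x
    return(rotation_about_axis(c(1, 0, 0), 180))
  }
  rotation_about_axis(v, atan2(s, c_) * 180 / pi)
}

#' RMSD between two coordinate sets in the same frame (no superposition)
#' @param X,Y n x 3 matrices with corresponding rows.
#' @export
coord_rmsd <- function(X, Y) {
  d <- as.matrix(X) - as.matrix(Y)
  sqrt(mean(rowSums(d * d)))
}

#' Optimal superposition by the Kabsch algorithm
#'
#' Finds the rigid transform minimizing the RMSD of `transform_points(X, tf)`
#' against `Y`. The rotation is constrained to be proper (determinant +1,
#' no reflection).
#'
#' @param X,Y n x 3 coordinate matrices (n >= 3) with corresponding rows.
#' @return list with `transform` (a `rigid_transform`) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n != nrow(Y)) stop("point counts differ")
  if (n < 3L) stop("at least 3 points are required")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  sx <- svd(Xc)$d
  if (sx[2] < 1e-8 * max(sx[1], 1e-8)) {
    stop("degenerate geometry: points are collinear or coincident")
  }
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cy - as.numeric(R %*% cx)
  dev <- Xc %*% t(R) - Yc
  list(transform = rigid_transform(R, tr),
       rmsd = sqrt(mean(rowSums(dev * dev))))
}

# z-y-z Euler angles (degrees, canonicalized to [0, 360)).
# Gimbal-lock orientations (beta = 0 or 180) resolve deterministically with
# gamma = 0 and all in-plane rotation assigned to alpha.
euler_zyz <- function(R) {
  cb <- min(1, max(-1, R[3, 3]))
  b <- acos(cb)
  if (sin(b) > 1e-9) {
    a <- atan2(R[2, 3], R[1, 3])
    g <- atan2(R[3, 2], -R[3, 1])
  } else if (cb > 0) {
    b <- 0
    g <- 0
    a <- atan2(R[2, 1], R[1, 1])
  } else {
    b <- pi
    g <- 0
    a <- atan2(-R[2, 1], -R[1, 1])
  }
  ang <- c(a, b, g) * 180 / pi
  ang %% 360
}

#' 6-D transform hash
#'
#' Bins a rigid transform into six integers: three translation bins and
#' three z-y-z Euler-angle bins. Identical transforms always map to the
#' same key; transforms within half a bin of each other in every dimension
#' differ by at most one per dimension.
#'
#' @param tf `rigid_transform`.
#' @param translation_bin bin width for translations (Angstrom).
#' @param angle_bin bin width for Euler angles (degrees).
#' @return Integer vector of length 6 (tx, ty, tz, alpha, beta, gamma bins).
#' @export
transform_hash <- function(tf, translation_bin = 1, angle_bin = 3) {
  stopifnot(translation_bin > 0, angle_bin > 0)
  ang <- euler_zyz(tf$R)
  key <- c(floor(tf$t / translation_bin), floor(ang / angle_bin))
  as.integer(key)
}
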