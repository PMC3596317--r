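#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1) and translation minimizing the
#' RMSD between paired coordinate sets, via singular value decomposition of
#' the covariance matrix.
#'
#' @param mobile n x 3 matrix of coordinates to be moved.
#' @param reference n x 3 matrix of target coordinates, row-paired with
#'   \code{mobile}.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3,
#'   applied after rotation), and \code{rmsd} (post-fit, Angstrom). The
#'   fitted coordinates are \code{mobile \%*\% t(rotation) + translation}.
#' @export
kabschSuperpose <- function(mobile, reference) {
    mobile <- as.matrix(mobile); reference <- as.matrix(reference)
    if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3)
        stop("coordinate sets must be paired n x 3 matrices")
    if (nrow(mobile) < 3) stop("need at least 3 points for superposition")
    cm <- colMeans(mobile); cr <- colMeans(reference)
    A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
    H <- t(A) %*% B
    sv <- svd(H)
    if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12))
        stop("degenerate fit: points are (nearly) collinear")
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    fitted <- A %*% t(R)
    rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
    list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector added after rotation.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(xyz, rotation, translation = c(0, 0, 0)) {
    sweep(as.matrix(xyz) %*% t(rotation), 2, -translation)
}

#' RMSD without superposition
#' @param a,b paired n x 3 coordinate matrices.
#' @return root-mean-square deviation in Angstrom.
#' @export
rmsdNoFit <- function(a, b) {
    a <- as.matrix(a); b <- as.matrix(b)
    if (nrow(a) != nrow(b)) stop("coordinate pairing mismatch: ",
                                 nrow(a), " vs ", nrow(b), " points")
    sqrt(mean(rowSums((a - b)^2)))
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: 0 for cis, 180 for trans; result in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return dihedral angle in degrees.
#' @export
measureDihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 || sqrt(sum(b3^2)) < 1e-9)
        stop("undefined dihedral: consecutive points coincide")
    n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
    if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
        stop("undefined dihedral: collinear points")
    m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
    ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
    if (ang <= -180) ang <- ang + 360
    ang
}

.cross3 <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
}

# Rotation matrix from axis (unit not required) and angle in degrees.
.rotation_about <- function(axis, angle_deg) {
    a <- axis / sqrt(sum(axis^2))
    th <- angle_deg * pi / 180
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation matrix from a rotation vector (axis * angle in radians).
.rotation_from_vector <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    .rotation_about(v / th, th * 180 / pi)
}

# Uniform random rotation via quaternion.
.random_rotation <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
}
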