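# --- internal helpers ---------------------------------------------------

DEG <- pi / 180

deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 10)
    stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# single-axis rotation matrix, column convention (maps local coords to
# parent coords; columns are the images of the basis vectors)
axis_rot <- function(axis, angle_deg) {
  a <- deg2rad(angle_deg)
  ca <- cos(a); sa <- sin(a)
  switch(toupper(axis),
    X = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L, 3L),
    Y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3L, 3L),
    Z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L),
    stop("axis label must be one of 'X', 'Y', 'Z'", call. = FALSE))
}

# --- orientation --------------------------------------------------------

#' Create an orientation (relative rotation matrix, row convention)
#'
#' An orientation encodes the pose of the distal anatomical coordinate
#' system (ACS) in the proximal ACS.  Row `i` of the matrix is the unit
#' endpoint of the distal frame's i-th axis (X, Y, Z) expressed in
#' proximal-frame coordinates, so plotting the rows directly gives the
#' frame trace on the unit sphere.
#'
#' @param m a 3x3 proper rotation matrix (orthonormal rows, determinant +1
#'   within `tol`).
#' @param tol validation tolerance for orthonormality and determinant.
#' @return an object of class `"orientation"` (a 3x3 matrix).
#' @examples
#' orientation(diag(3))
#' from_euler(c(30, 0, 0), sequence = "ZYX")
#' @export
orientation <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  chk <- validate_orientation(m, tol = tol)
  if (!chk$pass)
    stop(sprintf(
      "not a proper rotation matrix (orthonormality residual %.3g, det - 1 = %.3g, tol %.1g)",
      chk$orthonormality, chk$determinant - 1, tol), call. = FALSE)
  structure(m, class = "orientation")
}

#' Validate a candidate rotation matrix
#'
#' Always returns a report rather than throwing: the maximum absolute
#' off-unit / off-orthogonal entry of `m %*% t(m) - I`, the determinant,
#' and a pass flag at tolerance `tol`.
#'
#' @param m any 3x3 numeric matrix.
#' @param tol pass/fail tolerance.
#' @return a list with elements `orthonormality` (residual),
#'   `determinant`, `pass`.
#' @export
validate_orientation <- function(m, tol = 1e-9) {
  m <- unclass(as.matrix(m))
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)) || anyNA(m))
    return(list(orthonormality = Inf, determinant = NA_real_, pass = FALSE))
  res <- max(abs(m %*% t(m) - diag(3)))
  d <- det(m)
  list(orthonormality = res, determinant = d,
       pass = res <= tol && abs(d - 1) <= tol)
}

#' @export
print.orientation <- function(x, ...) {
  cat("orientation (rows = distal axis endpoints in the proximal frame)\n")
  print(unclass(x), ...)
  invisible(x)
}

# --- Euler sequences ----------------------------------------------------

parse_sequence <- function(sequence) {
  ax <- strsplit(toupper(sequence), "")[[1L]]
  if (length(ax) < 1L || !all(ax %in% c("X", "Y", "Z")))
    stop("Euler sequence must be a string of axis labels from {X, Y, Z}",
         call. = FALSE)
  if (length(ax) > 1L && any(ax[-1L] == ax[-length(ax)]))
    stop(sprintf("invalid Euler sequence '%s': consecutive axis labels must differ",
                 sequence), call. = FALSE)
  ax
}

#' Compose an orientation from an Euler-angle sequence
#'
#' The default convention is intrinsic Z-Y-X with Z as the
#' flexion/extension axis, the assignment commonly used for limb joints;
#' both the sequence and the intrinsic/extrinsic flag are configurable
#' because conventions vary between studies.
#'
#' @param angles numeric vector of rotation angles in degrees, one per
#'   letter of `sequence`, applied in the listed order.
#' @param sequence axis labels, e.g. `"ZYX"`, `"XY"`, `"Z"`; consecutive
#'   labels must differ.
#' @param intrinsic logical; `TRUE` (default) rotates about the moving
#'   frame's axes, `FALSE` about the fixed parent axes.
#' @return an [orientation()].
#' @export
from_euler <- function(angles, sequence = "ZYX", intrinsic = TRUE) {
  ax <- parse_sequence(sequence)
  if (length(angles) != length(ax))
    stop(sprintf("expected %d angles for sequence '%s', got %d",
                 length(ax), sequence, length(angles)), call. = FALSE)
  r <- diag(3)
  for (i in seq_along(ax)) {
    ri <- axis_rot(ax[i], angles[i])
    r <- if (intrinsic) r %*% ri else ri %*% r
  }
  # column-convention composite -> row convention
  orientation(t(r))
}

# --- quaternions --------------------------------------------------------

#' Convert an orientation to a unit quaternion
#'
#' The quaternion represents the frame rotation taking the proximal axes
#' onto the distal axes.  It is canonicalised to the hemisphere with
#' `w >= 0`; when `w == 0` the first nonzero vector component is made
#' positive, so every rotation has a unique representative.
#'
#' @param o an [orientation()] (or 3x3 rotation matrix).
#' @return named numeric vector `c(w, x, y, z)` with unit norm.
#' @export
to_quaternion <- function(o) {
  o <- orientation(o)
  r <- t(unclass(o))                 # column convention
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  # Shepperd's method: pick the largest of w^2, x^2, y^2, z^2
  if (tr >= r[1, 1] && tr >= r[2, 2] && tr >= r[3, 3]) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4,
           (r[3, 2] - r[2, 3]) / s,
           (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] >= r[2, 2] && r[1, 1] >= r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s,
           s / 4,
           (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] >= r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s,
           (r[1, 2] + r[2, 1]) / s,
           s / 4,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s,
           (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s,
           s / 4)
  }
  q <- q / vnorm(q)
  q <- canonical_quat(q)
  names(q) <- c("w", "x", "y", "z")
  q
}

canonical_quat <- function(q, tol = 1e-12) {
  if (q[1L] < -tol) return(-q)
  if (abs(q[1L]) <= tol) {
    v <- q[2:4]
    nz <- which(abs(v) > tol)
    if (length(nz) && v[nz[1L]] < 0) return(-q)
  }
  q
}

#' Convert a unit quaternion to an orientation
#'
#' @param q numeric vector `c(w, x, y, z)`; must have unit norm within
#'   `tol`.
#' @param tol norm tolerance.
#' @return an [orientation()].
#' @export
from_quaternion <- function(q, tol = 1e-9) {
  q <- as.numeric(q)
  if (length(q) != 4L || anyNA(q))
    stop("quaternion must be a numeric vector (w, x, y, z)", call. = FALSE)
  if (abs(vnorm(q) - 1) > tol)
    stop(sprintf("quaternion norm %.12g is not 1 within %.1g", vnorm(q), tol),
         call. = FALSE)
  q <- q / vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  r <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
    3L, 3L, byrow = TRUE)               # column convention
  orientation(t(r))
}

#' Rotation axis and angle of an orientation
#'
#' Returns the unit rotation axis (the normalised vector part of the pose
#' quaternion) and the rotation angle in degrees.  With the `w >= 0`
#' quaternion convention the angle is always in (0, 180] and a negative
#' rotation about an axis is reported as a positive rotation about the
#' negated axis.
#'
#' @param o an [orientation()].
#' @param tol identity tolerance in degrees: angles below it are treated
#'   as the identity, whose axis is undefined.
#' @return list with `axis` (unit 3-vector) and `angle` (degrees).
#' @export
rotation_axis <- function(o, tol = 1e-7) {
  q <- to_quaternion(o)
  ang <- rad2deg(2 * atan2(vnorm(q[2:4]), q[1L]))
  if (ang <= tol)
    stop("rotation axis is undefined for the identity orientation (angle 0)",
         call. = FALSE)
  list(axis = unname(q[2:4] / vnorm(q[2:4])), angle = unname(ang))
}

# --- orientation sets ---------------------------------------------------

#' Construct an orientation set
#'
#' The basic range-of-motion dataset: an ordered collection of
#' orientations, optionally time-stamped, stored internally as a 3x3xn
#' array.
#'
#' @param x a list of [orientation()]s/3x3 matrices, a single orientation,
#'   or a 3x3xn array.
#' @param timestamps optional numeric vector of sample times in seconds.
#' @param label provenance label carried through downstream objects.
#' @param tol per-item validation tolerance.
#' @return object of class `"orientation_set"`.
#' @export
orientation_set <- function(x, timestamps = NULL, label = "", tol = 1e-9) {
  if (is.matrix(x) && identical(dim(x), c(3L, 3L))) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!identical(dim(x)[1:2], c(3L, 3L)))
      stop("array input must be 3 x 3 x n", call. = FALSE)
    x <- lapply(seq_len(dim(x)[3L]), function(i) x[, , i])
  }
  if (!is.list(x) || length(x) == 0L)
    stop("an orientation set must contain at least one orientation",
         call. = FALSE)
  for (i in seq_along(x)) {
    chk <- validate_orientation(x[[i]], tol = tol)
    if (!chk$pass)
      stop(sprintf("item %d is not a valid orientation (orthonormality residual %.3g, det %.6g)",
                   i, chk$orthonormality, chk$determinant), call. = FALSE)
  }
  if (!is.null(timestamps) && length(timestamps) != length(x))
    stop("timestamps must match the number of orientations", call. = FALSE)
  arr <- array(unlist(lapply(x, unclass)), dim = c(3L, 3L, length(x)))
  structure(list(rotations = arr, timestamps = timestamps, label = label),
            class = "orientation_set")
}

#' @export
length.orientation_set <- function(x) dim(x$rotations)[3L]

#' @export
`[.orientation_set` <- function(x, i) {
  orientation_set(x$rotations[, , i, drop = FALSE],
                  timestamps = if (!is.null(x$timestamps)) x$timestamps[i],
                  label = x$label)
}

#' @export
`[[.orientation_set` <- function(x, i) {
  structure(x$rotations[, , i], class = "orientation")
}

#' @export
print.orientation_set <- function(x, ...) {
  cat(sprintf("orientation set: %d orientations%s%s\n", length(x),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              if (!is.null(x$timestamps)) ", time-stamped" else ""))
  invisible(x)
}

#' Apply a global rotation to every orientation in a set
#'
#' Re-expresses the whole dataset in a proximal frame rotated by `g`:
#' every traced axis endpoint `p` becomes `g %*% p`, so the frame trace
#' and any fitted polygons rotate rigidly with `g`.
#'
#' @param x an [orientation_set()].
#' @param g a 3x3 rotation (column convention: maps old proximal coords
#'   to new).
#' @return a new orientation set.
#' @export
rotate_set <- function(x, g) {
  stopifnot(inherits(x, "orientation_set"))
  chk <- validate_orientation(g)
  if (!chk$pass) stop("g must be a proper rotation matrix", call. = FALSE)
  g <- unclass(as.matrix(g))
  arr <- x$rotations
  out <- array(0, dim = dim(arr))
  for (i in seq_len(dim(arr)[3L])) out[, , i] <- arr[, , i] %*% t(g)
  orientation_set(out, timestamps = x$timestamps, label = x$label)
}

#' Geodesic distance between two orientations
#'
#' The angle (degrees) of the relative rotation taking `a` to `b`; the
#' natural metric on rotation space, free of the distortion of
#' Euler-space distances.
#'
#' @param a,b orientations.
#' @return angle in degrees, in \code{[0, 180]}.
#' @export
rotation_distance <- function(a, b) {
  ra <- unclass(orientation(a)); rb <- unclass(orientation(b))
  rel <- ra %*% t(rb)
  cosang <- (sum(diag(rel)) - 1) / 2
  rad2deg(acos(max(-1, min(1, cosang))))
}
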