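# Homogeneous rigid-transform algebra and the marker-to-joint chain:
# from motion-capture rigid-body poses to the joint-centric orientation
# that the SFP consumes.

#' Construct a 4x4 homogeneous rigid transform
#'
#' `T = [R t; 0 1]` maps homogeneous coordinates from one frame to
#' another; in the frame notation used throughout, `A_T_B` maps
#' B-frame coordinates into frame A.  Lengths are millimetres by
#' convention.
#'
#' @param r 3x3 proper rotation block, or a full 4x4 matrix (then `t` is
#'   ignored).
#' @param t length-3 translation (mm).
#' @param tol validation tolerance.
#' @return object of class `"rigid_transform"` (a 4x4 matrix).
#' @export
rigid_transform <- function(r = diag(3), t = c(0, 0, 0), tol = 1e-9) {
  if (is.matrix(r) && all(dim(r) == c(4L, 4L))) {
    m <- unclass(r)
  } else {
    m <- diag(4)
    m[1:3, 1:3] <- as.matrix(r)
    m[1:3, 4L] <- as.numeric(t)
  }
  chk <- validate_transform(m, tol = tol)
  if (!chk$pass)
    stop(sprintf("invalid rigid transform: %s", chk$reason), call. = FALSE)
  structure(m, class = "rigid_transform")
}

#' Validate a 4x4 homogeneous transform
#'
#' @param m any 4x4 matrix.
#' @param tol tolerance for rotation orthonormality / determinant and
#'   the bottom row.
#' @return list with `pass`, `reason`, `rotation_residual`.
#' @export
validate_transform <- function(m, tol = 1e-9) {
  m <- unclass(as.matrix(m))
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)) || anyNA(m))
    return(list(pass = FALSE, reason = "not a numeric 4x4 matrix",
                rotation_residual = Inf))
  if (max(abs(m[4L, ] - c(0, 0, 0, 1))) > tol)
    return(list(pass = FALSE, reason = "bottom row is not (0, 0, 0, 1)",
                rotation_residual = Inf))
  chk <- validate_orientation(m[1:3, 1:3], tol = tol)
  if (!chk$pass)
    return(list(pass = FALSE,
                reason = sprintf("rotation block is not a proper rotation (residual %.3g, det %.6g)",
                                 chk$orthonormality, chk$determinant),
                rotation_residual = chk$orthonormality))
  list(pass = TRUE, reason = "", rotation_residual = chk$orthonormality)
}

#' Exact inverse of a rigid transform
#'
#' The rotation block is transposed and the translation becomes
#' `-R^T t`.  (For a homogeneous matrix the plain matrix transpose
#' equals the inverse only when the translation is zero; the exact form
#' is used here so the full chain is correct for arbitrary rig
#' offsets, while the extracted rotational component is unaffected
#' either way.)
#'
#' @param x a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(x) {
  m <- unclass(rigid_transform(x))
  r <- m[1:3, 1:3]
  out <- diag(4)
  out[1:3, 1:3] <- t(r)
  out[1:3, 4L] <- -t(r) %*% m[1:3, 4L]
  structure(out, class = "rigid_transform")
}

#' @export
solve.rigid_transform <- function(a, b, ...) {
  if (missing(b)) invert_transform(a) else solve(unclass(a), b, ...)
}

#' Compose rigid transforms left to right
#'
#' `compose_transforms(A_T_B, B_T_C)` returns `A_T_C`.
#'
#' @param ... rigid transforms (or 4x4 matrices).
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(...) {
  ts <- list(...)
  m <- Reduce(`%*%`, lapply(ts, function(x) unclass(rigid_transform(x))))
  rigid_transform(m)
}

#' Apply a rigid transform to 3D points
#'
#' @param x a [rigid_transform()].
#' @param p n x 3 matrix (or 3-vector) of points.
#' @return transformed points, same shape.
#' @export
transform_points <- function(x, p) {
  m <- unclass(rigid_transform(x))
  single <- is.null(dim(p))
  if (single) p <- matrix(p, 1L)
  out <- p %*% t(m[1:3, 1:3]) + matrix(m[1:3, 4L], nrow(p), 3L, byrow = TRUE)
  if (single) out[1L, ] else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform (rotation | translation mm):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Joint orientation from the marker-to-joint transform chain
#'
#' Implements the capture-rig chain: the proximal anatomical frame is
#' located in the base (global) frame through its mounting plate,
#' `pACS_T_base = pACS_T_pPlate %*% pPlate_T_base`, the distal frame is
#' located in the marker frame through its plate,
#' `dACS_T_markers = dACS_T_dPlate %*% dPlate_T_markers`, and the
#' time-varying marker pose closes the chain:
#' `dACS_T_pACS = dACS_T_markers %*% markers_T_base %*% base_T_pACS`.
#' Only the rotational component is returned - the orientation of the
#' distal ACS in the proximal ACS, which is exactly what the SFP plots -
#' so the result is invariant to every translational offset in the
#' chain.
#'
#' @param markers_T_base per-frame marker rigid-body pose (maps base
#'   coords to marker coords).
#' @param pACS_T_pPlate,pPlate_T_base proximal side of the chain.
#' @param dACS_T_dPlate,dPlate_T_markers distal side of the chain.
#' @return an [orientation()] (the rotation block of `dACS_T_pACS`).
#' @export
joint_orientation <- function(markers_T_base, pACS_T_pPlate, pPlate_T_base,
                              dACS_T_dPlate, dPlate_T_markers) {
  args <- list(markers_T_base = markers_T_base,
               pACS_T_pPlate = pACS_T_pPlate,
               pPlate_T_base = pPlate_T_base,
               dACS_T_dPlate = dACS_T_dPlate,
               dPlate_T_markers = dPlate_T_markers)
  for (nm in names(args)) {
    chk <- validate_transform(unclass(as.matrix(args[[nm]])))
    if (!chk$pass)
      stop(sprintf("invalid transform '%s': %s", nm, chk$reason),
           call. = FALSE)
  }
  pACS_T_base <- compose_transforms(pACS_T_pPlate, pPlate_T_base)
  base_T_pACS <- invert_transform(pACS_T_base)
  dACS_T_markers <- compose_transforms(dACS_T_dPlate, dPlate_T_markers)
  dACS_T_pACS <- compose_transforms(dACS_T_markers, markers_T_base,
                                    base_T_pACS)
  orientation(unclass(dACS_T_pACS)[1:3, 1:3])
}

# --- frame fitting ------------------------------------------------------

#' Recursive cross-product orthogonalisation of a near-orthogonal triad
#'
#' Iteratively replaces each axis by the normalised average of itself
#' and the (sign-matched) cross product of the other two, cycling
#' through the axes, until every pairwise dot product is zero within
#' `tol`.  Each cross product is orthogonal to the other two axes, so
#' the averaging attracts or repels each axis marginally in turn and the
#' residual contracts rapidly near orthogonality.
#'
#' @param axes 3x3 matrix, rows = three near-orthogonal unit vectors
#'   (pairwise |dot| must be below 0.5).
#' @param tol convergence tolerance on the maximum pairwise |dot|
#'   (default 1e-12).
#' @param max_iter iteration cap.
#' @param handedness `"correct"` (default) flips the third axis of a
#'   left-handed input before iterating; `"reject"` errors instead.
#' @return 3x3 matrix of exactly orthonormal, right-handed rows, with
#'   attributes `iterations` and `residual`.
#' @export
orthogonalise <- function(axes, tol = 1e-12, max_iter = 10000L,
                          handedness = c("correct", "reject")) {
  handedness <- match.arg(handedness)
  a <- as.matrix(axes)
  if (!identical(dim(a), c(3L, 3L)) || anyNA(a))
    stop("axes must be a numeric 3x3 matrix (rows = axes)", call. = FALSE)
  a <- a / sqrt(rowSums(a^2))
  dots <- function(a) max(abs(c(sum(a[1, ] * a[2, ]), sum(a[1, ] * a[3, ]),
                                sum(a[2, ] * a[3, ]))))
  if (dots(a) >= 0.5)
    stop("input axes are too far from orthogonal (pairwise |dot| >= 0.5)",
         call. = FALSE)
  if (det(a) < 0) {
    if (handedness == "reject")
      stop("input triad is left-handed", call. = FALSE)
    a[3L, ] <- -a[3L, ]
  }
  it <- 0L
  res <- dots(a)
  while (res > tol && it < max_iter) {
    a <- ortho_step(a, it %% 3L + 1L)
    it <- it + 1L
    res <- dots(a)
  }
  if (res > tol)
    stop(sprintf("orthogonalisation did not converge in %d iterations (residual %.3g)",
                 max_iter, res), call. = FALSE)
  structure(a, iterations = it, residual = res)
}

# one orthogonalisation step: replace axis i by the normalised average
# of itself and the sign-matched cross product of the other two
ortho_step <- function(a, i) {
  jk <- switch(i, c(2L, 3L), c(3L, 1L), c(1L, 2L))
  cp <- cross3(a[jk[1L], ], a[jk[2L], ])
  cp <- cp / vnorm(cp)
  if (sum(cp * a[i, ]) < 0) cp <- -cp
  a[i, ] <- unitize((a[i, ] + cp) / 2)
  a
}

# least-squares plane through points: list(normal, offset, residual)
fit_plane <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L)
    stop("a plane fit needs at least 3 points", call. = FALSE)
  cen <- colMeans(pts)
  x <- sweep(pts, 2L, cen)
  sv <- svd(x)
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    stop("plane fit is degenerate: points are collinear", call. = FALSE)
  normal <- sv$v[, 3L]
  resid <- max(abs(x %*% normal))
  list(normal = normal, centroid = cen,
       offset = sum(normal * cen), residual = resid)
}

# principal-direction line through points: list(direction, centroid,
# residual)
fit_line <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L)
    stop("a line fit needs at least 2 points", call. = FALSE)
  cen <- colMeans(pts)
  x <- sweep(pts, 2L, cen)
  sv <- svd(x)
  if (sv$d[1L] < 1e-12)
    stop("line fit is degenerate: points are coincident", call. = FALSE)
  dir <- sv$v[, 1L]
  perp <- x - (x %*% dir) %*% t(dir)
  list(direction = dir, centroid = cen,
       residual = max(sqrt(rowSums(perp^2))))
}

#' Fit a mounting-plate frame from placed landmark points
#'
#' A plate frame has axes parallel to the plate edges and its origin at
#' a designated corner.  Three labelled face groups (each >= 3
#' non-collinear points on one plate face) give three least-squares
#' plane normals; the normals are oriented outward (away from the
#' landmark centroid), formally orthogonalised with [orthogonalise()],
#' and the origin is the intersection of the three fitted planes - the
#' corner where the faces meet.
#'
#' @param landmarks data.frame with columns `group`, `x`, `y`, `z` (mm);
#'   may carry extra columns (e.g. `label`).
#' @param face_groups character vector of three group names, in the
#'   order of the frame axes (default `c("face_x", "face_y",
#'   "face_z")`).
#' @return list of class `"frame_fit"`: `transform` (a
#'   [rigid_transform()] mapping plate-frame coords to the landmark
#'   frame; columns of its rotation block are the plate axes),
#'   `residuals` (max point-to-plane distance per face, mm) and
#'   `axis_dot` (max pairwise |dot| after orthogonalisation).
#' @export
fit_plate_frame <- function(landmarks,
                            face_groups = c("face_x", "face_y", "face_z")) {
  landmarks <- as.data.frame(landmarks)
  need <- c("group", "x", "y", "z")
  if (!all(need %in% names(landmarks)))
    stop("landmarks need columns group, x, y, z", call. = FALSE)
  if (length(face_groups) != 3L)
    stop("exactly three face groups are required", call. = FALSE)
  allpts <- as.matrix(landmarks[, c("x", "y", "z")])
  cen_all <- colMeans(allpts)
  fits <- lapply(face_groups, function(g) {
    pts <- as.matrix(landmarks[landmarks$group == g, c("x", "y", "z")])
    if (nrow(pts) < 3L)
      stop(sprintf("face group '%s' needs at least 3 points", g),
           call. = FALSE)
    f <- fit_plane(pts)
    if (sum(f$normal * (f$centroid - cen_all)) < 0) {
      f$normal <- -f$normal
      f$offset <- -f$offset
    }
    f
  })
  axes <- t(vapply(fits, `[[`, numeric(3), "normal"))
  axes <- orthogonalise(axes, handedness = "correct")
  # corner: intersection of the three (orthogonalised) planes
  nmat <- unclass(axes)
  d <- vapply(seq_len(3L), function(i) {
    g <- face_groups[i]
    pts <- as.matrix(landmarks[landmarks$group == g, c("x", "y", "z")])
    mean(pts %*% nmat[i, ])
  }, numeric(1))
  origin <- solve(nmat, d)
  structure(list(
    transform = rigid_transform(t(nmat), origin),
    residuals = vapply(fits, `[[`, numeric(1), "residual"),
    axis_dot = attr(axes, "residual"),
    iterations = attr(axes, "iterations")), class = "frame_fit")
}

#' Fit a bone frame from proximal- and distal-edge point rows
#'
#' For organically shaped bones where geometric primitives fit poorly:
#' points are placed along the proximal and distal edges, a
#' principal-direction line is fitted through each edge set, the long
#' axis joins the two edge-line midpoints, the second axis comes from
#' the proximal edge-line direction, and the third completes a
#' right-handed triad; all three are then formally orthogonalised.  The
#' origin sits at the proximal midpoint.
#'
#' @param proximal_pts,distal_pts n x 3 matrices (or data.frames with
#'   x, y, z), >= 2 points each.
#' @return a `"frame_fit"` list as in [fit_plate_frame()]; `residuals`
#'   holds the max point-to-line distance for the two edges (mm).
#' @export
fit_bone_frame <- function(proximal_pts, distal_pts) {
  getm <- function(p) {
    if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y", "z")])
    as.matrix(p)
  }
  pp <- getm(proximal_pts); dp <- getm(distal_pts)
  lp <- fit_line(pp); ld <- fit_line(dp)
  long <- ld$centroid - lp$centroid
  if (vnorm(long) < 1e-9)
    stop("degenerate bone geometry: proximal and distal edge midpoints coincide",
         call. = FALSE)
  ax1 <- unitize(long)                       # long axis
  edge <- lp$direction
  edge <- edge - sum(edge * ax1) * ax1
  if (vnorm(edge) < 1e-9)
    stop("degenerate bone geometry: proximal edge is parallel to the long axis",
         call. = FALSE)
  ax2 <- unitize(edge)                       # mediolateral from proximal edge
  ax3 <- cross3(ax1, ax2)                    # completes right-handed triad
  axes <- orthogonalise(rbind(ax1, ax2, ax3), handedness = "correct")
  nmat <- unclass(axes)
  structure(list(
    transform = rigid_transform(t(nmat), lp$centroid),
    residuals = c(proximal = lp$residual, distal = ld$residual),
    axis_dot = attr(axes, "residual"),
    iterations = attr(axes, "iterations")), class = "frame_fit")
}

#' @export
print.frame_fit <- function(x, ...) {
  cat("fitted frame\n")
  cat(sprintf("  max fit residual: %.4g mm; max axis |dot|: %.3g (%d orthogonalisation iterations)\n",
              max(x$residuals), x$axis_dot, x$iterations))
  print(x$transform)
  invisible(x)
}
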