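# Synthetic ground truth: range-of-motion generators in the 1/2/3-DoF
# and coupled regimes, and a virtual capture-rig session (marker
# trajectories + passive-torque channels) whose forward model is the
# exact inverse of the marker-to-joint chain.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Describe a synthetic joint's reachable rotation set
#'
#' A generative specification of a joint's range of motion: per-axis
#' half-ranges in degrees, the (intrinsic) rotation order, the sampling
#' scheme, and - for the coupled regime - a piecewise-linear rule that
#' limits one axis as a function of another, emulating joints whose
#' freedom about one axis opens up only after rotation about another.
#'
#' @param mode one of `"one_dof"`, `"two_dof"`, `"three_dof_box"`,
#'   `"coupled"`.
#' @param half_ranges non-negative half-ranges in degrees, one per axis
#'   in `axes`.
#' @param axes rotation axes in application order, e.g. `c("X", "Y")`;
#'   length must match the mode (1, 2, 3, and >= 2 for coupled).
#' @param step grid sampling step in degrees (used when `n` is `NULL`).
#' @param n number of uniform-random samples; `NULL` (default) selects
#'   grid sampling.
#' @param seed RNG seed for random sampling.
#' @param coupling for `mode = "coupled"`: a list with `driver` and
#'   `limited` (axis indices into `axes`) and `table`, a data.frame with
#'   columns `angle` (driver angle, degrees) and `half_range` (allowed
#'   half-range of the limited axis at that driver angle); intermediate
#'   driver angles are interpolated linearly.
#' @param intrinsic rotation composition convention (see
#'   [from_euler()]).
#' @return object of class `"rom_spec"`.
#' @export
rom_spec <- function(mode = c("one_dof", "two_dof", "three_dof_box",
                              "coupled"),
                     half_ranges, axes = NULL, step = 5, n = NULL,
                     seed = NULL, coupling = NULL, intrinsic = TRUE) {
  mode <- match.arg(mode)
  ndof <- switch(mode, one_dof = 1L, two_dof = 2L, three_dof_box = 3L,
                 coupled = length(half_ranges))
  if (is.null(axes)) axes <- c("X", "Y", "Z")[seq_len(ndof)]
  axes <- toupper(axes)
  if (length(half_ranges) != length(axes))
    stop("half_ranges and axes must have the same length", call. = FALSE)
  if (mode != "coupled" && length(axes) != ndof)
    stop(sprintf("mode '%s' needs exactly %d axes", mode, ndof),
         call. = FALSE)
  if (any(half_ranges < 0))
    stop("half-ranges must be non-negative", call. = FALSE)
  parse_sequence(paste(axes, collapse = ""))
  if (!is.null(n) && n < 1L) stop("n must be positive", call. = FALSE)
  if (is.null(n) && step <= 0) stop("grid step must be > 0", call. = FALSE)
  if (mode == "coupled") {
    if (length(axes) < 2L)
      stop("coupled mode needs at least two axes", call. = FALSE)
    if (is.null(coupling) ||
        !all(c("driver", "limited", "table") %in% names(coupling)))
      stop("coupled mode needs coupling = list(driver, limited, table)",
           call. = FALSE)
    tab <- coupling$table
    if (!all(c("angle", "half_range") %in% names(tab)) || nrow(tab) < 2L)
      stop("coupling table needs >= 2 rows with columns angle, half_range",
           call. = FALSE)
  }
  structure(list(mode = mode, half_ranges = half_ranges, axes = axes,
                 step = step, n = n, seed = seed, coupling = coupling,
                 intrinsic = intrinsic), class = "rom_spec")
}

#' @export
print.rom_spec <- function(x, ...) {
  cat(sprintf("RoM spec: %s about %s, half-ranges %s deg, %s sampling\n",
              x$mode, paste(x$axes, collapse = "-"),
              paste(x$half_ranges, collapse = "/"),
              if (is.null(x$n)) sprintf("grid (step %g deg)", x$step)
              else sprintf("random (n = %d)", x$n)))
  invisible(x)
}

#' Generate a synthetic range-of-motion orientation dataset
#'
#' Samples joint-angle tuples according to the spec (full grid or
#' seeded uniform-random), drops tuples that violate the coupling rule
#' in coupled mode, and composes each tuple into an orientation with
#' [from_euler()].  Deterministic for a given spec and seed.
#'
#' @param spec a [rom_spec()].
#' @return an [orientation_set()]; the sampled angle tuples are attached
#'   as attribute `"angles"` (degrees, one column per axis).
#' @export
generate_rom <- function(spec) {
  stopifnot(inherits(spec, "rom_spec"))
  h <- spec$half_ranges
  nd <- length(h)
  if (is.null(spec$n)) {
    axes_vals <- lapply(h, function(hr) {
      if (hr == 0) 0 else seq(-hr, hr, by = spec$step)
    })
    ang <- as.matrix(expand.grid(axes_vals))
  } else {
    ang <- with_seed(spec$seed, {
      matrix(stats::runif(spec$n * nd, -1, 1), ncol = nd) *
        matrix(h, spec$n, nd, byrow = TRUE)
    })
  }
  colnames(ang) <- spec$axes
  if (spec$mode == "coupled") {
    cp <- spec$coupling
    lim <- stats::approx(cp$table$angle, cp$table$half_range,
                         xout = ang[, cp$driver], rule = 2L)$y
    ang <- ang[abs(ang[, cp$limited]) <= lim, , drop = FALSE]
  }
  if (nrow(ang) == 0L)
    stop("the sampled range of motion is empty (zero ranges or coupling rejected every tuple)",
         call. = FALSE)
  seqstr <- paste(spec$axes, collapse = "")
  mats <- lapply(seq_len(nrow(ang)), function(i)
    unclass(from_euler(ang[i, ], sequence = seqstr,
                       intrinsic = spec$intrinsic)))
  out <- orientation_set(mats, label = sprintf("synthetic %s RoM", spec$mode))
  attr(out, "angles") <- ang
  out
}

#' Describe a virtual capture rig
#'
#' The constant geometry of the simulated rig: the fixed transforms
#' placing the proximal mounting plate in the base frame and the distal
#' plate in the marker frame, the marker-tree local coordinates (>= 4
#' non-coplanar points, mm), and the passive-torque model.  Soft-tissue
#' resistance is modelled as a piecewise power-law spring per joint
#' axis: zero inside the soft-limit onset, `stiffness * excess^exponent`
#' N.mm beyond it - the simplest nonlinear stand-in for soft-tissue
#' stress-strain behaviour.
#'
#' @param pPlate_T_base,dPlate_T_markers constant rig transforms.
#' @param marker_tree m x 3 matrix of marker positions in the marker
#'   (handle) frame, mm; must be non-coplanar.
#' @param soft_onset soft-limit onset angle, degrees.
#' @param stiffness torque coefficient, N.mm / deg^exponent.
#' @param exponent nonlinearity exponent (default 3).
#' @param threshold,upper audio-feedback torque cut-off and upper limit,
#'   N.mm.
#' @return object of class `"rig_geometry"`.
#' @export
rig_geometry <- function(
    pPlate_T_base = rigid_transform(t(unclass(from_euler(c(15, 0, 0)))),
                                    c(40, 25, 10)),
    dPlate_T_markers = rigid_transform(t(unclass(from_euler(c(0, -20, 10)))),
                                       c(-12, 8, 30)),
    marker_tree = rbind(c(0, 0, 0), c(50, 0, 0), c(0, 40, 0),
                        c(20, 15, 30)),
    soft_onset = 25, stiffness = 0.5, exponent = 3,
    threshold = 5, upper = 50) {
  marker_tree <- as.matrix(marker_tree)
  if (nrow(marker_tree) < 4L)
    stop("the marker tree needs at least 4 markers", call. = FALSE)
  x <- sweep(marker_tree, 2L, colMeans(marker_tree))
  if (svd(x)$d[3L] < 1e-9)
    stop("marker tree is degenerate: markers are coplanar", call. = FALSE)
  if (threshold >= upper)
    stop("torque threshold must be below the upper limit", call. = FALSE)
  structure(list(
    pPlate_T_base = rigid_transform(pPlate_T_base),
    dPlate_T_markers = rigid_transform(dPlate_T_markers),
    marker_tree = marker_tree,
    soft_onset = soft_onset, stiffness = stiffness, exponent = exponent,
    threshold = threshold, upper = upper), class = "rig_geometry")
}

#' Simulate a virtual capture-rig session
#'
#' For every ground-truth joint pose, the marker-to-joint chain is
#' composed *forwards*: the joint pose places the distal plate, hence
#' the marker tree, in the base frame, and the marker positions are
#' recorded with isotropic Gaussian noise.  Passive joint torque per
#' rotation axis follows the rig's soft-limit spring model.  The session
#' carries its ground truth, so chain recovery can be verified exactly.
#'
#' @param spec a [rom_spec()].
#' @param geom a [rig_geometry()].
#' @param pACS_T_pPlate,dACS_T_dPlate specimen-specific bone-on-plate
#'   transforms (defaults are fixed non-trivial mounts).
#' @param noise_sd isotropic marker noise, mm (default 0.1, a typical
#'   optical motion-capture residual; 0 gives exact recovery).
#' @param seed RNG seed for the noise (and passed to random RoM
#'   sampling if the spec has none).
#' @param rate sampling rate in Hz for the timestamps.
#' @return object of class `"rig_session"`: marker positions (n x m x 3,
#'   base frame, mm), marker names, timestamps, ground-truth
#'   [orientation_set()], joint angles, torque (n x 3, N.mm), and the
#'   geometry used.
#' @export
simulate_session <- function(spec, geom = rig_geometry(),
                             pACS_T_pPlate = rigid_transform(
                               t(unclass(from_euler(c(5, 10, -5)))),
                               c(3, -2, 6)),
                             dACS_T_dPlate = rigid_transform(
                               t(unclass(from_euler(c(-8, 4, 12)))),
                               c(-1, 5, -4)),
                             noise_sd = 0.1, seed = NULL, rate = 100) {
  stopifnot(inherits(spec, "rom_spec"), inherits(geom, "rig_geometry"))
  if (is.null(spec$seed) && !is.null(seed)) spec$seed <- seed
  truth <- generate_rom(spec)
  ang <- attr(truth, "angles")
  n <- length(truth)
  pACS_T_base <- compose_transforms(pACS_T_pPlate, geom$pPlate_T_base)
  dACS_T_markers <- compose_transforms(dACS_T_dPlate, geom$dPlate_T_markers)
  markers_T_dACS <- invert_transform(dACS_T_markers)
  m <- nrow(geom$marker_tree)
  markers <- array(0, dim = c(n, m, 3L))
  noise <- if (noise_sd > 0) {
    with_seed(seed, array(stats::rnorm(n * m * 3L, sd = noise_sd),
                          dim = c(n, m, 3L)))
  } else array(0, dim = c(n, m, 3L))
  for (i in seq_len(n)) {
    joint <- rigid_transform(unclass(truth[[i]]))   # rotation only
    markers_T_base <- compose_transforms(markers_T_dACS, joint, pACS_T_base)
    base_T_markers <- invert_transform(markers_T_base)
    markers[i, , ] <- transform_points(base_T_markers, geom$marker_tree) +
      noise[i, , ]
  }
  # per-axis soft-limit spring torque from the sampled joint angles
  torque <- matrix(0, n, 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  for (j in seq_len(ncol(ang))) {
    axis <- tolower(colnames(ang)[j])
    exc <- pmax(0, abs(ang[, j]) - geom$soft_onset)
    torque[, axis] <- torque[, axis] +
      sign(ang[, j]) * geom$stiffness * exc^geom$exponent
  }
  structure(list(
    markers = markers,
    marker_names = paste0("m", seq_len(m)),
    time = (seq_len(n) - 1L) / rate,
    truth = truth, angles = ang, torque = torque,
    geom = geom, pACS_T_pPlate = rigid_transform(pACS_T_pPlate),
    dACS_T_dPlate = rigid_transform(dACS_T_dPlate),
    noise_sd = noise_sd, rate = rate), class = "rig_session")
}

#' @export
print.rig_session <- function(x, ...) {
  cat(sprintf("virtual rig session: %d frames, %d markers, noise sd %g mm\n",
              dim(x$markers)[1L], dim(x$markers)[2L], x$noise_sd))
  invisible(x)
}

#' Classify per-frame torque against feedback thresholds
#'
#' Reproduces the audio-feedback logic: frames whose torque magnitude is
#' below the cut-off threshold are silent (`"below"`), frames at or
#' above it enter the feedback zone where pitch rises linearly with
#' magnitude, and frames at or above the upper limit are `"above_limit"`
#' with pitch fraction 1.
#'
#' @param x a [simulate_session()] result, or an n x 3 torque matrix
#'   (N.mm).
#' @param threshold feedback cut-off, N.mm (defaults to the session
#'   rig's value).
#' @param upper upper torque limit, N.mm.
#' @return data.frame with `magnitude`, `category` (factor: below /
#'   feedback / above_limit) and `pitch_fraction` in \code{[0, 1]}.
#' @export
classify_torque <- function(x, threshold = NULL, upper = NULL) {
  if (inherits(x, "rig_session")) {
    if (is.null(threshold)) threshold <- x$geom$threshold
    if (is.null(upper)) upper <- x$geom$upper
    tau <- x$torque
  } else {
    tau <- as.matrix(x)
    if (is.null(threshold) || is.null(upper))
      stop("threshold and upper are required for a bare torque matrix",
           call. = FALSE)
  }
  if (threshold >= upper)
    stop("threshold must be below the upper limit", call. = FALSE)
  mag <- sqrt(rowSums(tau^2))
  category <- cut(mag, c(-Inf, threshold, upper, Inf),
                  labels = c("below", "feedback", "above_limit"),
                  right = FALSE)
  frac <- pmin(pmax((mag - threshold) / (upper - threshold), 0), 1)
  data.frame(magnitude = mag, category = category, pitch_fraction = frac)
}
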