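# The spherical frame projection itself: frame traces, occupancy-grid
# boundary fitting, and the fitted "sfp" object with its methods.

#' Trace the frame axes of an orientation dataset on the unit sphere
#'
#' Each orientation contributes one point per axis: row i of the
#' rotation matrix is the endpoint of the distal frame's i-th axis in
#' the proximal frame.  The three resulting clouds (X, Y, Z) are the raw
#' material of a spherical frame projection.
#'
#' @param data an [orientation_set()].
#' @return object of class `"frame_trace"`: list of n x 3 matrices `x`,
#'   `y`, `z` plus the source size and label.
#' @export
frame_trace <- function(data) {
  if (!inherits(data, "orientation_set"))
    data <- orientation_set(data)
  arr <- data$rotations
  n <- dim(arr)[3L]
  structure(list(
    x = t(arr[1L, , ]), y = t(arr[2L, , ]), z = t(arr[3L, , ]),
    n = n, label = data$label), class = "frame_trace")
}

#' @export
print.frame_trace <- function(x, ...) {
  cat(sprintf("frame trace: %d orientations -> 3 clouds of %d sphere points\n",
              x$n, x$n))
  cat(sprintf("  cloud diameters (deg): X %.3f, Y %.3f, Z %.3f\n",
              arc_diameter(x$x), arc_diameter(x$y), arc_diameter(x$z)))
  invisible(x)
}

#' Fit a spherical boundary polygon around a point cloud
#'
#' Automates the patch-selection idiom: patches of a subdivided
#' icosahedral grid that contain at least one point are marked occupied,
#' the occupied region is optionally dilated by whole patch rings, and
#' the outer perimeter of the region is extracted as an ordered vertex
#' loop.  Every input point lies inside the returned polygon by
#' construction.
#'
#' @param points n x 3 matrix of unit vectors (>= 1 point).
#' @param subdivisions grid resolution (see [sphere_grid()]); default 3,
#'   i.e. 1280 patches.
#' @param dilation non-negative integer: number of patch rings to grow
#'   the occupied region by before extracting the perimeter (default 0,
#'   tight fit).
#' @param grid optionally, a prebuilt [sphere_grid()] (overrides
#'   `subdivisions`).
#' @return a [sphere_polygon()] with attributes `occupied` (face
#'   indices), `occupied_area` (sum of patch solid angles) and `grid`.
#' @export
fit_boundary <- function(points, subdivisions = 3L, dilation = 0L,
                         grid = NULL) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  points <- as.matrix(points)
  if (nrow(points) < 1L)
    stop("boundary fitting needs at least one point", call. = FALSE)
  points <- points / sqrt(rowSums(points^2))
  if (is.null(grid)) grid <- sphere_grid(subdivisions)
  occ <- locate_patch_all(grid, points)
  if (dilation > 0L) {
    for (r in seq_len(dilation)) {
      occ <- sort(unique(c(occ, unlist(grid$vertex_adjacency[occ]))))
    }
  }
  if (length(occ) == nrow(grid$faces))
    stop("occupied patches cover the whole sphere: no boundary exists; use a finer grid resolution",
         call. = FALSE)
  # resolve pinch vertices (occupied patches meeting only at a vertex)
  # by occupying the smallest angular gaps of the patch fan around
  # them, so the region becomes edge-connected with minimal growth
  repeat {
    pinch <- pinch_vertices(occ, grid)
    if (!length(pinch)) break
    add <- unlist(lapply(pinch, pinch_bridge_faces, occ = occ,
                         grid = grid, cloud = points))
    if (!length(add)) break
    occ <- sort(unique(c(occ, add)))
    if (length(occ) == nrow(grid$faces))
      stop("occupied patches cover the whole sphere: no boundary exists; use a finer grid resolution",
           call. = FALSE)
  }
  comp <- region_components(occ, grid$edge_adjacency)
  if (length(comp) > 1L)
    stop(sprintf("ambiguous boundary: the occupied region splits into %d disconnected patch clusters; increase `dilation`, use a coarser grid, or fit the clusters separately",
                 length(comp)), call. = FALSE)
  loops <- boundary_loops(occ, grid$faces)
  if (!length(loops))
    stop("ambiguous boundary: the occupied region has no consistent perimeter; use a finer grid resolution",
         call. = FALSE)
  if (length(loops) > 1L) {
    warning("occupied region has holes or pinch points; using the longest boundary loop as the outer perimeter")
    loops <- loops[order(lengths(loops), decreasing = TRUE)]
  }
  loop <- loops[[1L]]
  w <- grid$solid_angles[occ]
  interior <- colSums(grid$centroids[occ, , drop = FALSE] * w)
  if (vnorm(interior) < 1e-6)
    stop("ambiguous boundary: occupied region spans the sphere too symmetrically to define an interior; use a finer grid resolution or fit sub-regions",
         call. = FALSE)
  interior <- unitize(interior)
  poly <- sphere_polygon(grid$vertices[loop, , drop = FALSE], interior)
  attr(poly, "occupied") <- occ
  attr(poly, "occupied_area") <- sum(w)
  attr(poly, "grid") <- grid
  poly
}

# vertices whose occupied incident-face fan is not edge-connected: the
# perimeter would have to pass through them twice
pinch_vertices <- function(occ, grid) {
  verts <- sort(unique(as.vector(grid$faces[occ, , drop = FALSE])))
  inocc <- logical(nrow(grid$faces))
  inocc[occ] <- TRUE
  out <- integer(0)
  for (v in verts) {
    fan <- grid$vertex_faces[[as.character(v)]]
    fan <- fan[inocc[fan]]
    if (length(fan) < 2L) next
    if (length(region_components(fan, grid$edge_adjacency)) > 1L)
      out <- c(out, v)
  }
  out
}

# faces that bridge the occupied wedges around a pinch vertex: the fan
# is ordered cyclically and, of the unoccupied gaps between wedges, the
# ones lying closest to the point cloud are filled (one fewer than the
# number of gaps, which is what edge-connects the wedges)
pinch_bridge_faces <- function(v, occ, grid, cloud) {
  fan <- grid$vertex_faces[[as.character(v)]]
  vp <- grid$vertices[v, ]
  # cyclic order of the fan by centroid angle in the tangent plane
  ref <- grid$centroids[fan[1L], ]
  e1 <- ref - sum(ref * vp) * vp
  e1 <- e1 / vnorm(e1)
  e2 <- cross3(vp, e1)
  ang <- vapply(fan, function(f) {
    cc <- grid$centroids[f, ]
    atan2(sum(cc * e2), sum(cc * e1))
  }, numeric(1))
  fan <- fan[order(ang)]
  inocc <- fan %in% occ
  k <- length(fan)
  if (all(inocc) || !any(inocc)) return(integer(0))
  # runs of unoccupied faces, cyclically
  gaps <- list()
  i <- 1L
  # rotate so position 1 is occupied
  start <- which(inocc)[1L]
  idx <- c(start:k, seq_len(start - 1L))
  fan <- fan[idx]; inocc <- inocc[idx]
  cur <- integer(0)
  for (i in seq_len(k)) {
    if (!inocc[i]) cur <- c(cur, fan[i])
    else if (length(cur)) { gaps[[length(gaps) + 1L]] <- cur; cur <- integer(0) }
  }
  if (length(cur)) gaps[[length(gaps) + 1L]] <- cur
  if (length(gaps) <= 1L) return(integer(0))   # single wedge: no pinch here
  # cost of a gap: how far its patches sit from the data, then width
  cost <- vapply(gaps, function(gf) {
    cen <- grid$centroids[gf, , drop = FALSE]
    d <- cen %*% t(cloud)
    min(acos(pmin(1, pmax(-1, apply(d, 1L, max)))))
  }, numeric(1))
  drop_gap <- order(-cost, -lengths(gaps))[1L]
  unlist(gaps[-drop_gap])
}

region_components <- function(occ, adj) {
  seen <- integer(0)
  comps <- list()
  inocc <- logical(length(adj))
  inocc[occ] <- TRUE
  remaining <- occ
  while (length(remaining)) {
    queue <- remaining[1L]
    comp <- integer(0)
    while (length(queue)) {
      f <- queue[[1L]]; queue <- queue[-1L]
      if (f %in% comp) next
      comp <- c(comp, f)
      nb <- adj[[f]]
      queue <- c(queue, nb[inocc[nb] & !(nb %in% comp)])
    }
    comps[[length(comps) + 1L]] <- comp
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# directed boundary edges of a face set (occupied face on the left),
# chained into closed vertex loops
boundary_loops <- function(occ, faces) {
  fo <- faces[occ, , drop = FALSE]
  tails <- c(fo[, 1L], fo[, 2L], fo[, 3L])
  heads <- c(fo[, 2L], fo[, 3L], fo[, 1L])
  key <- paste(tails, heads)
  rkey <- paste(heads, tails)
  isb <- !(rkey %in% key)
  bt <- tails[isb]; bh <- heads[isb]
  if (!length(bt)) return(list())
  used <- logical(length(bt))
  loops <- list()
  out_of <- split(seq_along(bt), bt)
  while (any(!used)) {
    s <- which(!used)[1L]
    loop <- bt[s]
    cur <- s
    repeat {
      used[cur] <- TRUE
      nv <- bh[cur]
      if (nv == loop[1L]) break
      loop <- c(loop, nv)
      cand <- out_of[[as.character(nv)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) return(list())   # broken chain: no perimeter
      cur <- cand[1L]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Fit a spherical frame projection
#'
#' The main fitting function: traces the X, Y and Z axis endpoints of an
#' orientation dataset on the unit sphere and fits one boundary polygon
#' per axis with [fit_boundary()].  The result is the SFP - a triplet of
#' spherical regions, one per frame axis, drawn around the null-pose
#' reference frame.
#'
#' @param data an [orientation_set()] (or anything `orientation_set()`
#'   accepts).
#' @param subdivisions occupancy-grid resolution (default 3: 1280
#'   patches).
#' @param dilation patch rings of dilation before perimeter extraction.
#' @return object of class `"sfp"`: polygons `$x`, `$y`, `$z`, the frame
#'   trace, the null-pose frame (identity) and fitting metadata.
#'   Supports `print`, `summary`, `plot` and `predict` (pose membership,
#'   see [check_pose()]).
#' @examples
#' rom <- generate_rom(rom_spec("two_dof", half_ranges = c(30, 15),
#'                              axes = c("X", "Y"), step = 5))
#' fit <- sfp(rom)
#' summary(fit)
#' @export
sfp <- function(data, subdivisions = 3L, dilation = 0L) {
  if (!inherits(data, "orientation_set")) data <- orientation_set(data)
  tr <- frame_trace(data)
  grid <- sphere_grid(subdivisions)
  polys <- lapply(list(x = tr$x, y = tr$y, z = tr$z), function(cloud) {
    fit_boundary(cloud, dilation = dilation, grid = grid)
  })
  structure(list(
    polygons = polys, trace = tr, null_pose = diag(3),
    grid = grid, subdivisions = as.integer(subdivisions),
    dilation = as.integer(dilation), method = "occupancy-grid perimeter",
    n = length(data), label = data$label, call = match.call()),
    class = "sfp")
}

#' @export
print.sfp <- function(x, ...) {
  cat("Spherical frame projection\n")
  cat(sprintf("  %d orientations%s; grid: %d patches (%d subdivisions), dilation %d\n",
              x$n, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$grid$faces), x$subdivisions, x$dilation))
  a <- vapply(x$polygons, polygon_area, numeric(1))
  cat(sprintf("  polygon solid angles (sr): X %.4f, Y %.4f, Z %.4f\n",
              a[1L], a[2L], a[3L]))
  invisible(x)
}

#' @export
summary.sfp <- function(object, ...) {
  a <- vapply(object$polygons, polygon_area, numeric(1))
  v <- vapply(object$polygons, function(p) nrow(p$vertices), integer(1))
  occ <- vapply(object$polygons, function(p) length(attr(p, "occupied")),
                integer(1))
  di <- c(arc_diameter(object$trace$x), arc_diameter(object$trace$y),
          arc_diameter(object$trace$z))
  out <- list(
    n = object$n, label = object$label,
    patches = nrow(object$grid$faces), subdivisions = object$subdivisions,
    dilation = object$dilation, patch_width = grid_patch_width(object$grid),
    table = data.frame(
      axis = c("X", "Y", "Z"), vertices = v, occupied_patches = occ,
      solid_angle_sr = unname(a), cloud_diameter_deg = di))
  class(out) <- "summary.sfp"
  out
}

#' @export
print.summary.sfp <- function(x, ...) {
  cat(sprintf("Spherical frame projection of %d orientations%s\n", x$n,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("Occupancy grid: %d patches (%d subdivisions, ~%.2f deg patch width), dilation %d\n",
              x$patches, x$subdivisions, x$patch_width, x$dilation))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-axis membership of a pose in a fitted SFP
#'
#' Tests whether each axis endpoint of `o` lies inside the corresponding
#' boundary polygon.  All three inside is a *necessary* condition for
#' the pose to be reachable but not a sufficient one: the three
#' endpoints could each have been visited by different source poses, so
#' an all-inside pose may still be anatomically infeasible.  Use
#' [check_pose_path()] for a stronger, path-based check.
#'
#' @param object a fitted [sfp()].
#' @param o an [orientation()] (or 3x3 rotation matrix).
#' @return list with logicals `x`, `y`, `z`, the combined flag
#'   `all_inside`, and `note` restating the necessary-not-sufficient
#'   caveat.
#' @export
check_pose <- function(object, o) {
  stopifnot(inherits(object, "sfp"))
  o <- orientation(o)
  m <- unclass(o)
  res <- list(
    x = contains(object$polygons$x, m[1L, ]),
    y = contains(object$polygons$y, m[2L, ]),
    z = contains(object$polygons$z, m[3L, ]))
  res$all_inside <- res$x && res$y && res$z
  res$note <- "all_inside is necessary but not sufficient for reachability"
  res
}

#' @rdname check_pose
#' @param newdata for the `predict` method: an orientation, 3x3 matrix,
#'   or [orientation_set()]; defaults to the training data.
#' @param ... unused.
#' @return the `predict` method returns a data.frame with one row per
#'   pose and logical columns `x`, `y`, `z`, `all_inside`.
#' @export
predict.sfp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    tr <- object$trace
    n <- tr$n
    rows <- lapply(seq_len(n), function(i)
      rbind(tr$x[i, ], tr$y[i, ], tr$z[i, ]))
  } else {
    if (!inherits(newdata, "orientation_set")) {
      newdata <- orientation_set(newdata)
    }
    n <- length(newdata)
    rows <- lapply(seq_len(n), function(i) unclass(newdata[[i]]))
  }
  out <- data.frame(x = logical(n), y = logical(n), z = logical(n))
  for (i in seq_len(n)) {
    m <- rows[[i]]
    out$x[i] <- contains(object$polygons$x, m[1L, ])
    out$y[i] <- contains(object$polygons$y, m[2L, ])
    out$z[i] <- contains(object$polygons$z, m[3L, ])
  }
  out$all_inside <- out$x & out$y & out$z
  out
}

#' Path-based pose viability check
#'
#' The polygon membership test of [check_pose()] admits false positives;
#' this check is stronger: it asks whether the target pose can be
#' reached from a known viable start pose through the sampled dataset,
#' moving only between poses whose relative rotation is at most
#' `step_max` degrees.  A graph is built over the dataset (edges between
#' poses within `step_max`; poses left isolated by that rule fall back
#' to their `k` nearest neighbours), the start and target are anchored
#' to their nearest samples, and viability is graph connectivity.  This
#' remains a heuristic: it certifies reachability only up to the density
#' of the sampled dataset.
#'
#' @param data an [orientation_set()] of sampled (known-viable) poses.
#' @param start an orientation; must be within `step_max` of a sample.
#' @param target an orientation.
#' @param k nearest-neighbour fallback degree for otherwise isolated
#'   samples (default 6).
#' @param step_max maximum relative-rotation step in degrees (default
#'   10).
#' @return list with `viable` (logical), `path` (an [orientation_set()]
#'   of the pose sequence from start to target, or `NULL`), and
#'   `distances` (per-step relative rotations, degrees).
#' @export
check_pose_path <- function(data, start, target, k = 6L, step_max = 10) {
  if (!inherits(data, "orientation_set")) data <- orientation_set(data)
  start <- orientation(start); target <- orientation(target)
  n <- length(data)
  q <- t(vapply(seq_len(n), function(i) to_quaternion(data[[i]]),
                numeric(4)))
  qs <- to_quaternion(start); qt <- to_quaternion(target)
  dist_to <- function(qq) {
    d <- abs(q %*% qq)
    d[d > 1] <- 1
    rad2deg(2 * acos(d))
  }
  ds <- dist_to(qs); dt <- dist_to(qt)
  is0 <- which.min(ds)
  if (ds[is0] > step_max)
    stop(sprintf("start pose is not anchored: nearest sample is %.2f deg away (> step_max = %g)",
                 ds[is0], step_max), call. = FALSE)
  it0 <- which.min(dt)
  target_anchored <- dt[it0] <= step_max
  # pairwise rotational distances via quaternion dot products
  g <- abs(q %*% t(q))
  g[g > 1] <- 1
  dmat <- rad2deg(2 * acos(g))
  adj <- dmat <= step_max
  diag(adj) <- FALSE
  iso <- which(rowSums(adj) == 0L)
  for (i in iso) {                      # k-nearest fallback
    nb <- order(dmat[i, ])[-1L][seq_len(min(k, n - 1L))]
    adj[i, nb] <- TRUE
    adj[nb, i] <- TRUE
  }
  # BFS from the start anchor
  prev <- rep(NA_integer_, n)
  seen <- logical(n)
  queue <- is0; seen[is0] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    nb <- which(adj[cur, ] & !seen)
    prev[nb] <- cur
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  viable <- target_anchored && seen[it0]
  if (!viable)
    return(list(viable = FALSE, path = NULL, distances = numeric(0)))
  idx <- it0
  while (!is.na(prev[idx[1L]])) idx <- c(prev[idx[1L]], idx)
  mats <- c(list(unclass(start)),
            lapply(idx, function(i) unclass(data[[i]])),
            list(unclass(target)))
  # drop duplicated endpoints (start/target equal to their anchors)
  keep <- c(TRUE, vapply(seq_along(mats)[-1L], function(i)
    max(abs(mats[[i]] - mats[[i - 1L]])) > 1e-12, logical(1)))
  mats <- mats[keep]
  path <- orientation_set(mats, label = "viability path")
  dists <- vapply(seq_len(length(mats) - 1L), function(i)
    rotation_distance(mats[[i]], mats[[i + 1L]]), numeric(1))
  list(viable = TRUE, path = path, distances = dists)
}

#' Plot a spherical frame projection
#'
#' Orthographic view of the unit sphere with the three boundary polygons
#' (X red, Y green, Z blue), optionally the trace points, and the
#' null-pose frame drawn from the centre.
#'
#' @param x a fitted [sfp()].
#' @param view unit 3-vector: viewing direction (default `c(1, 1, 1)`,
#'   normalised internally).
#' @param points logical: draw the trace clouds (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sfp <- function(x, view = c(1, 1, 1), points = TRUE, ...) {
  view <- unitize(as.numeric(view))
  up0 <- if (abs(view[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitize(cross3(up0, view))
  e2 <- cross3(view, e1)
  proj <- function(p) {
    p <- matrix(p, ncol = 3L)
    vis <- p %*% view > -0.05
    cbind(p %*% e1, p %*% e2, vis)
  }
  graphics::plot(NA, NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1),
                 asp = 1, xlab = "", ylab = "", axes = FALSE, ...)
  th <- seq(0, 2 * pi, length.out = 361L)
  graphics::lines(cos(th), sin(th), col = "grey60")
  cols <- c(x = "red3", y = "green4", z = "blue3")
  for (ax in c("x", "y", "z")) {
    if (points) {
      pp <- proj(x$trace[[ax]])
      vis <- pp[, 3L] > 0
      graphics::points(pp[vis, 1L], pp[vis, 2L], pch = 16, cex = 0.25,
                       col = grDevices::adjustcolor(cols[[ax]], 0.35))
    }
    poly <- x$polygons[[ax]]
    v <- poly$vertices
    v <- rbind(v, v[1L, ])
    # densify edges so arcs render as curves
    dens <- do.call(rbind, lapply(seq_len(nrow(v) - 1L), function(i) {
      a <- v[i, ]; b <- v[i + 1L, ]
      tt <- seq(0, 1, length.out = 8L)
      s <- sapply(tt, function(u) unitize((1 - u) * a + u * b))
      t(s)
    }))
    pp <- proj(dens)
    seg <- pp[, 3L] > 0
    xx <- ifelse(seg, pp[, 1L], NA)
    yy <- ifelse(seg, pp[, 2L], NA)
    graphics::lines(xx, yy, col = cols[[ax]], lwd = 2)
  }
  # null-pose frame from the centre
  for (i in 1:3) {
    axis_end <- diag(3)[i, ]
    pp <- proj(rbind(c(0, 0, 0), axis_end))
    graphics::arrows(pp[1L, 1L], pp[1L, 2L], pp[2L, 1L], pp[2L, 2L],
                     length = 0.08, col = cols[[i]], lwd = 2)
  }
  graphics::title(main = sprintf("SFP (%d poses)", x$n))
  invisible(x)
}
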