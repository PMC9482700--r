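# Spherical polygons: closed loops of unit vertices joined by minor
# great-circle arcs, with an explicit interior reference point to say
# which side of the loop is "inside".

#' Geodesic arc length between two points on the unit sphere
#'
#' Computed with the two-argument arctangent of the cross- and
#' dot-product magnitudes, which is numerically stable for both nearly
#' coincident and nearly antipodal points.
#'
#' @param a,b unit 3-vectors.
#' @param tol unit-norm validation tolerance.
#' @return angle in degrees, in \code{[0, 180]}.
#' @export
arc_length <- function(a, b, tol = 1e-6) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L ||
      abs(vnorm(a) - 1) > tol || abs(vnorm(b) - 1) > tol)
    stop("arc_length expects unit 3-vectors", call. = FALSE)
  rad2deg(atan2(vnorm(cross3(a, b)), sum(a * b)))
}

# pairwise geodesic distances (degrees) within a point cloud; the cloud
# "diameter" is the max entry
arc_diameter <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) < 2L) return(0)
  g <- p %*% t(p)
  g[g > 1] <- 1; g[g < -1] <- -1
  max(rad2deg(acos(g)))
}

#' Construct a spherical polygon
#'
#' Vertices are stored counter-clockwise viewed from outside the sphere
#' (interior on the left of the directed boundary); the constructor
#' reverses the supplied order if needed, using `interior` to decide
#' which side is inside.
#'
#' @param vertices n x 3 matrix of unit vectors, n >= 3, consecutive
#'   vertices non-antipodal; the loop is closed implicitly.
#' @param interior a unit 3-vector strictly inside the intended region.
#' @return object of class `"sphere_polygon"`.
#' @export
sphere_polygon <- function(vertices, interior) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L || nrow(vertices) < 3L)
    stop("a spherical polygon needs at least 3 vertices (n x 3 matrix)",
         call. = FALSE)
  nrm <- sqrt(rowSums(vertices^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("polygon vertices must be unit vectors", call. = FALSE)
  vertices <- vertices / nrm
  dimnames(vertices) <- NULL
  nxt <- c(2:nrow(vertices), 1L)
  gap <- rowSums(vertices * vertices[nxt, , drop = FALSE])
  if (any(gap < -1 + 1e-9))
    stop("consecutive polygon vertices must not be antipodal", call. = FALSE)
  if (any(gap > 1 - 1e-14))
    stop("consecutive polygon vertices must be distinct", call. = FALSE)
  interior <- unitize(as.numeric(interior))
  p <- structure(list(vertices = vertices, interior = interior),
                 class = "sphere_polygon")
  if (!point_on_left_side(p)) {
    p$vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  }
  a <- polygon_area(p)
  if (!(a > 0 && a < 4 * pi))
    stop("polygon does not enclose a valid region (solid angle must be in (0, 4*pi))",
         call. = FALSE)
  p
}

#' @export
print.sphere_polygon <- function(x, ...) {
  cat(sprintf("spherical polygon: %d vertices, solid angle %.6f sr\n",
              nrow(x$vertices), polygon_area(x)))
  invisible(x)
}

# is the stored interior reference point on the left of the directed
# boundary?  Tested by parity of great-circle crossings between the
# interior point and a probe point placed just inside-left of an edge.
point_on_left_side <- function(p) {
  v <- p$vertices
  n <- nrow(v)
  eps <- 1e-4
  for (e in seq_len(n)) {           # try edges until an unambiguous probe
    a <- v[e, ]; b <- v[e %% n + 1L, ]
    gn <- cross3(a, b)
    if (vnorm(gn) < 1e-12) next
    gn <- gn / vnorm(gn)
    m <- unitize(a + b)
    # travel direction at m is gn x m; the left of travel (seen from
    # outside the sphere) is gn itself
    probe <- unitize(m * cos(eps) + gn * sin(eps))
    par <- try(crossing_parity(p, probe, p$interior), silent = TRUE)
    if (inherits(par, "try-error") || is.na(par)) next
    return(par %% 2L == 0L)
  }
  TRUE                               # degenerate: accept as given
}

# number of boundary crossings of the geodesic from a to b, or NA when
# the configuration is degenerate (crossing at a vertex / endpoint on an
# edge / coplanar arcs)
crossing_parity <- function(p, a, b, tol = 1e-10) {
  v <- p$vertices
  n <- nrow(v)
  gn <- cross3(a, b)
  if (vnorm(gn) < 1e-12) return(NA_integer_)   # coincident or antipodal
  gn <- gn / vnorm(gn)
  lab <- arc_rad(a, b)
  crossings <- 0L
  for (e in seq_len(n)) {
    c1 <- v[e, ]; c2 <- v[e %% n + 1L, ]
    en <- cross3(c1, c2)
    if (vnorm(en) < 1e-12) return(NA_integer_)
    en <- en / vnorm(en)
    d <- cross3(gn, en)
    nd <- vnorm(d)
    if (nd < 1e-12) {
      # arcs on the same great circle: degenerate if they overlap
      if (on_arc(c1, a, b, tol) || on_arc(c2, a, b, tol) ||
          on_arc(a, c1, c2, tol) || on_arc(b, c1, c2, tol))
        return(NA_integer_)
      next
    }
    d <- d / nd
    for (s in c(1, -1)) {
      x <- s * d
      on_ab <- on_arc(x, a, b, tol)
      on_cd <- on_arc(x, c1, c2, tol)
      if (on_ab && on_cd) {
        # degenerate when the hit sits at an endpoint of either segment
        if (arc_rad(x, a) < tol || arc_rad(x, b) < tol ||
            arc_rad(x, c1) < tol || arc_rad(x, c2) < tol)
          return(NA_integer_)
        crossings <- crossings + 1L
      }
    }
  }
  crossings
}

arc_rad <- function(a, b) atan2(vnorm(cross3(a, b)), sum(a * b))

on_arc <- function(x, a, b, tol = 1e-10) {
  abs(arc_rad(a, x) + arc_rad(x, b) - arc_rad(a, b)) < tol
}

#' Solid angle enclosed by a spherical polygon
#'
#' Gauss-Bonnet on the unit sphere: the enclosed area equals
#' `2*pi` minus the sum of signed exterior (turning) angles along the
#' boundary, which generalises the interior-angle spherical-excess
#' formula to non-convex loops.  The area is measured on the side of the
#' stored interior reference point.
#'
#' @param p a [sphere_polygon()].
#' @return solid angle in steradians, in (0, 4*pi).
#' @export
polygon_area <- function(p) {
  stopifnot(inherits(p, "sphere_polygon"))
  v <- p$vertices
  n <- nrow(v)
  turn <- 0
  for (i in seq_len(n)) {
    a <- v[(i - 2L) %% n + 1L, ]   # previous vertex
    b <- v[i, ]
    cc <- v[i %% n + 1L, ]         # next vertex
    n1 <- unitize(cross3(a, b))
    n2 <- unitize(cross3(b, cc))
    t_in <- cross3(n1, b)          # arrival direction at b
    t_out <- cross3(n2, b)         # departure direction at b
    turn <- turn + atan2(sum(cross3(t_in, t_out) * b), sum(t_in * t_out))
  }
  area <- 2 * pi - turn
  if (area < 0) area <- area + 4 * pi
  if (area >= 4 * pi) area <- area - 4 * pi
  area
}

#' Point-in-polygon test on the sphere
#'
#' Counts great-circle crossings along the geodesic from the polygon's
#' interior reference point to the query point: an even count means the
#' query is on the interior side.  The region is closed: points within
#' `edge_tol` of a boundary arc are classified inside, so every point
#' used to fit a boundary also tests inside it.  Degenerate paths
#' (through a vertex, or antipodal to the reference) are resolved by
#' deterministically jittering the reference point.
#'
#' @param p a [sphere_polygon()].
#' @param q unit 3-vector.
#' @param edge_tol angular tolerance (radians) for on-edge
#'   classification.
#' @return logical.
#' @export
contains <- function(p, q, edge_tol = 1e-9) {
  stopifnot(inherits(p, "sphere_polygon"))
  q <- unitize(as.numeric(q))
  v <- p$vertices
  n <- nrow(v)
  # on-edge (closed region) check first
  for (e in seq_len(n)) {
    a <- v[e, ]; b <- v[e %% n + 1L, ]
    en <- unitize(cross3(a, b))
    if (abs(sum(en * q)) < edge_tol && on_arc(q, a, b, edge_tol * 10))
      return(TRUE)
    if (arc_rad(q, a) < edge_tol) return(TRUE)
  }
  ref <- p$interior
  for (try in 0:8) {
    par <- crossing_parity(p, ref, q)
    if (!is.na(par)) return(par %% 2L == 0L)
    # deterministic jitter: small rotation of the reference point
    ax <- switch(try %% 3L + 1L, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    ang <- 1e-5 * (try + 1)
    k <- unitize(cross3(p$interior, ax + c(0.11, 0.07, 0.05) * (try + 1)))
    ref <- unitize(p$interior * cos(ang) + cross3(k, p$interior) * sin(ang))
  }
  stop("point-in-polygon test is degenerate for this query (antipodal or vertex-aligned path persisted through jitter)",
       call. = FALSE)
}

#' Vectorised point-in-polygon test
#'
#' Same classification as [contains()] but for many query points at
#' once: crossing parity is evaluated with chunked matrix arithmetic,
#' and the rare degenerate queries (paths through a vertex, points on an
#' edge) fall back to the scalar routine.
#'
#' @param p a [sphere_polygon()].
#' @param q m x 3 matrix of unit vectors.
#' @return logical vector of length m.
#' @export
contains_points <- function(p, q) {
  stopifnot(inherits(p, "sphere_polygon"))
  q <- as.matrix(q)
  if (ncol(q) != 3L) stop("q must be m x 3", call. = FALSE)
  q <- q / sqrt(rowSums(q^2))
  v <- p$vertices
  nedge <- nrow(v)
  ref <- p$interior
  m <- nrow(q)
  out <- logical(m)
  tol <- 1e-10
  chunk <- 50000L
  rowcross <- function(a, b) {
    cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
          a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
          a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  }
  arcm <- function(a, b) {            # rowwise arc between a (m x 3) and b
    cr <- rowcross(a, b)
    atan2(sqrt(rowSums(cr^2)), rowSums(a * b))
  }
  for (s in seq(1L, m, by = chunk)) {
    idx <- s:min(m, s + chunk - 1L)
    qq <- q[idx, , drop = FALSE]
    mm <- nrow(qq)
    refm <- matrix(ref, mm, 3L, byrow = TRUE)
    gn <- rowcross(refm, qq)
    gnn <- sqrt(rowSums(gn^2))
    degen <- gnn < 1e-12
    gn <- gn / pmax(gnn, 1e-300)
    lref <- arcm(refm, qq)
    crossings <- integer(mm)
    for (e in seq_len(nedge)) {
      a <- v[e, ]; b <- v[e %% nedge + 1L, ]
      en <- unitize(cross3(a, b))
      lab <- arc_rad(a, b)
      d <- rowcross(gn, matrix(en, mm, 3L, byrow = TRUE))
      nd <- sqrt(rowSums(d^2))
      degen <- degen | nd < 1e-12
      d <- d / pmax(nd, 1e-300)
      am <- matrix(a, mm, 3L, byrow = TRUE)
      bm <- matrix(b, mm, 3L, byrow = TRUE)
      for (sgn in c(1, -1)) {
        x <- sgn * d
        s1 <- arcm(refm, x) + arcm(x, qq) - lref   # on ref->q path
        s2 <- arcm(am, x) + arcm(x, bm) - lab      # on the edge
        hit <- abs(s1) < tol & abs(s2) < tol
        near_end <- hit & (arcm(x, refm) < tol | arcm(x, qq) < tol |
                           arcm(x, am) < tol | arcm(x, bm) < tol)
        degen <- degen | near_end
        crossings <- crossings + as.integer(hit)
      }
    }
    res <- crossings %% 2L == 0L
    if (any(degen))
      res[degen] <- vapply(which(degen), function(i)
        contains(p, qq[i, ]), logical(1))
    out[idx] <- res
  }
  out
}

#' Boundary section of a polygon along a great circle
#'
#' Intersects the polygon boundary with the great circle through
#' `center` with tangent direction `direction`, returning the crossing
#' points.  The maximal pairwise arc between crossings measures the
#' polygon's geodesic extent along that direction (e.g. the side lengths
#' of a range-of-motion rectangle through the null pose).
#'
#' @param p a [sphere_polygon()].
#' @param center unit 3-vector on the scan circle.
#' @param direction tangent direction at `center` (need not be unit or
#'   exactly tangent; it is orthogonalised against `center`).
#' @return list with `points` (k x 3 matrix of crossings) and `extent`
#'   (degrees, max pairwise arc; 0 when fewer than 2 crossings).
#' @export
polygon_section <- function(p, center, direction) {
  stopifnot(inherits(p, "sphere_polygon"))
  center <- unitize(as.numeric(center))
  direction <- as.numeric(direction)
  direction <- direction - sum(direction * center) * center
  direction <- unitize(direction)
  gn <- unitize(cross3(center, direction))   # normal of the scan circle
  v <- p$vertices
  n <- nrow(v)
  pts <- matrix(numeric(0), 0L, 3L)
  for (e in seq_len(n)) {
    a <- v[e, ]; b <- v[e %% n + 1L, ]
    en <- cross3(a, b)
    d <- cross3(gn, en)
    if (vnorm(d) < 1e-12) next
    d <- d / vnorm(d)
    for (s in c(1, -1)) {
      x <- s * d
      if (on_arc(x, a, b, 1e-9)) pts <- rbind(pts, x)
    }
  }
  if (nrow(pts) > 1L) pts <- unique(round(pts, 12L))
  ext <- if (nrow(pts) >= 2L) arc_diameter(pts) else 0
  list(points = pts, extent = ext)
}
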