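# File formats: orientation tables (CSV/TSV; rotation-matrix,
# quaternion or Euler columns), Qualisys-style marker TSV, SFP JSON /
# OBJ export, and the run configuration.

fmt_num <- function(x, digits = 12L) formatC(x, digits = digits, format = "g")

#' Write an orientation set to a CSV/TSV table
#'
#' Column names declare the representation: `r11..r33` (rotation-matrix
#' rows), `qw, qx, qy, qz` (unit quaternion) or `seq, conv, a1, a2, a3`
#' (Euler angles in degrees with the sequence and
#' intrinsic/extrinsic convention spelled out per row).  Numeric values
#' carry 12 significant digits, so matrix and quaternion tables
#' round-trip within 1e-9.
#'
#' @param data an [orientation_set()].
#' @param path output file.
#' @param format `"matrix"`, `"quaternion"` or `"euler"`.
#' @param sequence,intrinsic Euler convention used when
#'   `format = "euler"`.
#' @param sep field separator (`","` -> CSV, `"\t"` -> TSV).
#' @return `path`, invisibly.
#' @export
write_orientations <- function(data, path, format = c("matrix",
                                                      "quaternion",
                                                      "euler"),
                               sequence = "ZYX", intrinsic = TRUE,
                               sep = ",") {
  format <- match.arg(format)
  stopifnot(inherits(data, "orientation_set"))
  n <- length(data)
  df <- switch(format,
    matrix = {
      m <- t(vapply(seq_len(n), function(i) as.vector(t(data[[i]])),
                    numeric(9)))
      colnames(m) <- c("r11", "r12", "r13", "r21", "r22", "r23",
                       "r31", "r32", "r33")
      as.data.frame(m)
    },
    quaternion = {
      q <- t(vapply(seq_len(n), function(i) to_quaternion(data[[i]]),
                    numeric(4)))
      colnames(q) <- c("qw", "qx", "qy", "qz")
      as.data.frame(q)
    },
    euler = {
      ang <- t(vapply(seq_len(n), function(i)
        matrix_to_euler(unclass(data[[i]]), sequence, intrinsic),
        numeric(3)))
      data.frame(seq = sequence,
                 conv = if (intrinsic) "intrinsic" else "extrinsic",
                 a1 = ang[, 1L], a2 = ang[, 2L], a3 = ang[, 3L])
    })
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Euler angles (degrees) from a row-convention rotation, ZYX-style
# sequences; used for the euler export format
matrix_to_euler <- function(m, sequence = "ZYX", intrinsic = TRUE) {
  ax <- parse_sequence(sequence)
  if (length(ax) != 3L)
    stop("euler export needs a 3-axis sequence", call. = FALSE)
  r <- t(m)                          # column convention
  if (!intrinsic) {
    # extrinsic abc == intrinsic cba with reversed angles
    ang <- matrix_to_euler(m, paste(rev(ax), collapse = ""), TRUE)
    return(rev(ang))
  }
  idx <- function(a) match(a, c("X", "Y", "Z"))
  i <- idx(ax[1L]); j <- idx(ax[2L]); k <- idx(ax[3L])
  if (i != k) {                      # Tait-Bryan
    s <- if (((i - j) %% 3L) == 2L) 1 else -1   # even permutation sign
    a2 <- asin(pmin(1, pmax(-1, s * r[i, k])))
    a1 <- atan2(-s * r[j, k], r[k, k])
    a3 <- atan2(-s * r[i, j], r[i, i])
    rad2deg(c(a1, a2, a3))
  } else {
    stop("proper (symmetric) Euler sequences are not supported for export",
         call. = FALSE)
  }
}

#' Read an orientation table
#'
#' Detects the representation from the header (see
#' [write_orientations()]) unless `format` is given.  Every row is
#' validated; malformed rows are reported together with their file line
#' numbers.
#'
#' @param path CSV/TSV file.
#' @param format optional override: `"matrix"`, `"quaternion"` or
#'   `"euler"`.
#' @param tol row validation tolerance (orthonormality / quaternion
#'   norm); Euler rows are exact by construction.
#' @return an [orientation_set()] labelled with the file name.
#' @export
read_orientations <- function(path, format = NULL, tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  nm <- names(df)
  if (is.null(format)) {
    format <- if (all(c("r11", "r33") %in% nm)) "matrix"
    else if (all(c("qw", "qx", "qy", "qz") %in% nm)) "quaternion"
    else if (all(c("seq", "a1", "a2", "a3") %in% nm)) "euler"
    else stop(sprintf(
      "unknown orientation representation: header (%s) declares neither r11..r33, qw..qz, nor seq,a1..a3",
      paste(nm, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(df)
  if (n == 0L) stop("orientation table is empty", call. = FALSE)
  mats <- vector("list", n)
  bad <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(switch(format,
      matrix = {
        m <- matrix(as.numeric(unlist(df[i, c("r11", "r12", "r13",
                                              "r21", "r22", "r23",
                                              "r31", "r32", "r33")])),
                    3L, 3L, byrow = TRUE)
        chk <- validate_orientation(m, tol = tol)
        if (!chk$pass)
          stop(sprintf("orthonormality residual %.3g, det %.6g",
                       chk$orthonormality, chk$determinant))
        # snap to the nearest rotation so downstream 1e-9 checks hold
        sv <- svd(m)
        m <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
        m
      },
      quaternion = {
        q <- as.numeric(unlist(df[i, c("qw", "qx", "qy", "qz")]))
        unclass(from_quaternion(q / 1, tol = tol))
      },
      euler = {
        sq <- as.character(df$seq[i])
        conv <- if ("conv" %in% nm) as.character(df$conv[i]) else "intrinsic"
        unclass(from_euler(as.numeric(unlist(df[i, c("a1", "a2", "a3")[
          seq_len(nchar(sq))]])), sequence = sq,
          intrinsic = !identical(conv, "extrinsic")))
      }), error = function(e) e)
    if (inherits(res, "error")) {
      bad <- c(bad, sprintf("line %d: %s", i + 1L, conditionMessage(res)))
    } else mats[[i]] <- res
  }
  if (length(bad))
    stop(sprintf("%d malformed orientation row(s) in %s:\n  %s",
                 length(bad), path, paste(bad, collapse = "\n  ")),
         call. = FALSE)
  orientation_set(mats, label = basename(path))
}

# --- mocap TSV ----------------------------------------------------------

#' Write a rig session as a Qualisys-style marker TSV
#'
#' Header lines carry the frame count, marker count, frequency and
#' marker names; each data row holds tab-separated x/y/z triplets per
#' marker (mm, base frame).  Occluded markers would appear as NaN.
#'
#' @param session a [simulate_session()] result.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_session_tsv <- function(session, path) {
  stopifnot(inherits(session, "rig_session"))
  n <- dim(session$markers)[1L]
  m <- dim(session$markers)[2L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NO_OF_FRAMES\t%d", n),
    sprintf("NO_OF_MARKERS\t%d", m),
    sprintf("FREQUENCY\t%g", session$rate),
    paste0("MARKER_NAMES\t",
           paste(session$marker_names, collapse = "\t"))), con)
  flat <- matrix(aperm(session$markers, c(3L, 2L, 1L)), nrow = n,
                 byrow = TRUE)
  utils::write.table(
    matrix(fmt_num(flat), nrow = n), con, sep = "\t",
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read rigid-body poses from a Qualisys-style marker TSV
#'
#' Parses the marker trajectories and fits, per frame, the rigid
#' transform carrying the marker-tree model onto the observed markers
#' (orthogonal Procrustes / Kabsch).  Markers recorded as NaN (or NA)
#' are treated as occluded; frames with at least `min_markers` visible
#' markers are still solved but flagged, frames below that are dropped
#' with a warning.
#'
#' @param path TSV file (see [write_session_tsv()]).
#' @param marker_model m x 3 matrix of marker positions in the marker
#'   frame (mm), same order as the file's markers.
#' @param min_markers minimum visible markers for a pose fit (default
#'   3).
#' @return list with `markers_T_base` (list of [rigid_transform()], one
#'   per retained frame), `frame` (original frame indices), `flagged`
#'   (logical: partial occlusion), `rms` (per-frame fit RMS, mm).
#' @export
read_mocap <- function(path, marker_model, min_markers = 3L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  is_header <- grepl("^[A-Z_]+\t", lines)
  hdr <- lines[is_header]
  dat <- lines[!is_header]
  dat <- dat[nzchar(dat)]
  if (!length(dat)) stop("no data rows in mocap file", call. = FALSE)
  vals <- lapply(strsplit(dat, "\t"), as.numeric)
  nc <- lengths(vals)
  if (length(unique(nc)) != 1L || unique(nc) %% 3L != 0L)
    stop("malformed mocap rows: expected x/y/z triplets per marker",
         call. = FALSE)
  m <- unique(nc) / 3L
  marker_model <- as.matrix(marker_model)
  if (nrow(marker_model) != m)
    stop(sprintf("marker model has %d markers but file has %d",
                 nrow(marker_model), m), call. = FALSE)
  nf <- length(vals)
  transforms <- vector("list", nf)
  flagged <- logical(nf)
  rms <- rep(NA_real_, nf)
  keep <- logical(nf)
  for (i in seq_len(nf)) {
    obs <- matrix(vals[[i]], ncol = 3L, byrow = TRUE)
    vis <- stats::complete.cases(obs)
    if (sum(vis) < min_markers) next
    fit <- kabsch(marker_model[vis, , drop = FALSE],
                  obs[vis, , drop = FALSE])
    base_T_markers <- rigid_transform(fit$r, fit$t)
    transforms[[i]] <- invert_transform(base_T_markers)
    flagged[i] <- any(!vis)
    rms[i] <- fit$rms
    keep[i] <- TRUE
  }
  if (!any(keep))
    stop("all frames dropped: fewer than min_markers visible markers everywhere",
         call. = FALSE)
  if (any(!keep))
    warning(sprintf("%d frame(s) dropped for excess marker occlusion",
                    sum(!keep)))
  list(markers_T_base = transforms[keep], frame = which(keep),
       flagged = flagged[keep], rms = rms[keep])
}

# orthogonal Procrustes: rotation r, translation t with obs ~ r %*% model + t
kabsch <- function(model, obs) {
  cm <- colMeans(model); co <- colMeans(obs)
  x <- sweep(model, 2L, cm); y <- sweep(obs, 2L, co)
  h <- t(x) %*% y
  sv <- svd(h)
  d <- det(sv$v %*% t(sv$u))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- co - as.vector(r %*% cm)
  fitted <- sweep(model %*% t(r), 2L, t, `+`)
  list(r = r, t = t, rms = sqrt(mean(rowSums((fitted - obs)^2))))
}

# --- SFP JSON / OBJ -----------------------------------------------------

#' Export a fitted SFP to JSON
#'
#' Vertices and interior reference of the three polygons, their solid
#' angles, and the fitting metadata; numeric precision is full double,
#' so write/read round-trips are lossless at 1e-12.
#'
#' @param x a fitted [sfp()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_sfp <- function(x, path) {
  stopifnot(inherits(x, "sfp"))
  obj <- list(
    type = "sfp",
    metadata = list(n = x$n, label = x$label,
                    subdivisions = x$subdivisions, dilation = x$dilation,
                    patches = nrow(x$grid$faces), method = x$method),
    polygons = lapply(x$polygons, function(p) list(
      vertices = unname(p$vertices), interior = p$interior,
      solid_angle_sr = polygon_area(p))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an SFP back from JSON
#'
#' @param path JSON file written by [write_sfp()].
#' @return an object of class `"sfp"` (polygons and metadata; the trace
#'   and grid are not stored, so `predict`/area work but `plot` shows
#'   polygons only).
#' @export
read_sfp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "sfp"))
    stop("not an SFP JSON file", call. = FALSE)
  polys <- lapply(obj$polygons, function(p)
    sphere_polygon(p$vertices, p$interior))
  structure(list(
    polygons = polys,
    trace = NULL, null_pose = diag(3), grid = NULL,
    subdivisions = obj$metadata$subdivisions,
    dilation = obj$metadata$dilation,
    method = obj$metadata$method, n = obj$metadata$n,
    label = obj$metadata$label %||% "", call = NULL), class = "sfp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export SFP polygons as a Wavefront OBJ mesh
#'
#' Each polygon is triangulated as a fan from its interior reference
#' point, giving a surface patch on the unit sphere that generic 3D
#' viewers can load.
#'
#' @param x a fitted [sfp()].
#' @param path output `.obj` file.
#' @return `path`, invisibly.
#' @export
export_sfp_obj <- function(x, path) {
  stopifnot(inherits(x, "sfp"))
  lines <- c("# spherical frame projection polygons",
             "# axes: x, y, z polygon groups")
  off <- 0L
  for (ax in c("x", "y", "z")) {
    p <- x$polygons[[ax]]
    v <- rbind(p$interior, p$vertices)
    lines <- c(lines, sprintf("g polygon_%s", ax),
               sprintf("v %.9f %.9f %.9f", v[, 1L], v[, 2L], v[, 3L]))
    n <- nrow(p$vertices)
    f <- vapply(seq_len(n), function(i)
      sprintf("f %d %d %d", off + 1L, off + 1L + i,
              off + 1L + (i %% n) + 1L), character(1))
    lines <- c(lines, f)
    off <- off + n + 1L
  }
  writeLines(lines, path)
  invisible(path)
}

#' Render an SFP to a PNG file
#'
#' @param x a fitted [sfp()].
#' @param path output PNG.
#' @param width,height image size in pixels.
#' @param ... passed to [plot.sfp()].
#' @return `path`, invisibly.
#' @export
render_sfp <- function(x, path, width = 800, height = 800, ...) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(x, ...)
  invisible(path)
}

# --- configuration ------------------------------------------------------

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with validation and a
#' lossless JSON round trip.
#'
#' @param sequence,intrinsic Euler convention.
#' @param subdivisions,dilation boundary-fitting grid parameters.
#' @param step_max,k path-check parameters (degrees / neighbours).
#' @param tol validation tolerance for rotations.
#' @param seed RNG seed.
#' @return object of class `"sfp_config"`.
#' @export
sfp_config <- function(sequence = "ZYX", intrinsic = TRUE,
                       subdivisions = 3L, dilation = 0L,
                       step_max = 10, k = 6L, tol = 1e-9,
                       seed = 1L) {
  parse_sequence(sequence)
  if (subdivisions < 0L || subdivisions > 7L)
    stop("subdivisions must be in 0..7", call. = FALSE)
  if (dilation < 0L) stop("dilation must be >= 0", call. = FALSE)
  if (step_max <= 0 || step_max > 180)
    stop("step_max must be in (0, 180]", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(sequence = sequence, intrinsic = intrinsic,
                 subdivisions = as.integer(subdivisions),
                 dilation = as.integer(dilation), step_max = step_max,
                 k = as.integer(k), tol = tol, seed = as.integer(seed)),
            class = "sfp_config")
}

#' @rdname sfp_config
#' @param path JSON file.
#' @export
write_config <- function(x, path) {
  stopifnot(inherits(x, "sfp_config"))
  jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname sfp_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sfp_config, obj)
}
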