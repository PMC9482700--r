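# Pose-space coverage accounting: the "paint the sphere" feedback idiom,
# where a patch saturates after three independent passes.

#' Create an empty coverage grid
#'
#' A spherical patch decomposition with a per-patch pass counter.
#' Intensity is `min(passes, saturation) / saturation`; the default
#' saturation of 3 reproduces the three-independent-passes rule used for
#' live coverage feedback during range-of-motion trials.
#'
#' @param subdivisions grid resolution (see [sphere_grid()]).
#' @param saturation pass count at which a patch reaches full intensity.
#' @param grid optionally a prebuilt [sphere_grid()].
#' @return object of class `"coverage_grid"`.
#' @export
coverage_grid <- function(subdivisions = 3L, saturation = 3L, grid = NULL) {
  if (is.null(grid)) grid <- sphere_grid(subdivisions)
  structure(list(grid = grid, counts = integer(nrow(grid$faces)),
                 saturation = as.integer(saturation),
                 last_patch = NA_integer_),
            class = "coverage_grid")
}

#' Update a coverage grid with a trace of sphere points
#'
#' The point stream is interpreted as an ordered trace: consecutive
#' samples falling in the same patch belong to one *pass*, and a patch's
#' counter increments once per pass.  Leaving a patch and re-entering it
#' later (after at least one sample elsewhere) counts as a new pass.
#' Streams may be split across calls; the dwell state is carried in the
#' grid object.
#'
#' @param cov a [coverage_grid()].
#' @param points n x 3 matrix of unit vectors (ordered trace); may be
#'   empty.
#' @return the updated [coverage_grid()].
#' @export
coverage_update <- function(cov, points) {
  stopifnot(inherits(cov, "coverage_grid"))
  if (is.null(dim(points))) {
    if (length(points) == 0L) return(cov)
    points <- matrix(points, 1L)
  }
  points <- as.matrix(points)
  if (nrow(points) == 0L) return(cov)
  ids <- locate_patch(cov$grid, points)
  runs <- rle(ids)$values
  if (!is.na(cov$last_patch) && length(runs) &&
      runs[1L] == cov$last_patch)
    runs <- runs[-1L]                  # continuation of the open dwell
  for (f in runs) cov$counts[f] <- cov$counts[f] + 1L
  cov$last_patch <- ids[length(ids)]
  cov
}

#' Per-patch coverage intensity
#'
#' @param cov a [coverage_grid()].
#' @return numeric vector in \code{[0, 1]}, one value per patch:
#'   `min(passes, saturation) / saturation`.
#' @export
coverage_intensity <- function(cov) {
  stopifnot(inherits(cov, "coverage_grid"))
  pmin(cov$counts, cov$saturation) / cov$saturation
}

#' @export
print.coverage_grid <- function(x, ...) {
  inten <- coverage_intensity(x)
  cat(sprintf("coverage grid: %d patches, %d touched, %d saturated (saturation = %d passes)\n",
              length(x$counts), sum(x$counts > 0L), sum(inten >= 1),
              x$saturation))
  invisible(x)
}
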