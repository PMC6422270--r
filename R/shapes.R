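#' Figural path templates
#'
#' Closed planar paths traced repeatedly by the tongue sensor during
#' syllable repetition. A template is a list with analytic position and
#' first/second parameter derivatives on `u` in `[0, 2*pi)`, so downstream
#' curvature is exact. The long axis lies along `y` (superior), matching the
#' closing/opening direction of a tongue-palate constriction.
#'
#' Templates:
#' * `"ellipse"`: `(aspect*A cos u, A sin u)`.
#' * `"bent_loop"` (default): an ellipse with a second-harmonic bend of the
#'   superior coordinate, `y = A (sin u + bend cos 2u)`. Curvature varies
#'   continuously within a cycle and stays strictly positive for the default
#'   `bend`, which keeps the log curvature-log speed design non-degenerate.
#'
#' @param shape `"ellipse"`, `"bent_loop"`, or a custom template list with
#'   functions `f`, `d1`, `d2` mapping `u` to 2- or 3-column matrices.
#' @param extent peak-to-peak excursion along the principal (superior) axis,
#'   mm.
#' @param aspect minor/major axis ratio of the in-plane figure.
#' @param bend relative second-harmonic amplitude of the bent loop.
#' @param lateral RMS of the lateral (z) component relative to the in-plane
#'   RMS displacement (0 for a planar figure). The lateral course is a
#'   second-harmonic sweep, so the figure is genuinely non-planar.
#' @return a `figural_path` list with elements `f`, `d1`, `d2`, `extent`.
#' @export
figural_path <- function(shape = c("bent_loop", "ellipse"), extent = 15,
                         aspect = 0.6, bend = 0.12, lateral = 0) {
  if (is.list(shape)) {
    stopifnot(is.function(shape$f), is.function(shape$d1), is.function(shape$d2))
    return(structure(c(shape, list(extent = extent)), class = "figural_path"))
  }
  shape <- match.arg(shape)
  A <- extent / 2
  b <- aspect * A
  xy <- switch(shape,
    ellipse = list(
      f  = function(u) cbind(x = b * cos(u),  y = A * sin(u)),
      d1 = function(u) cbind(x = -b * sin(u), y = A * cos(u)),
      d2 = function(u) cbind(x = -b * cos(u), y = -A * sin(u))),
    bent_loop = list(
      f  = function(u) cbind(x = b * cos(u),
                             y = A * (sin(u) + bend * cos(2 * u))),
      d1 = function(u) cbind(x = -b * sin(u),
                             y = A * (cos(u) - 2 * bend * sin(2 * u))),
      d2 = function(u) cbind(x = -b * cos(u),
                             y = A * (-sin(u) - 4 * bend * cos(2 * u)))))
  if (lateral > 0) {
    # calibrate the lateral amplitude on a u-uniform grid so that
    # RMS(z) / RMS(in-plane) matches the requested fraction
    ug <- seq(0, 2 * pi, length.out = 2048L)
    pg <- xy$f(ug)
    rip <- sqrt(mean(scale(pg[, 1], scale = FALSE)^2 +
                       scale(pg[, 2], scale = FALSE)^2))
    zf <- function(u) sin(2 * u + 0.7)
    az <- lateral * rip / sqrt(mean(scale(zf(ug), scale = FALSE)^2))
    tpl <- list(
      f  = function(u) cbind(xy$f(u),  z = az * sin(2 * u + 0.7)),
      d1 = function(u) cbind(xy$d1(u), z = 2 * az * cos(2 * u + 0.7)),
      d2 = function(u) cbind(xy$d2(u), z = -4 * az * sin(2 * u + 0.7)))
  } else tpl <- xy
  structure(c(tpl, list(extent = extent, shape = shape, lateral = lateral)),
            class = "figural_path")
}

#' Curvature and speed-per-parameter of a figural path
#'
#' Works for planar (2-column) and 3D (3-column) templates; curvature is
#' the cross-product form evaluated on the analytic parameter derivatives.
#'
#' @param path a [figural_path()].
#' @param u parameter values.
#' @return data.frame with `u`, `ds_du` (mm per unit parameter) and `kappa`
#'   (1/mm, unsigned).
#' @export
path_geometry <- function(path, u) {
  d1 <- path$d1(u); d2 <- path$d2(u)
  if (ncol(d1) == 2L) { d1 <- cbind(d1, 0); d2 <- cbind(d2, 0) }
  ds <- sqrt(rowSums(d1^2))
  cx <- d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2]
  cy <- d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3]
  cz <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  data.frame(u = u, ds_du = ds, kappa = sqrt(cx^2 + cy^2 + cz^2) / ds^3)
}
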