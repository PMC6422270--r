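#' Penalized quintic regression spline of a recording
#'
#' Represents each axis of each sensor analytically by a least-squares
#' quintic (order-6 B-spline) regression with equidistant knots at the
#' sampling period, so that position, velocity, acceleration and jerk are
#' all available from one spline object. Quintic B-splines on this knot
#' grid are C4-continuous, which implies the required C3 continuity; the
#' least-squares problem with one knot per sample is rank-deficient by a
#' few basis functions, so a small roughness penalty on the integrated
#' squared 4th derivative (relative weight `lambda_rel`) pins the solution
#' without visible bias on band-limited signals.
#'
#' @param rec a [trajectory_recording()] (83.33 Hz after the conditioning
#'   chain, but any uniform rate works).
#' @param sensors sensors to fit; default all.
#' @param lambda_rel relative roughness penalty weight; the absolute weight
#'   is scaled by the ratio of the traces of the Gram and penalty matrices.
#' @return a named list of `smooth_trajectory` objects (one per sensor),
#'   or a single object if one sensor was requested.
#' @export
fit_quintic_spline <- function(rec, sensors = NULL, lambda_rel = 1e-8) {
  if (is.null(sensors)) sensors <- names(rec$channels)
  n <- rec_length(rec)
  if (n < 12)
    stop("need at least 12 samples per channel to fit the quintic spline, got ", n)
  h <- 1 / rec$sample_rate
  t <- rec_times(rec)
  deg <- 5L; ord <- 6L
  knots <- rec$t0 + seq(-deg, n - 1L + deg) / rec$sample_rate
  B <- splines::splineDesign(knots, t, ord = ord, sparse = TRUE)
  # exact penalty on the integral of the squared 4th derivative: the 4th
  # derivative of a quintic spline is piecewise linear, so 2-point Gauss
  # quadrature per inter-knot interval integrates it exactly
  mids <- rec$t0 + (seq_len(n - 1L) - 0.5) / rec$sample_rate
  gauss <- c(mids - h / (2 * sqrt(3)), mids + h / (2 * sqrt(3)))
  D4 <- splines::splineDesign(knots, gauss, ord = ord, derivs = 4, sparse = TRUE)
  P <- (h / 2) * Matrix::crossprod(D4)
  BtB <- Matrix::crossprod(B)
  lambda <- lambda_rel * sum(Matrix::diag(BtB)) / sum(Matrix::diag(P))
  A <- BtB + lambda * P
  fits <- lapply(sensors, function(s) {
    y <- rec$channels[[s]]
    coef <- as.matrix(Matrix::solve(A, Matrix::crossprod(B, y)))
    colnames(coef) <- c("x", "y", "z")
    structure(list(knots = knots, coef = coef, ord = ord,
                   t_range = range(t), sample_rate = rec$sample_rate,
                   sensor = s, metadata = rec$metadata),
              class = "smooth_trajectory")
  })
  names(fits) <- sensors
  if (length(fits) == 1L) fits[[1]] else fits
}

#' @export
print.smooth_trajectory <- function(x, ...) {
  cat(sprintf("<smooth_trajectory> sensor %s on [%.3f, %.3f] s (%d quintic basis fns)\n",
              x$sensor, x$t_range[1], x$t_range[2], nrow(x$coef)))
  invisible(x)
}

#' Evaluate a smooth trajectory or its derivatives
#'
#' @param object a `smooth_trajectory` from [fit_quintic_spline()].
#' @param t evaluation times; must lie within the fitted domain.
#' @param deriv derivative order, 0 (position) to 3 (jerk).
#' @param ... unused.
#' @return length(t) x 3 matrix with columns `x`, `y`, `z` (mm, mm/s, ...).
#' @export
predict.smooth_trajectory <- function(object, t, deriv = 0, ...) {
  stopifnot(deriv %in% 0:3)
  eps <- 1e-9 * diff(object$t_range)
  if (any(t < object$t_range[1] - eps | t > object$t_range[2] + eps))
    stop(sprintf("evaluation outside spline domain [%.6f, %.6f]",
                 object$t_range[1], object$t_range[2]))
  t <- pmin(pmax(t, object$t_range[1]), object$t_range[2])
  B <- splines::splineDesign(object$knots, t, ord = object$ord,
                             derivs = rep(deriv, length(t)), sparse = TRUE)
  out <- as.matrix(B %*% object$coef)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Spline domain
#' @param smooth a `smooth_trajectory`.
#' @return numeric length-2 vector, start and end time (s).
#' @export
spline_domain <- function(smooth) smooth$t_range

#' Serialize / restore a smooth trajectory as JSON
#'
#' Knots and coefficients round-trip losslessly (full double precision), so
#' spline fits can be cached on disk as plain text.
#'
#' @param smooth a `smooth_trajectory`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `smooth_trajectory` (read).
#' @export
write_spline_json <- function(smooth, path) {
  jsonlite::write_json(list(knots = smooth$knots,
                            coef = as.data.frame(smooth$coef),
                            ord = smooth$ord, t_range = smooth$t_range,
                            sample_rate = smooth$sample_rate,
                            sensor = smooth$sensor),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spline_json
#' @export
read_spline_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(knots = j$knots, coef = as.matrix(j$coef), ord = j$ord,
                 t_range = j$t_range, sample_rate = j$sample_rate,
                 sensor = j$sensor, metadata = list()),
            class = "smooth_trajectory")
}

# Fornberg's algorithm: weights of the finite-difference approximation of
# the m-th derivative at z from function values on the (arbitrary) grid x.
fornberg_weights <- function(z, x, m) {
  n <- length(x) - 1L
  c1 <- 1; c4 <- x[1] - z
  C <- matrix(0, n + 1L, m + 1L)
  C[1, 1] <- 1
  for (i in 1:n) {
    mn <- min(i, m)
    c2 <- 1; c5 <- c4; c4 <- x[i + 1L] - z
    for (j in 0:(i - 1L)) {
      c3 <- x[i + 1L] - x[j + 1L]
      c2 <- c2 * c3
      if (j == i - 1L) {
        if (mn >= 1) for (k in mn:1)
          C[i + 1L, k + 1L] <- c1 * (k * C[i, k] - c5 * C[i, k + 1L]) / c2
        C[i + 1L, 1] <- -c1 * c5 * C[i, 1] / c2
      }
      if (mn >= 1) for (k in mn:1)
        C[j + 1L, k + 1L] <- (c4 * C[j + 1L, k + 1L] - k * C[j + 1L, k]) / c3
      C[j + 1L, 1] <- c4 * C[j + 1L, 1] / c3
    }
    c1 <- c2
  }
  C[, m + 1L]
}

#' Nine-point stencil numerical differentiation
#'
#' First or second derivative of a uniformly sampled series using nine-point
#' finite differences with eighth-order accuracy. Interior points use the
#' symmetric stencil; the first and last four points use shifted nine-point
#' stencils of the same accuracy order, so the output has the input length.
#'
#' @param series numeric vector (length >= 9).
#' @param h sampling period, s.
#' @param deriv_order 1 or 2.
#' @return numeric vector of derivative values.
#' @export
nine_point_derivative <- function(series, h, deriv_order = 1) {
  stopifnot(deriv_order %in% c(1, 2), h > 0)
  n <- length(series)
  if (n < 9) stop("series must have at least 9 samples, got ", n)
  np <- 9L
  offs <- 0:(np - 1L)
  out <- numeric(n)
  # boundary stencils: evaluation point at position p of a 9-point window
  for (p in 1:4) {
    wL <- fornberg_weights(p - 1, offs, deriv_order) / h^deriv_order
    out[p] <- sum(wL * series[1:np])
    wR <- fornberg_weights(np - p, offs, deriv_order) / h^deriv_order
    out[n - p + 1L] <- sum(wR * series[(n - np + 1L):n])
  }
  wC <- fornberg_weights(4, offs, deriv_order) / h^deriv_order
  if (n > 8L) {
    idx <- 5:(n - 4L)
    acc <- numeric(length(idx))
    for (j in seq_len(np)) acc <- acc + wC[j] * series[idx + (j - 5L)]
    out[idx] <- acc
  }
  out
}
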