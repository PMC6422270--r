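#' Two-stage FIR decimation of a recording
#'
#' Reduces the sampling rate by the product of `stages` (default 15 = 5 x 3,
#' i.e. 1250 Hz to 83.33 Hz) with two successive 30th-order equiripple
#' (Parks-McClellan) FIR lowpass stages and an effective cutoff at the final
#' Nyquist region of 41.67 Hz. Each stage's linear-phase group delay
#' (order/2 samples) is compensated by an index shift, so the chain has no
#' net delay; edges are handled by odd reflection padding.
#'
#' Band edges: both stages place the passband edge at 0.8 x the effective
#' cutoff; the first (large-factor) stage only needs to suppress energy that
#' would alias into the final band, so its stopband starts at the first
#' alias boundary of its output rate, while the second stage's stopband
#' starts at 1.2 x the effective cutoff with the passband weighted 5:1.
#' This keeps the passband flat to well within 1% at filter order 30.
#'
#' @param rec a [trajectory_recording()].
#' @param stages integer decimation factors, applied in order.
#' @param fir_order FIR filter order per stage.
#' @return the decimated [trajectory_recording()].
#' @export
decimate_two_stage <- function(rec, stages = c(5L, 3L), fir_order = 30L) {
  if (any(stages != round(stages)) || any(stages < 2))
    stop("decimation stages must be integers >= 2; for a total factor of ",
         prod(stages), " try, e.g., ",
         paste(rev(sort(stages_factor(prod(round(stages))))), collapse = " x "))
  fs <- rec$sample_rate
  fc_eff <- fs / prod(stages) / 2          # effective cutoff = final Nyquist
  channels <- rec$channels
  for (si in seq_along(stages)) {
    q <- stages[si]
    fs_out <- fs / q
    pass <- 0.8 * fc_eff
    if (si < length(stages)) {
      stopb <- fs_out - fc_eff             # first alias boundary
      wt <- c(1, 1)
    } else {
      stopb <- 1.2 * fc_eff
      wt <- c(5, 1)
    }
    h <- signal::remez(fir_order, c(0, pass, stopb, fs / 2) / (fs / 2),
                       c(1, 1, 0, 0), w = wt)
    h <- h / sum(h)                        # exact unit DC gain
    delay <- fir_order / 2
    channels <- lapply(channels, function(p) {
      out <- apply(p, 2, function(x) fir_zero_delay(x, h, delay))
      out[seq(1, nrow(out), by = q), , drop = FALSE]
    })
    fs <- fs_out
  }
  trajectory_recording(channels, fs, t0 = rec$t0, roles = rec$roles,
                       metadata = rec$metadata)
}

stages_factor <- function(m) {
  f <- integer(0); d <- 2L
  while (m > 1L && d * d <= m) {
    while (m %% d == 0L) { f <- c(f, d); m <- m %/% d }
    d <- d + 1L
  }
  if (m > 1L) f <- c(f, m)
  f
}

# linear-phase FIR with group-delay compensation and odd reflection padding
fir_zero_delay <- function(x, h, delay) {
  n <- length(x)
  np <- length(h)
  pad_l <- 2 * x[1] - x[seq(np + 1, 2)]
  pad_r <- 2 * x[n] - x[seq(n - 1, n - np)]
  y <- stats::filter(c(pad_l, x, pad_r), h, method = "convolution", sides = 1)
  as.numeric(y[np + delay + seq_len(n)])
}

#' Zero-delay Butterworth lowpass filter
#'
#' Fourth-order Butterworth lowpass (25 Hz by default) applied forward and
#' backward, so the net phase is zero and the effective magnitude response
#' is the squared one-pass response. Edges use odd reflection padding of
#' 3 x the filter order (configurable).
#'
#' @param rec a [trajectory_recording()].
#' @param cutoff cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order of the one-pass filter.
#' @param pad_factor reflection padding length as a multiple of `order`.
#' @return the filtered [trajectory_recording()].
#' @export
lowpass_zero_delay <- function(rec, cutoff = 25, order = 4, pad_factor = 3) {
  nyq <- rec$sample_rate / 2
  if (cutoff >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyq))
  bf <- signal::butter(order, cutoff / nyq)
  np <- max(pad_factor * order, 1L)
  channels <- lapply(rec$channels, function(p)
    apply(p, 2, function(x) iir_filtfilt(x, bf$b, bf$a, np)))
  trajectory_recording(channels, rec$sample_rate, t0 = rec$t0,
                       roles = rec$roles, metadata = rec$metadata)
}

iir_filtfilt <- function(x, b, a, np) {
  n <- length(x)
  np <- min(np, n - 1L)
  xe <- c(2 * x[1] - x[seq(np + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - np)])
  # filter relative to the edge value so the zero-state step transient of
  # each pass vanishes (DC passes exactly)
  x0 <- xe[1]
  y <- as.numeric(signal::filter(b, a, xe - x0)) + x0
  y1 <- y[length(y)]
  y <- rev(as.numeric(signal::filter(b, a, rev(y) - y1)) + y1)
  as.numeric(y[np + seq_len(n)])
}

#' Least-squares rigid transform between point sets (Horn's method)
#'
#' Closed-form absolute orientation by the unit-quaternion method: the
#' rotation maximizing the alignment is the leading eigenvector of the
#' 4x4 quaternion matrix built from the cross-covariance of the centered
#' point sets; translation follows from the centroids. Minimizes
#' `sum ||R s_i + T - t_i||^2`. No scaling is estimated.
#'
#' @param source N x 3 matrix of source points (N >= 3, non-collinear).
#' @param target N x 3 matrix of corresponding target points.
#' @return a `rigid_transform` list with `rotation` (3x3, det +1),
#'   `translation` (length 3) and `quaternion` (w, x, y, z).
#' @export
estimate_rigid_transform <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3, ncol(target) == 3,
            nrow(source) == nrow(target))
  if (nrow(source) < 3) stop("need at least 3 corresponding points")
  cs <- colMeans(source); ct <- colMeans(target)
  S <- sweep(source, 2, cs); T2 <- sweep(target, 2, ct)
  sv <- svd(S)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300))
    stop("degenerate point configuration: source points are collinear ",
         "(rank < 2); the rotation is not identifiable")
  M <- crossprod(S, T2)                     # sum s_c t_c^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N4 <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  eg <- eigen(N4, symmetric = TRUE)
  q <- eg$vectors[, 1]
  if (q[1] < 0) q <- -q
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  structure(list(rotation = R, translation = as.numeric(ct - R %*% cs),
                 quaternion = q),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tr a `rigid_transform` from [estimate_rigid_transform()].
#' @param points N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_rigid_transform <- function(tr, points) {
  sweep(as.matrix(points) %*% t(tr$rotation), 2, tr$translation, `+`)
}

#' Head-movement correction and occlusal frame alignment
#'
#' Estimates, per frame, the rigid transform carrying the reference-sensor
#' positions back to a fixed template (their positions at the first frame by
#' default) and applies it to all channels, removing rigid head motion.
#' Afterwards an optional constant occlusal transform maps landmark points
#' onto the convention axes (origin at `origin`, `anterior` on +x, `plane`
#' in the x-y plane with positive y). With `occlusal = NULL` (the synthetic
#' default) the data are left in the template frame.
#'
#' @param rec a [trajectory_recording()] containing sensors with role
#'   `"reference"`.
#' @param reference_labels sensor names used as references; defaults to all
#'   sensors with role `"reference"`.
#' @param occlusal optional list with 3-vectors `origin`, `anterior`,
#'   `plane` defining the occlusal frame, or `NULL` for identity.
#' @param template optional K x 3 matrix of reference positions defining the
#'   target head frame; defaults to the first frame.
#' @return corrected [trajectory_recording()].
#' @export
correct_head_and_align <- function(rec, reference_labels = NULL,
                                   occlusal = NULL, template = NULL) {
  if (is.null(reference_labels)) reference_labels <- rec_sensors(rec, "reference")
  missing <- setdiff(reference_labels, names(rec$channels))
  if (length(missing) || length(reference_labels) < 3)
    stop("need >= 3 reference sensors; expected {",
         paste(reference_labels, collapse = ", "), "}, found {",
         paste(intersect(reference_labels, names(rec$channels)),
               collapse = ", "), "}")
  n <- rec_length(rec)
  K <- length(reference_labels)
  if (is.null(template))
    template <- t(vapply(reference_labels,
                         function(s) rec$channels[[s]][1, ], numeric(3)))
  frame_pts <- array(NA_real_, c(K, 3, n))
  for (i in seq_len(K)) frame_pts[i, , ] <- t(rec$channels[[reference_labels[i]]])
  channels <- rec$channels
  for (f in seq_len(n)) {
    src <- matrix(frame_pts[, , f], K, 3)
    tr <- estimate_rigid_transform(src, template)
    for (nm in names(channels))
      channels[[nm]][f, ] <- tr$rotation %*% channels[[nm]][f, ] + tr$translation
  }
  if (!is.null(occlusal)) {
    otr <- occlusal_transform(occlusal)
    channels <- lapply(channels, function(p) apply_rigid_transform(otr, p))
  }
  trajectory_recording(channels, rec$sample_rate, t0 = rec$t0,
                       roles = rec$roles, metadata = rec$metadata)
}

# constant transform mapping occlusal landmarks onto the convention axes
occlusal_transform <- function(occ) {
  stopifnot(all(c("origin", "anterior") %in% names(occ)))
  ex <- occ$anterior - occ$origin
  ex <- ex / sqrt(sum(ex^2))
  up <- if (!is.null(occ$plane)) occ$plane - occ$origin else c(0, 1, 0)
  ey <- up - sum(up * ex) * ex
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)
  structure(list(rotation = R, translation = as.numeric(-R %*% occ$origin),
                 quaternion = NULL),
            class = "rigid_transform")
}
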