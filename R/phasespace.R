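#' Phase-space occupancy density of the principal-component signal
#'
#' Histogram of visited states in the (displacement, velocity) plane of the
#' principal component, normalized to unit mass, optionally smoothed with a
#' small Gaussian kernel. Uniform-in-time sampling makes the density an
#' occupancy (sojourn-time) measure: slow regions accumulate mass, so a
#' point attractor shows up as a localized dark blob and a limit cycle as a
#' ring.
#'
#' @param pm a [principal_motion()] (or any list with numeric `scores` and
#'   `score_velocity`).
#' @param nbins grid cells per axis.
#' @param qbox quantile pair defining the bounding box per axis (clipped
#'   samples are assigned to edge cells).
#' @param smooth_sd Gaussian smoothing bandwidth in cells; 0 disables.
#' @return a `phase_density` list with `density` (nbins x nbins, sums to
#'   1), `x_edges`, `v_edges`.
#' @export
phase_density <- function(pm, nbins = 100, qbox = c(0.01, 0.99),
                          smooth_sd = 1) {
  x <- pm$scores; v <- pm$score_velocity
  if (!length(x) || !all(is.finite(x)) || !all(is.finite(v)))
    stop("empty or non-finite phase-space signal")
  bx <- stats::quantile(x, qbox, names = FALSE)
  bv <- stats::quantile(v, qbox, names = FALSE)
  if (diff(bx) == 0) bx <- bx + c(-0.5, 0.5)
  if (diff(bv) == 0) bv <- bv + c(-0.5, 0.5)
  xe <- seq(bx[1], bx[2], length.out = nbins + 1L)
  ve <- seq(bv[1], bv[2], length.out = nbins + 1L)
  ix <- pmin(pmax(findInterval(x, xe, all.inside = TRUE), 1L), nbins)
  iv <- pmin(pmax(findInterval(v, ve, all.inside = TRUE), 1L), nbins)
  dens <- matrix(0, nbins, nbins)
  tab <- table(factor(ix, levels = 1:nbins), factor(iv, levels = 1:nbins))
  dens[] <- as.numeric(tab)
  if (smooth_sd > 0) dens <- gauss_smooth2(dens, smooth_sd)
  dens <- dens / sum(dens)
  structure(list(density = dens, x_edges = xe, v_edges = ve),
            class = "phase_density")
}

gauss_smooth2 <- function(m, sd) {
  r <- ceiling(3 * sd)
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  pad_conv <- function(mm) {
    n <- nrow(mm)
    idx <- pmin(pmax(seq(1 - r, n + r), 1L), n)   # replicate edges
    mp <- mm[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(mm))
    for (j in seq_along(k)) out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Point-like vs ring-like regime score
#'
#' Quantifies whether a [phase_density()] is dominated by a localized blob
#' (fixed-point control regime) or a spread-out ring (limit-cycle regime).
#' Rule: cells at or above `level` x the maximum density form the
#' high-density region; the connected component containing the global mode
#' is the mode blob. Its mean density relative to the mean density of all
#' occupied cells is the concentration factor `C` (1 for a uniform
#' density, order 10 for a ring spread over many cells, order 100+ for a
#' dwell point). The score is the saturating map `C / (C + c0)`, in [0, 1]:
#' scores above 0.5 indicate point-like (fixed-point) structure, below 0.5
#' ring-like. Densities with no salient structure -- the mode blob covers
#' most of the occupied area, or most of the grid is occupied at a
#' concentration close to uniform -- are flagged indeterminate.
#'
#' @param pd a `phase_density`.
#' @param level blob threshold as a fraction of the maximum density.
#' @param c0 concentration scale of the score's saturating map.
#' @param occupied_floor density floor (fraction of uniform mass) above
#'   which a cell counts as occupied.
#' @return list with `score`, `concentration`, `blob_mass`, `blob_cells`,
#'   `occupied_cells`, `indeterminate`.
#' @export
regime_score <- function(pd, level = 0.5, c0 = 10, occupied_floor = 0.05) {
  d <- pd$density
  nb <- nrow(d)
  occ <- d > occupied_floor / length(d)
  mode_idx <- arrayInd(which.max(d), dim(d))
  high <- d >= level * max(d)
  blob <- flood_fill(high, mode_idx[1], mode_idx[2])
  blob_mass <- sum(d[blob])
  blob_cells <- sum(blob)
  occ_cells <- max(sum(occ), 1L)
  conc <- (blob_mass / blob_cells) / (sum(d[occ]) / occ_cells)
  occ_frac <- occ_cells / length(d)
  list(score = conc / (conc + c0),
       concentration = conc,
       blob_mass = blob_mass,
       blob_cells = blob_cells,
       occupied_cells = occ_cells,
       indeterminate = blob_cells > 0.8 * occ_cells ||
         (occ_frac > 0.5 && conc < 3))
}

# connected component (4-neighbour) of a logical matrix containing (i0, j0)
flood_fill <- function(mask, i0, j0) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  start <- (j0 - 1L) * nr + i0
  if (!mask[start]) { out[start] <- TRUE; return(out) }
  queue <- integer(nr * nc)
  queue[1] <- start
  head <- 1L; tail <- 1L
  out[start] <- TRUE
  while (head <= tail) {
    id <- queue[head]; head <- head + 1L
    i <- (id - 1L) %% nr + 1L
    j <- (id - 1L) %/% nr + 1L
    for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      ii <- nb[1]; jj <- nb[2]
      if (ii < 1L || jj < 1L || ii > nr || jj > nc) next
      nid <- (jj - 1L) * nr + ii
      if (mask[nid] && !out[nid]) {
        out[nid] <- TRUE
        tail <- tail + 1L
        queue[tail] <- nid
      }
    }
  }
  out
}

#' Write a phase density as TSV matrix plus JSON metadata
#' @param pd a `phase_density`.
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @export
write_phase_density <- function(pd, path) {
  utils::write.table(pd$density, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(x_edges = pd$x_edges, v_edges = pd$v_edges),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}
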