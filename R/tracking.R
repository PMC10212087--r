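# Template-matching tip tracker: zero-mean normalised cross-correlation
# over a windowed search, parabolic sub-pixel refinement, and conversion
# of loaded-vs-reference position differences into deflections.

#' Match a template inside a search window
#'
#' Zero-mean normalised cross-correlation (NCC) of the template against
#' every candidate anchor position whose patch lies inside the window.
#' Ties on the maximum score are broken by the smallest row, then the
#' smallest column.
#'
#' @param frame Numeric matrix (grayscale image).
#' @param template A [tip_template()].
#' @param row_range,col_range Integer length-2 vectors bounding the
#'   candidate anchor positions (inclusive). Defaults: every position at
#'   which the template fits inside the frame.
#' @return List with `pos` (`c(x, y)`, integer), `score` (max NCC in
#'   `[-1, 1]`), and `surface` (the score matrix, rows = anchor rows).
#' @export
match_template <- function(frame, template,
                           row_range = NULL, col_range = NULL) {
  stopifnot(inherits(template, "tip_template"))
  tr <- template$raster
  th <- nrow(tr); tw <- ncol(tr)
  ar <- template$anchor[1L]; ac <- template$anchor[2L]
  # anchor bounds keeping the patch inside the frame
  rmin <- ar; rmax <- nrow(frame) - (th - ar)
  cmin <- ac; cmax <- ncol(frame) - (tw - ac)
  if (is.null(row_range)) row_range <- c(rmin, rmax)
  if (is.null(col_range)) col_range <- c(cmin, cmax)
  row_range <- as.integer(round(row_range)); col_range <- as.integer(round(col_range))
  abort_if(row_range[1] < rmin || row_range[2] > rmax ||
           col_range[1] < cmin || col_range[2] > cmax,
           "search window must keep the template inside the frame")
  abort_if(row_range[1] > row_range[2] || col_range[1] > col_range[2],
           "empty search window")
  rows <- row_range[1]:row_range[2]
  cols <- col_range[1]:col_range[2]
  # window variance check (constant window -> NCC undefined)
  win <- frame[(rows[1] - ar + 1L):(rows[length(rows)] - ar + th),
               (cols[1] - ac + 1L):(cols[length(cols)] - ac + tw)]
  abort_if(stats::sd(win) == 0,
           "search window is constant: correlation undefined")
  tc <- tr - mean(tr)
  tnorm <- sqrt(sum(tc^2))
  surface <- matrix(-Inf, length(rows), length(cols))
  for (i in seq_along(rows)) {
    r0 <- rows[i] - ar + 1L
    for (j in seq_along(cols)) {
      c0 <- cols[j] - ac + 1L
      p <- frame[r0:(r0 + th - 1L), c0:(c0 + tw - 1L)]
      pc <- p - mean(p)
      pn <- sqrt(sum(pc^2))
      if (pn > 0) surface[i, j] <- sum(pc * tc) / (pn * tnorm)
    }
  }
  best <- max(surface)
  abort_if(!is.finite(best), "all candidate patches are constant")
  hits <- which(surface == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  i <- hits[1L, 1L]; j <- hits[1L, 2L]
  list(pos = c(x = cols[j], y = rows[i]), score = best, surface = surface,
       surface_rows = rows, surface_cols = cols)
}

#' Parabolic sub-pixel peak refinement
#'
#' Separable 1-D parabola through the peak and its two axis neighbours on
#' the score surface; the offset is clamped to `(-0.5, 0.5)` per axis.
#' A peak on the surface border is returned unrefined with a warning.
#'
#' @param surface Score matrix.
#' @param peak Integer `c(row, col)` index of the peak in `surface`.
#' @return Numeric `c(row, col)` with sub-pixel offsets applied.
#' @export
refine_subpixel <- function(surface, peak) {
  i <- peak[1L]; j <- peak[2L]
  if (i <= 1L || i >= nrow(surface) || j <= 1L || j >= ncol(surface)) {
    warning("peak on the border of the score surface; no sub-pixel refinement",
            call. = FALSE)
    return(c(row = i, col = j))
  }
  para <- function(sm, s0, sp) {
    den <- sm - 2 * s0 + sp
    if (abs(den) < .Machine$double.eps * max(1, abs(s0))) return(0)
    off <- 0.5 * (sm - sp) / den
    max(-0.5, min(0.5, off))
  }
  c(row = i + para(surface[i - 1L, j], surface[i, j], surface[i + 1L, j]),
    col = j + para(surface[i, j - 1L], surface[i, j], surface[i, j + 1L]))
}

#' Track both cantilever tips through an image sequence
#'
#' Per step, each tip is searched in a window of `search_radius` pixels
#' around its position at the previous step (the supplied initial
#' positions seed step 0). Tracking fails loudly when the best match score
#' drops below `score_floor` (occlusion or a lost tip) rather than
#' drifting silently.
#'
#' @param frames List of grayscale matrices (step 0 first).
#' @param template A [tip_template()].
#' @param initial_positions 2 x 2 matrix, rows `upper`/`lower`, columns
#'   `(x, y)` in pixels: approximate tip positions in the first frame.
#' @param search_radius Search half-width (px); must cover the per-step
#'   motion.
#' @param score_floor Minimum acceptable NCC score (default 0.5).
#' @param run Label stored with the trajectory (`"reference"` or
#'   `"loaded"`).
#' @return Object of class `tip_trajectory`: a data frame with columns
#'   `step`, `tip`, `x_px`, `y_px`, `score`.
#' @export
track_tips <- function(frames, template, initial_positions,
                       search_radius = 6L, score_floor = 0.5,
                       run = "reference") {
  initial_positions <- as.matrix(initial_positions)
  abort_if(nrow(initial_positions) != 2L || ncol(initial_positions) != 2L,
           "'initial_positions' must be a 2 x 2 (tip x (x, y)) matrix")
  tips <- c("upper", "lower")
  prev <- initial_positions
  rows <- vector("list", length(frames) * 2L)
  k <- 0L
  for (s in seq_along(frames)) {
    for (t in 1:2) {
      ctr <- round(prev[t, ])
      m <- match_template(frames[[s]], template,
                          row_range = clamp_range(ctr[2L] + c(-1, 1) * search_radius,
                                                  frames[[s]], template, "row"),
                          col_range = clamp_range(ctr[1L] + c(-1, 1) * search_radius,
                                                  frames[[s]], template, "col"))
      abort_if(m$score < score_floor,
               sprintf("tracking lost: %s tip at step %d (score %.3f < %.2f)",
                       tips[t], s - 1L, m$score, score_floor))
      pk <- which(m$surface == m$score, arr.ind = TRUE)
      pk <- pk[order(pk[, 1L], pk[, 2L]), , drop = FALSE][1L, ]
      sub <- suppressWarnings(refine_subpixel(m$surface, pk))
      y <- m$surface_rows[1L] + sub[1L] - 1
      x <- m$surface_cols[1L] + sub[2L] - 1
      prev[t, ] <- c(x, y)
      k <- k + 1L
      rows[[k]] <- data.frame(step = s - 1L, tip = tips[t],
                              x_px = x, y_px = y, score = m$score)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "run") <- run
  class(out) <- c("tip_trajectory", "data.frame")
  out
}

clamp_range <- function(rng, frame, template, axis) {
  tr <- template$raster
  if (axis == "row") {
    lo <- template$anchor[1L]; hi <- nrow(frame) - (nrow(tr) - template$anchor[1L])
  } else {
    lo <- template$anchor[2L]; hi <- ncol(frame) - (ncol(tr) - template$anchor[2L])
  }
  out <- c(max(lo, floor(rng[1])), min(hi, ceiling(rng[2])))
  abort_if(out[1] > out[2], "search window falls outside the frame")
  out
}

#' Deflections from loaded and reference trajectories
#'
#' Per tip and step, the deflection is the loaded-minus-reference position
#' difference projected on the compression axis and converted to
#' micrometres. Also reports the loaded tip separation per step (the input
#' to the compression series).
#'
#' @param loaded,reference [track_tips()] results with equal step counts.
#' @param pixel_pitch_um Physical pixel size (um/px).
#' @param axis Unit vector of the compression axis (default vertical,
#'   `c(0, 1)`).
#' @return Object of class `deflection_series`: list with `step`,
#'   `upper_um`, `lower_um` (signed deflections; the upper tip deflects
#'   toward negative axis values, the lower toward positive),
#'   `separation_um` (loaded tip separation) and `pixel_pitch_um`.
#' @export
compute_deflections <- function(loaded, reference, pixel_pitch_um,
                                axis = c(0, 1)) {
  assert_number(pixel_pitch_um, "pixel_pitch_um", positive = TRUE)
  axis <- axis / sqrt(sum(axis^2))
  steps <- sort(unique(loaded$step))
  abort_if(!identical(steps, sort(unique(reference$step))),
           "loaded and reference runs have different step counts")
  proj <- function(traj, tip) {
    d <- traj[traj$tip == tip, ]
    d <- d[order(d$step), ]
    d$x_px * axis[1L] + d$y_px * axis[2L]
  }
  up <- (proj(loaded, "upper") - proj(reference, "upper")) * pixel_pitch_um
  lo <- (proj(loaded, "lower") - proj(reference, "lower")) * pixel_pitch_um
  sep <- (proj(loaded, "lower") - proj(loaded, "upper")) * pixel_pitch_um
  structure(list(step = steps, upper_um = up, lower_um = lo,
                 separation_um = sep, pixel_pitch_um = pixel_pitch_um),
            class = "deflection_series")
}

#' Write a trajectory (or pair of runs) as CSV
#'
#' One row per tip per step: `step, tip, x_px, y_px, score`.
#' @param traj A [track_tips()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
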