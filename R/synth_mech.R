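# Synthetic compression experiment: renders image sequences of two
# cantilever tips approaching (reference run) or pressing on a spheroid
# (loaded run), with full ground truth.
#
# Frames are numeric matrices in [0, 1]; row = image y, column = image x.
# A pixel (r, c) has its centre at image coordinates (x = c, y = r).

#' Image geometry for synthetic compression sequences
#'
#' @param width_px,height_px Frame size in pixels.
#' @param pixel_pitch_um Physical size of one pixel (um/px).
#' @return A list of class `image_spec`.
#' @export
image_spec <- function(width_px = 80L, height_px = 300L, pixel_pitch_um = 2) {
  assert_number(width_px, "width_px", positive = TRUE)
  assert_number(height_px, "height_px", positive = TRUE)
  assert_number(pixel_pitch_um, "pixel_pitch_um", positive = TRUE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_pitch_um = pixel_pitch_um),
            class = "image_spec")
}

#' Construct a tip template
#'
#' A template is the grayscale pattern stamped at (and matched against)
#' each cantilever tip, together with the anchor pixel reported as "the tip
#' position".
#'
#' @param raster Numeric matrix in `[0, 1]` with non-zero variance.
#' @param anchor Length-2 integer `(row, col)` inside the raster; defaults
#'   to the centre pixel.
#' @return Object of class `tip_template`.
#' @export
tip_template <- function(raster, anchor = (dim(raster) + 1) %/% 2) {
  raster <- as.matrix(raster)
  abort_if(stats::sd(raster) == 0, "template must have non-zero variance")
  abort_if(anchor[1] < 1 || anchor[1] > nrow(raster) ||
           anchor[2] < 1 || anchor[2] > ncol(raster),
           "anchor must lie inside the template")
  structure(list(raster = raster, anchor = as.integer(anchor)),
            class = "tip_template")
}

#' Default smooth tip template
#'
#' An isotropic Gaussian spot. A wide smooth pattern keeps the correlation
#' surface locally quadratic, which is what the parabolic sub-pixel
#' refinement assumes.
#'
#' @param size Odd template side length (px).
#' @param sigma Gaussian width (px).
#' @return A [tip_template()].
#' @export
default_tip_template <- function(size = 21L, sigma = 3) {
  stopifnot(size %% 2 == 1)
  c0 <- (size + 1) / 2
  d2 <- outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, "+")
  tip_template(0.85 * exp(-d2 / (2 * sigma^2)))
}

#' Render one frame with tips stamped at sub-pixel positions
#'
#' The template is stamped at each tip position with bilinear sub-pixel
#' placement on a zero background; Gaussian pixel noise is added and the
#' result clipped to `[0, 1]`.
#'
#' @param tip_positions A 2 x 2 matrix, one row per tip, columns `(x, y)`
#'   in pixel coordinates (fractional allowed).
#' @param template A [tip_template()].
#' @param spec An [image_spec()].
#' @param noise_sd Gaussian noise SD as a fraction of the intensity range.
#' @param seed Optional integer seed for the noise (ignored if `NULL`;
#'   the caller may manage the RNG stream instead).
#' @return Numeric matrix `height_px x width_px` in `[0, 1]`.
#' @export
render_tip_frame <- function(tip_positions, template, spec,
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(template, "tip_template"), inherits(spec, "image_spec"))
  tip_positions <- as.matrix(tip_positions)
  abort_if(nrow(tip_positions) < 1L || ncol(tip_positions) != 2L,
           "'tip_positions' must be an n x 2 (x, y) matrix")
  tr <- template$raster
  abort_if(nrow(tr) >= spec$height_px || ncol(tr) >= spec$width_px,
           "template must be smaller than the frame")
  frame <- matrix(0, spec$height_px, spec$width_px)
  boxes <- vector("list", nrow(tip_positions))
  for (i in seq_len(nrow(tip_positions))) {
    st <- stamp_bilinear(tip_positions[i, 1L], tip_positions[i, 2L],
                         tr, template$anchor)
    abort_if(st$r0 < 1L || st$c0 < 1L ||
             st$r0 + nrow(st$raster) - 1L > spec$height_px ||
             st$c0 + ncol(st$raster) - 1L > spec$width_px,
             sprintf("tip %d at (%.2f, %.2f) px leaves the field of view",
                     i, tip_positions[i, 1L], tip_positions[i, 2L]))
    boxes[[i]] <- c(st$r0, st$r0 + nrow(st$raster) - 1L,
                    st$c0, st$c0 + ncol(st$raster) - 1L)
    frame[st$r0:(st$r0 + nrow(st$raster) - 1L),
          st$c0:(st$c0 + ncol(st$raster) - 1L)] <-
      frame[st$r0:(st$r0 + nrow(st$raster) - 1L),
            st$c0:(st$c0 + ncol(st$raster) - 1L)] + st$raster
  }
  if (nrow(tip_positions) == 2L) {
    b1 <- boxes[[1L]]; b2 <- boxes[[2L]]
    overlap <- b1[1] <= b2[2] && b2[1] <= b1[2] &&
               b1[3] <= b2[4] && b2[3] <= b1[4]
    abort_if(overlap, "the two tip stamps overlap")
  }
  add_noise <- function() {
    if (noise_sd > 0)
      frame <<- frame + matrix(stats::rnorm(length(frame), 0, noise_sd),
                               nrow(frame))
  }
  if (is.null(seed)) add_noise() else with_seed(seed, add_noise())
  pmin(pmax(frame, 0), 1)
}

# Bilinear placement: returns the shifted raster and the frame row/col of
# its top-left pixel, such that the template anchor lands at (x, y).
stamp_bilinear <- function(x, y, raster, anchor) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  th <- nrow(raster); tw <- ncol(raster)
  out <- matrix(0, th + 1L, tw + 1L)
  out[1:th, 1:tw]               <- out[1:th, 1:tw] + (1 - fy) * (1 - fx) * raster
  out[2:(th + 1L), 1:tw]        <- out[2:(th + 1L), 1:tw] + fy * (1 - fx) * raster
  out[1:th, 2:(tw + 1L)]        <- out[1:th, 2:(tw + 1L)] + (1 - fy) * fx * raster
  out[2:(th + 1L), 2:(tw + 1L)] <- out[2:(th + 1L), 2:(tw + 1L)] + fy * fx * raster
  list(raster = out,
       r0 = as.integer(y0) - anchor[1L] + 1L,
       c0 = as.integer(x0) - anchor[2L] + 1L)
}

#' Simulate a full compression experiment (reference + loaded runs)
#'
#' Generates the image sequences a tweezer compression produces: a
#' reference run with no sample (tips follow the commanded actuation
#' exactly) and a loaded run in which each step's tip deflection solves
#' the force balance against the compressed sphere
#' ([solve_equilibrium_step()]). Frames include step 0 (before actuation).
#' Identical seeds give bit-identical output.
#'
#' @param profile An [build_actuation_profile()].
#' @param cantilever A [cantilever_spec()].
#' @param spheroid A [spheroid_spec()].
#' @param spec An [image_spec()].
#' @param template A [tip_template()] used for rendering (and, downstream,
#'   for matching).
#' @param noise_sd Pixel noise SD as a fraction of the intensity range.
#' @param seed Integer seed controlling all pixel noise.
#' @param initial_gap_um Initial clearance between the tips and the
#'   spheroid surface (um).
#' @return Object of class `compression_experiment`: lists of frames
#'   `reference` and `loaded` (length `n_steps + 1`), the `truth` ground
#'   truth (commanded separations, deflections, forces, compressions, and
#'   per-run tip positions in um and px), plus the inputs.
#' @export
simulate_compression_experiment <- function(profile,
                                            cantilever = cantilever_preset(),
                                            spheroid = spheroid_preset("day5"),
                                            spec = image_spec(),
                                            template = default_tip_template(),
                                            noise_sd = 0.02,
                                            seed = 1L,
                                            initial_gap_um = 40) {
  stopifnot(inherits(profile, "actuation_profile"),
            inherits(spheroid, "spheroid_spec"))
  s0 <- spheroid$diameter_um + initial_gap_um
  steps <- 0:profile$n_steps
  s_cmd <- s0 - steps * 2 * profile$per_step_displacement
  abort_if(any(s_cmd <= 0), "actuation drives the commanded separation below 0")

  eq <- lapply(s_cmd, solve_equilibrium_step,
               cantilever = cantilever, spheroid = spheroid)
  d_um     <- vapply(eq, `[[`, numeric(1), "tip_deflection_um")
  force_n  <- vapply(eq, `[[`, numeric(1), "contact_force_n")
  delta_um <- vapply(eq, `[[`, numeric(1), "compression_um")

  pitch <- spec$pixel_pitch_um
  cx <- (spec$width_px + 1) / 2
  cy <- (spec$height_px + 1) / 2
  pos_px <- function(sep_half_um) {
    lapply(seq_along(steps), function(i)
      rbind(upper = c(cx, cy - sep_half_um[i] / pitch),
            lower = c(cx, cy + sep_half_um[i] / pitch)))
  }
  ref_half <- s_cmd / 2                 # no sample: tips at commanded positions
  load_half <- s_cmd / 2 + d_um         # sample pushes the tips apart
  ref_pos  <- pos_px(ref_half)
  load_pos <- pos_px(load_half)

  render_run <- function(pos_list, run) {
    lapply(seq_along(pos_list), function(i) {
      tryCatch(render_tip_frame(pos_list[[i]], template, spec,
                                noise_sd = noise_sd),
               error = function(e)
                 stop(sprintf("%s run, step %d: %s", run, i - 1L,
                              conditionMessage(e)), call. = FALSE))
    })
  }
  frames <- with_seed(seed, list(
    reference = render_run(ref_pos, "reference"),
    loaded    = render_run(load_pos, "loaded")
  ))

  structure(list(
    reference = frames$reference,
    loaded    = frames$loaded,
    truth = list(
      step = steps,
      commanded_separation_um = s_cmd,
      deflection_um = d_um,
      force_n = force_n,
      compression_um = delta_um,
      reference_positions_px = ref_pos,
      loaded_positions_px = load_pos,
      loaded_separation_um = 2 * load_half,
      seed = seed
    ),
    template = template, image_spec = spec, profile = profile,
    cantilever = cantilever, spheroid = spheroid,
    noise_sd = noise_sd, seed = seed
  ), class = "compression_experiment")
}

#' Write a frame sequence as step-indexed grayscale TIFFs
#'
#' One 16-bit file per step, zero-padded index (`prefix_0000.tif`, ...).
#'
#' @param frames List of numeric matrices in `[0, 1]`.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Invisibly, the written paths.
#' @export
write_image_sequence <- function(frames, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("%s_%04d.tif", prefix, i - 1L))
    tiff::writeTIFF(frames[[i]], p, bits.per.sample = 16L)
    p
  }, character(1))
  invisible(paths)
}

#' Read a step-indexed TIFF sequence
#'
#' @param dir Directory holding the sequence.
#' @param prefix Filename prefix used when writing.
#' @return List of numeric matrices, in step order.
#' @export
read_image_sequence <- function(dir, prefix = "frame") {
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "_\\d+\\.tif$"),
                           full.names = TRUE))
  abort_if(!length(files), sprintf("no '%s_*.tif' frames found in %s", prefix, dir))
  lapply(files, function(f) {
    m <- tiff::readTIFF(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  })
}
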