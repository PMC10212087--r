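# Instrument and sample descriptions: piezo actuation schedule, cantilever
# geometry, and the spheroid treated as a homogeneous elastic sphere.

#' Build a piezo actuation profile
#'
#' Converts a voltage schedule into commanded per-step tip motion. The
#' instrument steps the piezo by `volts_per_step` up to `max_volts`; the
#' tweezer tip advances `gain` micrometres per volt, so each step moves each
#' tip by `volts_per_step * gain`. Both tips are actuated symmetrically, so
#' the commanded tip separation decreases by twice that amount per step.
#'
#' @param volts_per_step Voltage increment per step (V), > 0.
#' @param max_volts Total voltage range (V), >= `volts_per_step`.
#' @param gain Tip displacement per volt (um/V), > 0.
#' @return An object of class `actuation_profile` with fields
#'   `volts_per_step`, `n_steps`, `gain`, `per_step_displacement` (um/step)
#'   and `symmetric` (always `TRUE`).
#' @examples
#' # 1.1 V steps over a 40 V range, tuned to 4.9 um of tip travel per step
#' build_actuation_profile(1.1, 40, gain = 4.9 / 1.1)
#' @export
build_actuation_profile <- function(volts_per_step, max_volts, gain) {
  assert_number(volts_per_step, "volts_per_step", positive = TRUE)
  assert_number(max_volts, "max_volts", positive = TRUE)
  assert_number(gain, "gain", positive = TRUE)
  abort_if(max_volts < volts_per_step,
           "'max_volts' must be at least one voltage step")
  structure(list(
    volts_per_step = volts_per_step,
    n_steps = as.integer(floor(max_volts / volts_per_step)),
    gain = gain,
    per_step_displacement = volts_per_step * gain,
    symmetric = TRUE
  ), class = "actuation_profile")
}

#' Default actuation preset
#'
#' 1.1 V per step from 0 to 40 V (36 steps), with the gain chosen so each
#' tip advances 4.9 um per step.
#' @return An [build_actuation_profile()] object.
#' @export
actuation_preset <- function() {
  build_actuation_profile(1.1, 40, gain = 4.9 / 1.1)
}

#' Describe a force-sensing micro-cantilever
#'
#' Geometry in SI metres plus either a material modulus (from which the
#' spring constant follows via the Euler-Bernoulli tip-load relation, see
#' [cantilever_spring_constant()]) or an explicit spring constant.
#'
#' @param length_m,width_m,thickness_m Beam dimensions (m), all > 0.
#' @param material_modulus_pa Young's modulus of the beam material (Pa),
#'   or `NULL` if `spring_constant` is given directly.
#' @param spring_constant Optional spring constant (N/m); when supplied it
#'   overrides the geometric derivation.
#' @return An object of class `cantilever_spec`.
#' @examples
#' cantilever_preset()
#' @export
cantilever_spec <- function(length_m = 1.6e-3, width_m = 100e-6,
                            thickness_m = 15e-6,
                            material_modulus_pa = 4e9,
                            spring_constant = NULL) {
  assert_number(length_m, "length_m", positive = TRUE)
  assert_number(width_m, "width_m", positive = TRUE)
  assert_number(thickness_m, "thickness_m", positive = TRUE)
  if (!is.null(material_modulus_pa))
    assert_number(material_modulus_pa, "material_modulus_pa", positive = TRUE)
  if (!is.null(spring_constant))
    assert_number(spring_constant, "spring_constant", positive = TRUE)
  structure(list(length_m = length_m, width_m = width_m,
                 thickness_m = thickness_m,
                 material_modulus_pa = material_modulus_pa,
                 spring_constant = spring_constant),
            class = "cantilever_spec")
}

#' Cantilever preset (1.6 mm x 100 um x 15 um beam)
#'
#' The printed beam geometry with a 4 GPa (SU-8-like) material modulus,
#' giving a spring constant of about 0.082 N/m.
#' @return A [cantilever_spec()] object.
#' @export
cantilever_preset <- function() cantilever_spec()

#' Describe a spheroid as a homogeneous elastic sphere
#'
#' @param diameter_um Spheroid diameter (um), > 0.
#' @param youngs_modulus_pa Effective Young's modulus (Pa), >= 0
#'   (0 models the no-sample reference condition).
#' @param poisson_ratio Poisson ratio in `[0, 0.5]`; defaults to 0.5
#'   (incompressible soft tissue).
#' @return An object of class `spheroid_spec`.
#' @examples
#' spheroid_preset("day20")
#' @export
spheroid_spec <- function(diameter_um, youngs_modulus_pa,
                          poisson_ratio = 0.5) {
  assert_number(diameter_um, "diameter_um", positive = TRUE)
  assert_number(youngs_modulus_pa, "youngs_modulus_pa", nonneg = TRUE)
  assert_number(poisson_ratio, "poisson_ratio", nonneg = TRUE)
  abort_if(poisson_ratio > 0.5 + 1e-9, "'poisson_ratio' must be <= 0.5")
  structure(list(diameter_um = diameter_um,
                 youngs_modulus_pa = youngs_modulus_pa,
                 poisson_ratio = poisson_ratio),
            class = "spheroid_spec")
}

#' Spheroid presets for young and old cultures
#'
#' `"day5"`: 421 um diameter, 260 Pa. `"day20"`: 457 um diameter, 680 Pa.
#' These are the measured group means for size-matched T47D spheroids at the
#' two culture ages.
#'
#' @param preset `"day5"` or `"day20"`.
#' @return A [spheroid_spec()] object.
#' @export
spheroid_preset <- function(preset = c("day5", "day20")) {
  preset <- match.arg(preset)
  switch(preset,
         day5  = spheroid_spec(421, 260),
         day20 = spheroid_spec(457, 680))
}
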