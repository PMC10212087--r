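# Contact mechanics: cantilever stiffness, the sphere-between-plates Hertz
# model, per-step force balance, and Young's modulus fitting.
#
# Public interfaces take micrometres where lengths describe the experiment;
# conversion to SI happens once at the module boundary and everything
# internal is N, m, Pa.

UM <- 1e-6  # metres per micrometre

#' Cantilever spring constant from beam geometry
#'
#' Euler-Bernoulli tip-loaded beam: `k = 3 * E_c * I / L^3` with second
#' moment `I = w * t^3 / 12`. If the spec carries an explicit
#' `spring_constant` it is returned unchanged and the geometry is ignored.
#'
#' @param spec A [cantilever_spec()].
#' @return Spring constant in N/m.
#' @examples
#' cantilever_spring_constant(cantilever_preset())  # ~0.0824 N/m
#' @export
cantilever_spring_constant <- function(spec) {
  stopifnot(inherits(spec, "cantilever_spec"))
  if (!is.null(spec$spring_constant)) return(spec$spring_constant)
  abort_if(is.null(spec$material_modulus_pa),
           "need either 'material_modulus_pa' or an explicit 'spring_constant'")
  I <- spec$width_m * spec$thickness_m^3 / 12
  3 * spec$material_modulus_pa * I / spec$length_m^3
}

#' Contact force on a sphere compressed between two rigid plates
#'
#' Two Hertzian plate contacts act in series, each indenting the sphere by
#' half the total compression:
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * (delta/2)^(3/2)`.
#'
#' @param E Young's modulus (Pa), >= 0.
#' @param nu Poisson ratio in `[0, 0.5]`.
#' @param R_m Sphere radius (m), > 0.
#' @param delta_m Total compression, i.e. diameter reduction (m), >= 0.
#'   Vectorised over `delta_m`.
#' @return Contact force (N).
#' @examples
#' hertz_force(600, 0.5, 212.5e-6, 40e-6)  # ~1.39e-6 N
#' @export
hertz_force <- function(E, nu, R_m, delta_m) {
  assert_number(E, "E", nonneg = TRUE)
  assert_number(nu, "nu", nonneg = TRUE)
  abort_if(nu > 0.5 + 1e-9, "'nu' must be <= 0.5")
  assert_number(R_m, "R_m", positive = TRUE)
  abort_if(any(delta_m < 0), "compression 'delta_m' must be >= 0")
  (4 / 3) * E / (1 - nu^2) * sqrt(R_m) * (delta_m / 2)^1.5
}

# Geometry factor g(delta) such that F = E * g(delta); SI inputs.
hertz_geometry_factor <- function(nu, R_m, delta_m) {
  (4 / 3) / (1 - nu^2) * sqrt(R_m) * (delta_m / 2)^1.5
}

#' Solve the per-step force balance of the loaded tweezer
#'
#' At a commanded tip separation `s`, each cantilever deflects outward by
#' `d` so that the elastic restoring force `k * d` balances the contact
#' force of the compressed sphere, whose compression is
#' `delta = max(0, D0 - (s + 2 d))`. The balance is monotone in `d` and is
#' solved by bisection to a force residual below 1e-12 N.
#'
#' @param commanded_separation_um Commanded tip separation (um).
#' @param cantilever A [cantilever_spec()].
#' @param spheroid A [spheroid_spec()].
#' @return A list with `tip_deflection_um`, `contact_force_n` and
#'   `compression_um`.
#' @export
solve_equilibrium_step <- function(commanded_separation_um, cantilever,
                                   spheroid) {
  k <- cantilever_spring_constant(cantilever)
  abort_if(k <= 0, "spring constant must be > 0")
  D0 <- spheroid$diameter_um * UM
  s  <- commanded_separation_um * UM
  E  <- spheroid$youngs_modulus_pa
  nu <- spheroid$poisson_ratio
  R  <- D0 / 2
  if (s >= D0)  # tips not touching the sphere
    return(list(tip_deflection_um = 0, contact_force_n = 0,
                compression_um = 0))
  if (E == 0)   # nothing pushes back
    return(list(tip_deflection_um = 0, contact_force_n = 0,
                compression_um = (D0 - s) / UM))
  resid <- function(d) k * d - hertz_force(E, nu, R, max(0, D0 - (s + 2 * d)))
  lo <- 0; hi <- (D0 - s) / 2  # resid(lo) <= 0 <= resid(hi)
  d <- hi / 2
  for (it in seq_len(200L)) {
    r <- resid(d)
    if (abs(r) < 1e-12) break
    if (r > 0) hi <- d else lo <- d
    d <- (lo + hi) / 2
  }
  abort_if(abs(resid(d)) >= 1e-12,
           "equilibrium bisection failed to converge (internal error)")
  delta <- max(0, D0 - (s + 2 * d))
  list(tip_deflection_um = d / UM,
       contact_force_n = k * d,
       compression_um = delta / UM)
}

#' Per-step contact force from tip deflections
#'
#' By symmetry the two contact forces are equal and opposite, so the force
#' is the spring constant times the mean absolute deflection of the two
#' tips. Negative individual deflections (tips apparently pulled inward,
#' which only arises from tracking noise) are clipped to zero with a
#' warning.
#'
#' @param deflections A [compute_deflections()] result, or a list with
#'   `upper_um` and `lower_um` numeric vectors (um per step).
#' @param k Spring constant (N/m), > 0.
#' @return Numeric vector of forces (N), one per step.
#' @export
force_from_deflection <- function(deflections, k) {
  assert_number(k, "k", positive = TRUE)
  up <- deflections$upper_um
  lo <- deflections$lower_um
  # the upper tip is pushed toward smaller y, the lower toward larger y;
  # outward deflection magnitudes are -up and +lo
  mag_up <- -up
  mag_lo <- lo
  if (any(mag_up < -1e-9) || any(mag_lo < -1e-9))
    warning("negative (inward) deflections clipped to 0", call. = FALSE)
  k * (pmax(0, mag_up) + pmax(0, mag_lo)) / 2 * UM
}

#' Compression series from measured tip separations
#'
#' `delta(step) = max(0, diameter - separation(step))`; the contact step is
#' the first step with positive compression.
#'
#' @param separation_um Measured tip separation per step (um).
#' @param diameter_um Spheroid diameter (um), > 0.
#' @return List with `delta_um` (per-step compression) and `contact_step`
#'   (index into the series).
#' @export
compression_series <- function(separation_um, diameter_um) {
  assert_number(diameter_um, "diameter_um", positive = TRUE)
  delta <- pmax(0, diameter_um - separation_um)
  abort_if(all(delta <= 0),
           "tip separation never falls below the spheroid diameter: no contact")
  list(delta_um = delta, contact_step = which(delta > 0)[1L])
}

#' Assemble a force-displacement curve
#'
#' @param delta_um Per-step compression (um), non-negative.
#' @param force_n Per-step force (N), same length.
#' @param radius_um Sphere radius (um).
#' @param poisson_ratio Poisson ratio.
#' @param contact_step First step in contact (default: first `delta > 0`).
#' @return Object of class `force_displacement_curve`.
#' @export
force_displacement_curve <- function(delta_um, force_n, radius_um,
                                     poisson_ratio = 0.5,
                                     contact_step = which(delta_um > 0)[1L]) {
  abort_if(length(delta_um) != length(force_n),
           "'delta_um' and 'force_n' must have equal length")
  abort_if(any(delta_um < 0), "compression must be >= 0")
  structure(list(delta_um = delta_um, force_n = force_n,
                 radius_um = radius_um, poisson_ratio = poisson_ratio,
                 contact_step = contact_step),
            class = "force_displacement_curve")
}

#' Fit the Young's modulus to a force-displacement curve
#'
#' The plate-contact model is linear in the modulus, `F = E * g(delta)`
#' with `g(delta) = (4/3) (1-nu^2)^-1 sqrt(R) (delta/2)^(3/2)`, so the
#' least-squares modulus has the closed form `E = sum(g F) / sum(g^2)`
#' over post-contact points (zero intercept). No iterative optimiser is
#' involved.
#'
#' @param curve A [force_displacement_curve()].
#' @return Object of class `modulus_estimate`: `youngs_modulus_pa`,
#'   `residual_n` (RMS force residual), `n_points`, `method`.
#' @export
fit_modulus <- function(curve) {
  stopifnot(inherits(curve, "force_displacement_curve"))
  use <- curve$delta_um > 0
  abort_if(sum(use) < 2L, "need at least 2 post-contact points")
  g <- hertz_geometry_factor(curve$poisson_ratio, curve$radius_um * UM,
                             curve$delta_um[use] * UM)
  F <- curve$force_n[use]
  if (all(F == 0)) {
    warning("all forces are zero; returning modulus 0", call. = FALSE)
    E <- 0
  } else {
    E <- sum(g * F) / sum(g * g)
  }
  structure(list(youngs_modulus_pa = E,
                 residual_n = sqrt(mean((F - E * g)^2)),
                 n_points = sum(use),
                 method = "closed_form"),
            class = "modulus_estimate")
}

#' Grid-search modulus oracle
#'
#' Exhaustive scan of a modulus grid minimising the RMS force residual;
#' an independent check on [fit_modulus()].
#'
#' @param curve A [force_displacement_curve()].
#' @param E_grid Candidate moduli (Pa).
#' @return Object of class `modulus_estimate` with `method = "grid_oracle"`.
#' @export
modulus_oracle <- function(curve, E_grid = seq(1, 2000, by = 1)) {
  stopifnot(inherits(curve, "force_displacement_curve"))
  use <- curve$delta_um > 0
  abort_if(sum(use) < 1L, "need at least 1 post-contact point")
  g <- hertz_geometry_factor(curve$poisson_ratio, curve$radius_um * UM,
                             curve$delta_um[use] * UM)
  F <- curve$force_n[use]
  rms <- vapply(E_grid, function(E) sqrt(mean((F - E * g)^2)), numeric(1))
  i <- which.min(rms)
  if (i == 1L || i == length(E_grid))
    warning("grid-search minimum at the grid edge; enlarge 'E_grid'",
            call. = FALSE)
  structure(list(youngs_modulus_pa = E_grid[i], residual_n = rms[i],
                 n_points = sum(use), method = "grid_oracle"),
            class = "modulus_estimate")
}

#' Model-predicted force ratio of two moduli
#'
#' Under the plate-contact model the force at fixed geometry and
#' compression is proportional to the modulus, so the ratio equals
#' `E_a / E_b` at any indentation depth.
#'
#' @param E_a,E_b Moduli (Pa); `E_b > 0`.
#' @param nu Poisson ratio.
#' @param R_um Sphere radius (um).
#' @param delta_um Compression (um), > 0.
#' @return Dimensionless force ratio.
#' @examples
#' force_ratio(680, 260)  # ~2.615
#' @export
force_ratio <- function(E_a, E_b, nu = 0.5, R_um = 212.5, delta_um = 40) {
  assert_number(E_b, "E_b", positive = TRUE)
  assert_number(delta_um, "delta_um", positive = TRUE)
  hertz_force(E_a, nu, R_um * UM, delta_um * UM) /
    hertz_force(E_b, nu, R_um * UM, delta_um * UM)
}

#' @export
print.modulus_estimate <- function(x, ...) {
  cat(sprintf("Young's modulus estimate: %.1f Pa (%s, %d points, RMS residual %.3g N)\n",
              x$youngs_modulus_pa, x$method, x$n_points, x$residual_n))
  invisible(x)
}
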