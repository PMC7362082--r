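#' Spring and bond constants of the fibrin model
#'
#' Constructs the full parameter set of the multiscale fibrin model: the
#' fibrinogen monomer spring (`k1`, `k2`, `d2`), the knob-hole (A-a) D-E bond
#' law (`k3`, `d3`), the gamma-gamma D-D bond law (`k4`, `d4`) and the lumped
#' inter-protofibril binding spring (`k5`, `k6`, `d5`). Defaults are the
#' calibrated values used throughout the model; all units are pN and nm.
#'
#' `k6` is conventionally tied to `k5` by `k6 = k5 / 500`; a user override
#' that breaks the relation is allowed but triggers a warning.
#'
#' @param k1 Linear monomer stiffness, pN/nm.
#' @param k2 Cubic monomer stiffness, pN/nm^3.
#' @param d2 Extension at which the monomer cubic term switches on
#'   (the fibrinogen molecule length), nm.
#' @param k3 Knob-hole (D-E) saturation force, pN.
#' @param d3 Knob-hole extension scale, nm.
#' @param k4 Gamma-gamma (D-D) saturation force, pN.
#' @param d4 Gamma-gamma extension scale, nm.
#' @param k5 Binding-spring linear stiffness, pN/nm. Setting `k5 = 0`
#'   (with `k6 = 0`) switches the binding force off.
#' @param k6 Binding-spring cubic stiffness, pN/nm^3.
#' @param d5 Binding-spring cubic onset, nm (one quarter of the element
#'   rest length under the default geometry).
#'
#' @return An object of class `fibrin_params`: a named list of the ten
#'   constants.
#' @examples
#' p <- fibrin_params()
#' p$k3 / p$k4   # knob-hole bonds are 10x stronger than gamma-gamma
#' @export
fibrin_params <- function(k1 = 1.5, k2 = 3e-4, d2 = 46,
                          k3 = 130, d3 = 10,
                          k4 = 13, d4 = 20,
                          k5 = 0.1, k6 = k5 / 500, d5 = 11.5) {
  p <- structure(
    list(k1 = k1, k2 = k2, d2 = d2, k3 = k3, d3 = d3,
         k4 = k4, d4 = d4, k5 = k5, k6 = k6, d5 = d5),
    class = "fibrin_params"
  )
  stop_on_violations(validate_parameters(p))
  if (!isTRUE(all.equal(p$k6, p$k5 / 500, tolerance = 1e-8, scale = max(p$k6, 1e-12)))) {
    warn(sprintf(
      "k6 = %g breaks the conventional relation k6 = k5/500 = %g (allowed, not enforced)",
      p$k6, p$k5 / 500))
  }
  p
}

#' Validate a fibrin parameter set
#'
#' Checks every invariant of [fibrin_params()]: all stiffnesses and distances
#' non-negative, and the erf extension scales `d3`, `d4` strictly positive.
#'
#' @param p A `fibrin_params` object (or plain named list with the same
#'   fields).
#' @return A character vector of violation messages, each naming the
#'   offending field; empty when the set is valid.
#' @examples
#' validate_parameters(fibrin_params())        # character(0)
#' @export
validate_parameters <- function(p) {
  v <- character()
  fields <- c("k1", "k2", "d2", "k3", "d3", "k4", "d4", "k5", "k6", "d5")
  for (f in fields) {
    x <- p[[f]]
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      v <- c(v, sprintf("%s: must be a single finite number", f))
    } else if (x < 0) {
      v <- c(v, sprintf("%s: must be >= 0 (got %g)", f, x))
    }
  }
  for (f in c("d3", "d4")) {
    x <- p[[f]]
    if (is.numeric(x) && length(x) == 1 && is.finite(x) && x == 0) {
      v <- c(v, sprintf("%s: must be > 0", f))
    }
  }
  v
}

#' Fibrin fiber geometry
#'
#' Geometry of a single fibrin fiber from which the network size is derived:
#' the number of monomers per cross-section scales the per-monomer force to
#' the fiber force, and the number of protofibril elements along the fiber
#' sets the chain length. Defaults describe a 12 um long, 330 nm diameter
#' fiber with 30% protein content and a 2.25 nm monomer radius, for which
#' 1614 monomers per cross-section and 261 elements are derived.
#'
#' @param fiber_length Fiber length, nm.
#' @param fiber_diameter Fiber diameter, nm.
#' @param protein_fraction Protein volume fraction of the fiber, in (0, 1].
#' @param monomer_radius Fibrin monomer radius, nm.
#' @param element_rest_length Rest length of one protofibril element, nm
#'   (the fibrinogen molecule length).
#' @return An object of class `fiber_geometry`.
#' @seealso [derive_cross_section_count()], [derive_element_count()]
#' @examples
#' g <- fiber_geometry()
#' derive_cross_section_count(g)
#' @export
fiber_geometry <- function(fiber_length = 12000, fiber_diameter = 330,
                           protein_fraction = 0.30, monomer_radius = 2.25,
                           element_rest_length = 46) {
  g <- structure(
    list(fiber_length = fiber_length, fiber_diameter = fiber_diameter,
         protein_fraction = protein_fraction, monomer_radius = monomer_radius,
         element_rest_length = element_rest_length),
    class = "fiber_geometry"
  )
  v <- character()
  for (f in names(unclass(g))) {
    x <- g[[f]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      v <- c(v, sprintf("%s: must be a single finite number > 0", f))
    }
  }
  if (length(v) == 0) {
    if (g$protein_fraction > 1) {
      v <- c(v, "protein_fraction: must be in (0, 1]")
    }
    if (g$fiber_length < g$element_rest_length) {
      v <- c(v, "fiber_length: must be >= element_rest_length")
    }
  }
  stop_on_violations(v)
  g
}

#' Fibrin clot geometry and density
#'
#' Macroscale inputs of the eight-chain clot model: clot diameter, fiber
#' number density and fiber length. Inputs are in the macroscopic units they
#' are usually quoted in (mm, fibers/um^3, um) and are converted internally.
#'
#' @param clot_diameter_mm Clot diameter, mm.
#' @param fiber_density_per_um3 Fiber number density `v`, fibers per um^3.
#' @param fiber_length_um Fiber length `L`, um.
#' @return An object of class `clot_params`.
#' @examples
#' effective_fiber_count(clot_params())   # ~ pi * 1e6
#' @export
clot_params <- function(clot_diameter_mm = 2, fiber_density_per_um3 = 0.5,
                        fiber_length_um = 12) {
  cp <- structure(
    list(clot_diameter_mm = clot_diameter_mm,
         fiber_density_per_um3 = fiber_density_per_um3,
         fiber_length_um = fiber_length_um),
    class = "clot_params"
  )
  v <- character()
  for (f in names(unclass(cp))) {
    x <- cp[[f]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      v <- c(v, sprintf("%s: must be a single finite number > 0", f))
    }
  }
  stop_on_violations(v)
  cp
}

#' Simulation controls for the force continuation
#'
#' @param force_max Maximum applied force per monomer, pN.
#' @param n_steps Number of continuation steps from 0 to `force_max`
#'   (inclusive of the zero-force start).
#' @param solver_tolerance Residual 2-norm bound for convergence, pN.
#' @param break_extension_factor Optional cap on element extension as a
#'   multiple of the rest length; `Inf` (default) disables the cap and
#'   rupture is signalled by solver non-convergence alone.
#' @param random_seed Reserved for future stochastic fiber arrangements;
#'   the present model is fully deterministic.
#' @return An object of class `sim_controls`.
#' @export
sim_controls <- function(force_max = 200, n_steps = 500,
                         solver_tolerance = 1e-8,
                         break_extension_factor = Inf,
                         random_seed = NULL) {
  c0 <- structure(
    list(force_max = force_max, n_steps = n_steps,
         solver_tolerance = solver_tolerance,
         break_extension_factor = break_extension_factor,
         random_seed = random_seed),
    class = "sim_controls"
  )
  v <- character()
  if (!is.numeric(c0$force_max) || length(c0$force_max) != 1 ||
      !is.finite(c0$force_max) || c0$force_max <= 0) {
    v <- c(v, "force_max: must be a single finite number > 0")
  }
  if (!is.numeric(c0$n_steps) || length(c0$n_steps) != 1 ||
      c0$n_steps != round(c0$n_steps) || c0$n_steps < 2) {
    v <- c(v, "n_steps: must be an integer >= 2")
  }
  if (!is.numeric(c0$solver_tolerance) || length(c0$solver_tolerance) != 1 ||
      !is.finite(c0$solver_tolerance) || c0$solver_tolerance <= 0) {
    v <- c(v, "solver_tolerance: must be a single finite number > 0")
  }
  if (!is.numeric(c0$break_extension_factor) ||
      length(c0$break_extension_factor) != 1 || c0$break_extension_factor <= 0) {
    v <- c(v, "break_extension_factor: must be > 0 (Inf allowed)")
  }
  stop_on_violations(v)
  c0$n_steps <- as.integer(c0$n_steps)
  c0$force_max <- as.double(c0$force_max)
  c0$solver_tolerance <- as.double(c0$solver_tolerance)
  c0
}

stop_on_violations <- function(v) {
  if (length(v) > 0) {
    abort(paste0("invalid parameter value(s):\n", paste0("  - ", v, collapse = "\n")),
          class = "fibrinet_validation_error")
  }
  invisible(NULL)
}

#' @export
print.fibrin_params <- function(x, ...) {
  cat("<fibrin_params> (pN, nm units)\n")
  cat(sprintf("  monomer:   k1 = %g pN/nm, k2 = %g pN/nm^3, d2 = %g nm\n",
              x$k1, x$k2, x$d2))
  cat(sprintf("  knob-hole: k3 = %g pN, d3 = %g nm\n", x$k3, x$d3))
  cat(sprintf("  gamma-gamma: k4 = %g pN, d4 = %g nm\n", x$k4, x$d4))
  cat(sprintf("  binding:   k5 = %g pN/nm, k6 = %g pN/nm^3, d5 = %g nm\n",
              x$k5, x$k6, x$d5))
  invisible(x)
}

#' @export
print.fiber_geometry <- function(x, ...) {
  cat("<fiber_geometry>\n")
  cat(sprintf("  length %g nm, diameter %g nm, protein fraction %g\n",
              x$fiber_length, x$fiber_diameter, x$protein_fraction))
  cat(sprintf("  monomer radius %g nm, element rest length %g nm\n",
              x$monomer_radius, x$element_rest_length))
  cat(sprintf("  -> %d monomers / cross-section, %d elements\n",
              derive_cross_section_count(x), derive_element_count(x)))
  invisible(x)
}
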