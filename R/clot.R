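#' Internal fiber stretch of the eight-chain cell
#'
#' In the eight-chain continuum cell, fibers span the corners of a unit cube
#' to its centre. Under uniaxial principal stretch `lambda1` with
#' incompressibility (`lambda2 = lambda3 = 1/sqrt(lambda1)`), every internal
#' fiber stretches by `sqrt((lambda1^2 + 2/lambda1) / 3)`. This is >= 1 for
#' all `lambda1 > 0` (AM-GM), with equality only at `lambda1 = 1`.
#'
#' @param lambda1 Principal stretch along the loading axis (> 0).
#'   Vectorised.
#' @return Fiber stretch, dimensionless.
#' @examples
#' eight_chain_fiber_stretch(2)   # sqrt(5/3) = 1.29099
#' @export
eight_chain_fiber_stretch <- function(lambda1) {
  if (any(!is.finite(lambda1)) || any(lambda1 <= 0)) {
    abort("lambda1 must be finite and > 0")
  }
  sqrt((lambda1^2 + 2 / lambda1) / 3)
}

#' Effective fiber count of the eight-chain clot cell
#'
#' The dimensionless prefactor `pi * D^2 * v * L / 24` of the clot force
#' relation: the number of fibers effectively engaged across the clot
#' cross-section. Computed in consistent units (everything converted to um),
#' so it is invariant under a global change of length unit.
#'
#' @param clot A [clot_params()] object.
#' @return Dimensionless effective fiber count.
#' @examples
#' effective_fiber_count(clot_params())   # pi * 1e6 for the defaults
#' @export
effective_fiber_count <- function(clot) {
  stopifnot(inherits(clot, "clot_params"))
  D_um <- clot$clot_diameter_mm * 1000
  pi * D_um^2 * clot$fiber_density_per_um3 * clot$fiber_length_um / 24
}

# monotone shape-preserving interpolant force(stretch) from a fiber curve;
# the fiber model is force-controlled, the clot relation needs
# stretch-controlled evaluation, so the strictly monotone sampled curve is
# inverted by interpolation (passes through every sample exactly)
fiber_force_interpolant <- function(fiber) {
  stopifnot(inherits(fiber, "force_extension_curve"),
            curve_scale(fiber) == "fiber")
  if (nrow(fiber) < 2) abort("fiber curve needs at least 2 samples")
  splinefun(fiber$stretch, fiber$force_pN, method = "monoH.FC")
}

#' Clot force at a principal stretch (macroscale model)
#'
#' The modified eight-chain force relation for a cylindrical fibrin clot
#' under uniaxial extension:
#' `F_clot = (lambda1 - 1/lambda1^2) * (pi D^2 v L / 24) *
#' F_fiber(lambda_fiber) / lambda_fiber`, with the fiber force taken from a
#' mesoscale [fiber_curve()] by monotone interpolation. Exactly zero at
#' `lambda1 = 1`.
#'
#' @param lambda1 Principal stretch (> 0). Vectorised.
#' @param clot A [clot_params()] object.
#' @param fiber A fiber-scale `force_extension_curve`.
#' @return Clot force in pN (see [clot_curve()] for mN output). `NA` where
#'   the required fiber stretch exceeds the fiber curve's range (clot
#'   rupture).
#' @export
clot_force <- function(lambda1, clot = clot_params(), fiber) {
  lf <- eight_chain_fiber_stretch(lambda1)
  interp <- fiber_force_interpolant(fiber)
  f_fib <- interp(lf)
  out_of_range <- lf > max(fiber$stretch) | lf < min(fiber$stretch)
  f_fib[out_of_range] <- NA_real_
  (lambda1 - 1 / lambda1^2) * effective_fiber_count(clot) * f_fib / lf
}

#' Clot force-stretch curve (macroscale model)
#'
#' Samples the eight-chain clot relation on a uniform principal-stretch grid
#' `lambda1 in [1, lambda_max]`. Each point maps `lambda1` to the internal
#' fiber stretch, interpolates the mesoscale fiber force there, and applies
#' the continuum prefactor. The curve is truncated where the required fiber
#' stretch exceeds the fiber curve's last (pre-rupture) sample — reported as
#' clot rupture in the metadata, not an error.
#'
#' @param params A [fibrin_params()] object.
#' @param geometry A [fiber_geometry()] object.
#' @param clot A [clot_params()] object.
#' @param controls A [sim_controls()] object (for the underlying fiber run).
#' @param lambda_max Upper end of the principal-stretch grid (> 1).
#' @param n_lambda Number of grid points.
#' @param fiber Optionally a precomputed fiber-scale curve (skips the
#'   mesoscale solve).
#' @return A `force_extension_curve` of scale `"clot"` with columns
#'   `lambda1`, `lambda_fiber`, `clot_force_mN`.
#' @examples
#' fib <- fiber_curve(controls = sim_controls(force_max = 200, n_steps = 100))
#' cl <- clot_curve(fiber = fib, lambda_max = 2, n_lambda = 50)
#' glance(cl)
#' @export
clot_curve <- function(params = fibrin_params(), geometry = fiber_geometry(),
                       clot = clot_params(), controls = sim_controls(),
                       lambda_max = 2.5, n_lambda = 200, fiber = NULL) {
  if (!is.finite(lambda_max) || lambda_max <= 1) abort("lambda_max must be > 1")
  if (is.null(fiber)) {
    fiber <- fiber_curve(params = params, geometry = geometry,
                         controls = controls)
  }
  lambda1 <- seq(1, lambda_max, length.out = n_lambda)
  lf <- eight_chain_fiber_stretch(lambda1)
  f_pN <- clot_force(lambda1, clot = clot, fiber = fiber)
  ruptured <- is.na(f_pN)
  rupture_index <- if (any(ruptured)) which(ruptured)[1] else NA_integer_
  keep <- if (is.na(rupture_index)) seq_along(lambda1) else seq_len(rupture_index - 1)
  samples <- tibble(
    lambda1 = lambda1[keep],
    lambda_fiber = lf[keep],
    clot_force_mN = f_pN[keep] * 1e-9    # pN -> mN
  )
  new_force_extension_curve(
    samples, scale = "clot",
    metadata = list(
      params = unclass(params), geometry = unclass(geometry),
      clot = unclass(clot), lambda_max = lambda_max, n_lambda = n_lambda,
      effective_fiber_count = effective_fiber_count(clot),
      fiber_break_index = curve_metadata(fiber)$break_index,
      break_index = rupture_index
    )
  )
}
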