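# erf via the Gaussian CDF identity; abs error < 1e-15 (pnorm is the
# platform special-function routine).
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# linear + Heaviside-gated cubic law shared by the monomer and binding
# springs. H(0) := 1; immaterial since the cubic factor vanishes at onset.
# Compression (x < 0): linear term only, a symmetric restoring force.
cubic_law <- function(x, k_lin, k_cub, onset) {
  k_lin * x + k_cub * ifelse(x >= onset, (x - onset)^3, 0)
}

cubic_law_energy <- function(x, k_lin, k_cub, onset) {
  0.5 * k_lin * x^2 + 0.25 * k_cub * ifelse(x >= onset, (x - onset)^4, 0)
}

cubic_law_stiffness <- function(x, k_lin, k_cub, onset) {
  k_lin + 3 * k_cub * ifelse(x >= onset, (x - onset)^2, 0)
}

erf_law <- function(x, k_sat, d_scale) k_sat * erf(x / d_scale)

erf_law_energy <- function(x, k_sat, d_scale) {
  k_sat * (x * erf(x / d_scale) +
             d_scale / sqrt(pi) * (exp(-(x / d_scale)^2) - 1))
}

erf_law_stiffness <- function(x, k_sat, d_scale) {
  k_sat * 2 / (d_scale * sqrt(pi)) * exp(-(x / d_scale)^2)
}

#' Fibrinogen monomer force law
#'
#' Force-extension relationship of a single fibrinogen molecule: a linear
#' spring plus a cubic spring gated by a Heaviside function,
#' `F = k1 x + k2 H(x - d2) (x - d2)^3`. The cubic term switches on at the
#' molecule length `d2`, where unfolding of the beta-structure stiffens the
#' response. Vectorised over `x`; negative `x` (compression) engages the
#' linear term only.
#'
#' @param x Extension between the end-to-end D-regions, nm. May be a vector.
#' @param params A [fibrin_params()] object.
#' @return Force in pN, same length as `x`.
#' @examples
#' fibrinogen_force(46)   # cubic onset: 1.5 * 46 = 69 pN
#' fibrinogen_force(56)   # 84 + 0.0003 * 10^3 = 84.3 pN
#' @export
fibrinogen_force <- function(x, params = fibrin_params()) {
  stopifnot(all(is.finite(x)))
  cubic_law(x, params$k1, params$k2, params$d2)
}

#' Knob-hole (D-E) bond force law
#'
#' The noncovalent knob-hole (A-a) interaction between a monomer's central
#' E-region and a neighbouring D-region, modelled as an error-function law
#' `F = k3 erf(x / d3)`: linear resistance at small separation, saturating
#' at the rupture force `k3` for large extension. Odd in `x`.
#'
#' @inheritParams fibrinogen_force
#' @return Force in pN.
#' @examples
#' knob_hole_force(10)      # 130 * erf(1) = 109.55 pN
#' knob_hole_force(1e4)     # saturation at k3 = 130 pN
#' @export
knob_hole_force <- function(x, params = fibrin_params()) {
  stopifnot(all(is.finite(x)))
  erf_law(x, params$k3, params$d3)
}

#' Gamma-gamma (D-D) crosslink force law
#'
#' The gamma-gamma crosslink between abutting D-regions of adjacent monomers
#' in one strand, `F = k4 erf(x / d4)`. With defaults it is 10 times weaker
#' than the knob-hole bond and its extension scale twice as large.
#'
#' @inheritParams fibrinogen_force
#' @return Force in pN.
#' @examples
#' gamma_gamma_force(20)    # 13 * erf(1) = 10.955 pN
#' @export
gamma_gamma_force <- function(x, params = fibrin_params()) {
  stopifnot(all(is.finite(x)))
  erf_law(x, params$k4, params$d4)
}

#' Inter-protofibril binding force law
#'
#' Lumped lateral interaction between protofibrils (alpha-C crosslinking,
#' Factor XIIIa, solvent and electrostatic effects), acting in parallel
#' across each protofibril element:
#' `F = k5 x_elem + k6 H(x_elem - d5) (x_elem - d5)^3`. Setting `k5 = 0`
#' (with `k6` tied as `k5/500`) switches the binding force off.
#'
#' @param x_elem Elongation of a single protofibril element, nm.
#' @param params A [fibrin_params()] object.
#' @return Force in pN.
#' @examples
#' binding_force(11.5)      # 0.1 * 11.5 = 1.15 pN (cubic zero at onset)
#' @export
binding_force <- function(x_elem, params = fibrin_params()) {
  stopifnot(all(is.finite(x_elem)))
  cubic_law(x_elem, params$k5, params$k6, params$d5)
}

spring_kinds <- c("monomer_half", "knob_hole", "gamma_gamma", "binding",
                  "rigid_tie")

# Half-monomer springs use (2 k1, 8 k2, d2/2) so that two in series
# reproduce the whole-molecule law exactly: each half at extension x/2 and
# force F satisfies 2 k1 (x/2) + 8 k2 ((x - d2)/2)^3 = k1 x + k2 (x - d2)^3.
spring_law_constants <- function(kind, params) {
  switch(kind,
    monomer_half = list(type = "cubic", k_lin = 2 * params$k1,
                        k_cub = 8 * params$k2, onset = params$d2 / 2),
    knob_hole    = list(type = "erf", k_sat = params$k3, d_scale = params$d3),
    gamma_gamma  = list(type = "erf", k_sat = params$k4, d_scale = params$d4),
    binding      = list(type = "cubic", k_lin = params$k5,
                        k_cub = params$k6, onset = params$d5),
    rigid_tie    = list(type = "rigid"),
    abort(sprintf("unknown spring kind: '%s'", kind))
  )
}

#' Force, energy and stiffness of a network spring
#'
#' Evaluates the force law (or its potential energy / derivative) attached to
#' one spring kind of the protofibril element network. Kinds are
#' `"monomer_half"` (half of a fibrinogen molecule; two in series reproduce
#' [fibrinogen_force()] exactly), `"knob_hole"`, `"gamma_gamma"`,
#' `"binding"`, and `"rigid_tie"` (a zero-length rigid attachment used for
#' the dummy load nodes, carrying no elastic energy).
#'
#' `spring_energy()` is the antiderivative of `spring_force()` with
#' `energy(0) = 0`; it backs the energy-minimization view of equilibrium.
#'
#' @param kind One of `"monomer_half"`, `"knob_hole"`, `"gamma_gamma"`,
#'   `"binding"`, `"rigid_tie"`.
#' @param x Spring extension (deviation from rest separation), nm.
#'   Vectorised.
#' @param params A [fibrin_params()] object.
#' @return `spring_force()`: pN; `spring_energy()`: pN nm;
#'   `spring_stiffness()`: pN/nm.
#' @examples
#' spring_energy("monomer_half", 10)    # 1.5 * 100 = 150 pN nm (linear regime)
#' @export
spring_force <- function(kind, x, params = fibrin_params()) {
  stopifnot(all(is.finite(x)))
  cst <- spring_law_constants(kind, params)
  switch(cst$type,
    cubic = cubic_law(x, cst$k_lin, cst$k_cub, cst$onset),
    erf   = erf_law(x, cst$k_sat, cst$d_scale),
    rigid = abort("rigid_tie springs are constraints; they have no force law")
  )
}

#' @rdname spring_force
#' @export
spring_energy <- function(kind, x, params = fibrin_params()) {
  stopifnot(all(is.finite(x)))
  cst <- spring_law_constants(kind, params)
  switch(cst$type,
    cubic = cubic_law_energy(x, cst$k_lin, cst$k_cub, cst$onset),
    erf   = erf_law_energy(x, cst$k_sat, cst$d_scale),
    rigid = rep(0, length(x))
  )
}

#' @rdname spring_force
#' @export
spring_stiffness <- function(kind, x, params = fibrin_params()) {
  stopifnot(all(is.finite(x)))
  cst <- spring_law_constants(kind, params)
  switch(cst$type,
    cubic = cubic_law_stiffness(x, cst$k_lin, cst$k_cub, cst$onset),
    erf   = erf_law_stiffness(x, cst$k_sat, cst$d_scale),
    rigid = abort("rigid_tie springs are constraints; they have no force law")
  )
}

#' Molecule-scale force-extension curve
#'
#' Samples [fibrinogen_force()] on a uniform extension grid, returning a
#' molecule-scale curve object ready for [write_curve_csv()] or
#' [autoplot()].
#'
#' @param params A [fibrin_params()] object.
#' @param x_max Maximum extension, nm.
#' @param n Number of samples.
#' @return A `force_extension_curve` tibble with columns `extension_nm` and
#'   `force_pN` (scale `"molecule"`).
#' @export
fibrinogen_curve <- function(params = fibrin_params(), x_max = 120, n = 200) {
  x <- seq(0, x_max, length.out = n)
  new_force_extension_curve(
    tibble(extension_nm = x, force_pN = fibrinogen_force(x, params)),
    scale = "molecule",
    metadata = list(params = unclass(params), x_max = x_max, n = n)
  )
}
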