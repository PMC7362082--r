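#' Single-fiber force-stretch curve (mesoscale model)
#'
#' Runs the quasi-static force continuation on the protofibril network: the
#' per-monomer force is stepped over a uniform grid from 0 to
#' `controls$force_max` (`controls$n_steps` samples), each equilibrium solved
#' by [solve_equilibrium()] warm-started from the previous step. Stretch is
#' the deformed fiber length over the rest length; the fiber force is the
#' per-monomer force times the number of monomers per cross-section (1614
#' with the default geometry, all protofibrils parallel and equally loaded).
#'
#' By default a single element is solved and replicated: under the rigid
#' crosshead grip every element of the chain deforms identically, so the
#' per-element extension times the element count is the fiber extension
#' exactly (see the replication-symmetry property in the package tests).
#' `full_chain = TRUE` solves all elements simultaneously instead.
#'
#' A step that fails to converge is retried over ten sub-steps from the last
#' converged state; if it still fails the fiber is considered ruptured and
#' the curve is truncated there, with the break step recorded in the
#' metadata.
#'
#' @param params A [fibrin_params()] object.
#' @param geometry A [fiber_geometry()] object.
#' @param controls A [sim_controls()] object.
#' @param full_chain Solve the full element chain instead of the replicated
#'   single element (slower; identical result).
#' @return A `force_extension_curve` of scale `"fiber"` with columns
#'   `stretch`, `extension_nm`, `force_pN`, `per_monomer_force_pN`,
#'   `converged`.
#' @examples
#' crv <- fiber_curve(controls = sim_controls(force_max = 50, n_steps = 25))
#' glance(crv)
#' @export
fiber_curve <- function(params = fibrin_params(), geometry = fiber_geometry(),
                        controls = sim_controls(), full_chain = FALSE) {
  n_elem <- derive_element_count(geometry)
  n_mono <- derive_cross_section_count(geometry)
  n_build <- if (full_chain) n_elem else 1L
  topology <- build_element_topology(geometry, n_elements = n_build)
  span_built <- n_build * geometry$element_rest_length
  span_fiber <- n_elem * geometry$element_rest_length

  forces <- seq(0, controls$force_max, length.out = controls$n_steps)
  stretch <- numeric(0); converged <- logical(0)
  break_index <- NA_integer_
  v <- numeric(topology$n_dof)
  res_fn <- function(vv, F) residual_from_dofs(topology, vv, F, params)
  jac_fn <- function(vv) residual_jacobian(topology, vv, params)

  solve_at <- function(F, v_init) {
    dogleg_root(function(vv) res_fn(vv, F), jac_fn, v_init,
                tol = controls$solver_tolerance)
  }

  for (j in seq_along(forces)) {
    F <- forces[j]
    sol <- solve_at(F, v)
    if (!sol$converged && j > 1) {
      # retry over ten sub-steps from the last converged state
      v_sub <- v
      F_prev <- forces[j - 1]
      ok <- TRUE
      for (Fs in seq(F_prev, F, length.out = 11)[-1]) {
        sub <- solve_at(Fs, v_sub)
        if (!sub$converged) { ok <- FALSE; break }
        v_sub <- sub$v
      }
      if (ok) sol <- list(v = v_sub, converged = TRUE)
    }
    if (!sol$converged) {
      break_index <- j
      break
    }
    v <- sol$v
    lam <- 1 + v[topology$crosshead_dof] / span_built
    if (lam - 1 > controls$break_extension_factor) {
      break_index <- j
      break
    }
    stretch <- c(stretch, lam)
    converged <- c(converged, TRUE)
  }

  kept <- seq_along(stretch)
  samples <- tibble(
    stretch = stretch,
    extension_nm = (stretch - 1) * span_fiber,
    force_pN = n_mono * forces[kept],
    per_monomer_force_pN = forces[kept],
    converged = converged
  )
  new_force_extension_curve(
    samples, scale = "fiber",
    metadata = list(
      params = unclass(params), geometry = unclass(geometry),
      controls = unclass(controls)[c("force_max", "n_steps", "solver_tolerance",
                                     "break_extension_factor")],
      n_elements = n_elem, monomers_per_cross_section = n_mono,
      full_chain = full_chain, break_index = break_index
    )
  )
}
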