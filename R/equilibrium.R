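# spring extensions given per-node displacements (1D: extension is the
# relative axial displacement of the endpoints; rest separation cancels)
spring_extensions <- function(topology, u) {
  s <- topology$springs
  u[s$node_b] - u[s$node_a]
}

# per-dof external load vector for per-monomer force F: each dummy node
# carries F, so the crosshead dof receives the total 2F per protofibril
external_load <- function(topology, force_per_monomer) {
  f <- numeric(topology$n_dof)
  d <- topology$nodes$dof[topology$loaded_nodes]
  for (dd in d) f[dd] <- f[dd] + force_per_monomer
  f
}

#' Quasi-static force-balance residual
#'
#' Net axial force on every free degree of freedom of a protofibril network:
#' the sum of spring forces exerted on the node(s) of each dof (each spring
#' evaluated at its extension, the relative displacement of its endpoints)
#' plus the external load on the loaded crosshead. The residual is the
#' negative gradient of [total_energy()] with respect to the free
#' displacements; equilibrium is its root.
#'
#' @param topology A [build_element_topology()] network.
#' @param u Per-node axial displacements, nm (fixed nodes must be zero and
#'   crosshead-tied nodes equal).
#' @param force_per_monomer Applied force per fibrin monomer, pN.
#' @param params A [fibrin_params()] object.
#' @return Numeric vector of length `topology$n_dof`, pN.
#' @examples
#' top <- build_element_topology(fiber_geometry(), n_elements = 1)
#' assemble_residual(top, rep(0, 9), 0, fibrin_params())  # zeros: rest state
#' @export
assemble_residual <- function(topology, u, force_per_monomer,
                              params = fibrin_params()) {
  v <- displacements_to_dofs(topology, u)  # validates dimensions/constraints
  residual_from_dofs(topology, v, force_per_monomer, params)
}

residual_from_dofs <- function(topology, v, force_per_monomer, params) {
  u <- dofs_to_displacements(topology, v)
  s <- topology$springs
  live <- s$kind != "rigid_tie"
  x <- (u[s$node_b] - u[s$node_a])[live]
  kindv <- s$kind[live]
  f <- numeric(length(x))
  for (k in unique(kindv)) {
    sel <- kindv == k
    f[sel] <- spring_force(k, x[sel], params)
  }
  da <- topology$nodes$dof[s$node_a[live]]
  db <- topology$nodes$dof[s$node_b[live]]
  r <- external_load(topology, force_per_monomer)
  # tension f > 0 pulls node_b backward and node_a forward
  oka <- !is.na(da); okb <- !is.na(db)
  r_add <- c(f[oka], -f[okb])
  idx <- c(da[oka], db[okb])
  agg <- rowsum(r_add, idx)
  r[as.integer(rownames(agg))] <- r[as.integer(rownames(agg))] + agg[, 1]
  r
}

#' Total potential energy of a protofibril network
#'
#' Sum of [spring_energy()] over all springs minus the work of the applied
#' load, `sum(F * u_loaded)`. Equilibrium states are stationary points:
#' [assemble_residual()] equals the negative gradient of this function with
#' respect to the free displacements, which is the independent check used by
#' the test suite's energy-minimization oracle.
#'
#' @inheritParams assemble_residual
#' @return Energy in pN nm.
#' @export
total_energy <- function(topology, u, force_per_monomer,
                         params = fibrin_params()) {
  if (length(u) != nrow(topology$nodes)) {
    abort(sprintf("displacements must have one entry per node (%d), got %d",
                  nrow(topology$nodes), length(u)))
  }
  s <- topology$springs
  live <- s$kind != "rigid_tie"
  x <- (u[s$node_b] - u[s$node_a])[live]
  kindv <- s$kind[live]
  e <- 0
  for (k in unique(kindv)) {
    sel <- kindv == k
    e <- e + sum(spring_energy(k, x[sel], params))
  }
  e - force_per_monomer * sum(u[topology$loaded_nodes])
}

# analytic tangent-stiffness Jacobian of the residual, sparse
residual_jacobian <- function(topology, v, params) {
  u <- dofs_to_displacements(topology, v)
  s <- topology$springs
  live <- s$kind != "rigid_tie"
  x <- (u[s$node_b] - u[s$node_a])[live]
  kindv <- s$kind[live]
  k <- numeric(length(x))
  for (kk in unique(kindv)) {
    sel <- kindv == kk
    k[sel] <- spring_stiffness(kk, x[sel], params)
  }
  da <- topology$nodes$dof[s$node_a[live]]
  db <- topology$nodes$dof[s$node_b[live]]
  # d r_da / d v = -k at da, +k at db ; d r_db / d v = +k at da, -k at db
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  oka <- !is.na(da); okb <- !is.na(db); okab <- oka & okb
  ii <- c(da[oka], db[okb], da[okab], db[okab])
  jj <- c(da[oka], db[okb], db[okab], da[okab])
  xx <- c(-k[oka], -k[okb], k[okab], k[okab])
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(topology$n_dof, topology$n_dof))
}

# Powell trust-region dogleg root solver on r(v) = 0 with analytic sparse
# Jacobian. Non-convergence is returned, never thrown.
#
# If the trust region collapses before the residual reaches `tol`, the
# result is still accepted when the residual is at the rounding floor of the
# tangent stiffness (eps * ||J||_inf * |v|): with near-rigid springs the
# force balance cannot be evaluated more precisely in double precision, and
# demanding it would misreport machine-precision equilibria as ruptures.
dogleg_root <- function(res_fn, jac_fn, v0, tol, max_iter = 200L) {
  v <- v0
  r <- res_fn(v)
  rnorm <- sqrt(sum(r^2))
  delta <- max(1, sqrt(sum(v^2)))
  delta_max <- 1e8
  iter <- 0L
  while (rnorm > tol && iter < max_iter) {
    iter <- iter + 1L
    J <- jac_fn(v)
    g <- as.numeric(Matrix::crossprod(J, r))       # grad of 0.5 ||r||^2
    Jg <- as.numeric(J %*% g)
    p_newton <- tryCatch(as.numeric(Matrix::solve(J, -r)),
                         error = function(e) NULL)
    step_taken <- FALSE
    while (!step_taken && delta > 1e-13) {
      p <- dogleg_step(r, g, Jg, p_newton, delta)
      r_trial <- res_fn(v + p)
      pred <- 0.5 * rnorm^2 - 0.5 * sum((r + as.numeric(J %*% p))^2)
      ared <- 0.5 * rnorm^2 - 0.5 * sum(r_trial^2)
      rho <- if (pred > 0) ared / pred else -1
      if (rho >= 1e-4) {
        v <- v + p
        r <- r_trial
        rnorm <- sqrt(sum(r^2))
        step_taken <- TRUE
        if (rho > 0.75 && sqrt(sum(p^2)) > 0.9 * delta) {
          delta <- min(2 * delta, delta_max)
        } else if (rho < 0.25) {
          delta <- delta / 4
        }
      } else {
        delta <- delta / 4
      }
    }
    if (!step_taken) break   # trust region collapsed: stalled
  }
  converged <- rnorm <= tol
  if (!converged) {
    noise_floor <- 100 * .Machine$double.eps *
      max(Matrix::rowSums(abs(jac_fn(v)))) * max(1, max(abs(v)))
    converged <- rnorm <= noise_floor
  }
  list(v = v, residual_norm = rnorm, converged = converged,
       iterations = iter)
}

dogleg_step <- function(r, g, Jg, p_newton, delta) {
  if (!is.null(p_newton) && all(is.finite(p_newton)) &&
      sqrt(sum(p_newton^2)) <= delta) {
    return(p_newton)
  }
  gnorm2 <- sum(g^2)
  Jgnorm2 <- sum(Jg^2)
  if (Jgnorm2 <= 0 || gnorm2 <= 0) {
    # degenerate gradient: fall back to a clipped Newton direction if any
    if (!is.null(p_newton) && all(is.finite(p_newton))) {
      return(p_newton * delta / sqrt(sum(p_newton^2)))
    }
    return(rep(0, length(g)))
  }
  p_cauchy <- -(gnorm2 / Jgnorm2) * g
  pc_norm <- sqrt(sum(p_cauchy^2))
  if (pc_norm >= delta) {
    return(-g * delta / sqrt(gnorm2))
  }
  if (is.null(p_newton) || !all(is.finite(p_newton))) {
    return(p_cauchy)
  }
  # dogleg segment from the Cauchy point towards the Newton point
  d <- p_newton - p_cauchy
  a <- sum(d^2)
  b <- 2 * sum(p_cauchy * d)
  cc <- pc_norm^2 - delta^2
  tau <- (-b + sqrt(max(b^2 - 4 * a * cc, 0))) / (2 * a)
  p_cauchy + tau * d
}

#' Solve a protofibril network for quasi-static equilibrium
#'
#' Finds nodal displacements at which every free degree of freedom is in
#' force balance under an applied per-monomer force, by trust-region dogleg
#' root finding on [assemble_residual()] with an analytic sparse tangent
#' Jacobian. Non-convergence is reported in the returned state (downstream it
#' is interpreted as fiber rupture), never thrown as an error.
#'
#' @inheritParams assemble_residual
#' @param force_per_monomer Applied force per fibrin monomer, pN.
#' @param init Optional per-node initial displacements (typically the
#'   previous continuation step's solution). Default: the rest state.
#' @param controls A [sim_controls()] object (supplies `solver_tolerance`).
#' @return An object of class `equilibrium_state`: list with
#'   `applied_force_per_monomer`, `displacements` (per node, fixed nodes
#'   exactly 0), `residual_norm`, `converged` and `iterations`.
#' @examples
#' top <- build_element_topology(fiber_geometry(), n_elements = 1)
#' st <- solve_equilibrium(top, force_per_monomer = 50)
#' st$converged
#' @export
solve_equilibrium <- function(topology, force_per_monomer,
                              params = fibrin_params(), init = NULL,
                              controls = sim_controls()) {
  v0 <- if (is.null(init)) {
    numeric(topology$n_dof)
  } else if (length(init) == nrow(topology$nodes)) {
    displacements_to_dofs(topology, init)
  } else if (length(init) == topology$n_dof) {
    init
  } else {
    abort(sprintf(
      "init must have one entry per node (%d) or per dof (%d), got %d",
      nrow(topology$nodes), topology$n_dof, length(init)))
  }
  sol <- dogleg_root(
    res_fn = function(v) residual_from_dofs(topology, v, force_per_monomer, params),
    jac_fn = function(v) residual_jacobian(topology, v, params),
    v0 = v0, tol = controls$solver_tolerance
  )
  structure(
    list(applied_force_per_monomer = force_per_monomer,
         displacements = dofs_to_displacements(topology, sol$v),
         residual_norm = sol$residual_norm,
         converged = sol$converged,
         iterations = sol$iterations),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_state> F = %g pN/monomer, %s (|r| = %.3g pN, %d iter), end displacement %.6g nm\n",
    x$applied_force_per_monomer,
    if (x$converged) "converged" else "NOT converged",
    x$residual_norm, x$iterations, max(x$displacements)))
  invisible(x)
}

#' @method tidy equilibrium_state
#' @export
tidy.equilibrium_state <- function(x, ...) {
  tibble(node_id = seq_along(x$displacements),
         displacement_nm = x$displacements)
}

#' @method glance equilibrium_state
#' @export
glance.equilibrium_state <- function(x, ...) {
  tibble(applied_force_per_monomer = x$applied_force_per_monomer,
         residual_norm = x$residual_norm,
         converged = x$converged,
         iterations = x$iterations)
}
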