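# Independent oracles used across the suite. None of these call the
# package's dogleg solver or its analytic Jacobian/energy identities for the
# quantity they check.

# Brute-force energy minimization: equilibrium as the minimizer of
# total_energy over the free dofs, found with a quasi-Newton optimizer using
# finite-difference gradients only.
minimize_energy_oracle <- function(topology, force, params,
                                   controls = sim_controls()) {
  n_nodes <- nrow(topology$nodes)
  dof <- topology$nodes$dof
  v2u <- function(v) ifelse(is.na(dof), 0, v[dof])
  fn <- function(v) total_energy(topology, v2u(v), force, params)
  res <- optim(rep(0, topology$n_dof), fn, method = "L-BFGS-B",
               control = list(maxit = 10000, factr = 10))
  # polish once more from the found point
  res <- optim(res$par, fn, method = "L-BFGS-B",
               control = list(maxit = 10000, factr = 10))
  v2u(res$par)
}

# central-difference gradient of total_energy with respect to the free dofs
energy_gradient_fd <- function(topology, v, force, params, h = 1e-6) {
  dof <- topology$nodes$dof
  v2u <- function(v) ifelse(is.na(dof), 0, v[dof])
  vapply(seq_along(v), function(i) {
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    (total_energy(topology, v2u(vp), force, params) -
       total_energy(topology, v2u(vm), force, params)) / (2 * h)
  }, numeric(1))
}

# closed-form serial-spring stretch: the whole-monomer law inverted by
# bisection, lambda(F) = 1 + x(F) / element_rest_length
serial_limit_stretch <- function(F, params = fibrin_params(), L = 46) {
  x <- vapply(F, function(f) {
    if (f == 0) return(0)
    uniroot(function(x) params$k1 * x +
              params$k2 * ifelse(x > params$d2, (x - params$d2)^3, 0) - f,
            c(0, 1e4), tol = 1e-13)$root
  }, numeric(1))
  1 + x / L
}

# frozen reference value: erf(1) from standard tables
ERF1 <- 0.842700792949715
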