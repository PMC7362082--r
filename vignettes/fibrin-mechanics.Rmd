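---
title: "Multiscale spring-network mechanics of fibrin fibers and clots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale spring-network mechanics of fibrin fibers and clots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrinet)
library(ggplot2)
```

## The model

Fibrin — the polymerised form of the plasma protein fibrinogen — is the
structural scaffold of blood clots. Its mechanics are unusual: single fibers
stretch to several times their rest length before breaking, and both fibers
and whole clots stiffen in a way that entropic worm-like-chain (WLC)
elasticity does not capture. fibrinet models this behaviour as a hierarchy
of nonlinear springs instead, at three coupled scales.

### Molecule scale

A fibrinogen monomer of rest length $d_2 = 46$ nm is a linear spring with a
Heaviside-gated cubic term that switches on at full extension, where
unfolding of the molecule's $\beta$-structure stiffens the response:

$$F_\text{molecule}(x) = k_1 x + k_2\, H(x - d_2)\,(x - d_2)^3 .$$

With $k_1 = 1.5$ pN/nm and $k_2 = 3\times10^{-4}$ pN/nm$^3$ the law runs
through the 150–300 pN range where $\beta$-sheet unfolding is observed.

### Fiber scale

Monomers polymerise into double-stranded, half-staggered protofibrils.
The repeating *protofibril element* (rest length 46 nm) is a small spring
network:

* each half-monomer is a spring with constants $(2k_1,\,8k_2,\,d_2/2)$, so
  two in series reproduce the whole-molecule law exactly;
* the knob–hole (A–a) bond between a central E-region and an opposing
  D-region follows the saturating law $F_{D\text{–}E} = k_3\,
  \mathrm{erf}(x/d_3)$ with $k_3 = 130$ pN (the single-bond rupture force)
  and $d_3 = 10$ nm (the assumed maximum elongation before rupture);
* the $\gamma$–$\gamma$ crosslink between abutting D-regions follows
  $F_{D\text{–}D} = k_4\,\mathrm{erf}(x/d_4)$, an order of magnitude weaker
  ($k_4 = 13$ pN) with twice the extension scale ($d_4 = 20$ nm);
* a lumped *binding* spring — $\alpha$C crosslinking, Factor XIIIa, solvent
  and electrostatic contributions — spans each element end-to-end in
  parallel, $F_\text{bind} = k_5 x + k_6 H(x - d_5)(x - d_5)^3$ with
  $k_5 = 0.1$ pN/nm, $k_6 = k_5/500$ and onset $d_5$ = one quarter of the
  element length. Setting $k_5 = 0$ switches it off.

Elements are chained by sharing boundary nodes; coincident boundary pairs
are joined by one knob–hole spring each. The network is one-dimensional:
every reported force in the free-body view is axial, so node state is a
scalar axial displacement.

At each applied per-monomer force $F$ the chain is in quasi-static
equilibrium: the net force on every free node is zero. `solve_equilibrium()`
finds that root with a trust-region dogleg Newton method using the analytic
sparse tangent stiffness. The force is continued over 500 uniform steps from
0 to 200 pN, each solve warm-started from the previous one. Fiber force is
the per-monomer force times the monomers per cross-section,

$$n_\text{cs} = \left\lceil \phi\,\frac{(D_f/2)^2}{r_m^2} \right\rceil ,$$

which is 1614 for the reference fiber (length 12 µm, diameter 330 nm,
protein fraction $\phi = 0.30$, monomer radius 2.25 nm); the element count
$\lceil L_f / 46\,\text{nm} \rceil = 261$. Ceiling is the rounding that
reproduces both reference counts (1614 from 1613.3, 261 from 260.9).

### Clot scale

The fiber curve is embedded in a modified Arruda–Boyce eight-chain cell:
fibers run from the corners of an incompressible unit cube to its centre, so
a principal stretch $\lambda_1$ (with $\lambda_2 = \lambda_3 =
1/\sqrt{\lambda_1}$) stretches every internal fiber by

$$\lambda_\text{fiber} = \sqrt{\tfrac{1}{3}\left(\lambda_1^2 +
2/\lambda_1\right)} \ \ge 1,$$

and the clot force is

$$F_\text{clot} = \left(\lambda_1 - \frac{1}{\lambda_1^2}\right)
\frac{\pi D^2 v L}{24}\, \frac{F_\text{fiber}(\lambda_\text{fiber})}
{\lambda_\text{fiber}} .$$

The prefactor $\pi D^2 v L / 24$ is dimensionless when computed in
consistent units — an effective fiber count, $\pi \times 10^6$ for the
reference clot (diameter $D = 2$ mm, density $v = 0.5\ \mu m^{-3}$, fiber
length $L = 12\ \mu m$). We read the relation's grouping this way precisely
because it makes the prefactor a fiber count; the prose statement of the
formula does not parenthesise it explicitly.

```{r pipeline}
fiber <- fiber_curve()                       # mesoscale: 500 force steps
glance(fiber)
clot <- clot_curve(fiber = fiber)            # macroscale
autoplot(clot)
```

## Design choices

**Load convention (rigid crosshead).** The element's two dummy nodes
transmit the applied load to the two strand ends. We tie the dummy nodes and
the strand-end pair into a single rigid crosshead carrying the total load
$2F$ per protofibril, rather than loading each strand end independently with
$F$. Physically this is the grip of a force-controlled pulling experiment.
It also has a structural consequence: under the crosshead, every element of
the chain deforms identically (boundary-pair offsets vanish), whereas
independent per-strand loads create a decaying boundary layer at the loaded
end, because the two strands do not naturally carry equal shares of the
load (strand A transmits its share through the compliant, saturating
$\gamma$–$\gamma$/knob–hole junction). Total load, and hence
$F_\text{fiber} = 1614 \times F$, is unchanged.

**Replication fast path.** Because all elements deform identically under
the crosshead, `fiber_curve()` by default solves a single element per force
step and replicates it; `full_chain = TRUE` solves all 261 elements
simultaneously. The two agree to better than $10^{-8}$ relative at every
step (asserted in the test suite at $10^{-6}$), so the default run
completes in about a second.

**Element wiring.** Which E-region pairs with which D via knob–hole springs
is the one structurally ambiguous part of the element; the implemented
wiring (central E against both coincident junction D nodes, one spring per
boundary pair) follows the half-staggered geometry and is isolated in
`build_element_topology()`, so alternative wirings are a one-function
change. The binding spring's attachment is likewise taken end-to-end
(between consecutive strand-B boundary D nodes).

**Compression and the Heaviside gate.** The cubic laws are applied as
written: the cubic term is active only beyond its onset, while the linear
term provides a symmetric restoring force under compression. Simulations
are tension-driven, so the compressive branch only stabilises the solver.
$H(0) := 1$, which is immaterial (the cubic factor vanishes at onset) but
recorded for bit-reproducibility. The erf laws are extended oddly to
negative extension; no rule for compressive bond behaviour is established,
and tension-driven runs never exercise it.

**Solver and tolerances.** The residual is solved to a 2-norm of
$10^{-8}$ pN by default. When springs are made near-rigid (e.g. the
$\times 10^6$ crosslink-stiffness limit used as a closed-form validation),
double-precision rounding of displacements alone produces residuals above
any fixed tolerance; the solver therefore also accepts an equilibrium whose
residual is at the rounding floor of the tangent stiffness
($100\,\varepsilon\,\lVert J \rVert_\infty \max(1, |v|)$). Genuine rupture
stalls sit many orders of magnitude above that floor. Non-convergence is
reported as a state (interpreted as rupture and truncating the curve),
never thrown; a failed continuation step is first retried over ten
sub-steps. `erf` is evaluated through the Gaussian CDF (absolute error
below $10^{-12}$).

**Equilibrium existence and rupture.** With the default parameters the
strand-B backbone and the binding spring carry unbounded cubic force, so
equilibria exist over the whole 0–200 pN default range and the reference
curve shows no break; rupture (solver stall) appears when the saturating
bonds are made to carry the load, e.g. under `break_extension_factor` caps
or modified parameters. The clot curve is truncated where the demanded
fiber stretch exceeds the fiber curve's sampled range — reported as clot
rupture, not an error.

**Stretch-controlled evaluation.** The fiber model is force-controlled, but
the clot relation needs $F_\text{fiber}$ at a prescribed stretch; the
strictly monotone sampled curve is inverted by shape-preserving monotone
cubic interpolation (`splinefun(..., "monoH.FC")`), which passes through
every sample and cannot overshoot.

## Tunable parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `k1`, `k2`, `d2` | monomer linear/cubic stiffness, cubic onset | 1.5, 3e-4, 46 | pN/nm, pN/nm³, nm |
| `k3`, `d3` | knob–hole saturation force, extension scale | 130, 10 | pN, nm |
| `k4`, `d4` | γ–γ saturation force, extension scale | 13, 20 | pN, nm |
| `k5`, `k6`, `d5` | binding linear/cubic stiffness, onset | 0.1, 2e-4, 11.5 | pN/nm, pN/nm³, nm |
| fiber geometry | length, diameter, protein fraction, monomer radius | 12000, 330, 0.30, 2.25 | nm, nm, –, nm |
| clot geometry | diameter, fiber density, fiber length | 2, 0.5, 12 | mm, µm⁻³, µm |
| continuation | max per-monomer force, steps, residual tol | 200, 500, 1e-8 | pN, –, pN |

Clot-scale inputs are converted to the internal nm/pN system on load; clot
forces are reported in mN since they are macroscopic.

## Sensitivity sweeps

`run_sweep()` regenerates fiber curves across geometry grids — radius 25 to
225 nm at fixed 12 µm length, and length 0.5 to 14 µm at fixed 165 nm
radius (9 and 10 evenly spaced values; only the ranges are prescribed, the
grids are package choices). Two trends are asserted numerically in the test
suite: at fixed stretch, fiber force is non-decreasing in radius (the
cross-section count grows as radius²), and at fixed force, absolute
extension is non-decreasing in length (more elements in series). Note that
stretch–force curves are length-invariant under the replicated-element
construction; absolute extension is what distinguishes fiber lengths.

```{r sweep, fig.width = 6, fig.height = 3.5}
sw <- run_sweep(sweep_spec("radius", c(50, 100, 165)),
                controls = sim_controls(force_max = 120, n_steps = 60))
autoplot(sw)
```

## What the defaults do and do not show

The package ships no experimental data. The default parameter set and
geometry reproduce the model's published operating point — the derived
counts (1614, 261), the bond-law saturation values, and the qualitative
fiber/clot stiffening including the plateau-then-stiffen shape produced by
bond saturation plus cubic unfolding. Validation against atomic-force
microscopy or rheometry curves requires the user to supply a digitised
two-column CSV (`read_reference_csv()`, compared via `rms_deviation()`).
Passing tests therefore demonstrate internal consistency (equilibria match
independent energy minimisation; the residual is the exact negative energy
gradient; closed-form limits are recovered) and the stated trends — not
agreement with any particular experiment.

## Known limitations

* The network is one-dimensional and deterministic: no 2D/3D
  interconnectivity, no stochastic protofibril arrangements, and no
  fragmentation of protofibrils into short (15–20 monomer) pieces.
* Quasi-static only: no loading-rate or time dependence, no viscoelasticity.
* Parameters are taken as given; no fitting to molecular-dynamics or AFM
  data is performed by the package.
* Problem sizes used in the shipped tests (element counts 1–261, up to 500
  force steps, default sweep grids) are the package's standard operating
  sizes; all are desk-scale runs.
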