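#' Monomers per fiber cross-section
#'
#' Number of fibrin monomers in one cross-section of the fiber: the protein
#' area fraction times the fiber cross-section divided by the monomer
#' cross-section, `ceil(protein_fraction * (fiber_diameter/2)^2 /
#' monomer_radius^2)` (the pi factors cancel). This count scales the
#' per-monomer force to the fiber force. The default geometry gives 1614.
#'
#' @param geometry A [fiber_geometry()] object.
#' @return Integer count.
#' @examples
#' derive_cross_section_count(fiber_geometry())             # 1614
#' derive_cross_section_count(fiber_geometry(fiber_diameter = 50))  # 38
#' @export
derive_cross_section_count <- function(geometry) {
  stopifnot(inherits(geometry, "fiber_geometry"))
  ratio <- geometry$protein_fraction * (geometry$fiber_diameter / 2)^2 /
    geometry$monomer_radius^2
  # tolerance guards exact-integer ratios against FP noise before ceiling
  as.integer(ceiling(ratio - 1e-9))
}

#' Protofibril elements along the fiber
#'
#' Number of protofibril elements spanning the fiber length,
#' `ceil(fiber_length / element_rest_length)`. The default geometry
#' (12 um fiber, 46 nm elements) gives 261.
#'
#' @param geometry A [fiber_geometry()] object.
#' @return Integer count.
#' @examples
#' derive_element_count(fiber_geometry())                    # 261
#' derive_element_count(fiber_geometry(fiber_length = 500))  # 11
#' @export
derive_element_count <- function(geometry) {
  stopifnot(inherits(geometry, "fiber_geometry"))
  as.integer(ceiling(geometry$fiber_length / geometry$element_rest_length - 1e-9))
}

#' Build the protofibril element network
#'
#' Constructs the 1D spring-network topology of a double-stranded,
#' half-staggered protofibril made of `n_elements` repeating elements of rest
#' length `element_rest_length`. Per element, strand B contributes one whole
#' monomer as two `monomer_half` springs D-E-D; strand A is half-staggered
#' with E-regions at the element boundaries and a gamma-gamma D-D junction
#' (two coincident D nodes) at the centre. `knob_hole` springs join each
#' E-region to the opposing strand's coincident D node(s): two at the centre
#' junction and one at each boundary. One `binding` spring spans each element
#' end-to-end, in parallel with the rest of the network. Consecutive elements
#' share their boundary nodes.
#'
#' The left boundary pair is fixed. The applied per-monomer force enters
#' through two dummy nodes rigidly tied to the right boundary pair; the tie
#' is a rigid crosshead (all four share one degree of freedom), so the loaded
#' end moves as a unit carrying the total load `2F` per protofibril — the
#' grip condition of a force-controlled single-fiber pulling experiment.
#' Under this convention every element of the chain deforms identically,
#' which is what makes the single-element replication fast path of
#' [fiber_curve()] exact.
#'
#' For `n_elements = 1` the node numbering matches the canonical 9-node
#' element: 1 (E, strand A) and 2 (D, strand B) fixed at the left; 3, 5
#' (D-D junction, strand A) and 4 (E, strand B) at the centre; 6 (D, strand
#' B) and 7 (E, strand A) at the right; 8, 9 the dummy load nodes.
#'
#' @param geometry A [fiber_geometry()] object (supplies the element rest
#'   length and cross-section count stored in the topology).
#' @param n_elements Number of chained elements (default: derived from the
#'   geometry).
#' @return An object of class `protofibril_topology`: a list with tibbles
#'   `nodes` (`node_id`, `role`, `strand`, `rest_position`, `fixed`, `dof`)
#'   and `springs` (`spring_id`, `kind`, `node_a`, `node_b`,
#'   `rest_separation`), plus `n_elements`, `monomers_per_cross_section`,
#'   `element_rest_length`, `n_dof`, `crosshead_dof` and `loaded_nodes`.
#' @examples
#' top <- build_element_topology(fiber_geometry(), n_elements = 1)
#' top$nodes
#' @export
build_element_topology <- function(geometry,
                                   n_elements = derive_element_count(geometry)) {
  stopifnot(inherits(geometry, "fiber_geometry"))
  n <- as.integer(n_elements)
  if (is.na(n) || n < 1) abort("n_elements must be >= 1")
  L <- geometry$element_rest_length

  # node ids: boundary 0 -> 1 (E_A), 2 (D_B); element i centre ->
  # 5(i-1)+3 (D_A1), +4 (E_B), +5 (D_A2); boundary j >= 1 -> 5j+1 (D_B),
  # 5j+2 (E_A); dummies 5n+3, 5n+4.
  EA <- function(j) ifelse(j == 0L, 1L, 5L * j + 2L)
  DB <- function(j) ifelse(j == 0L, 2L, 5L * j + 1L)
  DA1 <- function(i) 5L * (i - 1L) + 3L
  EB  <- function(i) 5L * (i - 1L) + 4L
  DA2 <- function(i) 5L * (i - 1L) + 5L
  dum1 <- 5L * n + 3L
  dum2 <- 5L * n + 4L
  n_nodes <- 5L * n + 4L

  role <- character(n_nodes); strand <- character(n_nodes)
  pos <- numeric(n_nodes)
  js <- 0:n; is <- seq_len(n)
  role[EA(js)] <- "E"; strand[EA(js)] <- "A"; pos[EA(js)] <- js * L
  role[DB(js)] <- "D"; strand[DB(js)] <- "B"; pos[DB(js)] <- js * L
  role[DA1(is)] <- "D"; strand[DA1(is)] <- "A"; pos[DA1(is)] <- (is - 0.5) * L
  role[DA2(is)] <- "D"; strand[DA2(is)] <- "A"; pos[DA2(is)] <- (is - 0.5) * L
  role[EB(is)] <- "E"; strand[EB(is)] <- "B"; pos[EB(is)] <- (is - 0.5) * L
  role[c(dum1, dum2)] <- "dummy"
  strand[c(dum1, dum2)] <- c("B", "A")
  pos[c(dum1, dum2)] <- n * L

  fixed <- rep(FALSE, n_nodes)
  fixed[c(EA(0L), DB(0L))] <- TRUE

  # degrees of freedom: one per free node, except the rigid crosshead group
  # {D_B(n), E_A(n), dummy, dummy} which shares a single dof (listed last)
  crosshead_nodes <- c(DB(n), EA(n), dum1, dum2)
  dof <- rep(NA_integer_, n_nodes)
  interior <- setdiff(which(!fixed), crosshead_nodes)
  dof[interior] <- seq_along(interior)
  crosshead_dof <- length(interior) + 1L
  dof[crosshead_nodes] <- crosshead_dof

  nodes <- tibble(
    node_id = seq_len(n_nodes), role = role, strand = strand,
    rest_position = pos, fixed = fixed, dof = dof
  )

  sa <- integer(0); sb <- integer(0); kind <- character(0); rest <- numeric(0)
  add <- function(a, b, k, r) {
    sa <<- c(sa, a); sb <<- c(sb, b); kind <<- c(kind, rep(k, length(a)))
    rest <<- c(rest, rep(r, length(a)))
  }
  add(DB(is - 1L), EB(is), "monomer_half", L / 2)
  add(EB(is), DB(is), "monomer_half", L / 2)
  add(EA(is - 1L), DA1(is), "monomer_half", L / 2)
  add(DA2(is), EA(is), "monomer_half", L / 2)
  add(DA1(is), DA2(is), "gamma_gamma", 0)
  add(EB(is), DA1(is), "knob_hole", 0)
  add(EB(is), DA2(is), "knob_hole", 0)
  add(DB(is - 1L), DB(is), "binding", L)
  add(DB(js), EA(js), "knob_hole", 0)
  add(DB(n), dum1, "rigid_tie", 0)
  add(EA(n), dum2, "rigid_tie", 0)

  springs <- tibble(
    spring_id = seq_along(sa), kind = kind,
    node_a = sa, node_b = sb, rest_separation = rest
  )

  structure(
    list(nodes = nodes, springs = springs,
         n_elements = n,
         monomers_per_cross_section = derive_cross_section_count(geometry),
         element_rest_length = L,
         n_dof = crosshead_dof,
         crosshead_dof = crosshead_dof,
         loaded_nodes = c(dum1, dum2)),
    class = "protofibril_topology"
  )
}

#' @export
print.protofibril_topology <- function(x, ...) {
  cat("<protofibril_topology>\n")
  cat(sprintf("  %d element(s), %d nodes (%d dummy), %d springs, %d free dofs\n",
              x$n_elements, nrow(x$nodes), sum(x$nodes$role == "dummy"),
              nrow(x$springs), x$n_dof))
  tab <- table(x$springs$kind)
  cat("  springs by kind:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  cat(sprintf("  rest span %g nm, %d monomers per cross-section\n",
              x$n_elements * x$element_rest_length, x$monomers_per_cross_section))
  invisible(x)
}

# per-node displacement vector from the free-dof vector v
dofs_to_displacements <- function(topology, v) {
  u <- numeric(nrow(topology$nodes))
  d <- topology$nodes$dof
  u[!is.na(d)] <- v[d[!is.na(d)]]
  u
}

# free-dof vector from a per-node displacement vector (validates constraints)
displacements_to_dofs <- function(topology, u) {
  nd <- topology$nodes
  if (length(u) != nrow(nd)) {
    abort(sprintf("displacements must have one entry per node (%d), got %d",
                  nrow(nd), length(u)))
  }
  if (any(abs(u[nd$fixed]) > 0)) abort("fixed nodes must have zero displacement")
  v <- numeric(topology$n_dof)
  ok <- !is.na(nd$dof)
  split_u <- split(u[ok], nd$dof[ok])
  rng <- vapply(split_u, function(z) max(z) - min(z), numeric(1))
  if (any(rng > 1e-9)) {
    abort("nodes tied by a rigid crosshead must share one displacement value")
  }
  v[as.integer(names(split_u))] <- vapply(split_u, `[[`, numeric(1), 1L)
  v
}
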