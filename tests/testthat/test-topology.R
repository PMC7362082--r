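g <- fiber_geometry()

test_that("derived counts match the reference geometry", {
  expect_identical(derive_cross_section_count(g), 1614L)
  expect_identical(derive_element_count(g), 261L)
  # smaller fiber: ceil(0.3 * 25^2 / 2.25^2) = ceil(37.04) = 38
  expect_identical(
    derive_cross_section_count(fiber_geometry(fiber_diameter = 50)), 38L)
  # ceil(500 / 46) = ceil(10.87) = 11
  expect_identical(
    derive_element_count(fiber_geometry(fiber_length = 500)), 11L)
  # one-element fiber
  expect_identical(
    derive_element_count(fiber_geometry(fiber_length = 46)), 1L)
  # exactly integral ratio is unchanged by the ceiling
  gi <- fiber_geometry(fiber_diameter = 20, protein_fraction = 0.25,
                       monomer_radius = 2.5)   # 0.25 * 100 / 6.25 = 4
  expect_identical(derive_cross_section_count(gi), 4L)
  expect_identical(
    derive_element_count(fiber_geometry(fiber_length = 460)), 10L)
})

test_that("cross-section count scales with radius squared", {
  c_full <- derive_cross_section_count(fiber_geometry(fiber_diameter = 330))
  c_half <- derive_cross_section_count(fiber_geometry(fiber_diameter = 165))
  expect_gte(c_full / c_half, 3.99)
  expect_lte(c_full / c_half, 4.01)
})

test_that("single element matches the canonical 9-node numbering", {
  top <- build_element_topology(g, n_elements = 1)
  nd <- top$nodes
  expect_identical(nrow(nd), 9L)
  expect_identical(nd$role[c(2, 3, 5, 6)], rep("D", 4))
  expect_identical(nd$role[c(1, 4, 7)], rep("E", 3))
  expect_identical(nd$role[c(8, 9)], rep("dummy", 2))
  # strand B monomer is the 2-4-6 node sequence
  expect_identical(nd$strand[c(2, 4, 6)], rep("B", 3))
  expect_identical(nd$strand[c(1, 3, 5, 7)], rep("A", 4))
  # rest positions: boundaries at 0 and 46, centre triplet at 23
  expect_equal(nd$rest_position, c(0, 0, 23, 23, 23, 46, 46, 46, 46))
  # left boundary fixed, loaded end + dummies share the crosshead dof
  expect_identical(which(nd$fixed), c(1L, 2L))
  expect_identical(length(unique(nd$dof[6:9])), 1L)
  expect_identical(top$n_dof, 4L)

  sp <- top$springs
  counts <- table(sp$kind)
  expect_identical(as.integer(counts[c("monomer_half", "knob_hole",
                                       "gamma_gamma", "binding", "rigid_tie")]),
                   c(4L, 4L, 1L, 1L, 2L))
  # gamma-gamma spans the 3-5 junction
  gsp <- sp[sp$kind == "gamma_gamma", ]
  expect_identical(sort(c(gsp$node_a, gsp$node_b)), c(3L, 5L))
  # centre knob-holes tie E(4) to both junction D nodes; boundary ones tie
  # the coincident boundary pairs
  kh <- sp[sp$kind == "knob_hole", ]
  pairs <- apply(cbind(kh$node_a, kh$node_b), 1, function(x) paste(sort(x), collapse = "-"))
  expect_setequal(pairs, c("3-4", "4-5", "1-2", "6-7"))
  # binding spans the element end-to-end
  bd <- sp[sp$kind == "binding", ]
  expect_identical(sort(c(bd$node_a, bd$node_b)), c(2L, 6L))
  expect_identical(bd$rest_separation, 46)
})

test_that("chained elements share boundary nodes and tile the fiber", {
  top2 <- build_element_topology(g, n_elements = 2)
  # 5 new nodes per extra element: 9 + 5 = 14 nodes
  expect_identical(nrow(top2$nodes), 14L)
  expect_identical(top2$n_dof, 9L)   # 2(n+1)+3n free - 2 fixed - 1 shared
  # one boundary knob-hole per boundary, not two per interior boundary
  expect_identical(sum(top2$springs$kind == "knob_hole"), 2L * 2L + 3L)

  top <- build_element_topology(g, n_elements = 261)
  expect_equal(max(top$nodes$rest_position), 261 * 46)   # 12006 ~ fiber length
  expect_identical(top$monomers_per_cross_section, 1614L)

  # the spring graph (ignoring dummies) is connected
  sp <- top$springs
  n_phys <- sum(top$nodes$role != "dummy")
  adj <- Matrix::sparseMatrix(i = pmin(sp$node_a, sp$node_b),
                              j = pmax(sp$node_a, sp$node_b), x = 1,
                              dims = rep(nrow(top$nodes), 2), symmetric = TRUE)
  reached <- rep(FALSE, nrow(top$nodes)); reached[1] <- TRUE
  repeat {
    new <- as.logical(adj %*% reached > 0) & !reached
    if (!any(new)) break
    reached <- reached | new
  }
  expect_true(all(reached))
})

test_that("topology rejects invalid element counts and displacements", {
  expect_error(build_element_topology(g, 0), "n_elements")
  top <- build_element_topology(g, 1)
  expect_error(assemble_residual(top, rep(0, 5), 10), "entry per node")
  u_bad <- rep(0, 9); u_bad[1] <- 1   # fixed node displaced
  expect_error(assemble_residual(top, u_bad, 10), "fixed")
  u_tie <- rep(0, 9); u_tie[6] <- 1   # crosshead nodes unequal
  expect_error(assemble_residual(top, u_tie, 10), "crosshead")
})
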