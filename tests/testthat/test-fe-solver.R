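test_that("von Mises scalar matches its closed forms", {
  expect_equal(von_mises(diag(c(7, 7, 7))), 0)
  expect_equal(von_mises(diag(c(13, 0, 0))), 13)
  tau <- 4.2
  shear <- matrix(c(0, tau, 0, tau, 0, 0, 0, 0, 0), 3)
  expect_equal(von_mises(shear), sqrt(3) * tau)
  expect_error(von_mises(matrix(c(0, 1, 0, 2, 0, 0, 0, 0, 0), 3)),
               "symmetric")
})

test_that("zero load gives zero displacement and stress", {
  m <- box_mesh(2, 1, 1)
  sf <- solve_linear_elastic(m, material_spec(), matrix(0, nrow(m$nodes), 3),
                             fixed_nodes = m$regions$nodes$root)
  expect_equal(max(abs(attr(sf, "displacements"))), 0)
  expect_equal(max(sf$vm_mpa), 0)
})

test_that("uniaxial patch test reproduces sigma = F/A in every element", {
  m <- generate_bar_mesh(100, 10, 10, 6, 2, 2)
  nd <- m$nodes
  rollers <- rbind(cbind(which(abs(nd[, 1]) < 1e-9), 1L),
                   cbind(which(abs(nd[, 2]) < 1e-9), 2L),
                   cbind(which(abs(nd[, 3]) < 1e-9), 3L))
  loads <- traction_loads(m, m$regions$facets$far, 200, c(1, 0, 0))
  for (fo in c("smoothed", "cst")) {
    sf <- solve_linear_elastic(m, material_spec(), loads,
                               fixed_dofs = rollers, formulation = fo)
    expect_lt(max(abs(sf$vm_mpa - 2) / 2), 1e-6)
  }
})

test_that("scenario loads always have the requested resultant", {
  mesh <- small_claw(6)
  for (kind in c("scratch_digging", "hook_and_pull", "piercing")) {
    loads <- assign_scenario_loads(mesh, load_scenario(kind))
    expect_equal(sqrt(sum(colSums(loads$forces)^2)), 200, tolerance = 1e-9)
    expect_identical(loads$fixed_nodes, mesh$regions$nodes$articular)
  }
  loads <- assign_scenario_loads(mesh, load_scenario("piercing",
                                                     total_force_n = 350))
  expect_equal(sqrt(sum(colSums(loads$forces)^2)), 350, tolerance = 1e-9)
})

test_that("hook-and-pull distributes force by facet area along inward normals", {
  # flat ventral strip: bar's z = -depth/2 face, uniform facets
  m <- generate_bar_mesh(10, 2, 2, 5, 2, 2)
  bottom <- which(apply(matrix(m$nodes[m$boundary, 3] < -1 + 1e-9,
                               nrow(m$boundary)), 1, all))
  m$regions$facets$ventral <- bottom
  m$regions$nodes$articular <- m$regions$nodes$root
  m$node_params <- NULL
  loads <- assign_scenario_loads(m, load_scenario("hook_and_pull"))
  f <- loads$forces
  # all force along +z (inward normal of the bottom face)
  expect_lt(max(abs(f[, 1:2])), 1e-12)
  expect_equal(sum(f[, 3]), 200, tolerance = 1e-9)
  na <- clawfsa:::facet_normals_areas(m$nodes, m$boundary[bottom, ])
  # uniform facets: per-facet share equals its area share
  expect_equal(length(unique(round(na$area, 9))), 1L)
})

test_that("scratch-digging loads exactly the ventral facets in the tip region", {
  mesh <- small_claw(7)
  loads <- assign_scenario_loads(mesh, load_scenario("scratch_digging"))
  loaded_nodes <- which(rowSums(abs(loads$forces)) > 0)
  u <- mesh$node_params$u
  fac <- mesh$boundary
  fu <- pmax(u[fac[, 1]], u[fac[, 2]], u[fac[, 3]])
  expected_rows <- intersect(which(fu >= 0.95), mesh$regions$facets$ventral)
  expected_nodes <- sort(unique(as.vector(fac[expected_rows, ])))
  expect_identical(loaded_nodes, expected_nodes)
  expect_gt(length(expected_rows), 0L)
})

test_that("missing region sets raise configuration errors naming the set", {
  mesh <- small_claw(8)
  mesh$regions$nodes$articular <- integer()
  expect_error(assign_scenario_loads(mesh, load_scenario("piercing")),
               "articular")
  mesh2 <- small_claw(8)
  mesh2$regions$facets$ventral <- integer()
  expect_error(assign_scenario_loads(mesh2, load_scenario("hook_and_pull")),
               "ventral")
})

test_that("rigid rotation leaves element von Mises stress unchanged", {
  mesh <- small_claw(9)
  mat <- material_spec()
  loads <- assign_scenario_loads(mesh, load_scenario("hook_and_pull"))
  sf0 <- solve_linear_elastic(mesh, mat, loads)
  R <- rotation_matrix(c(1, 2, 1), 0.7)
  rot <- rotate_mesh(mesh, R)
  loads_r <- assign_scenario_loads(rot, load_scenario("hook_and_pull"))
  sf1 <- solve_linear_elastic(rot, mat, loads_r)
  expect_lt(max(abs(sf1$vm_mpa - sf0$vm_mpa) / (abs(sf0$vm_mpa) + 1e-12)),
            1e-6)
})

test_that("doubling the force exactly doubles every stress", {
  mesh <- small_claw(10)
  mat <- material_spec()
  l1 <- assign_scenario_loads(mesh, load_scenario("piercing", 200))
  l2 <- assign_scenario_loads(mesh, load_scenario("piercing", 400))
  sf1 <- solve_linear_elastic(mesh, mat, l1)
  sf2 <- solve_linear_elastic(mesh, mat, l2)
  expect_equal(sf2$vm_mpa, 2 * sf1$vm_mpa, tolerance = 1e-12)
})

test_that("uniform geometric scaling with fixed force scales stress by s^-2", {
  mesh <- small_claw(11)
  mat <- material_spec()
  loads <- assign_scenario_loads(mesh, load_scenario("piercing"))
  sf1 <- solve_linear_elastic(mesh, mat, loads)
  s <- 2
  scaled <- mesh
  scaled$nodes <- mesh$nodes * s
  sf2 <- solve_linear_elastic(scaled, mat, loads)
  expect_lt(max(abs(sf2$vm_mpa - sf1$vm_mpa / s^2) /
                  (abs(sf1$vm_mpa / s^2) + 1e-300)), 1e-9)
})

test_that("unconstrained solves fail with an articular-set hint", {
  mesh <- small_claw(12)
  loads <- assign_scenario_loads(mesh, load_scenario("piercing"))
  expect_error(
    solve_linear_elastic(mesh, material_spec(), loads$forces,
                         fixed_nodes = integer()),
    "articular")
})
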