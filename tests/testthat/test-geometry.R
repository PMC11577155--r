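test_that("disk meshes satisfy the structural invariants across sizings", {
  for (h in list(c(0.8, 0.8), c(0.3, 0.6), c(0.15, 0.15))) {
    mesh <- build_disk_mesh(5, h[1], h[2], seed = 11)
    expect_true(validate_mesh(mesh))
    expect_true(all(triangle_areas(mesh) > 0))
    ## outward normals: unit length, positive radial component
    expect_equal(rowSums(mesh$boundary_normals^2), rep(1, nrow(mesh$boundary_normals)))
    mid <- (mesh$vertices[mesh$boundary_edges[, 1], ] +
            mesh$vertices[mesh$boundary_edges[, 2], ]) / 2
    expect_true(all(rowSums(mesh$boundary_normals * mid) > 0))
  }
})

test_that("mesh generation is deterministic given the seed", {
  m1 <- build_disk_mesh(5, 0.5, 0.5, seed = 7)
  m2 <- build_disk_mesh(5, 0.5, 0.5, seed = 7)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$triangles, m2$triangles)
})

test_that("study sizing reproduces the reference resolution and the sizing-field count oracle", {
  expect_equal(nrow(study_mesh()$vertices), 7499, tolerance = 0.2)
  ## independent oracle: vertex density integral of the sizing field
  m <- build_disk_mesh(5, 0.5, 0.5, seed = 1)
  expect_equal(nrow(m$vertices), expected_vertex_count(5, 0.5, 0.5),
               tolerance = 0.3)
})

test_that("degenerate coarsest sizing still yields a valid mesh", {
  m <- build_disk_mesh(5, 5, 5, seed = 1)
  expect_gte(nrow(m$vertices), 3)
  expect_gte(nrow(m$triangles), 1)
  expect_true(validate_mesh(m))
})

test_that("infeasible sizings are rejected", {
  expect_error(build_disk_mesh(5, 0.2, 6, seed = 1), "sizing")
  expect_error(build_disk_mesh(5, 0.5, 0.2, seed = 1), "sizing")
  expect_error(build_disk_mesh(5, -1, 0.5, seed = 1), "sizing")
})

test_that("mass matrix totals the domain area and boundary mass is boundary-supported", {
  fem <- coarse_fem()
  ## exact against the discrete (polygonal) domain area
  expect_equal(sum(fem$mass_matrix), sum(fem$areas), tolerance = 1e-12)
  ## study sizing: matches the analytic disk area to 1e-4 relative
  expect_equal(sum(study_fem()$mass_matrix), 25 * pi, tolerance = 1e-4)
  ## boundary mass vanishes at interior rows
  interior <- setdiff(seq_len(fem$n_nodes), fem$boundary_nodes)
  expect_equal(sum(abs(fem$boundary_mass[interior, ])), 0)
  ## M is symmetric with positive diagonal
  expect_lt(max(abs(fem$mass_matrix - Matrix::t(fem$mass_matrix))), 1e-14)
  expect_true(all(Matrix::diag(fem$mass_matrix) > 0))
})

test_that("unit reaction coefficient assembly reproduces the mass matrix", {
  fem <- coarse_fem()
  Ma <- assemble_operator(fem, a = 1)
  expect_lt(max(abs(Ma - fem$mass_matrix)), 1e-14)
  Kb <- assemble_operator(fem, b = 1)
  expect_lt(max(abs(Kb - fem$stiffness_matrix)), 1e-14)
})

test_that("field integration matches closed-form disk moments", {
  fem <- study_fem()
  v <- fem$mesh$vertices
  expect_equal(integrate_field(rep(1, fem$n_nodes), fem), 25 * pi,
               tolerance = 1e-4)
  ## odd symmetry
  expect_lt(abs(integrate_field(v[, 1], fem)), 1e-6)
  ## second moment: int x^2 = pi R^4 / 4 (P1 interpolation is O(h^2) high)
  expect_equal(integrate_field(v[, 1]^2, fem), pi * 5^4 / 4, tolerance = 2e-3)
  ## linearity through M
  cfield <- rep(3.7, fem$n_nodes)
  expect_equal(integrate_field(cfield, fem), 3.7 * integrate_field(rep(1, fem$n_nodes), fem))
  expect_error(integrate_field(1:3, fem), "expected length")
})

test_that("degenerate triangles abort assembly naming the element", {
  mesh <- coarse_mesh()
  bad <- mesh
  bad$triangles[5, ] <- rep(bad$triangles[5, 1], 3)
  bad$vertices <- mesh$vertices
  expect_error(assemble_fem(bad), "element 5|degenerate")
})

test_that("mesh VTK export writes a readable unstructured grid", {
  f <- tempfile(fileext = ".vtk")
  mesh <- coarse_mesh()
  write_mesh_vtk(mesh, f, point_data = list(r = sqrt(rowSums(mesh$vertices^2))))
  lines <- readLines(f)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", lines)))
  expect_true(any(grepl(sprintf("POINTS %d double", nrow(mesh$vertices)), lines)))
  expect_true(any(grepl("SCALARS r double", lines)))
})
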