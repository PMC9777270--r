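test_that("disk mesh satisfies its geometric invariants", {
  mesh <- disk10
  expect_true(all(triangle_areas(mesh) > 0))
  expect_lt(abs(mesh_area(mesh) / (pi * 0.01^2 / 4) - 1), 0.01)
  # measured diameter equals the nominal one within an edge length
  expect_lt(abs(measure_diameter(mesh) - 0.01), mesh$h)
  # the boundary edges form a single closed loop
  be <- mesh$boundary_edges
  deg <- table(as.vector(be))
  expect_true(all(deg == 2))
  expect_equal(nrow(be), length(unique(as.vector(be))))
  # vertex count follows the ring construction
  expect_equal(mesh$nvert, 1 + 3 * 10 * 11)
  expect_equal(nrow(mesh$triangles), 6 * 10^2)
})

test_that("boundary polygon converges to the circle under refinement", {
  perim_err <- sapply(c(6, 12, 24), function(rings) {
    m <- build_disk_mesh(0.01, rings = rings)
    bloop <- m$boundary_edges
    L <- sum(sqrt(rowSums((m$vertices[bloop[, 1], ] - m$vertices[bloop[, 2], ])^2)))
    abs(L - pi * 0.01)
  })
  expect_true(all(diff(perim_err) < 0))
  # resolution argument controls ring count
  m <- build_disk_mesh(0.01, resolution = 0.001)
  expect_equal(nrow(m$triangles), 6 * 5^2)
  expect_error(build_disk_mesh(0.01, resolution = 0.02), "resolution")
})

test_that("rigid-body basis detects rigid motions and ignores pure dilation", {
  mesh <- disk6
  Z <- poroTME:::.assemble_rigid_rows(mesh)
  np2 <- mesh$nvert + mesh$nedge
  xy <- mesh$p2_coords
  as_dofs <- function(ux, uy) c(ux, uy)
  # constant translation is seen by the first functional only
  u_tx <- as_dofs(rep(1, np2), rep(0, np2))
  expect_gt(abs((Z %*% u_tx)[1]), 1e-8)
  expect_lt(abs((Z %*% u_tx)[3]), 1e-18)
  # rotation field is seen by the rotation functional, positively
  u_rot <- as_dofs(-xy[, 2], xy[, 1])
  expect_gt((Z %*% u_rot)[3], 0)
  expect_lt(abs((Z %*% u_rot)[1]), 1e-15)
  # pure radial dilation of the centered disk projects to zero on all
  # three functionals, to quadrature round-off relative to the area scale
  u_dil <- as_dofs(xy[, 1], xy[, 2])
  expect_lt(max(abs(Z %*% u_dil)), 1e-12 * mesh_area(mesh))
  basis <- rigid_body_basis(mesh)
  expect_equal(basis$z3[, 1], -mesh$p2_coords[, 2])
})

test_that("warping scales, round-trips, and guards against inversion", {
  mesh <- disk6
  u0 <- matrix(0, mesh$nvert, 2)
  expect_equal(warp_mesh(mesh, u0)$vertices, mesh$vertices)
  # similarity: 10 percent dilation scales all radii and the diameter
  u <- 0.1 * mesh$vertices
  w <- warp_mesh(mesh, u)
  expect_equal(measure_diameter(w), 1.1 * measure_diameter(mesh), tolerance = 1e-12)
  expect_equal(mesh_area(w), 1.21 * mesh_area(mesh), tolerance = 1e-12)
  # warp by u then -u restores coordinates to round-off
  back <- warp_mesh(w, -u)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-14)
  # a wild non-smooth field inverts an element and is reported
  set.seed(4)
  bad <- matrix(rnorm(2 * mesh$nvert, sd = 0.004), ncol = 2)
  expect_error(warp_mesh(mesh, bad), "invert")
})

test_that("diameter measurement is rigid-motion invariant and sees anisotropy", {
  mesh <- disk6
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- mesh
  rot$vertices <- mesh$vertices %*% Rm + matrix(c(5, -3), mesh$nvert, 2, byrow = TRUE)
  expect_equal(measure_diameter(rot), measure_diameter(mesh), tolerance = 1e-12)
  # ellipse warp stretches the diameter along x only
  u <- cbind(0.2 * mesh$vertices[, 1], 0 * mesh$vertices[, 2])
  expect_equal(measure_diameter(warp_mesh(mesh, u)),
               1.2 * measure_diameter(mesh), tolerance = 1e-12)
  # brute-force oracle over all boundary vertex pairs
  w <- warp_mesh(mesh, u)
  b <- boundary_vertices(w)
  xy <- w$vertices[b, ]
  brute <- 0
  for (i in seq_along(b)) for (j in seq_along(b))
    brute <- max(brute, sum((xy[i, ] - xy[j, ])^2))
  expect_equal(measure_diameter(w), sqrt(brute))
})

test_that("mesh writers emit readable VTK and Gmsh text", {
  f1 <- tempfile(fileext = ".vtk")
  write_vtk(disk6, f1, point_data = list(r = sqrt(rowSums(disk6$vertices^2))))
  lines <- readLines(f1)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("^SCALARS r", lines)))
  f2 <- tempfile(fileext = ".msh")
  write_msh(disk6, f2)
  lines2 <- readLines(f2)
  expect_identical(lines2[1], "$MeshFormat")
  expect_equal(sum(grepl("^\\$", lines2)), 6L)
  unlink(c(f1, f2))
})
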