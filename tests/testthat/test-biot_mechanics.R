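test_that("zero excess volume and zero history give the trivial equilibrium", {
  op <- biot_operator(disk6, default_params, dt = 0.5)
  st <- solve_mechanics_step(op, rep(0, disk6$nvert))
  expect_equal(max(abs(st$U)), 0)
  expect_equal(max(abs(st$P)), 0)
  # determinism: two identical assemblies and solves agree bitwise
  op2 <- biot_operator(disk6, default_params, dt = 0.5)
  st1 <- solve_mechanics_step(op, rep(0.02, disk6$nvert))
  st2 <- solve_mechanics_step(op2, rep(0.02, disk6$nvert))
  expect_identical(st1$U, st2$U)
  expect_identical(st1$P, st2$P)
  # rigid-mode projections of any solution stay at solver tolerance
  Z <- poroTME:::.assemble_rigid_rows(disk6)
  expect_lt(max(abs(Z %*% st1$U)) / max(abs(st1$U)), 1e-10)
})

test_that("uniform eigenstress drives the closed-form drained dilation", {
  # radially symmetric closed form for the grad-grad elastic operator:
  # u = c x with c = K v* / (2 (K - 2G/3) + G)  (zero total traction)
  p <- default_params
  v <- 0.05
  c_exact <- p$K * v / (2 * (p$K - 2 * p$G / 3) + p$G)
  cc_coarse <- measured_dilation(disk6, p, v)
  cc_fine <- measured_dilation(disk10, p, v)
  expect_lt(max(abs(cc_coarse - c_exact)) / c_exact, 0.005)
  expect_lt(max(abs(cc_fine - c_exact)) / c_exact, 0.005)
  # the linear dilation lies in the quadratic element space, so the
  # discrete drained solution is exact to round-off at both resolutions
  expect_lt(max(abs(cc_fine - c_exact)) / c_exact, 1e-10)
})

test_that("one-dimensional consolidation follows the classical series", {
  Tv <- c(0.1, 0.2, 0.5, 1.0)
  U <- simulate_consolidation(Tv, nx = 2, ny = 24, dt_frac = 5e-4)
  expect_lt(max(abs(U - terzaghi_series(Tv))), 0.01)
})

test_that("manufactured solution converges at order 2 in u and >= 1 in p", {
  e1 <- mms_errors(6); e2 <- mms_errors(12); e3 <- mms_errors(24)
  order_u <- log2(c(e1["eu"] / e2["eu"], e2["eu"] / e3["eu"]))
  order_p <- log2(c(e1["ep"] / e2["ep"], e2["ep"] / e3["ep"]))
  expect_true(all(order_u > 1.8))
  expect_true(all(order_p > 1.0))
})

test_that("Darcy velocity fields follow the pressure gradient", {
  mesh <- disk10
  p <- default_params
  # uniform pressure: no flow
  dv0 <- darcy_velocity(mesh, rep(7, mesh$nvert), p$kappa)
  expect_equal(max(abs(dv0$element)), 0)
  # linear pressure: constant velocity -kappa * g
  g <- 3
  dv <- darcy_velocity(mesh, g * mesh$vertices[, 1], p$kappa)
  expect_equal(dv$element[, 1], rep(-p$kappa * g, nrow(mesh$triangles)),
               tolerance = 1e-10)
  expect_lt(max(abs(dv$element[, 2])), 1e-15 * p$kappa * g / p$kappa)
  # radially symmetric pressure: purely radial flow
  r2 <- rowSums(mesh$vertices^2)
  dvr <- darcy_velocity(mesh, 1e3 * r2, p$kappa)
  cent <- (mesh$vertices[mesh$triangles[, 1], ] +
           mesh$vertices[mesh$triangles[, 2], ] +
           mesh$vertices[mesh$triangles[, 3], ]) / 3
  tangential <- dvr$element[, 1] * (-cent[, 2]) + dvr$element[, 2] * cent[, 1]
  # the quadratic pressure is only interpolated by the linear elements, so
  # a small O(h^2) tangential residue remains; it must shrink on refinement
  fine <- build_disk_mesh(0.01, rings = 20)
  dvf <- darcy_velocity(fine, 1e3 * rowSums(fine$vertices^2), p$kappa)
  centf <- (fine$vertices[fine$triangles[, 1], ] +
            fine$vertices[fine$triangles[, 2], ] +
            fine$vertices[fine$triangles[, 3], ]) / 3
  tangf <- dvf$element[, 1] * (-centf[, 2]) + dvf$element[, 2] * centf[, 1]
  expect_lt(max(abs(tangential)) / max(abs(dvr$element)), 1e-3)
  expect_lt(max(abs(tangf)) / max(abs(dvf$element)),
            max(abs(tangential)) / max(abs(dvr$element)))
})

test_that("backward Euler dissipates the poroelastic energy", {
  op <- biot_operator(disk6, default_params, dt = 0.5)
  set.seed(11)
  st <- initial_mechanical_state(op)
  st$P <- runif(disk6$nvert) * 10
  st$P[boundary_vertices(disk6)] <- 0
  E <- poroelastic_energy(op, st)
  for (k in 1:15) {
    st <- solve_mechanics_step(op, rep(0, disk6$nvert), st)
    En <- poroelastic_energy(op, st)
    expect_lte(En, E * (1 + 1e-10))
    E <- En
  }
})

test_that("outputs are invariant to the reference blood pressure", {
  v <- rep(0.03, disk6$nvert)
  st1 <- solve_mechanics_step(biot_operator(disk6, model_parameters(p0 = 1.2e4),
                                            dt = 0.5), v)
  st2 <- solve_mechanics_step(biot_operator(disk6, model_parameters(p0 = 9e4),
                                            dt = 0.5), v)
  expect_identical(st1$U, st2$U)
  expect_identical(st1$P, st2$P)
})
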