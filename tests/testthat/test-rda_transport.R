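test_that("uniform equilibrium states are fixed points of the transport step", {
  op <- transport_operator(disk10, default_params, dt = 0.5)
  X <- uniform_state(disk10)
  for (k in 1:3) X <- advance_species(op, X, rp1)
  expect_lt(max(abs(X - 1)), 1e-12)
  # uniform non-equilibrium states stay spatially uniform (no-flux, no
  # advective coupling): the step commutes with the 0-D reduction
  X <- uniform_state(disk10, seq(0.8, 1.2, length.out = 14))
  X <- advance_species(op, X, rp1)
  expect_lt(max(apply(X, 1, function(z) diff(range(z)))), 1e-12)
})

test_that("immobile species receive no transport", {
  op <- transport_operator(disk10, default_params, dt = 0.5)
  X <- uniform_state(disk10)
  # impose a spatial profile on the immobile species; without reactions it
  # must stay exactly where it is
  r <- sqrt(rowSums(disk10$vertices^2))
  X[10, ] <- 1 + r / max(r)
  X2 <- advance_species(op, X, zero_reactions)
  expect_identical(X2[10, ], X[10, ])
  # a motile cytokine with the same profile spreads
  X[14, ] <- 1 + r / max(r)
  X3 <- advance_species(op, X, zero_reactions)
  expect_gt(max(abs(X3[14, ] - X[14, ])), 1e-9)
})

test_that("Dirichlet disk eigenmode decays at the Bessel rate", {
  mesh <- build_disk_mesh(0.01, rings = 14)
  R <- 0.005
  j01 <- 2.404825557695773
  lam <- default_params$D_H * (j01 / R)^2
  dt <- 0.002
  bn <- boundary_vertices(mesh)
  op <- transport_operator(mesh, default_params, dt = dt,
                           dirichlet = list(nodes = bn, values = rep(0, length(bn))))
  r <- sqrt(rowSums(mesh$vertices^2))
  mode <- besselJ(j01 * r / R, 0)
  X <- matrix(0, 14, mesh$nvert)
  X[14, ] <- mode
  nst <- 50
  for (k in seq_len(nst)) X <- advance_species(op, X, zero_reactions)
  amp <- max(X[14, r < 0.001]) / max(mode[r < 0.001])
  rate <- -log(amp) / (nst * dt)
  expect_lt(abs(rate - lam) / lam, 0.01)
})

test_that("conservative advection conserves mass exactly under no-flux", {
  mesh <- disk10
  op <- transport_operator(mesh, default_params, dt = 0.1,
                           advection = "conservative")
  ml <- poroTME:::assemble_p1_mass(mesh, lumped = TRUE)
  cent <- (mesh$vertices[mesh$triangles[, 1], ] +
           mesh$vertices[mesh$triangles[, 2], ] +
           mesh$vertices[mesh$triangles[, 3], ]) / 3
  vel <- 0.001 * cbind(-cent[, 2], cent[, 1])   # divergence-free rotation
  r <- sqrt(rowSums(mesh$vertices^2))
  X <- matrix(0, 14, mesh$nvert)
  X[9, ] <- exp(-(r / 0.002)^2)
  m0 <- sum(ml * X[9, ])
  for (k in 1:20) X <- advance_species(op, X, zero_reactions, vel)
  expect_lt(abs(sum(ml * X[9, ]) - m0) / m0, 1e-8)
  # the advection matrix itself has vanishing column sums (mass exactness
  # holds for any velocity, not just divergence-free ones)
  A <- poroTME:::.assemble_advection(mesh, vel + 0.5 * abs(vel))
  expect_lt(max(abs(Matrix::colSums(A))), 1e-18)
})

test_that("diffusion respects the comparison principle under no-flux", {
  op <- transport_operator(disk10, default_params, dt = 0.5)
  r <- sqrt(rowSums(disk10$vertices^2))
  X <- matrix(0, 14, disk10$nvert)
  X[14, ] <- 0.3 + exp(-(r / 0.002)^2)
  lo <- min(X[14, ]); hi <- max(X[14, ])
  for (k in 1:30) X <- advance_species(op, X, zero_reactions)
  expect_gte(min(X[14, ]), lo - 1e-12)
  expect_lte(max(X[14, ]), hi + 1e-12)
})

test_that("Robin condition: no-flux limit, influx sign, Dirichlet limit", {
  mesh <- disk10
  # alpha = 0 reduces exactly to no-flux
  bc0 <- boundary_spec("robin", rep(0, 14), rep(0, 14))
  op0 <- transport_operator(mesh, default_params, dt = 0.5, bc = bc0)
  opn <- transport_operator(mesh, default_params, dt = 0.5)
  X <- uniform_state(mesh, rep(0.7, 14))
  expect_identical(advance_species(op0, X, rp1), advance_species(opn, X, rp1))
  # an external level above the interior strictly raises the species
  # integral over one step, and conversely
  mk <- function(alpha, xhat) {
    a <- rep(0, 14); h <- rep(0, 14)
    a[2] <- alpha; h[2] <- xhat
    transport_operator(mesh, default_params, dt = 1,
                       bc = boundary_spec("robin", a, h))
  }
  X <- matrix(0, 14, mesh$nvert); X[2, ] <- 0.1
  i0 <- species_summary(X, mesh)$integral[2]
  up <- advance_species(mk(1e7, 0.5), X, zero_reactions)
  dn <- advance_species(mk(1e7, 0.0), X, zero_reactions)
  expect_gt(species_summary(up, mesh)$integral[2], i0)
  expect_lt(species_summary(dn, mesh)$integral[2], i0)
  # increasing alpha drives the boundary trace monotonically to Xhat
  trace <- sapply(c(1e7, 1e8, 1e9), function(a) {
    op <- mk(a, 0.5)
    X <- matrix(0, 14, mesh$nvert); X[2, ] <- 0.1
    for (k in 1:300) X <- advance_species(op, X, zero_reactions)
    mean(X[2, boundary_vertices(mesh)])
  })
  expect_true(all(diff(trace) > 0))
  expect_lt(abs(trace[3] - 0.5), 1e-3)
  # the immune-cell equilibrium of the standard Robin setting: a field
  # pinned at Xhat generates no boundary flux
  rob <- apply_robin(mk(100, 0.01), 2)
  flux <- rob$diag * 0.01 - rob$load
  expect_lt(max(abs(flux)), 1e-20)
  # warning for a Robin rate on a non-immune species
  a <- rep(0, 14); a[9] <- 5
  expect_warning(boundary_spec("robin", a, rep(0, 14)), "non-immune")
})

test_that("species summaries match direct scans and scale with warping", {
  mesh <- disk6
  set.seed(9)
  X <- matrix(runif(14 * mesh$nvert), 14)
  s <- species_summary(X, mesh)
  expect_equal(s$min, apply(X, 1, min))
  expect_equal(s$max, apply(X, 1, max))
  expect_equal(s$mean, rowMeans(X))
  # uniform field: integral is value times area
  Xu <- uniform_state(mesh, rep(2.5, 14))
  su <- species_summary(Xu, mesh)
  expect_equal(su$integral, rep(2.5 * mesh_area(mesh), 14), tolerance = 1e-12)
  # after a 10 percent dilation the same field integrates 1.21x larger
  w <- warp_mesh(mesh, 0.1 * mesh$vertices)
  sw <- species_summary(Xu, w)
  expect_equal(sw$integral / su$integral, rep(1.21, 14), tolerance = 1e-12)
})
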