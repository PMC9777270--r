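# shared fixtures, built once per test session

# calibrated synthetic network, seed 1
rp1 <- synthesize_parameters(1)

# parameter set with every reaction switched off (pure transport tests)
zero_reactions <- local({
  z <- rep(0, length(reaction_rate_names()))
  names(z) <- reaction_rate_names()
  z["C0"] <- 2
  reaction_parameters(z)
})

default_params <- model_parameters()

# small disk meshes reused across files
disk6 <- build_disk_mesh(0.01, rings = 6)
disk10 <- build_disk_mesh(0.01, rings = 10)

# uniform state matrix helper
uniform_state <- function(mesh, values = rep(1, 14)) {
  matrix(values, 14, mesh$nvert)
}

# classical one-dimensional consolidation series U(Tv)
terzaghi_series <- function(Tv, nterms = 200) {
  m <- pi * (2 * (0:nterms) + 1) / 2
  vapply(Tv, function(tv) 1 - sum(2 / m^2 * exp(-m^2 * tv)), numeric(1))
}

# degree-of-consolidation curve computed by the Biot solver on a strip
# (lateral displacement locked, load and drainage on the top face)
simulate_consolidation <- function(Tv_targets, nx = 3, ny = 30,
                                   dt_frac = 2.5e-4) {
  p <- model_parameters()
  L <- 0.01
  mesh <- build_rect_mesh(L / 5, L, nx = nx, ny = ny)
  np2 <- mesh$nvert + mesh$nedge
  Kv <- p$K + p$G / 3
  cv <- p$kappa / (p$c0 + p$alpha^2 / Kv)
  tchar <- L^2 / cv
  sig0 <- 1000
  s_d <- sig0 * L / Kv
  s_u <- sig0 * L / (Kv + p$alpha^2 * p$M_biot)
  bot <- poroTME:::.p2_nodes_among(mesh, mesh$sides$bottom)
  top_edges <- poroTME:::.boundary_edges_among(mesh, mesh$sides$top)
  bc <- list(u_fix = c(seq_len(np2), np2 + bot),
             u_val = rep(0, np2 + length(bot)),
             p_fix = mesh$sides$top, p_val = rep(0, length(mesh$sides$top)),
             traction = list(edge_ids = top_edges, tx = 0, ty = -sig0),
             rigid = FALSE)
  dt <- dt_frac * tchar
  op <- biot_operator(mesh, p, dt, bc)
  topnodes <- poroTME:::.p2_nodes_among(mesh, mesh$sides$top)
  st <- initial_mechanical_state(op)
  steps <- round(Tv_targets * tchar / dt)
  U <- numeric(length(steps))
  k <- 0
  for (m in seq_along(steps)) {
    while (k < steps[m]) {
      st <- solve_mechanics_step(op, rep(0, mesh$nvert), st)
      k <- k + 1
    }
    U[m] <- (-mean(st$u[topnodes, 2]) - s_u) / (s_d - s_u)
  }
  U
}

# one-step manufactured-solution errors for the coupled Biot system on the
# unit square (analytic trigonometric fields; loads derived by hand)
mms_errors <- function(n) {
  K <- 2; G <- 1; alpha <- 0.8; c0 <- 1; kap <- 1; dt <- 1
  A <- 0.01; B <- 1
  p <- model_parameters(K = K, G = G, alpha = alpha, kappa = kap,
                        M_biot = 1 / c0, c0 = c0, p0 = 0)
  mesh <- build_rect_mesh(1, 1, n, n)
  np2 <- mesh$nvert + mesh$nedge
  sx <- function(x) sin(pi * x); cx <- function(x) cos(pi * x)
  uex <- function(x, y) A * sx(x) * sx(y)
  pex <- function(x, y) B * sx(x) * sx(y)
  Fux <- function(x, y) -(K - 2 * G / 3) * A * pi^2 * (cx(x) * cx(y) - sx(x) * sx(y)) +
    2 * G * pi^2 * A * sx(x) * sx(y) + alpha * B * pi * cx(x) * sx(y)
  Fuy <- function(x, y) -(K - 2 * G / 3) * A * pi^2 * (cx(x) * cx(y) - sx(x) * sx(y)) +
    2 * G * pi^2 * A * sx(x) * sx(y) + alpha * B * pi * sx(x) * cx(y)
  Fp <- function(x, y) (c0 / dt) * B * sx(x) * sx(y) +
    (alpha / dt) * A * pi * (cx(x) * sx(y) + sx(x) * cx(y)) +
    2 * kap * pi^2 * B * sx(x) * sx(y)
  bverts <- boundary_vertices(mesh)
  bp2 <- poroTME:::.p2_nodes_among(mesh, bverts)
  bc <- list(u_fix = c(bp2, np2 + bp2), u_val = rep(0, 2 * length(bp2)),
             p_fix = bverts, p_val = rep(0, length(bverts)), rigid = FALSE)
  op <- biot_operator(mesh, p, dt, bc)
  load <- list(Fu = poroTME:::.p2_load_function(mesh, Fux, Fuy),
               Fp = poroTME:::.p1_load_function(mesh, Fp))
  st <- solve_mechanics_step(op, rep(0, mesh$nvert), extra_load = load)
  c(eu = poroTME:::.p2_l2_error(mesh, st$u, uex, uex),
    ep = poroTME:::.p1_l2_error(mesh, st$P, pex))
}

# uniform-eigenstress dilation coefficient measured from a drained solve
measured_dilation <- function(mesh, params, vstar, nsteps = 40) {
  op <- biot_operator(mesh, params, dt = 0.5)
  st <- NULL
  for (k in seq_len(nsteps))
    st <- solve_mechanics_step(op, rep(vstar, mesh$nvert), st)
  xy <- mesh$p2_coords
  r2 <- rowSums(xy^2)
  keep <- r2 > (0.2 * mesh$reference_diameter)^2
  (st$u[keep, 1] * xy[keep, 1] + st$u[keep, 2] * xy[keep, 2]) / r2[keep]
}
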