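## Quasi-static Biot poroelasticity with the biological eigenstress.
## Displacement is quadratic, pressure linear (an inf-sup stable pair), and
## on the pure-traction disk the three rigid-body motions are excluded by
## Lagrange multiplier constraints. The solver works in excess pressure
## p - p0, which is zero initially and on the boundary, so every output is
## invariant to the reference blood pressure. Time stepping is backward
## Euler; the system matrix depends only on mesh, parameters and step size,
## so it is factorized once per operator.
##
## The growth term enters as an isotropic eigenstress: the weak load is
## (K V*, div v) with zero *total* traction as the natural boundary
## condition, so a spatially uniform excess cell volume V* inflates the
## disk. (Keeping the eigenstress inside the traction instead would cancel
## the load identically and no uniform growth could occur.)

# per-row maximum absolute value of a sparse matrix
.row_abs_max <- function(M) {
  T <- as(M, "TsparseMatrix")
  out <- numeric(nrow(M))
  acc <- tapply(abs(T@x), T@i + 1L, max)
  out[as.integer(names(acc))] <- as.numeric(acc)
  out
}

#' Build the Biot mechanics operator for a mesh
#'
#' Assembles and factorizes the coupled saddle-point system for one
#' backward-Euler step of the quasi-static Biot equations: momentum balance
#' `a(u, v) + alpha*(grad p, v) = (K V*, div v)` with
#' `a(u, v) = ((K - 2G/3) div u, div v) + (G grad u, grad v)`, and storage
#' `c0 (p - p_prev)/dt + alpha div(u - u_prev)/dt = kappa Lap p`.
#'
#' @param mesh a `fem_mesh`.
#' @param params a `model_parameters` object.
#' @param dt time step, days.
#' @param bc boundary treatment: `"disk"` (zero total traction, excess
#'   pressure pinned to zero on the whole boundary, rigid-body constraints)
#'   or a list with optional elements `u_fix` (displacement dof indices),
#'   `u_val`, `p_fix` (pressure vertex indices), `p_val`, `traction`
#'   (list with `edge_ids`, `tx`, `ty`), and `rigid` (logical).
#' @return A `biot_operator` used by [solve_mechanics_step()].
#' @export
biot_operator <- function(mesh, params, dt, bc = "disk") {
  stopifnot(inherits(mesh, "fem_mesh"), inherits(params, "model_parameters"),
            dt > 0)
  np2 <- mesh$nvert + mesh$nedge
  ndu <- 2L * np2
  npp <- mesh$nvert

  if (identical(bc, "disk")) {
    bedge <- mesh$boundary_edge_id
    bc <- list(u_fix = integer(0), u_val = numeric(0),
               p_fix = boundary_vertices(mesh), p_val = NULL,
               traction = NULL, rigid = TRUE)
  }
  if (is.null(bc$p_val)) bc$p_val <- rep(0, length(bc$p_fix))
  if (is.null(bc$u_val)) bc$u_val <- rep(0, length(bc$u_fix))
  rigid <- isTRUE(bc$rigid)
  nl <- if (rigid) 3L else 0L

  A <- .assemble_elasticity(mesh, params$K, params$G)
  Gp <- .assemble_pressure_gradient(mesh)
  Cdiv <- .assemble_divergence(mesh)
  Mp <- assemble_p1_mass(mesh)
  Kp <- assemble_p1_stiffness(mesh)

  top <- cbind(A, params$alpha * Gp)
  mid <- cbind((params$alpha / dt) * Cdiv,
               (params$c0 / dt) * Mp + params$kappa * Kp)
  if (rigid) {
    Z <- .assemble_rigid_rows(mesh)
    Zs <- as(Matrix::Matrix(Z, sparse = TRUE), "generalMatrix")
    top <- cbind(top, -Matrix::t(Zs))
    mid <- cbind(mid, Matrix::Matrix(0, npp, nl, sparse = TRUE))
    bot <- cbind(Zs, Matrix::Matrix(0, nl, npp + nl, sparse = TRUE))
    M <- rbind(top, mid, bot)
  } else {
    Z <- NULL
    M <- rbind(top, mid)
  }

  fix <- c(bc$u_fix, ndu + bc$p_fix)
  if (length(fix)) {
    M[fix, ] <- 0
    M[cbind(fix, fix)] <- 1
  }
  traction_load <- numeric(ndu)
  if (!is.null(bc$traction))
    traction_load <- .p2_edge_load(mesh, bc$traction$edge_ids,
                                   bc$traction$tx, bc$traction$ty)

  # two-sided diagonal equilibration: the elasticity, storage and
  # constraint rows live on wildly different scales (moduli ~1e4 Pa,
  # element areas ~1e-8 m^2), far beyond what a sparse LU tolerates raw
  M <- as(M, "CsparseMatrix")
  rs <- 1 / pmax(.row_abs_max(M), 1e-300)
  Ms <- Matrix::Diagonal(x = rs) %*% M
  cs <- 1 / pmax(.row_abs_max(Matrix::t(Ms)), 1e-300)
  Ms <- Ms %*% Matrix::Diagonal(x = cs)

  structure(list(
    mesh = mesh, params = params, dt = dt, bc = bc,
    np2 = np2, ndu = ndu, npp = npp, nl = nl,
    A = A, Cdiv = Cdiv, CdivT = Matrix::t(Cdiv), Mp = Mp, Kp = Kp, Z = Z,
    M = M, lu = Matrix::lu(Ms), rs = rs, cs = cs, Mnorm = max(1 / rs),
    fix = fix, fix_val = c(bc$u_val, bc$p_val),
    traction_load = traction_load
  ), class = "biot_operator")
}

#' @export
print.biot_operator <- function(x, ...) {
  cat(sprintf("biot_operator: %d displacement + %d pressure dofs, %d constraints, dt = %g day\n",
              x$ndu, x$npp, x$nl, x$dt))
  invisible(x)
}

#' Initial (undeformed) mechanical state
#'
#' @param op a `biot_operator`.
#' @return A `mechanical_state` with zero displacement and excess pressure.
#' @export
initial_mechanical_state <- function(op) {
  structure(list(U = numeric(op$ndu), P = numeric(op$npp),
                 lambda = numeric(op$nl), t = 0),
            class = "mechanical_state")
}

#' Advance the mechanics by one backward-Euler step
#'
#' Solves the factorized saddle-point system for the displacement, excess
#' pore pressure and rigid-body multipliers, given the excess solid-cell
#' volume field `V*` (a vertex field) and the previous state. The relative
#' residual and the rigid-constraint functionals of the solution are
#' checked against 1e-10.
#'
#' @param op a `biot_operator`.
#' @param Vstar excess cell volume `V - V0` at the mesh vertices.
#' @param state_prev previous `mechanical_state`.
#' @param extra_load optional list with components `Fu` (length `2*np2`)
#'   and/or `Fp` (length `nvert`) added to the right-hand side; used by the
#'   manufactured-solution verification.
#' @return The new `mechanical_state`; element `u` holds the displacement
#'   at the P2 nodes as an `np2` x 2 matrix, `p_excess` the vertex excess
#'   pressure.
#' @export
solve_mechanics_step <- function(op, Vstar, state_prev = NULL,
                                 extra_load = NULL) {
  stopifnot(inherits(op, "biot_operator"))
  if (is.null(state_prev)) state_prev <- initial_mechanical_state(op)
  p <- op$params
  Fu <- p$K * as.numeric(op$CdivT %*% Vstar) + op$traction_load
  Fp <- as.numeric((p$alpha / op$dt) * (op$Cdiv %*% state_prev$U) +
                   (p$c0 / op$dt) * (op$Mp %*% state_prev$P))
  if (!is.null(extra_load)) {
    if (!is.null(extra_load$Fu)) Fu <- Fu + extra_load$Fu
    if (!is.null(extra_load$Fp)) Fp <- Fp + extra_load$Fp
  }
  rhs <- c(Fu, Fp, numeric(op$nl))
  if (length(op$fix)) rhs[op$fix] <- op$fix_val
  sol <- op$cs * as.numeric(Matrix::solve(op$lu, op$rs * rhs))
  res <- sqrt(sum((as.numeric(op$M %*% sol) - rhs)^2)) /
    (op$Mnorm * sqrt(sum(sol^2)) + sqrt(sum(rhs^2)) + 1e-300)
  if (!is.finite(res) || res > 1e-10)
    stop(sprintf("mechanics solve failed: relative residual %.3g", res),
         call. = FALSE)
  U <- sol[seq_len(op$ndu)]
  P <- sol[op$ndu + seq_len(op$npp)]
  lambda <- if (op$nl) sol[op$ndu + op$npp + seq_len(op$nl)] else numeric(0)
  if (op$nl) {
    cons <- abs(op$Z %*% U) / max(1, sqrt(sum(U^2)))
    if (max(cons) > 1e-8)
      stop("rigid-body constraints violated beyond tolerance", call. = FALSE)
  }
  structure(list(U = U, P = P, lambda = lambda, t = state_prev$t + op$dt,
                 u = cbind(U[seq_len(op$np2)], U[op$np2 + seq_len(op$np2)]),
                 p_excess = P),
            class = "mechanical_state")
}

#' @export
print.mechanical_state <- function(x, ...) {
  cat(sprintf("mechanical_state at t = %g day: max |u| = %.3g m, excess p in [%.3g, %.3g] Pa\n",
              x$t, max(abs(x$U)), min(x$P), max(x$P)))
  invisible(x)
}

#' Darcy velocity from the excess pressure field
#'
#' Evaluates `q = -kappa grad p` elementwise (the linear pressure makes the
#' velocity constant per element) and projects it to the vertices by
#' area-weighted averaging for reporting.
#'
#' @param mesh a `fem_mesh`.
#' @param p_excess excess pressure at the vertices, Pa.
#' @param kappa hydraulic conductivity, m^2 Pa^-1 day^-1.
#' @return List with `element` (ntri x 2) and `nodal` (nvert x 2) fields in
#'   m/day.
#' @export
darcy_velocity <- function(mesh, p_excess, kappa) {
  tt <- .tri_transform(mesh)
  g <- .p1_gradients(tt)
  tri <- mesh$triangles
  px <- g$gx[, 1] * p_excess[tri[, 1]] + g$gx[, 2] * p_excess[tri[, 2]] +
        g$gx[, 3] * p_excess[tri[, 3]]
  py <- g$gy[, 1] * p_excess[tri[, 1]] + g$gy[, 2] * p_excess[tri[, 2]] +
        g$gy[, 3] * p_excess[tri[, 3]]
  elem <- cbind(-kappa * px, -kappa * py)
  w <- tt$area / 3
  nodal <- cbind(.accum(as.vector(tri), rep(elem[, 1], 3) * rep(w, 3), mesh$nvert),
                 .accum(as.vector(tri), rep(elem[, 2], 3) * rep(w, 3), mesh$nvert))
  ml <- assemble_p1_mass(mesh, lumped = TRUE)
  list(element = elem, nodal = nodal / ml)
}

#' Discrete poroelastic energy
#'
#' `E = 1/2 a(u, u) + 1/2 c0 (p, p)`; with the eigenstress frozen and no
#' sources the backward-Euler step dissipates this energy.
#'
#' @param op a `biot_operator`.
#' @param state a `mechanical_state`.
#' @return Scalar energy (J/m, per unit thickness).
#' @export
poroelastic_energy <- function(op, state) {
  0.5 * sum(state$U * as.numeric(op$A %*% state$U)) +
    0.5 * op$params$c0 * sum(state$P * as.numeric(op$Mp %*% state$P))
}
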