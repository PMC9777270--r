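## Finite-element kernel on triangles: linear (P1) scalar fields for
## pressure and species, quadratic (P2) vector fields for displacement.
## Assembly is vectorized over elements; integrals use a six-point
## fourth-order triangle rule, exact for every bilinear form appearing in
## the model. Displacement degrees of freedom are laid out as all x
## components (1..np2) followed by all y components (np2+1..2*np2).

# affine map data per element
.tri_transform <- function(mesh) {
  tri <- mesh$triangles
  v1 <- mesh$vertices[tri[, 1], , drop = FALSE]
  v2 <- mesh$vertices[tri[, 2], , drop = FALSE]
  v3 <- mesh$vertices[tri[, 3], , drop = FALSE]
  det <- (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) -
         (v3[, 1] - v1[, 1]) * (v2[, 2] - v1[, 2])
  list(area = det / 2,
       # rows of inv(J)^T : physical gradient = [a11 a12; a21 a22] %*% ref gradient
       a11 = (v3[, 2] - v1[, 2]) / det, a12 = -(v2[, 2] - v1[, 2]) / det,
       a21 = -(v3[, 1] - v1[, 1]) / det, a22 = (v2[, 1] - v1[, 1]) / det,
       v1 = v1, v2 = v2, v3 = v3, tri = tri)
}

# P1 gradients (constant per element): columns are the three vertex functions
.p1_gradients <- function(tt) {
  gx2 <- tt$a11; gy2 <- tt$a21          # grad lambda2 (xi direction)
  gx3 <- tt$a12; gy3 <- tt$a22          # grad lambda3 (eta direction)
  list(gx = cbind(-gx2 - gx3, gx2, gx3),
       gy = cbind(-gy2 - gy3, gy2, gy3))
}

# six-point, order-4 triangle rule; weights sum to one so a physical
# integral is area * sum(w * f)
.quad_rule <- function() {
  a <- 0.445948490915965; b <- 0.091576213509771
  w1 <- 0.223381589678011; w2 <- 0.109951743655322
  lam <- rbind(c(a, a, 1 - 2 * a), c(a, 1 - 2 * a, a), c(1 - 2 * a, a, a),
               c(b, b, 1 - 2 * b), c(b, 1 - 2 * b, b), c(1 - 2 * b, b, b))
  # barycentric order (lambda2, lambda3, lambda1) -> reorder to (l1, l2, l3)
  lam <- lam[, c(3, 1, 2)]
  list(w = c(w1, w1, w1, w2, w2, w2), lam = lam)
}

# quadratic basis and reference gradients at one barycentric point
.p2_ref <- function(l1, l2, l3) {
  N <- c(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
         4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
  # d/dxi follows lambda2, d/deta follows lambda3, lambda1 = 1 - xi - eta
  dxi  <- c(-(4 * l1 - 1), 4 * l2 - 1, 0, 4 * (l1 - l2), 4 * l3, -4 * l3)
  deta <- c(-(4 * l1 - 1), 0, 4 * l3 - 1, -4 * l2, 4 * l2, 4 * (l1 - l3))
  list(N = N, dxi = dxi, deta = deta)
}

# global P2 node indices per element (6 columns)
.p2_index <- function(mesh) {
  cbind(mesh$triangles, mesh$nvert + mesh$tri2edge)
}

#' Assemble the P1 stiffness matrix
#'
#' `K[i, j] = integral of grad(phi_i) . grad(phi_j)`.
#' @param mesh a `fem_mesh`.
#' @return Sparse symmetric `nvert` x `nvert` matrix.
#' @keywords internal
assemble_p1_stiffness <- function(mesh) {
  tt <- .tri_transform(mesh)
  g <- .p1_gradients(tt)
  m <- nrow(tt$tri)
  ii <- jj <- integer(9L * m); xx <- numeric(9L * m)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * m + seq_len(m)
    ii[idx] <- tt$tri[, a]; jj[idx] <- tt$tri[, b]
    xx[idx] <- tt$area * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b])
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(mesh$nvert, mesh$nvert))
}

#' Assemble the P1 mass matrix
#'
#' @param mesh a `fem_mesh`.
#' @param lumped if `TRUE` return the diagonal (row-sum lumped) mass as a
#'   vector; otherwise the consistent sparse matrix.
#' @keywords internal
assemble_p1_mass <- function(mesh, lumped = FALSE) {
  area <- triangle_areas(mesh)
  tri <- mesh$triangles
  if (lumped) {
    ml <- numeric(mesh$nvert)
    for (a in 1:3) {
      acc <- tapply(area / 3, tri[, a], sum)
      ml[as.integer(names(acc))] <- ml[as.integer(names(acc))] + as.numeric(acc)
    }
    return(ml)
  }
  m <- nrow(tri)
  ii <- jj <- integer(9L * m); xx <- numeric(9L * m)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * m + seq_len(m)
    ii[idx] <- tri[, a]; jj[idx] <- tri[, b]
    xx[idx] <- area * (if (a == b) 1 / 6 else 1 / 12)
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(mesh$nvert, mesh$nvert))
}

# advection matrix in conservative form: A[i, j] = -int phi_j (v . grad phi_i),
# with v constant per element (two-column matrix). Column sums vanish, so the
# lumped total mass sum(M X) is exactly conserved by the semi-discrete form.
.assemble_advection <- function(mesh, vel_elem) {
  tt <- .tri_transform(mesh)
  g <- .p1_gradients(tt)
  m <- nrow(tt$tri)
  ii <- jj <- integer(9L * m); xx <- numeric(9L * m)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * m + seq_len(m)
    ii[idx] <- tt$tri[, a]; jj[idx] <- tt$tri[, b]
    xx[idx] <- -(vel_elem[, 1] * g$gx[, a] + vel_elem[, 2] * g$gy[, a]) *
      tt$area / 3
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(mesh$nvert, mesh$nvert))
}

# lumped boundary measure: bl[i] = half the length of the boundary edges
# touching vertex i (zero off the boundary)
.boundary_p1_lumped <- function(mesh) {
  be <- mesh$boundary_edges
  L <- sqrt(rowSums((mesh$vertices[be[, 1], , drop = FALSE] -
                     mesh$vertices[be[, 2], , drop = FALSE])^2))
  bl <- numeric(mesh$nvert)
  for (c in 1:2) {
    acc <- tapply(L / 2, be[, c], sum)
    bl[as.integer(names(acc))] <- bl[as.integer(names(acc))] + as.numeric(acc)
  }
  bl
}

# P2 vector-elasticity matrix for a(u,v) = ((K - 2G/3) div u, div v) + (G grad u, grad v)
.assemble_elasticity <- function(mesh, K, G) {
  tt <- .tri_transform(mesh)
  qr <- .quad_rule()
  p2 <- .p2_index(mesh)
  np2 <- mesh$nvert + mesh$nedge
  m <- nrow(tt$tri)
  Sxx <- Sxy <- Syy <- array(0, c(m, 6, 6))
  for (q in seq_along(qr$w)) {
    rf <- .p2_ref(qr$lam[q, 1], qr$lam[q, 2], qr$lam[q, 3])
    bx <- outer(tt$a11, rf$dxi) + outer(tt$a12, rf$deta)   # m x 6
    by <- outer(tt$a21, rf$dxi) + outer(tt$a22, rf$deta)
    wq <- qr$w[q] * tt$area
    for (a in 1:6) for (b in 1:6) {
      Sxx[, a, b] <- Sxx[, a, b] + wq * bx[, a] * bx[, b]
      Sxy[, a, b] <- Sxy[, a, b] + wq * bx[, a] * by[, b]
      Syy[, a, b] <- Syy[, a, b] + wq * by[, a] * by[, b]
    }
  }
  lam <- K - 2 * G / 3
  nblock <- 36L * m
  ii <- jj <- integer(4L * nblock); xx <- numeric(4L * nblock)
  k <- 0L
  put <- function(rows, cols, vals) {
    idx <- k + seq_len(m)
    ii[idx] <<- rows; jj[idx] <<- cols; xx[idx] <<- vals
    k <<- k + m
  }
  for (a in 1:6) for (b in 1:6) {
    ga <- p2[, a]; gb <- p2[, b]
    gg <- G * (Sxx[, a, b] + Syy[, a, b])
    put(ga, gb, lam * Sxx[, a, b] + gg)                       # xx block
    put(ga, np2 + gb, lam * Sxy[, a, b])                      # xy block
    put(np2 + ga, gb, lam * Sxy[, b, a])                      # yx block
    put(np2 + ga, np2 + gb, lam * Syy[, a, b] + gg)           # yy block
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2L * np2, 2L * np2))
}

# pressure-gradient coupling Gp[dof, j] = int (grad phi_j)_comp * N_dof
# (P1 pressure gradient is constant per element)
.assemble_pressure_gradient <- function(mesh) {
  tt <- .tri_transform(mesh)
  gp1 <- .p1_gradients(tt)
  qr <- .quad_rule()
  p2 <- .p2_index(mesh)
  np2 <- mesh$nvert + mesh$nedge
  m <- nrow(tt$tri)
  intN <- matrix(0, m, 6)                 # integral of each P2 basis over element
  for (q in seq_along(qr$w)) {
    rf <- .p2_ref(qr$lam[q, 1], qr$lam[q, 2], qr$lam[q, 3])
    intN <- intN + qr$w[q] * tt$area %o% rf$N
  }
  ii <- jj <- integer(2L * 18L * m); xx <- numeric(2L * 18L * m)
  k <- 0L
  for (a in 1:6) for (b in 1:3) {
    idx <- k + seq_len(m)
    ii[idx] <- p2[, a]; jj[idx] <- tt$tri[, b]
    xx[idx] <- gp1$gx[, b] * intN[, a]
    k <- k + m
    idx <- k + seq_len(m)
    ii[idx] <- np2 + p2[, a]; jj[idx] <- tt$tri[, b]
    xx[idx] <- gp1$gy[, b] * intN[, a]
    k <- k + m
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2L * np2, mesh$nvert))
}

# divergence coupling Cdiv[i, dof] = int phi_i * div(v_dof)
.assemble_divergence <- function(mesh) {
  tt <- .tri_transform(mesh)
  qr <- .quad_rule()
  p2 <- .p2_index(mesh)
  np2 <- mesh$nvert + mesh$nedge
  m <- nrow(tt$tri)
  ii <- jj <- integer(2L * 18L * m); xx <- numeric(2L * 18L * m)
  acc_x <- array(0, c(m, 3, 6)); acc_y <- array(0, c(m, 3, 6))
  for (q in seq_along(qr$w)) {
    rf <- .p2_ref(qr$lam[q, 1], qr$lam[q, 2], qr$lam[q, 3])
    bx <- outer(tt$a11, rf$dxi) + outer(tt$a12, rf$deta)
    by <- outer(tt$a21, rf$dxi) + outer(tt$a22, rf$deta)
    lamP1 <- qr$lam[q, ]                   # P1 values are the barycentrics
    wq <- qr$w[q] * tt$area
    for (i in 1:3) for (a in 1:6) {
      acc_x[, i, a] <- acc_x[, i, a] + wq * lamP1[i] * bx[, a]
      acc_y[, i, a] <- acc_y[, i, a] + wq * lamP1[i] * by[, a]
    }
  }
  k <- 0L
  for (i in 1:3) for (a in 1:6) {
    idx <- k + seq_len(m)
    ii[idx] <- tt$tri[, i]; jj[idx] <- p2[, a]; xx[idx] <- acc_x[, i, a]
    k <- k + m
    idx <- k + seq_len(m)
    ii[idx] <- tt$tri[, i]; jj[idx] <- np2 + p2[, a]; xx[idx] <- acc_y[, i, a]
    k <- k + m
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(mesh$nvert, 2L * np2))
}

# rigid-body constraint rows Z[i, dof] = int v_dof . z_i over the domain
.assemble_rigid_rows <- function(mesh) {
  tt <- .tri_transform(mesh)
  qr <- .quad_rule()
  p2 <- .p2_index(mesh)
  np2 <- mesh$nvert + mesh$nedge
  m <- nrow(tt$tri)
  intN <- matrix(0, m, 6); intxN <- matrix(0, m, 6); intyN <- matrix(0, m, 6)
  for (q in seq_along(qr$w)) {
    rf <- .p2_ref(qr$lam[q, 1], qr$lam[q, 2], qr$lam[q, 3])
    xq <- qr$lam[q, 1] * tt$v1[, 1] + qr$lam[q, 2] * tt$v2[, 1] + qr$lam[q, 3] * tt$v3[, 1]
    yq <- qr$lam[q, 1] * tt$v1[, 2] + qr$lam[q, 2] * tt$v2[, 2] + qr$lam[q, 3] * tt$v3[, 2]
    wq <- qr$w[q] * tt$area
    intN <- intN + wq %o% rf$N
    intxN <- intxN + (wq * xq) %o% rf$N
    intyN <- intyN + (wq * yq) %o% rf$N
  }
  Z <- matrix(0, 3, 2L * np2)
  for (a in 1:6) {
    gx <- p2[, a]; gy <- np2 + p2[, a]
    Z[1, ] <- Z[1, ] + .accum(gx, intN[, a], 2L * np2)
    Z[2, ] <- Z[2, ] + .accum(gy, intN[, a], 2L * np2)
    Z[3, ] <- Z[3, ] + .accum(gx, -intyN[, a], 2L * np2) +
                        .accum(gy, intxN[, a], 2L * np2)
  }
  Z
}

# scatter-add helper
.accum <- function(idx, vals, n) {
  out <- numeric(n)
  acc <- tapply(vals, idx, sum)
  out[as.integer(names(acc))] <- as.numeric(acc)
  out
}

# quadrature load vectors for analytic forcing functions and L2 errors
# against analytic fields (verification utilities)
.p2_load_function <- function(mesh, fx, fy) {
  tt <- .tri_transform(mesh); qr <- .quad_rule(); p2 <- .p2_index(mesh)
  np2 <- mesh$nvert + mesh$nedge
  F <- numeric(2L * np2)
  for (q in seq_along(qr$w)) {
    rf <- .p2_ref(qr$lam[q, 1], qr$lam[q, 2], qr$lam[q, 3])
    xq <- qr$lam[q, 1] * tt$v1[, 1] + qr$lam[q, 2] * tt$v2[, 1] + qr$lam[q, 3] * tt$v3[, 1]
    yq <- qr$lam[q, 1] * tt$v1[, 2] + qr$lam[q, 2] * tt$v2[, 2] + qr$lam[q, 3] * tt$v3[, 2]
    wq <- qr$w[q] * tt$area
    vx <- wq * fx(xq, yq); vy <- wq * fy(xq, yq)
    for (a in 1:6) {
      F <- F + .accum(p2[, a], vx * rf$N[a], 2L * np2) +
               .accum(np2 + p2[, a], vy * rf$N[a], 2L * np2)
    }
  }
  F
}

.p1_load_function <- function(mesh, f) {
  tt <- .tri_transform(mesh); qr <- .quad_rule()
  F <- numeric(mesh$nvert)
  for (q in seq_along(qr$w)) {
    xq <- qr$lam[q, 1] * tt$v1[, 1] + qr$lam[q, 2] * tt$v2[, 1] + qr$lam[q, 3] * tt$v3[, 1]
    yq <- qr$lam[q, 1] * tt$v1[, 2] + qr$lam[q, 2] * tt$v2[, 2] + qr$lam[q, 3] * tt$v3[, 2]
    wq <- qr$w[q] * tt$area * f(xq, yq)
    for (i in 1:3) F <- F + .accum(tt$tri[, i], wq * qr$lam[q, i], mesh$nvert)
  }
  F
}

.p2_l2_error <- function(mesh, u, ux_exact, uy_exact) {
  tt <- .tri_transform(mesh); qr <- .quad_rule(); p2 <- .p2_index(mesh)
  err2 <- 0
  for (q in seq_along(qr$w)) {
    rf <- .p2_ref(qr$lam[q, 1], qr$lam[q, 2], qr$lam[q, 3])
    xq <- qr$lam[q, 1] * tt$v1[, 1] + qr$lam[q, 2] * tt$v2[, 1] + qr$lam[q, 3] * tt$v3[, 1]
    yq <- qr$lam[q, 1] * tt$v1[, 2] + qr$lam[q, 2] * tt$v2[, 2] + qr$lam[q, 3] * tt$v3[, 2]
    uhx <- uhy <- 0
    for (a in 1:6) {
      uhx <- uhx + rf$N[a] * u[p2[, a], 1]
      uhy <- uhy + rf$N[a] * u[p2[, a], 2]
    }
    err2 <- err2 + sum(qr$w[q] * tt$area *
                       ((uhx - ux_exact(xq, yq))^2 + (uhy - uy_exact(xq, yq))^2))
  }
  sqrt(err2)
}

.p1_l2_error <- function(mesh, p, p_exact) {
  tt <- .tri_transform(mesh); qr <- .quad_rule()
  err2 <- 0
  for (q in seq_along(qr$w)) {
    xq <- qr$lam[q, 1] * tt$v1[, 1] + qr$lam[q, 2] * tt$v2[, 1] + qr$lam[q, 3] * tt$v3[, 1]
    yq <- qr$lam[q, 1] * tt$v1[, 2] + qr$lam[q, 2] * tt$v2[, 2] + qr$lam[q, 3] * tt$v3[, 2]
    ph <- qr$lam[q, 1] * p[tt$tri[, 1]] + qr$lam[q, 2] * p[tt$tri[, 2]] +
          qr$lam[q, 3] * p[tt$tri[, 3]]
    err2 <- err2 + sum(qr$w[q] * tt$area * (ph - p_exact(xq, yq))^2)
  }
  sqrt(err2)
}

# traction load on boundary edges: for each P2 boundary edge the endpoint
# basis functions integrate to L/6 and the midside one to 2L/3
.p2_edge_load <- function(mesh, edge_ids, tx, ty) {
  np2 <- mesh$nvert + mesh$nedge
  f <- numeric(2L * np2)
  for (e in edge_ids) {
    vs <- mesh$edges[e, ]
    L <- sqrt(sum((mesh$vertices[vs[1], ] - mesh$vertices[vs[2], ])^2))
    nodes <- c(vs, mesh$nvert + e)
    wts <- c(L / 6, L / 6, 2 * L / 3)
    f[nodes] <- f[nodes] + tx * wts
    f[np2 + nodes] <- f[np2 + nodes] + ty * wts
  }
  f
}
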