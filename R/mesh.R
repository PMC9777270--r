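## Structured triangulations of the reference domains. The tumor domain is
## a disk triangulated in concentric rings (ring i carries 6*i vertices),
## which keeps elements near-equilateral at every radius and makes the mesh
## exactly symmetric under the hexagonal rotation group. A structured
## rectangle mesh supports the one-dimensional consolidation and
## manufactured-solution benchmarks. Quadratic (P2) node numbering places
## the vertex nodes first and one midside node per unique edge after them.

# shared finalization: orient triangles CCW, extract unique edges, boundary,
# and the P2 node coordinates
.mesh_finalize <- function(vertices, triangles, reference_diameter, h) {
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  sa <- 0.5 * ((v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) -
               (v3[, 1] - v1[, 1]) * (v2[, 2] - v1[, 2]))
  flip <- sa < 0
  if (any(flip)) triangles[flip, 2:3] <- triangles[flip, 3:2]
  if (any(abs(sa) < 1e-30)) stop("degenerate triangle in mesh", call. = FALSE)

  m <- nrow(triangles)
  raw <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(raw[, 1], raw[, 2]), pmax(raw[, 1], raw[, 2]))
  uk <- !duplicated(key)
  edges <- cbind(pmin(raw[uk, 1], raw[uk, 2]), pmax(raw[uk, 1], raw[uk, 2]))
  edge_id <- match(key, key[uk])
  tri2edge <- matrix(edge_id, nrow = m, ncol = 3)
  boundary <- tabulate(edge_id, nbins = nrow(edges)) == 1L

  midpoints <- (vertices[edges[, 1], , drop = FALSE] +
                vertices[edges[, 2], , drop = FALSE]) / 2
  structure(list(
    vertices = vertices, triangles = triangles,
    edges = edges, tri2edge = tri2edge,
    boundary_edges = edges[boundary, , drop = FALSE],
    boundary_edge_id = which(boundary),
    p2_coords = rbind(vertices, midpoints),
    nvert = nrow(vertices), nedge = nrow(edges),
    reference_diameter = reference_diameter, h = h
  ), class = "fem_mesh")
}

#' Triangulate the reference disk
#'
#' Builds a structured triangulation of a disk centered at the origin from
#' concentric rings, so the rotation mode of the rigid-body basis needs no
#' centroid correction. `rings` controls resolution directly (the mesh has
#' `6 * rings^2` triangles, about 2000 at the default `rings = 18`);
#' alternatively pass a target edge length `resolution`.
#'
#' @param diameter disk diameter in meters.
#' @param rings number of concentric rings (overrides `resolution`).
#' @param resolution target edge length in meters.
#' @return A `fem_mesh` (also class `disk_mesh`) with vertices, CCW
#'   triangles, unique edges, boundary edges and P2 node coordinates.
#' @examples
#' mesh <- build_disk_mesh(0.01, rings = 6)
#' mesh_area(mesh) / (pi * 0.01^2 / 4) # close to 1
#' @export
build_disk_mesh <- function(diameter = 0.01, rings = 18, resolution = NULL) {
  if (!is.numeric(diameter) || diameter <= 0) stop("diameter must be positive", call. = FALSE)
  R <- diameter / 2
  if (!is.null(resolution)) {
    if (resolution <= 0 || resolution >= diameter)
      stop("resolution must lie in (0, diameter)", call. = FALSE)
    rings <- max(2L, as.integer(round(R / resolution)))
  }
  rings <- as.integer(rings)
  if (rings < 1L) stop("need at least one ring", call. = FALSE)

  idx0 <- function(i) 2L + 3L * i * (i - 1L)  # first vertex index of ring i
  nv <- 1L + 3L * rings * (rings + 1L)
  vertices <- matrix(0, nv, 2)
  for (i in seq_len(rings)) {
    k <- 0:(6L * i - 1L)
    th <- 2 * pi * k / (6 * i)
    r <- R * i / rings
    vertices[idx0(i) + k, ] <- cbind(r * cos(th), r * sin(th))
  }

  tris <- vector("list", rings)
  tris[[1]] <- cbind(1L, idx0(1L) + 0:5, idx0(1L) + c(1:5, 0L))
  if (rings >= 2L) for (i in 2:rings) {
    no <- 6L * i; ni <- 6L * (i - 1L)
    out <- integer(0); mid <- integer(0); inn <- integer(0)
    for (s in 0:5) {
      O <- idx0(i) + (s * i + 0:i) %% no
      I <- idx0(i - 1L) + (s * (i - 1L) + 0:(i - 1L)) %% ni
      j <- 1:i
      out <- c(out, O[j]); mid <- c(mid, O[j + 1L]); inn <- c(inn, I[j])
      if (i >= 2L) {
        j <- 1:(i - 1L)
        out <- c(out, O[j + 1L]); mid <- c(mid, I[j + 1L]); inn <- c(inn, I[j])
      }
    }
    tris[[i]] <- cbind(out, mid, inn)
  }
  triangles <- do.call(rbind, tris)
  mesh <- .mesh_finalize(vertices, triangles, diameter, h = R / rings)
  class(mesh) <- c("disk_mesh", class(mesh))
  mesh
}

#' Structured rectangle mesh
#'
#' Used by the consolidation and manufactured-solution benchmarks. Boundary
#' vertex sets for each side are tagged so Dirichlet conditions can be
#' applied per side.
#'
#' @param Lx,Ly side lengths in meters.
#' @param nx,ny number of cells per direction.
#' @return A `fem_mesh` with an extra `sides` element (lists of vertex
#'   indices `left`, `right`, `bottom`, `top`).
#' @export
build_rect_mesh <- function(Lx = 1, Ly = 1, nx = 8, ny = 8) {
  xs <- seq(0, Lx, length.out = nx + 1L)
  ys <- seq(0, Ly, length.out = ny + 1L)
  vertices <- as.matrix(expand.grid(x = xs, y = ys))
  dimnames(vertices) <- NULL
  vid <- function(i, j) i + (nx + 1L) * (j - 1L)  # i in 1..nx+1, j in 1..ny+1
  tris <- matrix(0L, 2L * nx * ny, 3L)
  k <- 1L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- vid(i, j); b <- vid(i + 1L, j); c <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
    tris[k, ] <- c(a, b, c); tris[k + 1L, ] <- c(a, c, d)
    k <- k + 2L
  }
  mesh <- .mesh_finalize(vertices, tris, max(Lx, Ly), h = max(Lx / nx, Ly / ny))
  tol <- 1e-12 * max(Lx, Ly)
  mesh$sides <- list(
    left   = which(abs(vertices[, 1]) < tol),
    right  = which(abs(vertices[, 1] - Lx) < tol),
    bottom = which(abs(vertices[, 2]) < tol),
    top    = which(abs(vertices[, 2] - Ly) < tol))
  mesh
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("fem_mesh: %d vertices, %d triangles, %d boundary edges, h = %.3g m\n",
              x$nvert, nrow(x$triangles), nrow(x$boundary_edges), x$h))
  invisible(x)
}

#' Triangle areas and total mesh area
#'
#' @param mesh a `fem_mesh`.
#' @return `triangle_areas`: vector of element areas; `mesh_area`: their sum.
#' @export
triangle_areas <- function(mesh) {
  v1 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  0.5 * ((v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) -
         (v3[, 1] - v1[, 1]) * (v2[, 2] - v1[, 2]))
}

#' @rdname triangle_areas
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Vertices on the domain boundary
#'
#' @param mesh a `fem_mesh`.
#' @return Sorted vector of boundary vertex indices.
#' @export
boundary_vertices <- function(mesh) sort(unique(as.vector(mesh$boundary_edges)))

# P2 node indices among a vertex set: the vertices themselves plus the
# midside nodes of edges with both endpoints in the set
.p2_nodes_among <- function(mesh, verts) {
  inset <- rep(FALSE, mesh$nvert)
  inset[verts] <- TRUE
  mids <- which(inset[mesh$edges[, 1]] & inset[mesh$edges[, 2]])
  c(verts, mesh$nvert + mids)
}

# boundary edge ids whose endpoints both lie in a vertex set
.boundary_edges_among <- function(mesh, verts) {
  inset <- rep(FALSE, mesh$nvert)
  inset[verts] <- TRUE
  ids <- mesh$boundary_edge_id
  ids[inset[mesh$edges[ids, 1]] & inset[mesh$edges[ids, 2]]]
}

#' Rigid-body mode basis
#'
#' The two translations and the in-plane rotation about the origin,
#' evaluated at the quadratic nodes: `z1 = (1, 0)`, `z2 = (0, 1)`,
#' `z3 = (-y, x)`. Pairing the displacement against these fields over the
#' domain and constraining the three pairings to zero removes the rigid
#' motions that a pure-traction elastic problem leaves undetermined.
#'
#' @param mesh a `fem_mesh`.
#' @param nodes `"p2"` (default) or `"vertex"`: which node set to evaluate on.
#' @return List of three two-column matrices `z1`, `z2`, `z3`.
#' @export
rigid_body_basis <- function(mesh, nodes = c("p2", "vertex")) {
  nodes <- match.arg(nodes)
  xy <- if (nodes == "p2") mesh$p2_coords else mesh$vertices
  n <- nrow(xy)
  list(z1 = cbind(rep(1, n), rep(0, n)),
       z2 = cbind(rep(0, n), rep(1, n)),
       z3 = cbind(-xy[, 2], xy[, 1]))
}

#' Warp a mesh by a displacement field
#'
#' Translates every vertex by the displacement evaluated at it. Used for
#' reporting the simulated domain shape and size; the governing equations
#' stay on the fixed reference mesh. Errors if any triangle inverts,
#' reporting the worst one.
#'
#' @param mesh a `fem_mesh`.
#' @param u displacement at the vertices: an `nvert` x 2 matrix (a P2 field
#'   may be passed; only its vertex rows are used).
#' @return The warped `fem_mesh`.
#' @export
warp_mesh <- function(mesh, u) {
  if (is.null(dim(u))) stop("u must be a two-column matrix", call. = FALSE)
  u <- u[seq_len(mesh$nvert), , drop = FALSE]
  out <- mesh
  out$vertices <- mesh$vertices + u
  sa <- triangle_areas(out)
  if (any(sa <= 0)) {
    worst <- which.min(sa)
    stop(sprintf("displacement inverts %d triangle(s); worst is element %d (signed area %.3g)",
                 sum(sa <= 0), worst, sa[worst]), call. = FALSE)
  }
  mids <- (out$vertices[out$edges[, 1], , drop = FALSE] +
           out$vertices[out$edges[, 2], , drop = FALSE]) / 2
  out$p2_coords <- rbind(out$vertices, mids)
  out
}

#' Measure the domain diameter
#'
#' The maximum pairwise distance between boundary vertices, evaluated by an
#' exact scan over the boundary loop. Invariant under rigid translations
#' and rotations of the mesh.
#'
#' @param mesh a `fem_mesh`.
#' @return Diameter in meters.
#' @export
measure_diameter <- function(mesh) {
  b <- boundary_vertices(mesh)
  xy <- mesh$vertices[b, , drop = FALSE]
  dx <- outer(xy[, 1], xy[, 1], "-")
  dy <- outer(xy[, 2], xy[, 2], "-")
  sqrt(max(dx * dx + dy * dy))
}

#' Write a mesh (with optional fields) as legacy ASCII VTK
#'
#' @param mesh a `fem_mesh`.
#' @param file output path (`.vtk`).
#' @param point_data named list of per-vertex scalars (length `nvert`).
#' @param cell_data named list of per-triangle scalars.
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- mesh$nvert; m <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "poroTME mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$vertices[, 1], mesh$vertices[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", point_data[[nm]][seq_len(n)]), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    }
  }
  invisible(file)
}

#' Write a mesh in Gmsh v2 ASCII format
#'
#' @param mesh a `fem_mesh`.
#' @param file output path (`.msh`).
#' @return The path, invisibly.
#' @export
write_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- mesh$nvert; m <- nrow(mesh$triangles)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               sprintf("%d", n)), con)
  writeLines(sprintf("%d %.10g %.10g 0", seq_len(n),
                     mesh$vertices[, 1], mesh$vertices[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", sprintf("%d", m)), con)
  writeLines(sprintf("%d 2 2 0 1 %d %d %d", seq_len(m), mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  writeLines("$EndElements", con)
  invisible(file)
}
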