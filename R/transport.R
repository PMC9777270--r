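## One backward-Euler transport step for the 14 species on the reference
## mesh. Motile species carry their class diffusivity; naive pools and
## necrotic debris have no transport and reduce to nodal relaxation.
## Reactions are handled semi-implicitly: removal terms (all proportional
## to the species being removed) are implicit, production terms explicit,
## which preserves nonnegativity together with the lumped mass matrix.
## Species are advanced in catalog order and each one sees the already
## updated earlier species (Gauss-Seidel sweep), mirroring the sequential
## mechanics-then-biology structure of the time loop.
##
## The advective coupling to the Darcy flow is selectable:
##  * "laplacian" (default): the species equation's advection term
##    b * X * kappa * Lap(p) evaluated with the discrete linear pressure,
##    whose elementwise Laplacian vanishes identically -- the published
##    discretization. Uniform states are then exact fixed points and the
##    uniform reference case coincides with the compartment reduction.
##  * "conservative": div(X v_f) with v_f = -kappa grad p in conservative
##    weak form; exactly mass-conserving (the discrete column sums vanish)
##    but a compressing flow field displaces uniform states.
##  * "none": advection disabled (equivalent to b = 0).

#' Boundary condition specification for the species system
#'
#' No-flux (`kind = "no-flux"`) leaves the natural boundary condition of
#' the diffusion operator in place. Robin influx
#' (`dX/dn + alpha_i (X_i - Xhat_i) = 0`) models exchange with blood and
#' lymph; its weak form adds the boundary terms `D_i alpha_i X` and
#' `D_i alpha_i Xhat` (the flux is scaled by the species diffusivity, as
#' the normal-derivative form of the condition dictates). A Robin rate on
#' a non-immune species is allowed for experimentation but warned about.
#'
#' @param kind `"no-flux"` or `"robin"`.
#' @param alpha length-14 vector of influx rates (1/m); used in robin mode.
#' @param Xhat length-14 vector of external scaled levels.
#' @return A `boundary_spec`.
#' @export
boundary_spec <- function(kind = c("no-flux", "robin"),
                          alpha = rep(0, 14), Xhat = rep(0, 14)) {
  kind <- match.arg(kind)
  stopifnot(length(alpha) == 14L, length(Xhat) == 14L)
  if (kind == "robin") {
    extra <- setdiff(which(alpha != 0), immune_influx_species())
    if (length(extra))
      warning("Robin influx on non-immune species: ",
              paste(species_catalog()$symbol[extra], collapse = ", "),
              call. = FALSE)
  }
  structure(list(kind = kind, alpha = alpha, Xhat = Xhat),
            class = "boundary_spec")
}

#' Interior / boundary source specification
#'
#' A constant-in-time source of one or more species, either in the
#' concentric disk of half the domain radius (`"center"`) or in the
#' outermost band of elements touching the boundary (`"boundary"`).
#'
#' @param species symbols (see [species_catalog()]) receiving a source.
#' @param region `"center"` or `"boundary"`, recycled over species.
#' @param magnitude source strength, scaled units per day, recycled.
#' @return A `source_spec`.
#' @export
source_spec <- function(species = character(0), region = "center",
                        magnitude = 0.5) {
  sym <- species_catalog()$symbol
  idx <- match(species, sym)
  if (anyNA(idx)) stop("unknown species: ",
                       paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  region <- rep_len(region, length(idx))
  magnitude <- rep_len(magnitude, length(idx))
  if (any(!region %in% c("center", "boundary")))
    stop("region must be 'center' or 'boundary'", call. = FALSE)
  if (any(magnitude < 0)) stop("source magnitude must be >= 0", call. = FALSE)
  structure(list(species = idx, region = region, magnitude = magnitude),
            class = "source_spec")
}

# nodal source *rates* (scaled/day against the lumped mass): magnitude on
# the nodes of the flagged element set, zero elsewhere
.source_rates <- function(mesh, src) {
  rates <- matrix(0, 14, mesh$nvert)
  if (is.null(src) || !length(src$species)) return(rates)
  area <- triangle_areas(mesh)
  ml <- assemble_p1_mass(mesh, lumped = TRUE)
  R <- mesh$reference_diameter / 2
  cent <- (mesh$vertices[mesh$triangles[, 1], ] +
           mesh$vertices[mesh$triangles[, 2], ] +
           mesh$vertices[mesh$triangles[, 3], ]) / 3
  rad <- sqrt(rowSums(cent^2))
  on_boundary <- rep(FALSE, mesh$nvert)
  on_boundary[boundary_vertices(mesh)] <- TRUE
  for (k in seq_along(src$species)) {
    flag <- if (src$region[k] == "center") rad <= R / 2 else
      on_boundary[mesh$triangles[, 1]] | on_boundary[mesh$triangles[, 2]] |
      on_boundary[mesh$triangles[, 3]]
    load <- .accum(as.vector(mesh$triangles[flag, ]),
                   rep(area[flag] / 3, 3), mesh$nvert)
    rates[src$species[k], ] <- rates[src$species[k], ] +
      src$magnitude[k] * load / ml
  }
  rates
}

#' Build the transport operator for a mesh
#'
#' Precomputes the mass, stiffness and boundary structures shared by every
#' species step.
#'
#' @param mesh a `fem_mesh`.
#' @param params a `model_parameters`.
#' @param dt time step, days.
#' @param bc a [boundary_spec()].
#' @param src a [source_spec()] or `NULL`.
#' @param advection `"laplacian"`, `"conservative"` or `"none"`.
#' @param dirichlet optional list `(nodes, values)` pinning species values
#'   at given vertices (used by verification benchmarks).
#' @return A `transport_operator`.
#' @export
transport_operator <- function(mesh, params, dt, bc = boundary_spec(),
                               src = NULL, advection = c("laplacian", "conservative", "none"),
                               dirichlet = NULL) {
  advection <- match.arg(advection)
  stopifnot(inherits(mesh, "fem_mesh"), inherits(params, "model_parameters"),
            inherits(bc, "boundary_spec"), dt > 0)
  cat <- species_catalog()
  Dvec <- c(none = 0, cell = params$D_cell, cyto = params$D_cyto,
            H = params$D_H)[cat$diffusion]
  op <- new.env(parent = emptyenv())
  op$mesh <- mesh; op$params <- params; op$dt <- dt; op$bc <- bc
  op$advection <- advection; op$dirichlet <- dirichlet
  op$D <- unname(Dvec); op$motile <- cat$motile
  op$Kp <- assemble_p1_stiffness(mesh)
  op$Ml <- assemble_p1_mass(mesh, lumped = TRUE)
  op$blump <- .boundary_p1_lumped(mesh)
  op$src_rates <- .source_rates(mesh, src)
  op$clip_count <- 0L
  op$cache <- vector("list", 14L)
  class(op) <- "transport_operator"
  op
}

#' Robin boundary contributions for one species
#'
#' Returns the lumped boundary bilinear diagonal `D_i alpha_i` (times the
#' boundary measure) and the corresponding load `D_i alpha_i Xhat_i`; with
#' `alpha_i = 0` both vanish and the step reduces exactly to no-flux.
#'
#' @param op a `transport_operator`.
#' @param i species index.
#' @return List with `diag` (length nvert) and `load` (length nvert).
#' @export
apply_robin <- function(op, i) {
  if (op$bc$kind != "robin" || op$bc$alpha[i] == 0)
    return(list(diag = numeric(op$mesh$nvert), load = numeric(op$mesh$nvert)))
  coeff <- op$D[i] * op$bc$alpha[i]
  list(diag = coeff * op$blump, load = coeff * op$bc$Xhat[i] * op$blump)
}

#' Advance all species by one backward-Euler step
#'
#' @param op a `transport_operator`.
#' @param X state matrix, 14 rows by nvert columns.
#' @param rp a `reaction_parameters`.
#' @param vel_elem elementwise Darcy velocity (ntri x 2), used only in
#'   conservative advection mode; `NULL` otherwise.
#' @return The updated state matrix.
#' @export
advance_species <- function(op, X, rp, vel_elem = NULL) {
  stopifnot(inherits(op, "transport_operator"), nrow(X) == 14L,
            ncol(X) == op$mesh$nvert)
  dt <- op$dt
  adv <- NULL
  if (op$advection == "conservative" && op$params$b != 0 && !is.null(vel_elem))
    adv <- op$params$b * .assemble_advection(op$mesh, vel_elem)
  for (i in 1:14) {
    s <- .reaction_split(X, rp)               # sees already-updated species
    g <- s$g[i, ] + op$src_rates[i, ]
    d <- s$d[i, ]
    if (!op$motile[i] || (op$D[i] == 0 && is.null(adv) && is.null(op$dirichlet))) {
      xi <- (X[i, ] / dt + g) / (1 / dt + d)
    } else {
      rob <- apply_robin(op, i)
      diag_part <- op$Ml * (1 / dt + d) + rob$diag
      rhs <- op$Ml * (X[i, ] / dt + g) + rob$load
      key <- list(d = d, robin = rob$diag, adv = !is.null(adv))
      if (is.null(adv) && !is.null(op$cache[[i]]) &&
          identical(op$cache[[i]]$key, key)) {
        fact <- op$cache[[i]]$fact
        if (!is.null(op$dirichlet)) rhs[op$dirichlet$nodes] <- op$dirichlet$values
        xi <- as.numeric(Matrix::solve(fact, rhs))
      } else {
        LHS <- op$D[i] * op$Kp + Matrix::Diagonal(x = diag_part)
        if (!is.null(adv)) LHS <- LHS + adv
        if (!is.null(op$dirichlet)) {
          LHS[op$dirichlet$nodes, ] <- 0
          LHS[cbind(op$dirichlet$nodes, op$dirichlet$nodes)] <- 1
          rhs[op$dirichlet$nodes] <- op$dirichlet$values
        }
        fact <- Matrix::lu(as(LHS, "CsparseMatrix"))
        if (is.null(adv)) op$cache[[i]] <- list(key = key, fact = fact)
        xi <- as.numeric(Matrix::solve(fact, rhs))
      }
    }
    neg <- xi < 0
    if (any(neg)) {
      if (min(xi) < -1e-8)
        warning(sprintf("species %s clipped at %.3g", species_catalog()$symbol[i],
                        min(xi)), call. = FALSE)
      op$clip_count <- op$clip_count + sum(neg)
      xi[neg] <- 0
    }
    if (max(xi) > 1e6)
      stop("transport blow-up detected for species ",
           species_catalog()$symbol[i], call. = FALSE)
    X[i, ] <- xi
  }
  X
}

#' Per-species summary statistics over the mesh
#'
#' Nodal minimum, maximum and mean plus the exact piecewise-linear domain
#' integral of every species field.
#'
#' @param X state matrix (14 x nvert).
#' @param mesh a `fem_mesh`.
#' @return Data frame with columns `species`, `min`, `max`, `mean`,
#'   `integral`.
#' @export
species_summary <- function(X, mesh) {
  ml <- assemble_p1_mass(mesh, lumped = TRUE)
  data.frame(species = species_catalog()$symbol,
             min = apply(X, 1, min),
             max = apply(X, 1, max),
             mean = rowMeans(X),
             integral = as.numeric(X %*% ml))
}
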