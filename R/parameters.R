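## Model constants: drained/undrained moduli, Biot coupling, hydraulic
## conductivity, diffusivities, advection switch, reference blood pressure,
## and the per-species solid-cell size weights. Everything is stored in the
## canonical m/day/Pa system.

.default_parameter_units <- list(
  K = "Pa", G = "Pa", Ku = "Pa", alpha = NULL, kappa = "m2.Pa-1.day-1",
  M_biot = "Pa", c0 = "Pa-1", phi = NULL,
  D_cell = "m2.day-1", D_cyto = "m2.day-1", D_H = "m2.day-1",
  b = NULL, p0 = "Pa"
)

#' Construct the mechanical and transport parameter set
#'
#' Defaults are the published sarcoma/tumor constants: drained bulk modulus
#' 40,000 Pa, shear modulus 30,000 Pa, Biot coefficient 0.7, Biot modulus
#' 2e5 Pa, porosity 0.2, hydraulic conductivity 6.9e-14 m^2/(Pa s), and
#' diffusivities 3.6e-8 cm^2/h (cells), 5.2e-5 cm^2/h (cytokines),
#' 3.3e-3 cm^2/h (HMGB1), all converted to m/day/Pa. All arguments are
#' assumed to already be canonical; use [load_parameters()] to convert from
#' declared units.
#'
#' Derived quantities: the storage coefficient defaults to `c0 = 1/M_biot`
#' and the undrained bulk modulus to `Ku = K + alpha^2 * M_biot` (the
#' classical Gassmann-type relation) when not supplied. The reference blood
#' pressure `p0` defaults to 1.2e4 Pa (about 90 mmHg); because the solvers
#' work in excess pressure and both the initial and the boundary pressure
#' equal `p0`, every output is invariant to this choice. Porosity is stored
#' for completeness but enters no governing equation.
#'
#' @param K,G drained bulk and shear modulus, Pa.
#' @param alpha Biot effective stress coefficient, in (0, 1].
#' @param kappa hydraulic conductivity, m^2 Pa^-1 day^-1.
#' @param M_biot Biot modulus, Pa.
#' @param phi porosity (stored, unused by the governing equations).
#' @param D_cell,D_cyto,D_H diffusivities for motile cells, generic
#'   cytokines, and HMGB1, m^2/day.
#' @param b advection coefficient (1 couples motile species to Darcy flow,
#'   0 disables advection).
#' @param p0 reference (blood) pressure, Pa.
#' @param c0 storage coefficient, Pa^-1; default `1/M_biot`.
#' @param Ku undrained bulk modulus, Pa; default `K + alpha^2 * M_biot`.
#' @param A length-4 weights (area per scaled unit) of the solid
#'   constituents Dn, D, C, N in the solid-cell volume.
#' @param reaction_params optional reaction parameter block (see
#'   [synthesize_parameters()]), carried along for scenario runs.
#' @return An object of class `model_parameters`.
#' @examples
#' p <- model_parameters()
#' p$kappa # canonical units, per day
#' @export
model_parameters <- function(K = 40000, G = 30000, alpha = 0.7,
                             kappa = normalize_units(6.9e-14, "m2.Pa-1.s-1"),
                             M_biot = 2e5, phi = 0.2,
                             D_cell = normalize_units(3.6e-8, "cm2.h-1"),
                             D_cyto = normalize_units(5.2e-5, "cm2.h-1"),
                             D_H = normalize_units(3.3e-3, "cm2.h-1"),
                             b = 1, p0 = 1.2e4,
                             c0 = NULL, Ku = NULL,
                             A = c(Dn = 1, D = 1, C = 1, N = 1),
                             reaction_params = NULL) {
  if (is.null(c0)) {
    if (!is.numeric(M_biot) || length(M_biot) != 1L || M_biot <= 0)
      stop("M_biot must be strictly positive to derive c0 = 1/M_biot",
           call. = FALSE)
    c0 <- 1 / M_biot
  }
  if (is.null(Ku)) Ku <- K + alpha^2 * M_biot
  A <- unlist(A)
  if (length(A) != 4L) stop("A must have 4 entries (Dn, D, C, N)", call. = FALSE)
  if (is.null(names(A)) || !all(nzchar(names(A)))) names(A) <- c("Dn", "D", "C", "N")
  p <- structure(list(K = K, G = G, Ku = Ku, alpha = alpha, kappa = kappa,
                      M_biot = M_biot, c0 = c0, phi = phi,
                      D_cell = D_cell, D_cyto = D_cyto, D_H = D_H,
                      b = b, p0 = p0, A = A,
                      reaction_params = reaction_params),
                 class = "model_parameters")
  validate_parameters(p)
  p
}

#' @rdname model_parameters
#' @param p a `model_parameters` object.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "model_parameters"))
  pos <- c("K", "G", "Ku", "M_biot", "kappa", "c0",
           "D_cell", "D_cyto", "D_H")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(nm, " must be a strictly positive number", call. = FALSE)
  }
  if (!is.numeric(p$alpha) || p$alpha <= 0 || p$alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(p$phi) || p$phi < 0 || p$phi >= 1)
    stop("phi must lie in [0, 1)", call. = FALSE)
  if (p$Ku < p$K)
    stop("Ku must be >= K (undrained response cannot be softer than drained)",
         call. = FALSE)
  if (!is.numeric(p$b) || length(p$b) != 1L || !is.finite(p$b))
    stop("b must be a finite number", call. = FALSE)
  if (any(!is.finite(p$A)) || any(p$A <= 0))
    stop("solid-cell size weights A must be positive", call. = FALSE)
  invisible(p)
}

#' Storage coefficient of the pore system
#'
#' Relates pressure change to fluid content at fixed strain. When the
#' configuration does not override it explicitly, `c0 = 1/M_biot`.
#'
#' @param params a `model_parameters` object.
#' @return The storage coefficient in Pa^-1.
#' @export
storage_coefficient <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  params$c0
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Tumor poroelastic model parameters (canonical units: m, day, Pa)\n")
  cat(sprintf("  K = %g Pa, G = %g Pa, Ku = %g Pa, alpha = %g\n",
              x$K, x$G, x$Ku, x$alpha))
  cat(sprintf("  M_biot = %g Pa, c0 = %g 1/Pa, kappa = %g m^2/(Pa day), phi = %g\n",
              x$M_biot, x$c0, x$kappa, x$phi))
  cat(sprintf("  D_cell = %g, D_cyto = %g, D_H = %g m^2/day, b = %g, p0 = %g Pa\n",
              x$D_cell, x$D_cyto, x$D_H, x$b, x$p0))
  cat("  solid-cell weights A:", paste(names(x$A), "=", signif(x$A, 4),
                                       collapse = ", "), "\n")
  if (!is.null(x$reaction_params))
    cat("  reaction parameters: set", format(attr(x$reaction_params, "cluster_id")), "\n")
  invisible(x)
}

# read a scalar that may be declared as {value:, unit:}
.read_quantity <- function(entry, key) {
  if (is.list(entry)) {
    if (is.null(entry$value)) stop("entry '", key, "' lacks a value", call. = FALSE)
    v <- as.numeric(entry$value)
    if (!is.null(entry$unit)) v <- normalize_units(v, entry$unit)
    v
  } else {
    as.numeric(entry)
  }
}

#' Load and validate a model configuration
#'
#' Reads a YAML document with sections `mechanics`, `transport`, `species`,
#' `reactions` and `scenario`. Each numeric entry is either a bare number
#' (assumed canonical m/day/Pa) or a `{value: , unit: }` pair converted via
#' [normalize_units()]. Keys that are absent fall back to the packaged
#' defaults; unknown keys raise a warning; invalid values raise an error.
#'
#' The packaged file `system.file("extdata", "published_defaults.yaml",
#' package = "poroTME")` spells out the default constants with their
#' original published units.
#'
#' @param file path to a YAML configuration file.
#' @param text YAML text (alternative to `file`).
#' @return A validated `model_parameters` object; the raw `scenario` and
#'   `reactions` sections, when present, are attached as attributes
#'   `scenario` and `reactions_config`.
#' @export
load_parameters <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop("provide exactly one of 'file' or 'text'", call. = FALSE)
  doc <- if (!is.null(file)) yaml::read_yaml(file) else yaml::yaml.load(text)
  if (is.null(doc)) doc <- list()
  known_sections <- c("mechanics", "transport", "species", "reactions", "scenario")
  unknown <- setdiff(names(doc), known_sections)
  if (length(unknown))
    warning("ignoring unknown configuration section(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)

  mech <- doc$mechanics %||% list()
  tran <- doc$transport %||% list()
  spec <- doc$species %||% list()

  mech_keys <- c("K", "G", "alpha", "kappa", "M_biot", "phi", "p0", "c0", "Ku")
  tran_keys <- c("D_cell", "D_cyto", "D_H", "b")
  unknown <- c(setdiff(names(mech), mech_keys), setdiff(names(tran), tran_keys),
               setdiff(names(spec), c("A")))
  if (length(unknown))
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)

  args <- list()
  for (k in mech_keys)
    if (!is.null(mech[[k]])) args[[k]] <- .read_quantity(mech[[k]], k)
  for (k in tran_keys)
    if (!is.null(tran[[k]])) args[[k]] <- .read_quantity(tran[[k]], k)
  if (!is.null(spec$A)) args$A <- vapply(spec$A, as.numeric, numeric(1))

  p <- do.call(model_parameters, args)
  if (!is.null(doc$scenario)) attr(p, "scenario") <- doc$scenario
  if (!is.null(doc$reactions)) attr(p, "reactions_config") <- doc$reactions
  p
}

#' Serialize model parameters to YAML text
#'
#' Values are written in canonical units with 17 significant digits so that
#' a serialize/load round trip reproduces the numbers bit for bit.
#'
#' @param p a `model_parameters` object.
#' @param file optional path; when given the text is also written there.
#' @return The YAML text, invisibly when `file` is given.
#' @export
write_parameters <- function(p, file = NULL) {
  validate_parameters(p)
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "mechanics:",
    sprintf("  %s: %s", c("K", "G", "alpha", "kappa", "M_biot", "phi", "p0",
                          "c0", "Ku"),
            num(c(p$K, p$G, p$alpha, p$kappa, p$M_biot, p$phi, p$p0,
                  p$c0, p$Ku))),
    "transport:",
    sprintf("  %s: %s", c("D_cell", "D_cyto", "D_H", "b"),
            num(c(p$D_cell, p$D_cyto, p$D_H, p$b))),
    "species:",
    "  A:",
    sprintf("    %s: %s", names(p$A), num(unname(p$A))))
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
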