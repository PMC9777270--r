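## Unit handling: every quantity is converted once, at load time, to the
## canonical meter / day / Pascal system. The biology evolves over hundreds
## of days while published mechanical constants mix seconds and hours, so a
## single canonical system avoids scattering conversion factors through the
## solvers.

# conversion factor of one atomic unit token into the canonical system
.unit_atoms <- list(
  m    = list(dim = "length",   factor = 1),
  cm   = list(dim = "length",   factor = 1e-2),
  mm   = list(dim = "length",   factor = 1e-3),
  um   = list(dim = "length",   factor = 1e-6),
  day  = list(dim = "time",     factor = 1),
  h    = list(dim = "time",     factor = 1 / 24),
  min  = list(dim = "time",     factor = 1 / 1440),
  s    = list(dim = "time",     factor = 1 / 86400),
  Pa   = list(dim = "pressure", factor = 1),
  kPa  = list(dim = "pressure", factor = 1e3),
  MPa  = list(dim = "pressure", factor = 1e6),
  mmHg = list(dim = "pressure", factor = 101325 / 760)
)

# parse "cm2.h-1" / "m2 Pa-1 s-1" into atoms and exponents
.parse_unit <- function(unit) {
  tokens <- strsplit(trimws(unit), "[.·* ]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty unit tag", call. = FALSE)
  m <- regmatches(tokens, regexec("^([A-Za-z]+)(-?[0-9]+)?$", tokens))
  lapply(seq_along(tokens), function(i) {
    g <- m[[i]]
    if (length(g) == 0L || !nzchar(g[2]))
      stop("unsupported unit token: '", tokens[i], "'", call. = FALSE)
    name <- g[2]
    if (is.null(.unit_atoms[[name]]))
      stop("unsupported unit '", name, "' in tag '", unit, "'", call. = FALSE)
    exp <- if (nzchar(g[3])) as.integer(g[3]) else 1L
    list(name = name, exp = exp)
  })
}

#' Convert a quantity with a declared unit to canonical units (m, day, Pa)
#'
#' Supported atoms are lengths (`m`, `cm`, `mm`, `um`), times (`s`, `min`,
#' `h`, `day`) and pressures (`Pa`, `kPa`, `MPa`, `mmHg`), combined with
#' integer exponents and separated by `.`, a centered dot, `*` or a space,
#' e.g. `"m2.Pa-1.s-1"` or `"cm2.h-1"`. Conversion is a single product of
#' the atomic factors, so normalizing an already-canonical quantity is the
#' identity.
#'
#' @param value numeric value(s) in the declared unit.
#' @param unit unit tag, e.g. `"cm2.h-1"`.
#' @return The value(s) expressed in the m/day/Pa system.
#' @examples
#' normalize_units(6.9e-14, "m2.Pa-1.s-1") # hydraulic conductivity per day
#' normalize_units(3.6e-8, "cm2.h-1")      # cell diffusivity in m^2/day
#' @export
normalize_units <- function(value, unit) {
  atoms <- .parse_unit(unit)
  factor <- 1
  for (a in atoms) factor <- factor * .unit_atoms[[a$name]]$factor^a$exp
  value * factor
}

#' @describeIn normalize_units the canonical spelling of a unit tag after
#'   normalization (e.g. `"cm2.h-1"` becomes `"m2.day-1"`).
#' @export
canonical_unit <- function(unit) {
  atoms <- .parse_unit(unit)
  canon <- c(length = "m", time = "day", pressure = "Pa")
  out <- vapply(atoms, function(a) {
    base <- canon[[.unit_atoms[[a$name]]$dim]]
    if (a$exp == 1L) base else paste0(base, a$exp)
  }, character(1))
  paste(out, collapse = ".")
}
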