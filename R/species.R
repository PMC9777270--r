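#' Catalog of the 14 tumor-microenvironment species
#'
#' The state vector of the model tracks 14 interacting populations of the
#' osteosarcoma tumor microenvironment: naive and activated macrophages
#' (`Mn`, `M`), naive T cells (`Tn`), helper/regulatory/cytotoxic T cells
#' (`Th`, `Tr`, `Tc`), naive and activated dendritic cells (`Dn`, `D`),
#' cancer cells (`C`), necrotic cells (`N`), and four cytokine pools:
#' IFN-gamma (`Ig`), the TGF-beta/IL-4/IL-10/IL-13 pool (`mu1`), the
#' IL-6/IL-17 pool (`mu2`), and HMGB1 (`H`).
#'
#' Each concentration is non-dimensionalized by its steady-state abundance
#' (the `scaling` column, group-1 values), so the homeostatic state of the
#' scaled system is the all-ones vector.
#'
#' Naive macrophages and naive T cells activate outside the tumor and are
#' modelled as well-mixed pools without spatial transport; necrotic cells are
#' immobile debris produced locally. All three carry `motile = FALSE`.
#' The solid skeleton of the tumor is built from the dendritic, cancer and
#' necrotic populations (`solid = TRUE`, indices 7--10); their weighted sum
#' is the solid-cell volume that drives the mechanics.
#'
#' @return A data frame with one row per species and columns
#'   `index`, `symbol`, `role` (`"cell"` or `"cytokine"`), `scaling`,
#'   `motile`, `solid`, and `diffusion` (which of the diffusion coefficients
#'   applies: `"cell"`, `"cyto"`, `"H"` or `"none"`).
#' @examples
#' species_catalog()
#' @export
species_catalog <- function() {
  df <- data.frame(
    index = 1:14,
    symbol = c("Mn", "M", "Tn", "Th", "Tr", "Tc", "Dn", "D", "C", "N",
               "Ig", "mu1", "mu2", "H"),
    role = c(rep("cell", 10), rep("cytokine", 4)),
    scaling = c(6.236e6, 1.977e7, 4.926e6, 7.092e6, 3.675e6, 2.292e7,
                4.826e5, 9.865e5, 1.343e10, 3.764e8,
                0.868, 21.510, 2.067, 5.076),
    motile = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
               TRUE, TRUE, TRUE, TRUE),
    solid = c(rep(FALSE, 6), rep(TRUE, 4), rep(FALSE, 4)),
    stringsAsFactors = FALSE
  )
  df$diffusion <- ifelse(!df$motile, "none",
                  ifelse(df$role == "cell", "cell",
                  ifelse(df$symbol == "H", "H", "cyto")))
  df
}

#' Indices of the solid-constituent species
#'
#' Dendritic, cancer and necrotic cells form the solid phase of the tumor.
#' @return Integer vector `c(7, 8, 9, 10)` (Dn, D, C, N).
#' @export
solid_species <- function() 7:10

#' Indices of the immune cell types eligible for boundary influx
#'
#' Macrophages, the three effector T-cell types and naive dendritic cells
#' exchange with blood and lymph across the tumor boundary; only these may
#' carry a Robin influx condition in the standard scenarios.
#' @return Integer vector of species indices (M, Th, Tr, Tc, Dn).
#' @export
immune_influx_species <- function() c(2L, 4L, 5L, 6L, 7L)
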