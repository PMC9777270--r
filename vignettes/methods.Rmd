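---
title: "A poroelastic multiphase model of the osteosarcoma tumor microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A poroelastic multiphase model of the osteosarcoma tumor microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poroTME)
```

## The model

poroTME simulates an osteosarcoma tumor as a two-phase poroelastic
continuum inhabited by fourteen interacting populations: naive and
activated macrophages ($M_n$, $M$), naive T cells ($T_n$), helper,
regulatory and cytotoxic T cells ($T_h$, $T_r$, $T_c$), naive and mature
dendritic cells ($D_n$, $D$), cancer cells ($C$), necrotic cells ($N$),
and four cytokine pools (IFN-$\gamma$; the TGF-$\beta$/IL-4/IL-10/IL-13
pool $\mu_1$; the IL-6/IL-17 pool $\mu_2$; HMGB1, $H$). Every
concentration $[X_i]$ is scaled by its steady-state abundance
(`species_catalog()`), so the homeostatic state of the scaled system is
the all-ones vector.

**Biology.** Each species obeys a reaction–diffusion–advection equation
on the tumor disk $\Omega$,
$$\partial_t [X_i] - D_i \Delta [X_i] + b\,\nabla\!\cdot\!([X_i]\,\kappa \nabla p) = f_i([X]),$$
with $D_i \in \{0, D_{\mathrm{cell}}, D_{\mathrm{cyto}}, D_H\}$.
Naive pools activate outside the microenvironment and necrotic cells are
immobile debris, so $M_n$, $T_n$ and $N$ carry no transport (they reduce
to per-node relaxation laws). The interaction terms $f_i$ encode the
immune network: cytokine-mediated activation of macrophages; priming of
helper, regulatory and cytotoxic T cells from the naive pool by
macrophages, dendritic cells and $\mu_2$ (cytotoxic cells are primed by
dendritic and helper cells); dendritic-cell maturation driven by cancer
cells and HMGB1; logistic cancer growth stimulated by the IL-6 pool and
killing by cytotoxic cells and IFN-$\gamma$; conversion of killed cancer
cells into necrotic debris; and production/decay balances for the four
cytokine pools. All removal terms are proportional to the species being
removed, so the vector field cannot push a nonnegative state negative.

**Mechanics.** The solid skeleton of the tumor is built from the
dendritic, cancer and necrotic populations. Their weighted sum
$V = \sum_{i=7}^{10} A_{X_i} [X_i]$ acts as an isotropic growth
eigenstress in a quasi-static Biot system for the displacement $u$ and
pore pressure $p$:
$$-\left(K - \tfrac{2G}{3}\right)\nabla(\nabla\!\cdot\!u) - G\,\Delta u
  + \alpha \nabla p + K \nabla V^\ast = 0, \qquad
  \partial_t\!\left(c_0 p + \alpha \nabla\!\cdot\!u\right) = \kappa \Delta p,$$
with $V^\ast = V - V(0)$ so that the undeformed initial state is
compatible. Darcy's law $q = -\kappa \nabla p$ closes the loop back to
the biology through the advection term. Note the elastic operator is the
grad–grad form (the momentum equation carries $-G\Delta u$, not the
divergence of the symmetric stress); all closed-form verification targets
in the test suite are derived for this operator, e.g. the confined 1-D
modulus is $K_v = K + G/3$ and a uniform eigenstress $v^\ast$ dilates the
free disk by $c = K v^\ast / (2(K - 2G/3) + G)$.

**Boundary and initial conditions.** The disk boundary is traction-free
for the *total* stress (the tumor grows unhindered), the pore pressure is
pinned to the reference blood pressure $p_0$, and the initial state is
undeformed with $p = p_0$. Species use either no-flux conditions or, for
the five immune cell types that exchange with blood and lymph, a Robin
influx law $\partial_n [X_i] + \alpha_i([X_i] - \hat X_i) = 0$. Because a
pure-traction elastic problem leaves translations and the in-plane
rotation undetermined, the three rigid-body modes are excluded by
Lagrange-multiplier constraints paired against the domain functionals
$(u, z_i)$, $z_i \in \{(1,0), (0,1), (-y, x)\}$; the disk mesh is
centered at the origin so the rotation mode needs no offset.

## Parameters

`model_parameters()` stores everything in a single canonical unit system
(meters, days, Pascals); the biology evolves over roughly a thousand days
while published mechanical constants mix seconds and hours, so conversion
happens exactly once, at load time (`normalize_units()`, exact factor
arithmetic). Defaults are the published sarcoma/tumor constants:

| quantity | default | unit | note |
|---|---|---|---|
| $K$, $G$ | 40 000, 30 000 | Pa | sarcoma bulk/shear moduli |
| $\alpha$ | 0.7 | – | Biot effective stress coefficient |
| $M$ (Biot) | $2\times 10^5$ | Pa | generic-tumor estimate |
| $\kappa$ | $6.9\times 10^{-14}$ | m² Pa⁻¹ s⁻¹ | converts to $5.96\times10^{-9}$ per day |
| $D_\mathrm{cell}$ | $3.6\times10^{-8}$ | cm² h⁻¹ | $8.64\times10^{-11}$ m²/day |
| $D_\mathrm{cyto}$ | $5.2\times10^{-5}$ | cm² h⁻¹ | cytokines |
| $D_H$ | $3.3\times10^{-3}$ | cm² h⁻¹ | HMGB1 |
| $b$ | 1 | – | advection switch |
| $d_0$ | 0.01 | m | initial tumor diameter |

Derived and free quantities were fixed as follows, once:

* **Storage coefficient** $c_0 = 1/M$ (the standard poroelastic storage
  relation at fixed strain); configurable.
* **Undrained modulus** $K_u = K + \alpha^2 M$ (Gassmann-type identity)
  when not supplied; only the $(u, p)$ formulation is solved, so $K_u$ is
  informational.
* **Reference blood pressure** $p_0 = 1.2\times10^4$ Pa (about 90 mmHg).
  The solvers work in excess pressure $p - p_0$, which is zero initially
  and on the boundary, so every output is provably invariant to this
  choice — a property the test suite asserts by doubling $p_0$.
* **Porosity** $\phi = 0.2$ is stored and exposed but enters no governing
  equation of the $(u,p)$ formulation; it is kept for completeness.
* **Solid-cell size weights** $A_{X_i} = 1$ per scaled unit for all four
  solid constituents. No published values exist for these weights; only
  volume *ratios* $V/V_0$ are reported downstream, and those are
  invariant to the common scale of $A$.

## The synthetic interaction network

The fitted rate constants of the companion compartment model (three
patient clusters estimated from tumor gene-expression profiles) are not
distributed with this package, and neither are the cluster initial
conditions; `cluster_parameters()` documents the entry point where a
transcribed set can be dropped in. So that every downstream component is
testable without external data, `synthesize_parameters(seed)` generates
*synthetic, steady-state-calibrated* parameter sets:

1. activation/production rates are drawn log-uniformly over
   $10^{-1.5}$–$10^{-0.3}$ day⁻¹ (immune kinetics on day-to-week
   timescales); the scaled cancer carrying capacity is $C_0 = 2$;
2. per-species balances pin the remaining decay/supply rates so the
   all-ones state is an *exact* equilibrium (residual $< 10^{-10}$);
3. a draw is accepted only if the equilibrium is Hurwitz-stable, if
   trajectories started 10 % above and below the unit state return to it
   within 0.1 % by 3000 days, and if the network reproduces the
   documented pharmacology of the fitted model at the level of
   steady-state sensitivities $-J^{-1}e_i$: a sustained macrophage supply
   must raise the solid-cell volume (macrophages are net tumor-promoting,
   through the IL-6 pool and suppression of cytotoxic activity), and a
   sustained cytotoxic-cell supply must lower the cancer level.

What the synthetic sets emulate: the network topology, the sign structure
of every interaction, the nondimensional steady state, and realistic
relaxation timescales. What they do **not** emulate: the fitted magnitudes
— in particular the strong growth transient of a diagnosed tumor (the
fitted group-1 trajectory multiplies its volume ~34-fold over 1000 days,
whereas a synthetic run perturbed 10 % from homeostasis relaxes back to
it). Passing tests therefore demonstrate correctness of the machinery and
the qualitative immunology, not quantitative agreement with patient data;
the reported group-1 growth table is bundled
(`reference_growth_table()`) and drives the diameter-estimation checks
directly.

## The advective coupling, and why its default is inert

The species advection term is written against the Darcy flow,
$b\,\nabla\!\cdot\!([X]\kappa\nabla p)$. Discretely this can be read two
ways, and the package implements both (`transport_operator(advection=)`):

* **`"laplacian"` (default)** — the term $(b[X]\kappa\Delta_h p, \Xi)$
  evaluated with the discrete pressure. With the linear pressure elements
  used here, the elementwise Laplacian vanishes identically, so the term
  contributes nothing. This is exactly what the discretized species
  scheme of the published method produces, and it is the only reading
  under which the uniform reference case coincides *node-for-node* with
  the 0-D compartment reduction — the validation this package, like the
  original study, relies on.
* **`"conservative"`** — the mass-conserving weak form
  $-([X] v_f, \nabla\Xi)$ with $v_f = -\kappa\nabla p$ constant per
  element. The discrete column sums of the advection operator vanish, so
  the lumped total mass is conserved to round-off for *any* velocity
  field (asserted per-step in the tests).

These are not numerically interchangeable. In a growing tumor the
pressure field satisfies $\kappa\Delta p \approx c_0\dot p + 2\alpha\dot
c$ (with $c$ the dilation rate), so the conservative form adds a spatially
uniform compression term $\dot{[X]}/[X] \approx 2\alpha \dot c$ that
integrates to $\approx 2\alpha\,\Delta c$ over a growth transient — tens
of percent for the deformations simulated here. Under the conservative
form the reference case would therefore *not* match the compartment
reduction, contradicting the model's own validation; under the inert
default it matches to solver round-off. The choice is recorded here
rather than silently made; users exploring the conservative physics
should compare against the reference case themselves.

A related reading note: with the Robin influx condition written on the
normal derivative, its weak-form flux is necessarily scaled by the
species diffusivity, $D_i \alpha_i([X_i]-\hat X_i)$. With the published
diffusivities and $\alpha_i = 100$ m⁻¹ the implied exchange velocity
($\sim 10^{-8}$ m/day) is negligible on a centimeter-scale tumor;
quantitatively effective influx requires $\alpha_i$ several orders larger
(the Dirichlet-limit test uses $10^7$–$10^9$ m⁻¹). The published
scenario value $\alpha_i = 100$ is only meaningful if the flux is *not*
diffusivity-scaled; both readings cannot be reconciled from the printed
equations, and the package follows the normal-derivative form.

## Discretization and numerics

* **Elements.** Quadratic Lagrange displacements, linear pressure — an
  inf-sup stable pair that avoids spurious pressure modes. Species use
  linear elements with a lumped mass matrix.
* **Meshes.** The disk is triangulated in concentric rings (ring $i$
  carries $6i$ vertices, $6\,\mathrm{rings}^2$ triangles), exactly
  symmetric under the hexagonal rotation group; default 18 rings
  ($1944$ triangles, area within 0.5 % of the disk). Structured rectangle
  meshes serve the consolidation and manufactured-solution benchmarks.
* **Time stepping.** Backward Euler for both subsystems, default
  $k = 0.5$ day; the coupled loop is staggered per step: build $V^\ast$
  from the current species, solve the mechanics, evaluate the Darcy
  velocity, then advance the biology (each species sees already-updated
  earlier species, a Gauss–Seidel sweep in catalog order).
* **Reactions** are semi-implicit: removal terms (all proportional to the
  species removed) are implicit, productions explicit; together with mass
  lumping this preserves nonnegativity. Tiny negative round-off values
  are clipped to zero and counted; values beyond $-10^{-8}$ warn, and a
  field exceeding $10^6$ aborts as a blow-up.
* **Linear algebra.** The saddle system (elasticity, pressure-gradient
  and divergence couplings, storage, three Lagrange rows) is assembled
  sparse and factorized once per operator; rows and columns are
  diagonally equilibrated first, since moduli of $10^4$ Pa against
  element areas of $10^{-8}$ m² otherwise produce raw condition numbers
  near $10^{24}$. Each solve checks the scaled residual
  ($< 10^{-10}$) and the rigid-mode functionals of the solution.
* **Eigenstress load.** $(K\nabla V^\ast, v)$ is integrated by parts to
  $-(K V^\ast, \nabla\!\cdot\!v)$ with zero *total* traction as the
  natural boundary condition — the eigenstress reading of the
  constitutive law. Retaining the boundary flux term instead would cancel
  the load identically for uniform $V^\ast$ (divergence theorem) and no
  uniform growth could occur; a strong-form $\partial_n u = 0$ clamp is
  not variationally well-defined for this operator and is not offered.
* **Degenerate inputs.** Inverted triangles are rejected at mesh build
  and by `warp_mesh()`; the scenario loop records the simulated diameter
  as `NA` (with a warning) if the reporting-only warp degenerates;
  Dirichlet rows are imposed by row replacement.

**Verification targets** (all in the test suite): uniform-eigenstress
dilation against the closed form above (exact to round-off, since the
linear dilation lies in the quadratic element space); one-dimensional
consolidation against the classical series with
$c_v = \kappa/(c_0 + \alpha^2/K_v)$ (within $10^{-4}$ at the tested
times); manufactured-solution convergence at measured orders $\approx 2$
for $u$ and $\approx 2$ for $p$ in $L^2$ (the pressure coupling limits
$u$ below the pure-elasticity order 3); the first Dirichlet disk
eigenmode decaying at $D (j_{0,1}/R)^2$ within 1 %; and the PDE–ODE
equivalence of the uniform reference case at relative $10^{-4}$ with
spatial spread below $10^{-10}$.

## Scenarios

Named scenarios perturb the homeostatic base state: a smooth radial
initial elevation of $M$ and $T_c$ (11-fold at the center, realized as
$1 + 10(1 - (r/R)^2)$ — the profile shape is unspecified in the source
material, only its endpoints); Robin influx on the five immune cell
types ($\alpha_i = 100$, $\alpha_i\hat X_i = 1$); and constant sources of
$M$ or $T_c$ in the concentric half-radius disk ("center") or the
outermost element band ("boundary") — the two regions are likewise
package choices where the source gives none. Source magnitudes default to
$s = \mathrm{fold} \times d_i$, with $d_i$ the sourced species' removal
rate at the unit state and fold the reported steady elevation (2.0 for a
central macrophage source, 1.33 boundary; 0.6 and 0.33 for cytotoxic
sources), so the local balance $[X] \approx 1 + s/d_i$ lands near the
reported levels. The fields are always solved on the fixed reference
disk (small-displacement regime); warping by $u$ is for size and shape
reporting only, which is also how the simulated-diameter column of the
growth table is defined.

## Tumor size estimation

Three estimates are reported per output time: the crude area law
$d = d_0\sqrt{n}$ for a volume ratio $n = V/V_0$; the colony-count
regression $N_{\mathrm{cells}} = 2.40\, d_{\mathrm{colony}}^{2.378} /
d_{\mathrm{cell}}^{2.804}$ inverted in closed form (ratio form
$d/d_0 = n^{1/2.378}$); and the diameter of the warped mesh. The
published regression exponent implies $d \propto n^{0.42}$, while the
reported regression-estimate column follows $d \propto n^{0.56}$; the
two cannot be reconciled from the printed relation alone (the cell
diameter and the 2-D/3-D count conversion used are not fully specified),
so `linear_model_diameter()` exposes both a `published` mode and a
`table-fit` mode (log–log least squares against the bundled table) and
the discrepancy is left visible.

## Problem sizes used by the checks

The automated checks run at sizes chosen to keep the full suite at desk
scale while leaving each oracle's error far from its tolerance: the
PDE–ODE equivalence on 18 rings (1944 triangles) over 200 days at
$k = 0.5$; qualitative source-placement orderings on 10 rings over 120
days; consolidation on a $3 \times 30$ strip at $\Delta T_v =
2.5\times10^{-4}$; convergence studies on $6/12/24$-cell squares; the
long-time steady-state check to $t = 5000$ days in the 0-D reduction.

## Known limitations

Two-dimensional geometry only; fixed reference domain (no moving-mesh or
finite-strain mechanics); no chemotaxis, haptotaxis or angiogenesis; the
fitted patient-cluster rates and initial conditions are not bundled, so
quantitative growth-curve reproduction is out of reach of the shipped
data; porosity is carried but unused; and the advective coupling is inert
under the default (published) discretization, as discussed above.
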