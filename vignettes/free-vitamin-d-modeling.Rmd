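---
title: "Modeling free vitamin D metabolites and monocyte cathelicidin induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling free vitamin D metabolites and monocyte cathelicidin induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdfree)
```

## The problem

Vitamin D status is judged from total serum 25-hydroxyvitamin D (25OHD), but
nearly all circulating 25OHD and 1,25-dihydroxyvitamin D (1,25(OH)2D) is
carried by the vitamin D binding protein (DBP, the *GC* gene product) and, at
lower affinity, by albumin. Under the free hormone hypothesis only the
unbound fraction crosses cell membranes and acts on target cells such as
monocytes. DBP circulates as three common allele products (GC1F, GC1S, GC2)
that differ in both affinity and plasma level, so two subjects with the same
total 25OHD can have very different free levels. `vitdfree` implements two
coupled steady-state models that quantify this:

* an **extracellular equilibrium model** for free 25OHD and 1,25(OH)2D given
  totals, the binder set and a DBP genotype, and
* an **intracellular model** that converts free extracellular levels into a
  normalized induction score for the cathelicidin antimicrobial peptide
  (CAMP) gene in monocytes.

## The extracellular equilibrium

With ligands $v_i$ ($i = 1$: 25OHD, $i = 2$: 1,25(OH)2D) and binders $b_j$
(DBP species and albumin), mass balance at binding equilibrium requires, for
each ligand,

$$V_i = v_i\left(1 + \sum_j \frac{B_j}{K_{ij}\,\bigl(1 + \sum_l v_l/K_{lj}\bigr)}\right),$$

where $V_i$, $B_j$ are totals, $K_{ij}$ dissociation constants, and the
inner sum is the competitive occupancy of binder $j$ by both ligands.
`solve_ess()` solves this coupled nonlinear system; the solution is unique
and each free level is bracketed by $[0, V_i]$.

All internal concentrations are micromolar. Source tables mix units
(association constants in 1/M; levels in uM, nM, pM), so configuration
parsing is strict: every value carries a unit tag and association constants
are inverted on load (`parse_affinity()`, `ka_to_kd_uM()`).

At the standard full-serum condition (5 uM genotype-averaged DBP with
association constants 7e8 and 4e7 /M; 650 uM albumin with 6e5 and 5.4e4 /M;
50 nM total 25OHD, 0.1 nM total 1,25(OH)2D) the model leaves well under
0.1% of 25OHD and about 0.4% of 1,25(OH)2D free:

```{r ess-example}
serum <- serum_context(list(mixed_dbp_binder(), albumin_binder()))
sol <- solve_ess(ligand_totals(50, 0.1, unit = "nM"), serum)
free_fraction(sol)
```

## Genotype calibration

Per-allele DBP affinities and plasma concentrations are literature
quantities of varying provenance, and only the dimensionless *binding
product* $P_g = B_g/K_g$ per genotype is identifiable from free/total
measurements. `calibrate_genotype_products()` therefore anchors each
genotype to the shipped reference table of free 25OHD (per genotype at 25,
50 and 100 nM total, full serum) via

$$P_g = \frac{V_1}{v_1} - 1 - \frac{B_{alb}}{K_{1,alb}},$$

using the 50 nM column by default, with a closed-form correction for the
(sub-printed-precision) competitive occupancy of albumin so that re-solving
the full model at the anchor reproduces the reference values exactly. The
calibrated genotype enters the solver as a *linear* (non-saturable) species:
binder saturation at physiological free levels is below 1%, under the
printed precision of the reference values, and the linear form keeps the
calibration an exact inverse of the solver. A reference-derived per-allele
default file ships for exploratory use (`default_gc_alleles()`,
`genotype_binders()`), clearly marked as overridable; quantitative claims
go through the calibration route only.

For the 1,25(OH)2D side only the in vivo range of free percentages
(0.4–1.3% at 100 pM total) is available. The package assigns the endpoints
to the extreme-affinity genotypes (GC1F/1F low, GC2/2 high) and
interpolates the free *percentage* of intermediate genotypes linearly in
their 25OHD product $P_g$. Among the simple schemes we examined
(interpolating the product itself, logarithmic and rank interpolation),
percentage-linear interpolation agrees best with the reference CAMP grids;
one activated middle-genotype prediction (GC1S/2 at 100 nM) still differs
from its reference value by 0.009 on the normalized CAMP scale — within
about twice the printed rounding step, and traceable to this unidentified
endocrine input. `reproduce_table("camp-status")` reports the comparison
cell by cell.

## The intracellular model

Free extracellular levels $v_1^o, v_2^o$ feed a monocyte with permeability
$d$ (per hr) to both metabolites. Intracellular free 25OHD $v_1^c$ balances
diffusion against CYP27B1 conversion (Michaelis–Menten, capacity
$v_{max} = k_{cat} Y_T$, constant $K_m$):

$$d\,(v_1^o - v_1^c) = \frac{v_{max}\,v_1^c}{K_m + v_1^c},$$

solved in closed form as the positive quadratic root (`solve_v1c()`).
Intracellular 1,25(OH)2D adds the endocrine and intracrine routes:

$$v_2^c = v_2^o + \frac{v_{max}}{d}\,\frac{v_1^c}{K_m + v_1^c}.$$

Both metabolites then compete for the VDR with cooperativity ($u_1 =
(v_1^c/K_{r1})^{mm}$, $u_2 = (v_2^c/K_{r2})^{pp}$; $r_i = R_T\,u_i/(1 + u_1
+ u_2)$), and the liganded complexes compete for the CAMP promoter VDRE
($w_1 = (r_1/K_{cc1})^m$, $w_2 = (r_2/K_{cc2})^p$; $o_i = w_i/(1 + w_1 +
w_2)$). The output is $\mathrm{CAMP} = \eta\,(o_1 + o_2) + \mathrm{CAMP}_0$,
bounded in $[\mathrm{CAMP}_0,\ \mathrm{CAMP}_0 + \eta]$. The VDR
denominators use the receptor-in-excess competitive form; at the occupancies
reached in all modeled scenarios ($r_1 + r_2 \ll R_T$ holds by
construction) a receptor-depleting variant is numerically indistinguishable,
which is why the reference-grid reproduction is used as the guard on the
functional form. The $o_1$ (25OHD-driven) term is retained even though it
is negligible in every scenario here.

### Parameters

Monocyte defaults of `cell_params()` (uM, hr):

| parameter | default | meaning |
|---|---|---|
| `d` | 6 /hr | membrane permeability to both metabolites |
| `K_m` | 1 uM | CYP27B1 Michaelis constant for 25OHD |
| `v_max` | 0.1 uM/hr | basal CYP27B1 capacity $k_{cat} Y_T$ |
| `R_T` | 1.2e-3 uM | total VDR (3000 copies, 10 um-radius sphere) |
| `K_r1`, `K_r2` | 5e-2, 1e-4 uM | VDR constants for 25OHD / 1,25(OH)2D |
| `K_cc1`, `K_cc2` | 1e-3, 1e-4 uM | complex–VDRE constants |
| `mm`, `pp`, `m`, `p` | 1, 2, 2, 2 | cooperativity exponents |
| `eta`, `camp0` | 1, 0.010 | normalized maximal and basal CAMP |

Only the product $v_{max} = k_{cat} Y_T$ enters the equations, so the
capacity is the single stored operative parameter; `k_cat` and `Y_T` can be
supplied for provenance and are otherwise left unset. The basal CAMP level
`camp0` is a parameter of the output map, fixed at 0.010 to match the
uniform basal level of the reference predictions. `R_T` derives from a
receptor count via `vdr_concentration_from_count()` (3000 molecules in a
10 um-radius sphere give 1.2 nM).

Immune activation is an expression effect only: `activated_state()`
multiplies `R_T` by 5 and `v_max` by 10, leaving every affinity unchanged.

```{r iss-example}
sc <- scenario_context(100, 0.1, genotype = "GC2/2",
                       activation = activated_state())
predict_camp(sc)
```

## Numerical choices

* **Equilibrium solver.** Damped fixed-point iteration from the
  fully-unsaturated guess, polished by Newton steps on the full system
  (analytic Jacobian), with bracketed per-ligand bisection as a fallback;
  default tolerance 1e-12 uM on the worst mass-balance defect. A
  non-convergent solve raises an error carrying the last residual.
* **Intracellular root.** Closed-form stable quadratic root; no iteration.
* **Kinetic oracle.** `ode_oracle()` validates both solvers by integrating
  the mass-action network (deSolve::lsoda, rtol 1e-10, atol 1e-16) over
  doubling horizons until the relative rate of change per unit time is
  below 1e-10 for every species. Individual rate constants are irrelevant
  at steady state, so the oracle uses $k^+ = 1$, $k^- = K_{ij}$; the
  enzyme pair uses $k_{on} = 2 k_{cat}/K_m$, $k_{off} = k_{cat}$ so its
  Michaelis constant matches the algebraic model.
* **Degenerate inputs.** No binders (or all-zero concentrations) return
  the totals as free; zero totals give zero free levels; free fractions of
  a zero total raise an undefined-fraction error rather than NaN.
* **Reporting.** Table reproduction rounds free 25OHD to 0.001 nM and CAMP
  to 0.001, the precision of the reference grids, and compares at ±0.001 nM
  and ±0.005 respectively (the latter absorbs calibration rounding).

## Synthetic dose–response data

`generate_dose_response()` produces in vitro-style dose–response sets from
known parameters: the full eSS+iSS chain is evaluated at each dose
(defaults: 1,25(OH)2D 0.1–6 nM or 25OHD 1–300 nM, GC1F/1F at 5% serum,
basal activation — the adherent-monocyte culture setting) and Gaussian
noise is added on the normalized response scale, with per-dose standard
deviations from a shipped fixture (0.02–0.08, a realistic spread for
qPCR-derived fold changes). Output is a pure function of the specification
and seed.

The generator emulates per-point measurement noise only. It does not
emulate donor-to-donor variability, qPCR technical-replicate structure,
metabolite degradation over the incubation, or any CYP24A1-mediated
catabolism, so parameter-recovery results bound estimator behaviour under
the model's own assumptions, not under every feature of real data.

## Staged fitting and identifiability

Fitting follows the staged recipe used for adapting the monocyte model to
other cell types: first the 1,25(OH)2D pathway (the mechanistically direct
route) on a 1,25(OH)2D dose–response (`fit_stage_125d()`: any of `K_r2`,
`K_cc2`, `pp`, `R_T` free), then the 25OHD side (`fit_stage_25ohd()`:
the capacity `v_max` only). The loss is weighted least squares (weights
$1/\mathrm{sd}^2$), minimized by L-BFGS-B on log10 parameters from the
documented starting point (the monocyte defaults) inside a ±3-decade box;
the integer exponent `pp` is searched over the grid {1, 2, 3} with a
continuous refit per grid point. Fits that end on a box bound are flagged
as non-converged. Lower 1,25(OH)2D sensitivity of a cell line expresses
itself as a larger fitted `K_r2`, and raising the CYP27B1 capacity is the
single identifiable 25OHD-side adjustment.

Three identifiability facts matter:

* `k_cat` and `Y_T` enter only through their product; the capacity is the
  fitted quantity.
* When the dosed metabolite is the only VDR ligand, `R_T` and `K_cc2`
  enter the curve only through $R_T/K_{cc2}$ and must not both be freed.
* The pair (`K_r2`, `K_cc2`) is structurally near-degenerate on a
  single-curve design: with $pp = p = 2$, VDRE-level saturation reproduces
  almost exactly the Hill-4 rise and plateau of VDR-level saturation, so
  under realistic noise the joint estimate wanders a flat ridge even
  though the noiseless joint fit recovers both to better than 1%.
  Simulation studies of noisy recovery therefore profile one parameter at
  a time; the package's own recovery study (50 seeded replicates at the
  fixture noise) recovers `K_r2` with negligible median bias.

The validation studies shipped with the package use problem sizes chosen to
exercise these properties thoroughly at desk scale: about one hundred
randomized equilibrium/kinetic oracle comparisons (two to three ligands,
two to four binders) and fifty-replicate recovery studies.

## Known limitations

* The free hormone hypothesis is assumed throughout; megalin/cubilin
  endocytotic uptake of DBP-bound 25OHD (dominant in renal proximal
  tubules) is out of scope, as is any "bioavailable" (free plus
  albumin-bound) summary.
* CYP24A1 catabolism is not modeled; predictions describe short-horizon
  induction before catabolic feedback becomes significant.
* Activation is a pair of expression folds, not a signaling mechanism.
* Per-genotype free 1,25(OH)2D percentages for intermediate genotypes are
  interpolated (see above); predictions that depend on them inherit that
  uncertainty, about ±0.01 on the CAMP scale in the worst observed case.
* The calibration fixes albumin at its standard concentration; subjects
  with abnormal albumin need a custom `albumin_binder()` and re-calibration.
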