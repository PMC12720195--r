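---
title: "Modeling tumor microenvironment acid-base composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor microenvironment acid-base composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmeacid)
```

## The problem

Cancer cells proliferate faster than their blood supply expands, so the
interstitial fluid of a solid tumor is not plasma: oxygen is consumed
faster than it arrives and metabolic acids accumulate behind diffusion
barriers. Experimentalists who impose "tumor-like" pH or hypoxia on
cultured cells need to know which combinations of pH, CO2 and HCO3- are
physically reachable, and how they couple to oxygen. This package builds
that envelope from three models of increasing realism — a closed/gas-open
compartment, a spheroid, and a perfused Krogh cylinder — plus a classifier
for dual-stress omics responses.

## Carbonic core

All acid-base arithmetic reduces to the carbonic buffer,
$K = \mathrm{[H^+][HCO_3^-]/[CO_2]}$ with apparent $pK = 6.1$, treated as
the dominant extracellular buffer and held near equilibrium by carbonic
anhydrase (CA). Fermentation (1 glucose $\to$ 2 lactate$^-$ + 2 H$^+$)
titrates HCO3- into CO2 one-to-one, conserving total inorganic carbon
(TIC); respiration (1 glucose + 6 O2 $\to$ 6 CO2 at RQ 1) adds TIC. Closed
compartments re-equilibrate through the quadratic in the H+ shift;
gas-open compartments clamp CO2 and follow Henderson-Hasselbalch.
Concentrations are stored in mM; the equilibrium ratio is evaluated in
molar. The arterial reference is pH 7.4 / 24 mM HCO3- / 1.2 mM CO2, with
5 mM glucose and 0.13 mM free O2 (13 kPa at the 10 uM/kPa solubility that
the 13 kPa = 130 uM conversion fixes).

## Transport world

The field models share one transport parameterization:

* **Geometry**: extracellular volume fraction $v_e = 0.25$. Extracellular
  species (glucose, lactate, HCO3-, H+) diffuse only through the
  interstitium (flux per tissue area $= v_e D \nabla C$); gases (O2, CO2)
  use the whole volume.
* **Diffusivities** (um^2/s): lactate = glucose = 1000, HCO3- = 2000,
  CO2 = O2 = 2500. These are anchored at the free-solution lactate value
  and chosen so that the *effective* tissue-scale mobilities stand exactly
  in the stated ratios CO2 : HCO3- : lactate = 10 : 2 : 1 (at
  $v_e = 0.25$), with glucose = lactate and O2 = CO2. We deliberately
  prioritized these ratios over individually "textbook" per-solute values,
  because every composition prediction depends on the ratios, not the
  absolute scale: the 10:2:1 choice is what makes HCO3- depletion outpace
  CO2 accumulation 5:1 in a fermentative spheroid core.
* **Rates**: fermentation
  $J_{ferm} = J_{ferm}^{max}\,\frac{G_i}{G_i + K_G}\,
  \frac{K_{an}^h}{H_i^h + K_{an}^h}$ with $K_G = 1$ mM, $pK_{an} = 7.1$,
  $h = 2.25$ (mM lactic acid/min; glucose consumed at half this rate).
  The printed first-order form is recoverable with `hill_an = 1`; applying
  the cooperativity to the H+ term is the reading that makes "cooperativity
  2.25" meaningful. Respiration
  $J_{resp} = J_{resp}^{max}\,\frac{G_i}{G_i + K_G}\,
  \frac{O_2}{O_2 + K_{O_2}}$ with $K_{O_2} = 1$ uM (mM glucose/min; O2
  consumed and CO2 produced at 6x).
* **Membranes**: symmetric saturable carriers for glucose (GLUT-like,
  $K_m$ 1 mM) and H+-lactate (MCT, $K_m$ 2 mM lactate, 0.1 uM H+), with
  maximal rates high enough (200 and 400 mM/min) that transport is never
  rate-limiting at the swept metabolic rates; gases are pooled across
  compartments (the infinite-permeability limit). Intracellular
  non-carbonic buffering is 25 mM/pH; a small (2 mM/pH) interstitial
  buffer keeps the extracellular H+ pool well-posed and is physically
  realistic (interstitial protein and phosphate).
* **CO2 hydration**: mass-action kinetics (0.15/min uncatalyzed) with a
  1000-fold CA acceleration in both compartments. The steady states sit at
  the fast-CA asymptote: accelerating a further 10x moves the fermentative
  core pH by < 0.01. Slowing 10x is *not* symmetric — interstitial H+
  falls measurably out of carbonic equilibrium and core pHe shifts
  acidward by up to ~0.08 — so CA activity matters below roughly 100x, and
  at small radii the residual pericellular acidification (~0.03-0.05 pH at
  full fermentative rate) is the CA disequilibrium itself, not a standing
  gradient.

## Numerics

There is no ODE/PDE library in this package's dependency set; the steady
states are computed by a hand-built pseudo-transient continuation (PTC):
backward-Euler steps whose linear systems use a banded finite-difference
Jacobian (cell-major ordering; grouped perturbations, 21 residual
evaluations per Jacobian) solved sparsely with Matrix. Acceptance of a
step is *nonmonotone*: a physical relaxation trajectory can transiently
raise the steady-state residual, so steps are rejected only on blow-up,
and the pseudo-time step grows faster while the residual falls. The
tolerance is a maximum residual of 1e-8 (mM/min; H+ rows in nM/min).
Concentrations are clamped non-negative after each step, and rate laws
clamp their inputs, so transient negative excursions cannot produce
unphysical rates. The spheroid uses conservative spherical finite volumes
(Dirichlet surface via a half-cell flux; symmetry at the center); surface
influx balances volume-integrated consumption to well below 1% and core pH
converges at first order or better under grid refinement (100 shells
default).

The Krogh cylinder exploits the absence of axial diffusion in tissue:
columns at different axial positions couple only through the blood, so the
solver marches downstream (first-order upwind, 200 nodes over 2 mm),
solving each radial column (25 cylindrical finite volumes, warm-started)
to steady state against the local blood composition and advancing the
blood with the wall fluxes of the solved column — which are
tissue-limited, hence bounded, even though the wall itself is nearly
transparent. Blood is radially well-mixed and carried in conserved
variables: TIC, "buffer base" $BB = \mathrm{HCO_3^-} + \beta(pH - 7.4)$,
total O2, glucose, lactate. Closure back to (pH, CO2, HCO3) is a 1-D root
solve on the buffer line; free O2 inverts the Hill dissociation curve
(capacity 9 mM, $n = 2.7$, P50 = 3.6 kPa = 36 uM free O2 — stated in kPa;
the solubility convention fixes the molar value). The non-carbonic blood
buffering is $\beta = 10$ mM/pH: closed-form arithmetic on the venous
states (a +6 mM TIC load splitting ~2.5 mM CO2 / ~3.5 mM HCO3- at pH ~7;
a ~9 mM lactic acid load leaving ~3 mM HCO3- depletion at pH ~6.7-6.8)
pins beta near 10, whereas the whole-blood textbook value of ~25 mM/pH
reproduces neither split — plasma-plus-capillary-hematocrit buffering is
indeed below the whole-blood value. Wall permeability is 3000 um/min for
paracellular solutes and 1e5 um/min for gases; both are deliberately
non-rate-limiting (sensitivity: the gas value matters only below ~1e4,
where O2 unloading of the 9 mM hemoglobin reservoir through a <= 0.13 mM
free-O2 difference becomes wall-limited).

## pHi regulation

The Na+/H+ exchanger follows
$J_{NHE} = J_{NHE}^{max} H_i^2 / (H_i^2 + K_{NHE}^2)$ with
$K_{NHE} = 10^{-6.7}$ and $J_{NHE}^{max} = 10$ mM/min. On its own this law
has no finite operating point at steady state: lactate efflux already
carries away all fermentative H+, so an unopposed extruder alkalinizes the
cytoplasm until its flux collapses, and the HCO3- generated by
intracellular CO2 hydration would accumulate without bound. A regulated
cell in this package therefore runs the exchanger against an
alkaline-activated acid loader (Cl-/HCO3- anion exchange, exporting
HCO3-), the standard partner in cancer-cell pHi regulation. The loader's
amplitude is derived so the two fluxes cross exactly at the pHi set-point
(7.2): the pair is corrective below the set-point, restraining above it,
and its *net* acid flux vanishes once pHi is settled — which is why
switching regulation on clamps pHi near 7.2 yet changes the maximal pHe
acidification by well under 0.1 units (the residual effect is the mild
stimulation of glycolysis at the more alkaline regulated pHi).

## Synthetic proteome

The interaction classifier needs no external data: the generator emulates
a dual-stress proteomic experiment at its published scale (~9400 proteins;
class mixture 28% additive, 9% antagonistic, 6% synergistic, 57%
non-significant; measurement noise 0.2 log2 units — a typical TMT-style
replicate sd). Significant single-stress effects are signed shifted
exponentials (floor 0.7, rate 1.2), interaction deltas are signed shifted
exponentials (floor 0.75, rate 1.5), and non-significant records are
truncated normals bounded so every classification quantity stays below the
0.5 cutoff. The floors guarantee exact class recovery at zero noise; at
the default noise the misclassification is the closed-form Gaussian
leakage across the 0.5 boundaries, which the tests verify against a
binomial envelope. What a green test establishes is that the classifier
implements the cutoff rule faithfully — not that the published class
counts are recoverable: those depend on an upstream significance filter
that is not operationally defined, so this package's non-significance rule
(all of |r_acid|, |r_hypoxia|, |r_combo|, |delta| below 0.5) is an
interpretation, stated as such.

## Known limitations, and what the models honestly predict

* Under the stated 10:2:1 mobility world, 5 mM of glucose can erect at
  most ~5 mM of HCO3- depletion and ~1 mM of CO2 accumulation, which
  bounds steady fermentative acidification near pH 7.0 at a spheroid core
  (this package computes 7.09 at the default kinetics, since acid
  inhibition leaves ~1 mM glucose unconsumed) and keeps Krogh tissue
  within ~0.1 pH of the local blood (volume-averaged 6.88 fermentative,
  6.87 mixed). Deeper tissue acidification requires lower interstitial
  mobilities than those ratios permit. Venous blood chemistry, being
  delivery-limited, is insensitive to this: the fermentative venous state
  (pH ~6.76, ~9.7 mM lactate, ~4.5 mM CO2, TIC constant) and the
  respiratory one (+2.6 mM CO2, +4.3 mM HCO3-, pH ~6.97, TIC up ~7 mM)
  come out as expected.
* At strict steady state with one-way advection and no axial tissue
  diffusion, blood pH cannot recover downstream of the metabolizing
  region — there is no acid sink — so mean tissue pH decreases
  monotonically with cylinder length rather than showing an interior
  nadir; pHi/pHe trajectories still reverse toward the identity line as
  glucose depletes.
* Glucose is the only substrate; NHE aside, active H+ pumping, HIF
  dynamics, electrostatics and non-steady growth are out of scope.

## Reproducing the figure-level experiments

```r
scenario_registry()
res <- run_scenario("fig3c", "full")   # spheroid radial profiles
res$summary
```

Each scenario returns tidy tables (and writes deterministic CSV/JSON when
given an output directory); `davenport_points()` extracts (pH, CO2, HCO3)
triples whose pH is computed from the CO2/HCO3- pair, so every plotted
point lies exactly on the carbonic equilibrium surface.
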