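---
title: "The ephapse microdomain model and cluster-association pipeline"
author: "ephapse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ephapse microdomain model and cluster-association pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephapse)
```

# Why a microdomain model

Cardiac myocytes are electrically coupled by gap junctions (GJ) at their
intercalated discs (ID), but the narrow extracellular clefts between
apposed membranes provide a second, *ephaptic* pathway: sodium current
flowing into a 15-nm cleft drives the cleft potential tens of millivolts
negative, which depolarizes the membrane on the other side of the cleft
without any junctional current. Whether this pathway matters depends on two
structural quantities that `ephapse` makes explicit and manipulable: the
closeness of membrane apposition (cleft width and effective cleft
conductivity) and the local density of sodium channels (the fraction of
Na~v~1.5 placed on junctional membrane). The package implements

* a 2-D sheet of 3-D brick myocytes with separable GJ and cleft coupling,
* activation-map velocimetry (CV~L~, CV~T~, anisotropy ratio AR),
* an object-based colocalization pipeline for two-channel super-resolution
  images of Cx43 and Na~v~1.5 clusters, and
* synthetic-data generators so that each stage can be validated against
  ground truth.

# The conduction model

## Geometry

Cells are rectangular prisms, 101 x 24.1 um in the plane with the
out-of-plane depth defaulting to the cell width (the sheet is isopotential
in that direction, so depth only scales areas). Footprints interlock in a
running bond: the end face of each cell steps at `transverseOffset` (50 %)
of the width, and the two halves of the stepped face are staggered by
`longitudinalOffset` (20 %) of the length. With nonzero offsets every
interior cell's end abuts the ends of two neighbours, which is what couples
the sheet transversely: there are no lateral gap junctions, so a transverse
wavefront advances by the same end-to-end contacts as a longitudinal one,
offset by half a cell width per hop.

One consequence is worth stating plainly: interlocked stepped footprints
necessarily carry slightly more membrane than a plain brick (the step adds
`2 * longitudinalOffset * length * depth` per cell, about 9 % at the nominal
offsets). `membraneAreas()` reports the exact prism identity
`2A + P*D`, which reduces to the plain-brick surface at zero offsets.

## Electrical formulation

Within each cell the intracellular potential solves Laplace's equation,
discretized with linear triangular finite elements on the corner nodes
(6 triangles per stepped footprint, scaled by `sigmaI * depth`). Membrane
patches — the in-plane faces plus per-triangle "cap" patches for the two
out-of-plane faces — carry capacitive and ionic current between their
intracellular nodes and their extracellular node:

$$\sigma_i \nabla\phi_i \cdot \hat n =
  -C_m \frac{\partial(\phi_i - \phi_e)}{\partial t} - I_{ion}
  + g(x)\,(\phi_n - \phi_i),$$

where $g(x)$ is the gap-junction coupling to the neighbour potential
$\phi_n$ on junctional patches.

The extracellular space has two levels:

* the **in-plane cleft network** — one node per cleft segment (a maximal
  stretch of facing membrane), with conductances
  $\sigma_{eff} \, w \, D / \ell$ along the cleft; junctional (ID) segments
  use the 15-nm width with $\bar\sigma_{effj} = 17.8$ mS/cm, lateral
  segments the 0.1-um width with $\bar\sigma_{effe} = 159.1$ mS/cm. Where
  several half-segments meet at a corner the star is reduced exactly to its
  equivalent mesh (Kron reduction), so no extra unknowns are introduced.
* a **bulk interstitial node**: the cap membrane faces it, every cleft
  segment drains into it through its out-of-plane edges
  ($G = 4\sigma w \ell / D$), and it serves as the potential reference.
  This encodes a perfused-monolayer assumption. It is not cosmetic: in a
  strictly in-plane network every return path has to thread the 15-nm ID
  clefts, and the junctional conductivity then acts as a dominant series
  resistance for propagation in *any* direction, drowning the microdomain
  effects the model exists to study. With the bulk compartment the narrow
  junctional clefts remain genuine microdomains (their drainage stays two
  orders of magnitude below a lateral cleft's) while the far-field return
  current takes the physiological low-resistance route.

Both models and interventions change only conductances, so
`assembleCleftNetwork()` can re-parameterize a mesh without rebuilding it.

## Ionic model and channel placement

The model's scientific contract is directional (trends of CV and AR), not absolute
action-potential fidelity, so the ionic model is a minimal
Hodgkin-Huxley-type formulation: a fast sodium current $g_{Na} m^3 h
(V - E_{Na})$ with Ebihara-Johnson-style rate constants and an
instantaneous potassium/leak current $g_K (V - E_K)$. The interface accepts
any ionic description (a passive leak model is included for solver
verification). `partitionChannels()` distributes the cell's total sodium
conductance: a junctional fraction of 0.11 reproduces a *uniform* surface
density (the junctional share of membrane area at nominal geometry), 0.90
is the *polarized*, ID-enriched model.

Gap junctions occupy plaques, not the whole disc: interface conductance is
`gjBar * plaqueFraction * area`, with `gjBar = 100` mS/cm^2 of plaque and
`plaqueFraction = 0.4`-ish disc coverage values reported for ventricular
myocardium; the default here is 0.3. This separation matters: with the
whole disc conducting, the GJ route is so strong that cleft drainage acts
purely as a series resistance and raising $\bar\sigma_{effj}$ (edema)
*speeds* conduction in both models; at plaque-scale coupling the polarized
model's transfer leans on the ephapse and edema slows it, which is the
directionality the model family was calibrated to reproduce.

## Calibration

As in the tradition of this model family, $g_{Na}$, $g_K$ and the coupling
scale were calibrated so that the polarized model reproduces the
experimental directionality under control and edema: control conducts in
both directions; raising both effective conductivities to their edema
values slows conduction, transversely more than longitudinally, raising
AR; the uniform model's CV~L~ is non-decreasing under the same change; and
GJ uncoupling or sodium-channel inhibition slows conduction in both
models. The defaults that meet these conditions on the 20 x 10 sweep sheet
are `gNa = 90` mS/cm^2 (average over the whole membrane; about
760 mS/cm^2 junctional density in the polarized model, consistent with the
several-fold ID enrichment reported for Na~v~1.5), `gK = 0.45` mS/cm^2,
`sigmaI = 6.7` mS/cm, `Cm = 1` uF/cm^2.

## Time stepping and numerics

* Crank-Nicolson on all conductive/capacitive terms; the ionic current is
  evaluated at the start-of-step voltage with gating frozen within the step
  (advanced between steps by exponential Rush-Larsen updates, which are the
  exact gate solution at frozen voltage). The system matrix is therefore
  constant and its sparse Cholesky factorization is computed once per
  assembly and reused for every step and for both pacing directions.
* `dt = 0.005` ms by default; the acceptance suite verifies that halving
  `dt` changes CV by under 2 %.
* The gauge is fixed by clamping the bulk interstitial node to 0 mV.
  Stimuli are transmembrane current pulses (1 ms, 150 uA/cm^2 over the
  stimulated edge cells), so charge is conserved exactly and no spurious
  current flows through the gauge.
* Degenerate inputs: a 1 x 1 sheet has no junctions (all membrane lateral);
  conduction block is detected (distal cells never depolarizing) and
  flagged on the sweep row rather than raising an error.

## Velocimetry

Activation time is the time of the maximum first derivative of the
upstroke (central differences, ties broken earliest, optional quadratic
sub-sample refinement — needed because a transverse hop takes only a few
time steps). For simulated sheets, CV is the inverse slope of the
least-squares fit of cell activation time against the cell-centre
coordinate along the propagation axis, trimming two columns/rows at the
stimulated and far edges. For camera-grid activation maps (90 x 60 sites,
16.5 x 12 mm by default), `computeCV()` fits the on-axis site rays through
the pacing origin, excluding a two-site near-field ring; the window is
configurable because the spatial extent used for experimental fits is a
free choice.

# The cluster-association pipeline

Each channel is thresholded by Otsu's method (exact histogram recursion;
the reported threshold is the midpoint between the best split level and the
next occupied level, so it falls strictly between the two classes).
Clusters are maximal connected components, 8-connected by default to match
the usual component-labeling convention for punctate immunosignal
(4-connectivity is available). Centroids are unweighted pixel means; sizes
are reported as equivalent circular diameters from calibrated areas —
whether a reported "cluster size" means equivalent diameter or a caliper
length is usually ambiguous, and this choice is the one that yields a comparable
length scale.

Association is object-based. A Na~v~1.5 cluster *overlaps* a Cx43 cluster
if they share a pixel; it is *perinexal* to it if disjoint but within the
perinexal width (default 200 nm, the extent of the perinexus from the GJ
plaque edge) measured **edge to edge**: the number of empty pixels
separating the clusters (minimum pixel-centre distance minus one pixel)
times the pixel size. Classification against the whole Cx43 mask uses its
Euclidean distance transform; per-pair partner counts use boundary-pixel
distances with bounding-box pruning. Each Na~v~1.5 cluster gets its best
class (overlap > perinexal > distal); partners are counted independently
per Cx43 cluster, so one Na~v~1.5 cluster may appear in several Cx43
clusters' counts — reported per-panel statistics rarely state how such
cases are de-duplicated, and this is the conservative reading. Distances
exactly at the perinexal width count as perinexal (ties included).

Z-stacks are analyzed per slice and pooled; no 3-D linkage is attempted.

# Synthetic data: what it does and does not emulate

`simulateLocalizationImages()` renders elliptical clusters (equivalent
diameter preserved under the random eccentricity) on a jittered exclusion
grid, so that the Na~v~1.5 clusters placed for one Cx43 site cannot
interact with another site. Blur is Gaussian with sigma = FWHM/2.355
(22 nm emulates the gSTED point-spread function at 10 nm sampling) and
noise is additive Gaussian. The generator records both the intended and the
post-rasterization realized edge-to-edge distance (on the unblurred masks,
same convention as the analysis), plus the class that distance implies —
so "ground-truth recovery" asserts agreement with what was actually drawn,
while rasterization itself is exercised rather than assumed. It does *not*
emulate STED photophysics, sarcolemmal background staining, chromatic
offsets or deconvolution artifacts; a pass on these images validates the
measurement chain, not the biology of real micrographs.

`simulateActivationMap()` produces the analytic elliptical field
$t = \sqrt{(x/v_L)^2 + (y/v_T)^2}$ with optional Gaussian time noise;
`simulateUpstroke()` produces sigmoidal upstrokes whose inflection is the
true activation time. All generators are bit-deterministic per seed.

# Problem sizes used by the test-suite and acceptance script

Intervention predictions are evaluated on a 20 x 10 cell sheet (the
default), the size at which the on-axis CV fits are stable while a full
two-model, five-condition table remains a desk-scale computation; solver
physics checks use 10 x 5 and single-cell meshes; image-pipeline checks use
1000-1200 px fields with 6-9 Cx43 sites and 20 seeds for the blurred
condition.

# Known limitations

* **AR rigidity under coupling changes.** In the interlocking tiling every
  junctional contact joins cells of adjacent half-width rows, so
  longitudinal and transverse propagation traverse the *same* sequence of
  end-to-end hops, only projected onto different axes. Any intervention
  that rescales junctional transfer uniformly (GJ uncoupling, sodium
  inhibition) therefore moves CV~L~ and CV~T~ almost proportionally and
  leaves AR nearly unchanged (about 8.4 at defaults, set by the hop
  geometry); AR reacts mainly where a model approaches conduction failure.
  Edema does shift AR (its junctional-conductivity component hits the
  single-interface transverse hop harder), but experimentally AR also
  rises under GJ uncoupling alone, and in this model family the AR-g~Na~
  relation steepens under uncoupling in the polarized model — responses
  this geometry reproduces only weakly or not at all. A geometry whose
  transverse coupling runs through dedicated small corner contacts,
  distinct from the main in-fiber end faces, would likely be needed; the
  interlocking pattern implemented here is one of several consistent with
  a brick sheet with corner inclusions.
* Absolute velocities are not the contract (the model family is tuned to
  trends); the anisotropy ratio of this tiling is well above the
  experimental ~2 because geometry alone fixes it.
* The ionic model has no calcium dynamics, no use-dependent drug block and
  no repolarization fidelity; sodium-channel inhibition is a pure
  conductance scale (0.86).
* The bulk interstitial compartment assumes a well-perfused monolayer;
  mid-wall tissue with confined interstitium would need the in-plane
  network re-derived with stacked sheets.
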