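# ephapse

Cardiac conduction depends not only on gap junctions (GJ) but potentially
also on *ephaptic* coupling: sodium current discharging into the very
narrow extracellular clefts of the intercalated disc (ID) — in particular
the **perinexus**, the ~200 nm microdomain around the Cx43 GJ plaque where
Na<sub>v</sub>1.5 is enriched and intermembrane spacing is ~10 nm — can
depolarize the apposed membrane without any junctional current. `ephapse`
packages the two computational halves of that hypothesis:

1. **A microdomain conduction model.** A 2-D sheet of 3-D brick myocytes
   with interlocking ends, linear-FEM intracellular domains, an explicit
   extracellular cleft network (junctional width 15 nm, effective
   conductivity σ̄<sub>effj</sub> = 17.8 mS/cm; lateral width 0.1 µm,
   σ̄<sub>effe</sub> = 159.1 mS/cm), end-to-end GJ coupling
   (ḡ<sub>j</sub> = 100 mS/cm² of plaque), and a Hodgkin–Huxley-type fast
   sodium / potassium-leak membrane whose sodium conductance can be placed
   uniformly (11 % at the ID) or polarized to the disc (90 %). The coupled
   system

   σ<sub>i</sub>∇φ<sub>i</sub>·n̂ = −C<sub>m</sub> ∂(φ<sub>i</sub>−φ<sub>e</sub>)/∂t − I<sub>ion</sub> + g(x)(φ<sub>n</sub>−φ<sub>i</sub>),  ∇²φ<sub>i</sub> = 0 in each cell

   is advanced by Crank–Nicolson steps with a cached sparse factorization.
   Named interventions reproduce the standard experimental manipulations:
   acute interstitial edema (AIE: σ̄<sub>effe</sub> → 203.5,
   σ̄<sub>effj</sub> → 62.8 mS/cm), GJ uncoupling (ḡ<sub>j</sub> → 50),
   and sodium-channel inhibition (g<sub>Na</sub> × 0.86).

2. **A cluster-association pipeline** for two-channel super-resolution
   micrographs: Otsu thresholding, 8-connected component labeling,
   calibrated centroids/areas/equivalent diameters, and object-based
   classification of every Na<sub>v</sub>1.5 cluster as *overlapping*,
   *perinexal* (edge-to-edge ≤ 200 nm) or *distal* relative to the Cx43
   clusters, with per-Cx43 partner-count histograms.

Synthetic-data generators (gSTED-like cluster images with known classes and
distances, analytic elliptical activation maps, sigmoidal upstrokes) make
every stage testable against ground truth without external data.

## Worked example

Conduction velocity and anisotropy of the polarized model under control and
edema on the default 20 × 10 sheet:

```r
library(ephapse)

ctrl <- modelConfig(junctionalFraction = channelDistribution("polarized"))
simulateCV(ctrl)
#> CVResult: CV_L 44.82 cm/s, CV_T 5.35 cm/s, AR 8.379

simulateCV(applyInterventions(ctrl, "AIE"))
#> CVResult: CV_L 32.31 cm/s, CV_T 3.81 cm/s, AR 8.474
```

Edema slows conduction in the polarized model — transversely slightly more
than longitudinally, so the anisotropy ratio rises — because raising the
junctional cleft conductivity drains the 15-nm ID cleft and weakens the
ephaptic transfer the polarized model leans on. The uniform model shows no
such slowing (its CV_L is flat to rising under the same change).

Cluster association on a synthetic gSTED-like field:

```r
img <- simulateLocalizationImages(nCx = 9, overlapPerCx = 1,
                                  perinexalPerCx = 1, distalPerCx = 1,
                                  imageSize = c(1200, 1200), seed = 42)
associateClusters(findClusters(img$cx43), findClusters(img$nav))
#> AssociationReport: 27 Nav1.5 vs 9 Cx43 clusters (perinexal width 200 nm)
#>   Nav1.5: 33.3% overlapping, 33.3% perinexal, 33.3% distal
#>   Cx43: 100.0% with overlapping, 100.0% with perinexal partners
```

Velocimetry on an analytic activation map (90 × 60 sites, 16.5 × 12 mm):

```r
m <- simulateActivationMap(vL = 60, vT = 30)
computeCV(m$map)
#> CVResult: CV_L 60.00 cm/s, CV_T 30.00 cm/s, AR 2.000
```

A thin command-line wrapper for simulation, sweeps and image analysis is
installed at `inst/scripts/ephapse-cli.R`.

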